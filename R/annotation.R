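# IUPAC monoisotopic masses (Da); carbon-12 is exact by definition
.elementMasses <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Si = 27.9769265325, Se = 79.9165213, B = 11.0093054, Fe = 55.9349375,
  Li = 7.01600455, Mg = 23.9850417, Ca = 39.96259098, Zn = 63.9291422
)
.electronMass <- 0.00054857990946
.protonMass <- .elementMasses[["H"]] - .electronMass
.waterMass <- 2 * .elementMasses[["H"]] + .elementMasses[["O"]]

#' Monoisotopic mass constants
#'
#' @return Named list with the element monoisotopic mass table (Da) and the
#'   electron, proton and water masses used in the adduct calculus.
#' @export
massConstants <- function() {
  list(elements = .elementMasses, electron = .electronMass,
       proton = .protonMass, water = .waterMass)
}

#' Monoisotopic mass of an elemental formula
#'
#' Parses element-count pairs (e.g. `"C6H13NO5"`) and sums element
#' monoisotopic masses times counts. An empty formula has mass 0; unknown
#' element symbols are an error.
#'
#' @param formula character vector of formulas.
#' @return Numeric monoisotopic mass(es) in Da.
#' @export
monoisotopicMass <- function(formula) {
  vapply(as.character(formula), function(f) {
    f <- gsub("\\s", "", f)
    if (!nchar(f)) return(0)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (sum(nchar(toks)) != nchar(f))
      stop("cannot parse formula: ", f)
    total <- 0
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.elementMasses))
        stop("unknown element symbol '", el, "' in formula ", f)
      total <- total + .elementMasses[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Built-in electrospray adduct table
#'
#' Mass deltas include the electron correction per unit charge (one
#' electron subtracted per positive charge, added per negative charge).
#'
#' @param polarity `"positive"`, `"negative"` or `"both"`.
#' @param multiCharge include multiply charged adducts (lipid search).
#' @return `data.frame` with `name`, `charge` and `massDelta` (Da).
#' @export
defaultAdducts <- function(polarity = c("both", "positive", "negative"),
                           multiCharge = TRUE) {
  polarity <- match.arg(polarity)
  H <- .elementMasses[["H"]]; e <- .electronMass
  Na <- .elementMasses[["Na"]]; K <- .elementMasses[["K"]]
  W <- .waterMass
  tab <- rbind(
    data.frame(name = "[M+H]+",      charge = 1L,  massDelta = H - e),
    data.frame(name = "[M+Na]+",     charge = 1L,  massDelta = Na - e),
    data.frame(name = "[M+K]+",      charge = 1L,  massDelta = K - e),
    data.frame(name = "[M+H-H2O]+",  charge = 1L,  massDelta = H - W - e),
    data.frame(name = "[M+2Na]2+",   charge = 2L,  massDelta = 2 * (Na - e)),
    data.frame(name = "[M+2H]2+",    charge = 2L,  massDelta = 2 * (H - e)),
    data.frame(name = "[M-H]-",      charge = -1L, massDelta = -(H - e)),
    data.frame(name = "[M-H-H2O]-",  charge = -1L, massDelta = -(H - e) - W)
  )
  if (polarity == "positive") tab <- tab[tab$charge > 0, ]
  if (polarity == "negative") tab <- tab[tab$charge < 0, ]
  if (!multiCharge) tab <- tab[abs(tab$charge) == 1L, ]
  rownames(tab) <- NULL
  tab
}

#' Theoretical adduct m/z
#'
#' m/z = (M + massDelta) / |charge|, with the electron correction already
#' folded into the adduct's mass delta.
#'
#' @param M neutral monoisotopic mass (Da), > 0 (0 is allowed for the
#'   degenerate bare-proton check).
#' @param adduct an adduct name (looked up in [defaultAdducts()]) or a
#'   one-row `data.frame` with `charge` and `massDelta`.
#' @return m/z in Th.
#' @export
adductMz <- function(M, adduct) {
  if (is.character(adduct)) {
    tab <- defaultAdducts()
    row <- tab[tab$name == adduct, ]
    if (!nrow(row)) stop("unknown adduct: ", adduct)
    adduct <- row
  }
  if (adduct$charge == 0) stop("adduct charge must be non-zero")
  (M + adduct$massDelta) / abs(adduct$charge)
}

#' Signed mass error in ppm
#'
#' `(measured - theoretical) / theoretical * 1e6`.
#'
#' @param measured,theoretical m/z values (Th); theoretical must be > 0.
#' @return Signed ppm error.
#' @export
ppmError <- function(measured, theoretical) {
  stopifnot(all(theoretical > 0))
  (measured - theoretical) / theoretical * 1e6
}

#' Read a local compound table
#'
#' CSV with columns `name` and `formula` and/or `monoisotopic_mass`
#' (an optional `class` column is carried through). Masses are computed
#' from formulas where absent.
#'
#' @param path CSV path.
#' @return `data.frame` with `name`, `formula`, `monoisotopicMass`, `class`.
#' @export
readCompoundTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  names(tab) <- sub("^monoisotopic_mass$", "monoisotopicMass", names(tab))
  if (!"name" %in% names(tab)) stop("compound table needs a 'name' column")
  if (!"monoisotopicMass" %in% names(tab)) tab$monoisotopicMass <- NA_real_
  if (!"formula" %in% names(tab)) tab$formula <- NA_character_
  miss <- is.na(tab$monoisotopicMass)
  if (any(miss)) {
    if (any(is.na(tab$formula[miss])))
      stop("compounds without formula or mass: ",
           paste(tab$name[miss & is.na(tab$formula)], collapse = ", "))
    tab$monoisotopicMass[miss] <- monoisotopicMass(tab$formula[miss])
  }
  if (!"class" %in% names(tab)) tab$class <- NA_character_
  tab
}

#' The bundled dried-milk-spot compound table
#'
#' Small local compound table covering the discriminative-ion annotations
#' of the lameness study (formulas and monoisotopic masses), used in place
#' of live metabolome-database queries.
#'
#' @return `data.frame` as from [readCompoundTable()].
#' @export
bundledCompoundTable <- function() {
  readCompoundTable(system.file("extdata", "compounds_lameness.csv",
                                package = "milkDIMS", mustWork = TRUE))
}

#' Annotate measured m/z values against a compound table
#'
#' All (compound, adduct) pairs whose theoretical m/z falls within the
#' tolerance of a measured m/z are reported, sorted by absolute ppm error
#' within each query. The tolerance is 5 ppm by default; an absolute m/z
#' tolerance (`tolMz`, e.g. 0.001 for lipid search) takes precedence when
#' given.
#'
#' @param measuredMz numeric vector of measured m/z values.
#' @param compounds compound `data.frame` (see [readCompoundTable()]);
#'   default the bundled table.
#' @param adducts adduct `data.frame` (see [defaultAdducts()]).
#' @param tolPpm ppm tolerance (default 5).
#' @param tolMz absolute m/z tolerance; overrides `tolPpm` when non-NULL.
#' @return `data.frame` of annotation hits: measured m/z, compound, adduct,
#'   theoretical m/z, signed and absolute ppm error.
#' @export
annotate <- function(measuredMz, compounds = bundledCompoundTable(),
                     adducts = defaultAdducts(), tolPpm = 5, tolMz = NULL) {
  stopifnot(nrow(adducts) >= 1)
  hits <- list()
  for (mz in measuredMz) {
    for (ci in seq_len(nrow(compounds))) {
      M <- compounds$monoisotopicMass[ci]
      for (ai in seq_len(nrow(adducts))) {
        theo <- adductMz(M, adducts[ai, ])
        err <- ppmError(mz, theo)
        ok <- if (!is.null(tolMz)) abs(mz - theo) <= tolMz
              else abs(err) <= tolPpm
        if (ok)
          hits[[length(hits) + 1L]] <- data.frame(
            measuredMz = mz, compound = compounds$name[ci],
            formula = compounds$formula[ci], monoisotopicMass = M,
            adduct = adducts$name[ai], theoreticalMz = theo,
            ppmError = err, absPpmError = abs(err),
            class = compounds$class[ci])
      }
    }
  }
  if (!length(hits))
    return(data.frame(measuredMz = numeric(0), compound = character(0),
                      formula = character(0), monoisotopicMass = numeric(0),
                      adduct = character(0), theoreticalMz = numeric(0),
                      ppmError = numeric(0), absPpmError = numeric(0),
                      class = character(0)))
  out <- do.call(rbind, hits)
  out[order(match(out$measuredMz, measuredMz), out$absPpmError), ]
}
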