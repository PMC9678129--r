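# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# ppm deviation of x from ref
ppmDev <- function(x, ref) (x - ref) / ref * 1e6

# run code under a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed and a stage offset, kept < 2^31
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# binary class labels -> 0/1 numeric; first factor level (or sorted unique
# value) is the reference (control) class coded 0
codeLabels <- function(y) {
  f <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(f) != 2L)
    stop("exactly two classes required, got: ",
         paste(levels(f), collapse = ", "))
  list(y01 = as.numeric(f) - 1, levels = levels(f), factor = f)
}

# FNV-1a 32-bit hash of a character string, as hex; used to stamp outputs.
# Arithmetic stays in doubles (bitwXor() cannot take values >= 2^31); the
# xor only ever touches the low byte because input bytes are < 256.
fnv1aHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lb <- h %% 256
    h <- h - lb + bitwXor(as.integer(lb), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# glmnet's small-class advisory fires constantly at n = 21 and drowns out
# real warnings; the sample size is a design property here, not a surprise
quietGlmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8|grouped=FALSE enforced", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# extract the numeric samples x features matrix from a FeatureSet or pass
# a plain matrix through
asSampleMatrix <- function(x) {
  if (is(x, "FeatureSet")) return(t(SummarizedExperiment::assay(x, "intensity")))
  as.matrix(x)
}
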