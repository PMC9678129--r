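#' Pipeline configuration
#'
#' Versioned defaults for the full workflow, matching the study's stated
#' settings: intensity threshold 100 000, 5 ppm alignment window, >20%
#' missingness filter, knn k = 10, TIC + log + Pareto preprocessing,
#' OPLS-DA with 1 predictive + 1 orthogonal component, VIP > 1, p < 0.05,
#' q < 0.05, top-10 ML importance lists, and 500/20/50 stability counts.
#'
#' @param outputDir directory for stage outputs.
#' @param seed global seed; every stage derives its RNG stream from it.
#' @param ... named overrides for any nested section (`simulate`, `paths`,
#'   `extraction`, `preprocessing`, `chemometrics`, `ml`, `stability`,
#'   `selection`, `annotation`), each a list merged over the defaults.
#' @return Nested list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outputDir = "milkdims_output", seed = 1, ...) {
  cfg <- list(
    version = "1",
    outputDir = outputDir,
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, nEffects = 10, log2FoldChange = 1.5,
                    design = list()),
    paths = list(metadata = NULL, compoundTable = NULL),
    extraction = list(intensityThreshold = 1e5, ppmWindow = 5,
                      maxMissingFrac = 0.2, k = 10),
    preprocessing = list(ticNormalize = TRUE, logTransform = TRUE,
                         paretoScale = TRUE, offset = 1),
    chemometrics = list(nPcaComponents = 6, nOrthogonal = 1, nPerm = 20),
    ml = list(topK = 10, nRepeats = 20, rfeNested = TRUE,
              rf = list(ntree = 500), enet = list(alpha = 0.5),
              svm = list(cost = 1), pls = list(nComp = 2)),
    stability = list(nBoot = 500, nPerm = 20, nPermBoot = 50,
                     alpha = 0.5, mcpGamma = 3, pCut = 0.05),
    selection = list(vipCut = 1, pCut = 0.05, qCut = 0.05),
    annotation = list(tolPpm = 5, polarityAdducts = TRUE)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the [pipelineConfig()] defaults.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig,
          c(y[intersect(names(y), c("outputDir", "seed"))],
            y[setdiff(names(y), c("outputDir", "seed", "version"))]))
}

configHash <- function(config) fnv1aHash(yaml::as.yaml(unclass(config)))

writeStamped <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# milkDIMS config %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

# deterministic planted-effect layout: evenly spread over both polarities,
# alternating direction
defaultEffects <- function(nEffects, nFeaturesPerPolarity, log2FoldChange) {
  if (nEffects < 1) return(NULL)
  nPos <- ceiling(nEffects / 2)
  nNeg <- nEffects - nPos
  idx <- c(round(seq(0.1, 0.9, length.out = nPos) * nFeaturesPerPolarity),
           nFeaturesPerPolarity +
             round(seq(0.15, 0.85, length.out = max(nNeg, 1)) *
                     nFeaturesPerPolarity)[seq_len(nNeg)])
  do.call(rbind, lapply(seq_along(idx), function(i)
    effectSpec(idx[i], if (i %% 2) "up" else "down", log2FoldChange)))
}

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full workflow
#'
#' Executes simulate/load, feature extraction, chemometrics (PCA on all
#' observations including QCs; OPLS-DA, LOOCV Q2, permutation test,
#' t-test + FDR and discriminative-ion selection on the first-day study
#' cows), machine-learning triangulation, stability selection over the
#' three penalised models, and adduct annotation of the selected ions.
#' All stage tables are written to the output directory with a config-hash
#' header line; identical config and seed give byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return A `RunReport` list with every stage's objects and tables.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  hash <- configHash(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs -------------------------------------------------------
  if (!isTRUE(config$simulate$enabled)) {
    md <- config$paths$metadata
    if (is.null(md) || !file.exists(md))
      stop("metadata file not found: ", md %||% "<unset>")
  }
  study <- runStage("simulate", {
    if (isTRUE(config$simulate$enabled)) {
      design <- do.call(studyDesign,
                        utils::modifyList(config$simulate$design,
                                          list(seed = config$seed)))
      effects <- defaultEffects(config$simulate$nEffects,
                                design@nFeaturesPerPolarity,
                                config$simulate$log2FoldChange)
      generateStudy(design, effects)
    } else {
      md <- read.csv(config$paths$metadata, stringsAsFactors = FALSE,
                     comment.char = "#")
      pls <- list()
      for (i in seq_len(nrow(md))) {
        pls[[paste(md$sample_id[i], md$polarity[i], sep = "_")]] <-
          loadPeakList(md$file[i], md$sample_id[i], md$polarity[i],
                       md$day[i])
      }
      list(peakLists = pls, samples = md, truth = NULL)
    }
  })
  meta <- study$samples

  # ---- feature extraction -------------------------------------------
  fused <- runStage("extract", {
    ex <- config$extraction
    perPol <- list()
    for (pol in unique(meta$polarity)) {
      rows <- which(meta$polarity == pol)
      pls <- lapply(rows, function(i) {
        key <- paste(meta$sample_id[i], pol, sep = "_")
        thresholdPeaks(study$peakLists[[key]], ex$intensityThreshold)
      })
      fm <- alignFeatures(pls, ex$ppmWindow)
      fm <- filterMissing(fm, ex$maxMissingFrac)
      perPol[[pol]] <- knnImpute(fm, ex$k)
    }
    if (length(perPol) == 2L)
      fusePolarities(perPol$positive, perPol$negative)
    else perPol[[1]]
  })
  writeFeatureSet(fused, file.path(config$outputDir, "feature_matrix.csv"))

  sampleMeta <- unique(meta[meta$polarity == meta$polarity[1],
                            c("sample_id", "cow_id", "class", "day", "role")])
  sampleMeta <- sampleMeta[match(colnames(fused), sampleMeta$sample_id), ]
  X <- asSampleMatrix(fused)

  day1 <- min(sampleMeta$day)
  studyIdx <- which(sampleMeta$role == "study" & sampleMeta$day == day1)
  yStudy <- factor(sampleMeta$class[studyIdx], levels = c("control", "lame"))
  Xstudy <- X[studyIdx, , drop = FALSE]

  # ---- chemometrics -------------------------------------------------
  chem <- runStage("chemometrics", {
    pp <- config$preprocessing
    spec <- preprocessSpec(pp$ticNormalize, pp$logTransform, pp$paretoScale,
                           pp$offset)
    Xall <- preprocessMatrix(X, spec)
    pca <- pcaModel(Xall, config$chemometrics$nPcaComponents)
    Xs <- preprocessMatrix(Xstudy, spec)
    opls <- fitOplsDa(Xs, yStudy, config$chemometrics$nOrthogonal)
    q2 <- loocvQ2(Xstudy, yStudy, config$chemometrics$nOrthogonal, spec)
    perm <- oplsPermutationTest(Xstudy, yStudy,
                                config$chemometrics$nOrthogonal,
                                nPerm = config$chemometrics$nPerm,
                                seed = deriveSeed(config$seed, 21),
                                spec = spec)
    uni <- tTestFdr(Xs, yStudy)
    sel <- selectDiscriminative(opls, uni, config$selection$vipCut,
                                config$selection$pCut, config$selection$qCut)
    roc <- lapply(names(sel), function(f)
      univariateRoc(Xs[, f], yStudy))
    names(roc) <- names(sel)
    list(prepSpec = spec, pca = pca, opls = opls, q2 = q2, perm = perm,
         uni = uni, selected = sel, roc = roc, Xs = Xs)
  })
  writeStamped(data.frame(sample = rownames(chem$pca$scores),
                          day = sampleMeta$day, role = sampleMeta$role,
                          chem$pca$scores, check.names = FALSE),
               file.path(config$outputDir, "pca_scores.csv"), hash)
  writeStamped(data.frame(feature = colnames(X), vip = vipScores(chem$opls),
                          splotStats(chem$opls), chem$uni,
                          selected = seq_len(ncol(X)) %in% chem$selected),
               file.path(config$outputDir, "chemometrics.csv"), hash)
  if (length(chem$roc))
    writeStamped(do.call(rbind, lapply(names(chem$roc), function(f)
      data.frame(feature = f, auc = chem$roc[[f]]$auc,
                 youdenThreshold = chem$roc[[f]]$youden[["threshold"]],
                 sensitivity = chem$roc[[f]]$youden[["sensitivity"]],
                 specificity = chem$roc[[f]]$youden[["specificity"]]))),
      file.path(config$outputDir, "roc_selected.csv"), hash)

  conventional <- names(chem$selected)

  # ---- machine-learning triangulation -------------------------------
  ml <- runStage("ml", {
    kinds <- c("random_forest", "elastic_net", "pls_da", "svm")
    hyper <- list(random_forest = config$ml$rf, elastic_net = config$ml$enet,
                  pls_da = config$ml$pls, svm = config$ml$svm)
    specs <- lapply(kinds, function(k)
      mlSpec(k, hyper = hyper[[k]], nRepeats = config$ml$nRepeats,
             seed = deriveSeed(config$seed, match(k, kinds))))
    names(specs) <- kinds
    curves <- lapply(specs, function(s)
      rfe(Xstudy, yStudy, s, nested = config$ml$rfeNested))
    topk <- lapply(specs, function(s)
      importanceTopk(Xstudy, yStudy, s, config$ml$topK))
    tri <- triangulate(conventional, topk)
    list(specs = specs, curves = curves, topk = topk, triangulation = tri)
  })
  for (k in names(ml$curves))
    writeStamped(data.frame(size = ml$curves[[k]]@sizes,
                            accuracy = ml$curves[[k]]@accuracy),
                 file.path(config$outputDir,
                           sprintf("rfe_accuracy_%s.csv", k)), hash)
  writeStamped(do.call(rbind, lapply(names(ml$topk), function(k)
    data.frame(model = k, rank = seq_along(ml$topk[[k]]),
               feature = ml$topk[[k]]))),
    file.path(config$outputDir, "ml_topk.csv"), hash)
  writeStamped(ml$triangulation,
               file.path(config$outputDir, "triangulation.csv"), hash)

  # ---- stability selection ------------------------------------------
  stab <- runStage("stability", {
    Xsd <- standardizeMatrix(Xstudy)
    st <- config$stability
    out <- list()
    for (pen in c("elastic_net", "lasso", "mcp")) {
      spec <- penalisedSpec(pen, alpha = st$alpha, mcpGamma = st$mcpGamma,
                            seed = deriveSeed(config$seed, 31))
      res <- stabilityScores(Xsd, yStudy, spec, nBoot = st$nBoot,
                             seed = deriveSeed(config$seed, 41))
      res@threshold <- permutationThreshold(Xsd, yStudy, spec,
                                            nPerm = st$nPerm,
                                            nPermBoot = st$nPermBoot,
                                            seed = deriveSeed(config$seed, 51))
      res@nPermutations <- as.integer(st$nPerm)
      res@nPermutationBootstraps <- as.integer(st$nPermBoot)
      out[[pen]] <- res
    }
    out
  })
  for (pen in names(stab))
    writeStamped(stabilityTable(stab[[pen]], pCut = config$stability$pCut),
                 file.path(config$outputDir,
                           sprintf("stability_%s.csv", pen)), hash)
  writeStamped(data.frame(penalty = names(stab),
                          threshold = vapply(stab, slot, numeric(1),
                                             "threshold"),
                          nBootstraps = vapply(stab, slot, integer(1),
                                               "nBootstraps")),
               file.path(config$outputDir, "stability_thresholds.csv"), hash)

  # ---- annotation ---------------------------------------------------
  ann <- runStage("annotation", {
    stable <- unique(unlist(lapply(stab, selectStable,
                                   pCut = config$stability$pCut)))
    targets <- union(conventional, stable)
    if (!length(targets)) return(NULL)
    mzTab <- SummarizedExperiment::rowData(fused)
    idx <- match(targets, rownames(fused))
    compounds <- if (is.null(config$paths$compoundTable))
      bundledCompoundTable() else readCompoundTable(config$paths$compoundTable)
    hitList <- lapply(seq_along(targets), function(i) {
      pol <- mzTab$polarity[idx[i]]
      add <- if (isTRUE(config$annotation$polarityAdducts))
        defaultAdducts(pol) else defaultAdducts("both")
      h <- annotate(mzTab$mz[idx[i]], compounds, add,
                    tolPpm = config$annotation$tolPpm)
      if (nrow(h)) cbind(feature = targets[i], h) else NULL
    })
    hits <- do.call(rbind, hitList)
    list(targets = targets, hits = hits)
  })
  if (!is.null(ann$hits))
    writeStamped(ann$hits, file.path(config$outputDir, "annotation.csv"),
                 hash)

  report <- list(config = config, configHash = hash, samples = sampleMeta,
                 featureSet = fused, truth = study$truth, chem = chem,
                 ml = ml, stability = stab, annotation = ann,
                 studyIdx = studyIdx, y = yStudy)
  class(report) <- "RunReport"
  report
}

#' Summarise the final candidate selection
#'
#' Ranks the conventionally selected features by elastic-net stability
#' score, then ML consensus count, then VIP; flags model-dependent
#' features; and designates the strongest candidate: the highest-stability
#' feature that also ranks in the top 2 of every ML model's importance
#' list.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @return `data.frame` of candidates (possibly empty, with a `note`
#'   attribute explaining why).
#' @export
summarizeSelection <- function(report) {
  stopifnot(inherits(report, "RunReport"))
  conv <- names(report$chem$selected)
  if (!length(conv)) {
    out <- data.frame(feature = character(0))
    attr(out, "note") <- "no feature passed the VIP/p/q gates"
    return(out)
  }
  tri <- report$ml$triangulation
  enet <- report$stability$elastic_net
  stabScore <- enet@stabilityScore[match(conv, enet@featureNames)]
  vip <- vipScores(report$chem$opls)[match(conv,
                                           colnames(asSampleMatrix(report$featureSet)))]
  top2all <- vapply(conv, function(f)
    all(vapply(report$ml$topk, function(tk)
      !is.na(match(f, tk)) && match(f, tk) <= 2, logical(1))), logical(1))
  out <- data.frame(feature = conv, stabilityScore = stabScore,
                    consensusCount = tri$consensusCount[match(conv, tri$feature)],
                    vip = vip,
                    modelDependent = tri$modelDependent[match(conv, tri$feature)],
                    top2AllModels = top2all)
  out <- out[order(-out$stabilityScore, -out$consensusCount, -out$vip), ]
  strongest <- out$feature[out$top2AllModels &
                             out$stabilityScore == max(out$stabilityScore)]
  out$strongestCandidate <- out$feature %in% strongest[1]
  rownames(out) <- NULL
  out
}
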