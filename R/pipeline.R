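# Staged, manifest-tracked pipeline:
# synth -> split -> [augment] -> extract {lbp,hog,deep} (deep after
# train_backbone) -> fuse -> train_svm -> evaluate.
# Every stage writes a manifest (stage, config hash, seed, package version,
# counts, elapsed seconds) beside its outputs; fuse refuses inputs whose
# config hashes disagree.

#' Default pipeline configuration
#'
#' A plain named list mirroring the module configurations, serializable as
#' YAML or JSON. \code{features} names the feature kinds to extract;
#' \code{fuse} the ordered pair to stack; \code{classify$features} the
#' table the SVM is fit on. The descriptor sides default to the study
#' geometry (LBP 512, HOG 256); \code{synth} and \code{backbone} default
#' to desk-scale sizes appropriate for a single CPU.
#'
#' @return a named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    synth = list(nPerClass = 20L, imageSide = 256L, shapeSeparation = 0.8,
                 textureSeparation = 0.8, noiseSd = 5, views = "upper",
                 classes = c("D_gigas", "I_argentinus", "E_luminosa",
                             "O_bartramii")),
    split = list(testFrac = 0.2, valFracOfRest = 0.2),
    augment = list(enabled = FALSE, pFlip = 0.5,
                   rotationRangeDeg = c(-45, 45), cropFracRange = c(0.7, 1),
                   aspectRange = c(0.8, 1.25), nPerImage = 1L),
    lbp = list(R = 1, P = 8L, gridN = 1L, side = 256L),
    hog = list(cellPx = 32L, side = 256L),
    backbone = list(profile = "deskSmall", inputSide = 48L, pooledDim = 64L,
                    epochs = 14L, batchSize = 8L),
    svm = list(C = 10, standardize = TRUE),
    features = c("hog", "deep"),
    fuse = c("hog", "deep"),
    classify = list(features = "fused"))
}

#' @rdname defaultPipelineConfig
#' @param path a YAML (or JSON) pipeline configuration file; keys override
#'   the defaults.
#' @export
readPipelineConfig <- function(path) {
  usr <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultPipelineConfig(), usr)
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname defaultPipelineConfig
#' @param config a pipeline configuration list.
#' @export
validatePipelineConfig <- function(config) {
  need <- c("seed", "synth", "split", "lbp", "hog", "backbone", "svm",
            "features", "classify")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("pipeline config is missing keys: ",
                         paste(miss, collapse = ", "))
  stopifnot(config$split$testFrac > 0, config$split$testFrac < 1,
            all(config$features %in% c("lbp", "hog", "deep")))
  if (!is.null(config$fuse) && length(config$fuse) != 2L)
    stop("fuse must name exactly two feature kinds")
  invisible(TRUE)
}

configHash <- function(config) {
  j <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  writeLines(j, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

writeManifest <- function(workdir, stage, config, extra = list()) {
  m <- c(list(stage = stage, configHash = configHash(config),
              seed = config$seed,
              package = as.character(utils::packageVersion("BeakFusion")),
              elapsedSec = round(as.numeric(extra$elapsed %||% NA), 3)),
         extra[setdiff(names(extra), "elapsed")])
  jsonlite::write_json(m, file.path(workdir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

readManifest <- function(workdir, stage) {
  p <- file.path(workdir, paste0(stage, ".manifest.json"))
  if (!file.exists(p))
    stop("stage '", stage, "' has not been run: missing artifact ", p)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

requireArtifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact ", path, "; run stage '", producer, "' first")
  path
}

synthConfigFrom <- function(config) {
  s <- config$synth
  SynthConfig(nPerClass = s$nPerClass, classes = s$classes, views = s$views,
              imageSide = s$imageSide, shapeSeparation = s$shapeSeparation,
              textureSeparation = s$textureSeparation, noiseSd = s$noiseSd,
              seed = config$seed)
}

lbpConfigFrom <- function(config)
  LBPConfig(R = config$lbp$R, P = config$lbp$P, gridN = config$lbp$gridN)

hogConfigFrom <- function(config) HOGConfig(cellPx = config$hog$cellPx)

backboneConfigFrom <- function(config, nClasses) {
  b <- config$backbone
  sched <- if (!is.null(b$lrSchedule)) matrix(unlist(b$lrSchedule), ncol = 3)
           else if (b$profile == "deskSmall") deskLrSchedule(b$epochs)
           else rbind(c(1, 50, 1e-3), c(51, 100, 1e-4))
  BackboneConfig(profile = b$profile, inputSide = b$inputSide,
                 nClasses = nClasses, pooledDim = b$pooledDim %||% 64L,
                 epochs = b$epochs, batchSize = b$batchSize,
                 lrSchedule = sched, seed = config$seed)
}

pipelineImages <- function(workdir, includeAugmented = FALSE) {
  root <- requireArtifact(file.path(workdir, "dataset"), "synth")
  imgs <- loadBeakDataset(root)
  if (includeAugmented && dir.exists(file.path(workdir, "augmented")))
    imgs <- c(imgs, loadBeakDataset(file.path(workdir, "augmented")))
  imgs
}

#' Run one pipeline stage
#'
#' Executes a single stage against a working directory, writing its
#' artifacts (feature CSV tables, split manifest JSON, loss history CSV,
#' metrics and confusion CSVs) plus a JSON manifest recording the config
#' hash, seed, package version, counts and timing. Stages check their
#' prerequisites explicitly and fail naming the missing artifact;
#' \code{fuse} fails if its two input feature tables were produced under
#' different config hashes. Re-running a stage with unchanged config and
#' seed reproduces its outputs.
#'
#' @param stage one of \code{synth}, \code{split}, \code{augment},
#'   \code{extract_lbp}, \code{extract_hog}, \code{train_backbone},
#'   \code{extract_deep}, \code{fuse}, \code{train_svm}, \code{evaluate}.
#' @param config a pipeline configuration list
#'   (\code{\link{defaultPipelineConfig}}).
#' @param workdir working directory for artifacts.
#' @return stage-dependent, invisibly (e.g. the metrics data.frame for
#'   \code{evaluate}).
#' @export
runStage <- function(stage, config = defaultPipelineConfig(),
                     workdir = ".") {
  validatePipelineConfig(config)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  elapsed <- function() proc.time()[["elapsed"]] - t0
  done <- function(extra = list(), value = NULL) {
    writeManifest(workdir, stage, config, c(extra, list(elapsed = elapsed())))
    invisible(value)
  }
  splitPath <- file.path(workdir, "split.json")

  if (stage == "synth") {
    sc <- synthConfigFrom(config)
    imgs <- generateBeakDataset(sc)
    writeBeakDataset(imgs, file.path(workdir, "dataset"))
    utils::write.csv(describeGroundTruth(sc),
                     file.path(workdir, "ground_truth.csv"),
                     row.names = FALSE)
    return(done(list(nImages = length(imgs)), length(imgs)))
  }

  if (stage == "split") {
    imgs <- pipelineImages(workdir)
    sp <- splitDataset(imgs, config$split$testFrac,
                       config$split$valFracOfRest, seed = config$seed)
    writeSplitJSON(sp, splitPath)
    return(done(list(train = length(sp@train), val = length(sp@val),
                     test = length(sp@test)), sp))
  }

  if (stage == "augment") {
    sp <- readSplitJSON(requireArtifact(splitPath, "split"))
    imgs <- pipelineImages(workdir)
    ids <- vapply(imgs, function(x) x@sourceId, "")
    a <- config$augment
    spec <- AugmentSpec(pFlip = a$pFlip, rotationRangeDeg = a$rotationRangeDeg,
                        cropFracRange = a$cropFracRange,
                        aspectRange = a$aspectRange,
                        nPerImage = a$nPerImage, seed = config$seed)
    aug <- unlist(lapply(imgs[ids %in% sp@train], sampleAugmentations,
                         spec = spec), recursive = FALSE)
    writeBeakDataset(aug, file.path(workdir, "augmented"))
    return(done(list(nAugmented = length(aug),
                     trainOnly = TRUE), length(aug)))
  }

  if (stage %in% c("extract_lbp", "extract_hog")) {
    requireArtifact(splitPath, "split")
    imgs <- pipelineImages(workdir, includeAugmented = TRUE)
    fs <- if (stage == "extract_lbp")
      lbpFeatures(imgs, lbpConfigFrom(config), config$lbp$side)
    else hogFeatures(imgs, hogConfigFrom(config), config$hog$side)
    kind <- sub("extract_", "", stage)
    writeFeatureCSV(fs, file.path(workdir,
                                  sprintf("features_%s.csv", kind)))
    return(done(list(nSamples = ncol(fs), dim = nrow(fs)), fs))
  }

  if (stage == "train_backbone") {
    sp <- readSplitJSON(requireArtifact(splitPath, "split"))
    imgs <- pipelineImages(workdir, includeAugmented = TRUE)
    ids <- vapply(imgs, function(x) x@sourceId, "")
    baseId <- sub("_aug[0-9]+$", "", ids)
    trainImgs <- imgs[baseId %in% sp@train]
    valImgs <- imgs[ids %in% sp@val]
    nClasses <- length(unique(vapply(trainImgs, function(x) x@label, "")))
    bb <- buildBackbone(backboneConfigFrom(config, nClasses))
    bb <- trainBackbone(bb, trainImgs, valImgs, seed = config$seed)
    saveRDS(bb, file.path(workdir, "backbone.rds"))
    utils::write.csv(bb@history, file.path(workdir, "loss_history.csv"),
                     row.names = FALSE)
    return(done(list(nTrain = length(trainImgs), nVal = length(valImgs),
                     bestValLoss = min(bb@history$valLoss)), bb))
  }

  if (stage == "extract_deep") {
    requireArtifact(splitPath, "split")
    bb <- readRDS(requireArtifact(file.path(workdir, "backbone.rds"),
                                  "train_backbone"))
    imgs <- pipelineImages(workdir, includeAugmented = TRUE)
    fs <- extractDeep(bb, imgs)
    writeFeatureCSV(fs, file.path(workdir, "features_deep.csv"))
    return(done(list(nSamples = ncol(fs), dim = nrow(fs)), fs))
  }

  if (stage == "fuse") {
    kinds <- config$fuse %||% c("hog", "deep")
    ms <- lapply(paste0("extract_", kinds), readManifest, workdir = workdir)
    if (ms[[1]]$configHash != ms[[2]]$configHash)
      stop("provenance error: feature tables '", kinds[1], "' and '",
           kinds[2], "' were produced under different config hashes")
    fss <- lapply(kinds, function(k)
      readFeatureCSV(requireArtifact(
        file.path(workdir, sprintf("features_%s.csv", k)),
        paste0("extract_", k)), k))
    fused <- fuseFeatures(fss[[1]], fss[[2]])
    writeFeatureCSV(fused, file.path(workdir, "features_fused.csv"))
    return(done(list(dim = nrow(fused)), fused))
  }

  if (stage == "train_svm") {
    kind <- config$classify$features
    sp <- readSplitJSON(requireArtifact(splitPath, "split"))
    fs <- readFeatureCSV(requireArtifact(
      file.path(workdir, sprintf("features_%s.csv", kind)),
      if (kind == "fused") "fuse" else paste0("extract_", kind)),
      if (kind == "fused") "fused" else kind)
    fitIds <- c(sp@train, sp@val)
    baseId <- sub("_aug[0-9]+$", "", colnames(fs))
    keep <- baseId %in% fitIds  # never test images, augmented or not
    clf <- fitClassifier(fs[, keep], config = SVMConfig(
      C = config$svm$C, standardize = isTRUE(config$svm$standardize)),
      seed = config$seed)
    writeClassifier(clf, file.path(workdir, sprintf("svm_%s.rds", kind)))
    return(done(list(nFit = sum(keep), kind = kind), clf))
  }

  if (stage == "evaluate") {
    kind <- config$classify$features
    sp <- readSplitJSON(requireArtifact(splitPath, "split"))
    fs <- readFeatureCSV(requireArtifact(
      file.path(workdir, sprintf("features_%s.csv", kind)), "extract/fuse"),
      if (kind == "fused") "fused" else kind)
    clf <- readClassifier(requireArtifact(
      file.path(workdir, sprintf("svm_%s.rds", kind)), "train_svm"),
      expectDim = nrow(fs))
    testFs <- fs[, colnames(fs) %in% sp@test]
    views <- SummarizedExperiment::colData(testFs)$view
    rows <- list()
    for (v in unique(views)) {
      sel <- views == v
      pred <- predictLabels(clf, testFs[, sel])
      cm <- confusionMatrix(featureLabels(testFs)[sel], pred,
                            clf@classOrder)
      writeConfusionCSV(cm, file.path(workdir,
                                      sprintf("confusion_%s_%s.csv", kind, v)))
      rep <- classMetrics(cm)
      all <- data.frame(view = v, class = "ALL",
                        t(rep@aggregate))
      per <- cbind(view = v, rep@perClass)
      rows[[v]] <- rbind(all, per)
    }
    metrics <- do.call(rbind, rows)
    utils::write.csv(metrics, file.path(workdir,
                                        sprintf("metrics_%s.csv", kind)),
                     row.names = FALSE)
    return(done(list(nTest = ncol(testFs)), metrics))
  }

  stop("unknown stage '", stage, "'")
}

#' Run the full pipeline
#'
#' Executes synth, split, optional augment, shallow extraction, backbone
#' training and deep extraction (when needed), fusion, SVM training and
#' evaluation, in dependency order.
#'
#' @param config a pipeline configuration list.
#' @param workdir working directory for artifacts.
#' @return the evaluation metrics data.frame.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        workdir = tempfile("beakpipe")) {
  validatePipelineConfig(config)
  runStage("synth", config, workdir)
  runStage("split", config, workdir)
  if (isTRUE(config$augment$enabled)) runStage("augment", config, workdir)
  kinds <- unique(c(config$features, config$fuse))
  for (k in setdiff(kinds, "deep"))
    runStage(paste0("extract_", k), config, workdir)
  if ("deep" %in% kinds) {
    runStage("train_backbone", config, workdir)
    runStage("extract_deep", config, workdir)
  }
  if (!is.null(config$fuse)) runStage("fuse", config, workdir)
  runStage("train_svm", config, workdir)
  runStage("evaluate", config, workdir)
}

#' In-memory classification experiment
#'
#' Convenience wrapper used by the validation suites: splits the images,
#' computes the requested feature sets (training a desk-scale backbone for
#' \code{"deep"}), fits one one-vs-rest RBF SVM per feature set on the
#' train+validation samples, and reports test accuracy per feature set.
#' Elements of \code{featureKinds} are single kinds (\code{"lbp"},
#' \code{"hog"}, \code{"deep"}) or ordered pairs to fuse
#' (\code{c("hog", "deep")}).
#'
#' @param images list of \linkS4class{BeakImage}s.
#' @param featureKinds list of kinds / pairs, see above.
#' @param lbpConfig,hogConfig descriptor configurations.
#' @param lbpSide,hogSide descriptor input sides.
#' @param backboneConfig a \linkS4class{BackboneConfig} for "deep"
#'   (nClasses must match the data).
#' @param svmConfig an \linkS4class{SVMConfig}.
#' @param testFrac,valFracOfRest split ratios.
#' @param seed integer seed driving split, backbone and SVM.
#' @return list with \code{accuracy} (named numeric), \code{reports}
#'   (named list of \linkS4class{MetricsReport}) and \code{split}.
#' @export
runBeakExperiment <- function(images,
                              featureKinds = list("hog", "deep",
                                                  c("hog", "deep")),
                              lbpConfig = LBPConfig(),
                              hogConfig = HOGConfig(cellPx = 32L),
                              lbpSide = 256L, hogSide = 256L,
                              backboneConfig = NULL,
                              svmConfig = SVMConfig(),
                              testFrac = 0.2, valFracOfRest = 0.2,
                              seed = 1L) {
  sp <- splitDataset(images, testFrac, valFracOfRest, seed = seed)
  ids <- vapply(images, function(x) x@sourceId, "")
  base <- list()
  kindsNeeded <- unique(unlist(featureKinds))
  if ("lbp" %in% kindsNeeded)
    base$lbp <- lbpFeatures(images, lbpConfig, lbpSide)
  if ("hog" %in% kindsNeeded)
    base$hog <- hogFeatures(images, hogConfig, hogSide)
  if ("deep" %in% kindsNeeded) {
    labs <- vapply(images, function(x) x@label, "")
    if (is.null(backboneConfig))
      backboneConfig <- BackboneConfig("deskSmall", inputSide = 48L,
                                       nClasses = length(unique(labs)),
                                       epochs = 14L, batchSize = 8L,
                                       lrSchedule = deskLrSchedule(14L),
                                       seed = childSeed(seed, 7L))
    bb <- buildBackbone(backboneConfig)
    bb <- trainBackbone(bb, images[ids %in% sp@train],
                        images[ids %in% sp@val],
                        seed = childSeed(seed, 11L))
    base$deep <- extractDeep(bb, images)
  }
  fitIdx <- ids %in% c(sp@train, sp@val)
  testIdx <- ids %in% sp@test
  accuracy <- numeric(0)
  reports <- list()
  for (fk in featureKinds) {
    fs <- if (length(fk) == 1L) base[[fk]]
          else fuseFeatures(base[[fk[1]]], base[[fk[2]]])
    nm <- paste(fk, collapse = "+")
    clf <- fitClassifier(fs[, fitIdx], config = svmConfig,
                         seed = childSeed(seed, 13L))
    pred <- predictLabels(clf, fs[, testIdx])
    cm <- confusionMatrix(featureLabels(fs)[testIdx], pred, clf@classOrder)
    reports[[nm]] <- classMetrics(cm)
    accuracy[nm] <- reports[[nm]]@aggregate[["accuracy"]]
  }
  list(accuracy = accuracy, reports = reports, split = sp)
}
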