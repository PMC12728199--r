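## Run configuration, seed derivation and run manifests.

#' Derive a per-stage seed from a global seed
#'
#' Deterministic counter scheme: stage k maps to
#' \code{(seed + k * 10007) mod (2^31 - 1)}, keeping every derived seed a
#' valid 32-bit integer. Stages are numbered per pipeline step so a single
#' global seed fans out to independent cohort, graph, training, protocol and
#' evaluation streams.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage counter.
#' @return Integer seed below 2^31.
#' @export
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) + as.numeric(stage) * 10007) %% 2147483647)
}

#' Read and validate a YAML run configuration
#'
#' Maps a nested YAML document onto the package's configuration objects,
#' filling defaults for absent keys and validating every sub-config. Top
#' level keys: \code{cohort}, \code{window}, \code{model}, \code{train},
#' \code{gossip}, \code{seed}, \code{outputDir}.
#'
#' @param path YAML file path.
#' @return Named list with elements \code{cohort} (\code{CohortConfig}),
#'   \code{window} (\code{WindowSpec}), \code{model} (\code{GatConfig}),
#'   \code{train} (\code{TrainConfig}), \code{gossip} (\code{GossipConfig}),
#'   \code{seed}, \code{outputDir}.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "window", "model", "train", "gossip", "seed",
             "outputDir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  callWith <- function(fn, args, allowed) {
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), allowed)
    if (length(bad)) {
      stop("unknown key(s): ", paste(bad, collapse = ", "))
    }
    do.call(fn, args)
  }
  cohort <- callWith(cohortConfig, c(raw$cohort,
    if (is.null(raw$cohort$seed)) list(seed = deriveSeed(seed, 1L))),
    c("nPatients", "prevalence", "lengthMean", "lengthSd", "missingRate",
      "plantedSignal", "seed"))
  window <- callWith(windowSpec, raw$window,
    c("windowHours", "historySteps", "corrThreshold", "horizonMin",
      "horizonMax"))
  model <- callWith(gatConfig, c(
    raw$model, if (is.null(raw$model$d0)) list(d0 = window@historySteps)),
    c("d0", "dh", "heads", "dropout", "leakySlope", "secondLayerMode"))
  train <- callWith(trainConfig, c(raw$train,
    if (is.null(raw$train$seed)) list(seed = deriveSeed(seed, 3L))),
    c("lr", "epochs", "batchSize", "seed"))
  gossip <- callWith(gossipConfig, c(raw$gossip,
    if (is.null(raw$gossip$seed)) list(seed = deriveSeed(seed, 4L))),
    c("nNodes", "rounds", "scheduling", "fineTuneLr", "fineTuneEpochs",
      "aggregationMode", "temperature", "seed"))
  for (obj in list(cohort, window, model, train, gossip)) validObject(obj)
  list(cohort = cohort, window = window, model = model, train = train,
       gossip = gossip, seed = seed,
       outputDir = if (is.null(raw$outputDir)) "." else raw$outputDir)
}

configAsList <- function(obj) {
  sl <- methods::slotNames(class(obj))
  out <- lapply(sl, function(s) methods::slot(obj, s))
  names(out) <- sl
  out[!vapply(out, is.matrix, logical(1))]
}

#' Write a reproducibility manifest for a run
#'
#' Records the full configuration, global seed, package version and any
#' run metrics as JSON, so a run can be reproduced from its manifest alone.
#'
#' @param path Output JSON path.
#' @param config A run configuration list (as from
#'   \code{\link{readRunConfig}}).
#' @param metrics Optional named list of computed quantities.
#' @return Invisibly, the manifest list.
#' @export
writeManifest <- function(path, config, metrics = list()) {
  manifest <- list(
    package = "akigraph",
    version = as.character(utils::packageVersion("akigraph")),
    seed = config$seed,
    cohort = configAsList(config$cohort),
    window = configAsList(config$window),
    model = configAsList(config$model),
    train = configAsList(config$train),
    gossip = configAsList(config$gossip),
    metrics = metrics
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Sensitivity sweep over graph-construction settings
#'
#' Re-runs graph construction and centralized training over a grid of
#' correlation thresholds and window lengths (the baseline sensitivity
#' layout: threshold varied at the default window, window varied at the
#' default threshold), reporting held-out AUROC and AUPRC per setting.
#'
#' @param trainCohort,testCohort Normalized cohorts.
#' @param thresholds Correlation thresholds (default 0.25/0.30/0.35).
#' @param windows Window lengths in hours (default 24/48/72).
#' @param config A \code{\link{gatConfig}}.
#' @param trainCfg A \code{\link{trainConfig}}.
#' @param seed Seed for graph building.
#' @return Data frame: setting, corrThreshold, windowHours, auroc, auprc.
#' @export
sensitivitySweep <- function(trainCohort, testCohort,
                             thresholds = c(0.25, 0.30, 0.35),
                             windows = c(24L, 48L, 72L),
                             config = gatConfig(), trainCfg = trainConfig(),
                             seed = 1L) {
  baseThr <- thresholds[ceiling(length(thresholds) / 2)]
  baseWin <- windows[ceiling(length(windows) / 2)]
  grid <- unique(rbind(
    data.frame(corrThreshold = thresholds, windowHours = baseWin),
    data.frame(corrThreshold = baseThr, windowHours = windows)
  ))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    spec <- windowSpec(windowHours = grid$windowHours[k],
                       historySteps = config@d0,
                       corrThreshold = grid$corrThreshold[k])
    gTrain <- buildGraphs(trainCohort, spec, seed = deriveSeed(seed, k))
    gTest <- buildGraphs(testCohort, spec, seed = deriveSeed(seed, 500L + k))
    fit <- trainCentralized(gTrain, NULL, config, trainCfg)
    ps <- predictionSet(vapply(gTest, graphLabel, integer(1)),
                        gatPredict(fit$model, gTest), "sweep")
    data.frame(
      setting = sprintf("r=%.2f, %dh", grid$corrThreshold[k],
                        grid$windowHours[k]),
      corrThreshold = grid$corrThreshold[k],
      windowHours = grid$windowHours[k],
      auroc = auroc(ps), auprc = auprc(ps)
    )
  })
  do.call(rbind, rows)
}
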