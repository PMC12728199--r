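## The pinned desk-scale signal-recovery study: synthetic cohort -> graphs ->
## centralized GAT vs 5-node gossip protocol -> held-out evaluation.

#' Desk-scale recovery-study configuration
#'
#' The package's pinned configuration for the end-to-end signal-recovery
#' experiment on the synthetic cohort: 2,000 patients at 15% prevalence, an
#' 85:15 split over five nodes, 24-hour windows at the default correlation
#' threshold, a width-reduced GAT (dh 16, 2 heads, dropout 0.1, learning
#' rate 5e-3, batch 64) and 18 gossip rounds with adaptive aggregation and
#' five fine-tuning epochs. The reductions relative to the full-size
#' defaults are discussed in the methods vignette.
#'
#' @param seed Global seed; all stage seeds derive from it.
#' @return Named list of configuration objects plus \code{centralEpochs}.
#' @export
recoveryStudyConfig <- function(seed = 1L) {
  list(
    cohort = cohortConfig(nPatients = 2000L, prevalence = 0.15,
                          seed = deriveSeed(seed, 1L)),
    window = windowSpec(windowHours = 24L),
    model = gatConfig(d0 = 3L, dh = 16L, heads = 2L, dropout = 0.1),
    train = trainConfig(lr = 0.005, epochs = 40L, batchSize = 64L,
                        seed = deriveSeed(seed, 3L)),
    gossip = gossipConfig(nNodes = 5L, rounds = 18L, fineTuneEpochs = 5L,
                          seed = deriveSeed(seed, 4L)),
    centralEpochs = 40L,
    seed = seed
  )
}

#' Run one seed of the signal-recovery study
#'
#' Generates the synthetic cohort, splits it 85:15 with five stratified
#' node shards, normalizes by training statistics, builds 24-hour feature
#' graphs, trains the centralized GAT and the 5-node gossip protocol, and
#' evaluates both on the held-out test graphs. Also computes the
#' attention-based feature importance of the centralized model.
#'
#' @param seed Global seed for this replicate.
#' @param cfg Configuration list (default \code{recoveryStudyConfig(seed)}).
#' @return List: \code{centralAuroc}, \code{gossipAuroc},
#'   \code{importance} (named, sums to 1), \code{creatinineRank},
#'   \code{nTrain}, \code{nTest}, \code{centralPreds}, \code{gossipPreds}.
#' @export
runRecoveryStudy <- function(seed = 1L, cfg = recoveryStudyConfig(seed)) {
  cohort <- generateCohort(cfg$cohort)
  sp <- splitCohort(cohort, 0.85, nNodes = cfg$gossip@nNodes,
                    seed = deriveSeed(seed, 2L))
  zs <- zscoreNormalize(sp$train)
  zTest <- zscoreNormalize(sp$test, zs$stats)$cohort
  gTrain <- suppressWarnings(
    buildGraphs(zs$cohort, cfg$window, seed = deriveSeed(seed, 5L))
  )
  gTest <- suppressWarnings(
    buildGraphs(zTest, cfg$window, seed = deriveSeed(seed, 6L))
  )
  shards <- lapply(seq_along(sp$shards), function(k) {
    z <- zscoreNormalize(sp$shards[[k]], zs$stats)$cohort
    gs <- suppressWarnings(
      buildGraphs(z, cfg$window, seed = deriveSeed(seed, 10L + k))
    )
    set.seed(deriveSeed(seed, 30L + k))
    vidx <- sample(length(gs), max(2L, round(0.15 * length(gs))))
    list(train = gs[-vidx], val = gs[vidx])
  })
  trainCfgC <- cfg$train
  trainCfgC@epochs <- as.integer(cfg$centralEpochs)
  fit <- trainCentralized(gTrain, NULL, cfg$model, trainCfgC)
  gos <- runGossip(shards, cfg$model, cfg$train, cfg$gossip)
  yTest <- vapply(gTest, graphLabel, integer(1))
  centralPreds <- predictionSet(yTest, gatPredict(fit$model, gTest),
                                "central")
  gossipPreds <- predictionSet(yTest, gatPredict(gos$model, gTest),
                               "gossip")
  importance <- attentionImportance(fit$model, gTest)
  list(
    centralAuroc = auroc(centralPreds),
    gossipAuroc = auroc(gossipPreds),
    importance = importance,
    creatinineRank = which(
      names(sort(importance, decreasing = TRUE)) == "Creatinine"
    ),
    nTrain = length(gTrain), nTest = length(gTest),
    centralPreds = centralPreds, gossipPreds = gossipPreds,
    centralModel = fit$model, gossipModel = gos$model
  )
}
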