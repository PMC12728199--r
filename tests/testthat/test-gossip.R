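## Small shared fixtures: tiny shards over separable toy graphs.
makeShards <- function(nNodes = 3L, perNode = 10L, Tn = 4L) {
  lapply(seq_len(nNodes), function(n) {
    gs <- makeSeparableGraphs(perNode, Tn = Tn)
    list(train = gs, val = gs[seq_len(max(2L, perNode %/% 3L))])
  })
}

tinyGat <- function() gatConfig(d0 = 3L, dh = 4L, heads = 2L, dropout = 0.2)
tinyTrain <- function(epochs = 1L) {
  trainConfig(lr = 0.01, epochs = epochs, batchSize = 8L, seed = 5L)
}

test_that("parameter deltas are exact differences on the flat view", {
  set.seed(7)
  cfg <- tinyGat()
  p0 <- initGatParams(cfg)
  node <- new("NodeState", nodeId = 1L, params = p0, prevParams = list(),
              valAccuracy = NA_real_, adamState = list(), rngState = 1L,
              trainPrep = list(), valPrep = list())
  expect_error(computeDelta(node), "previous")
  node@prevParams <- p0
  expect_equal(computeDelta(node), rep(0, parameterCount(p0)))
  v <- rnorm(parameterCount(p0))
  node@params <- unflattenParams(flattenParams(p0) + v, cfg)
  expect_equal(computeDelta(node), v)
})

test_that("a local epoch moves parameters", {
  set.seed(9)
  shards <- makeShards(1L, perNode = 12L)
  cfg <- tinyGat()
  nodes <- makeNodes(shards, cfg, gossipConfig(nNodes = 1L, seed = 3L))
  n1 <- akigraph:::nodeLocalEpoch(nodes[[1]], cfg, tinyTrain())
  expect_gt(sqrt(sum(computeDelta(n1)^2)), 0)
})

test_that("exchange merging averages pairs element-wise", {
  set.seed(11)
  cfg <- tinyGat()
  shards <- makeShards(2L, perNode = 6L)
  nodes <- makeNodes(shards, cfg, gossipConfig(nNodes = 2L, seed = 13L))
  fa <- rnorm(parameterCount(nodes[[1]]@params))
  fb <- rnorm(length(fa))
  nodes[[1]]@params <- unflattenParams(fa, cfg)
  nodes[[2]]@params <- unflattenParams(fb, cfg)
  merged <- akigraph:::mergePair(nodes, 1L, 2L, cfg)
  expect_equal(flattenParams(merged[[1]]@params), (fa + fb) / 2)
  expect_equal(flattenParams(merged[[2]]@params), (fa + fb) / 2)
  ## identical parameters are a fixed point of the exchange
  nodes[[2]]@params <- nodes[[1]]@params
  same <- akigraph:::mergePair(nodes, 1L, 2L, cfg)
  expect_equal(flattenParams(same[[1]]@params),
               flattenParams(nodes[[1]]@params))
})

test_that("scheduling ranks nodes by accuracy with id tie-breaks", {
  cfg <- tinyGat()
  mk <- function(id, acc) {
    new("NodeState", nodeId = id, params = list(), prevParams = list(),
        valAccuracy = acc, adamState = list(), rngState = 1L,
        trainPrep = list(), valPrep = list())
  }
  nodes <- list(mk(0L, 0.9), mk(1L, 0.7), mk(2L, 0.8))
  expect_identical(scheduleExchanges(nodes), c(0L, 2L, 1L))
  ties <- list(mk(0L, 0.5), mk(1L, 0.5), mk(2L, 0.5))
  expect_identical(scheduleExchanges(ties), c(0L, 1L, 2L))
  expect_identical(scheduleExchanges(list(mk(0L, 0.5))), integer(0))
})

test_that("aggregation weights are an exact softmax of accuracies", {
  expect_equal(aggregationWeights(rep(0.8, 5)), rep(0.2, 5))
  w <- aggregationWeights(c(1, 0, 0, 0, 0))
  expect_equal(w[1], exp(1) / (exp(1) + 4))
  expect_equal(sum(w), 1)
  ## independent softmax oracle on random accuracy vectors
  set.seed(17)
  for (rep in 1:50) {
    accs <- runif(sample(2:8, 1))
    w <- aggregationWeights(accs)
    expect_equal(w, exp(accs) / sum(exp(accs)), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(sum(aggregationWeights(accs, "equal")), 1,
                 tolerance = 1e-12)
  }
})

test_that("adaptive aggregation is a convex combination with exact fixed points", {
  set.seed(19)
  cfg <- tinyGat()
  shards <- makeShards(3L, perNode = 6L)
  nodes <- makeNodes(shards, cfg, gossipConfig(nNodes = 3L, seed = 23L))
  for (k in 1:3) nodes[[k]]@valAccuracy <- runif(1)
  ## identical parameters: global equals them for any accuracies
  agg <- adaptiveAggregate(nodes, cfg)
  expect_equal(flattenParams(agg$params), flattenParams(nodes[[1]]@params))
  expect_equal(sum(agg$weights), 1, tolerance = 1e-12)
  ## equal accuracies: adaptive and equal modes coincide exactly
  for (k in 1:3) nodes[[k]]@valAccuracy <- 0.75
  wA <- adaptiveAggregate(nodes, cfg, mode = "adaptive")
  wE <- adaptiveAggregate(nodes, cfg, mode = "equal")
  expect_equal(wA$weights, wE$weights)
  expect_equal(flattenParams(wA$params), flattenParams(wE$params))
})

test_that("distribution without fine-tuning leaves the global model intact", {
  set.seed(29)
  cfg <- tinyGat()
  shards <- makeShards(2L, perNode = 8L)
  gcfg <- gossipConfig(nNodes = 2L, fineTuneEpochs = 0L, seed = 31L)
  nodes <- makeNodes(shards, cfg, gcfg)
  glob <- initGatParams(cfg)
  out <- distributeAndFinetune(nodes, glob, cfg, tinyTrain(), gcfg)
  for (n in out) {
    expect_identical(flattenParams(n@params), flattenParams(glob))
  }
  ## eta = 0 also leaves parameters unchanged after any epochs
  gcfg0 <- gossipConfig(nNodes = 2L, fineTuneEpochs = 3L, fineTuneLr = 0,
                        seed = 31L)
  out0 <- distributeAndFinetune(nodes, glob, cfg, tinyTrain(), gcfg0)
  for (n in out0) {
    expect_identical(flattenParams(n@params), flattenParams(glob))
  }
})

test_that("fine-tuning descends the local loss on a separable shard", {
  set.seed(37)
  cfg <- gatConfig(d0 = 3L, dh = 4L, heads = 2L, dropout = 0)
  shards <- makeShards(1L, perNode = 20L)
  gcfg <- gossipConfig(nNodes = 1L, rounds = 8L, fineTuneEpochs = 6L,
                       fineTuneLr = 0.02, seed = 41L)
  nodes <- makeNodes(shards, cfg, gcfg)
  lossOf <- function(params) {
    akigraph:::bceLoss(
      akigraph:::predictPrep(params, cfg, nodes[[1]]@trainPrep),
      nodes[[1]]@trainPrep$y
    )
  }
  glob <- nodes[[1]]@params
  before <- lossOf(glob)
  out <- distributeAndFinetune(nodes, glob, cfg, tinyTrain(), gcfg)
  expect_lt(lossOf(out[[1]]@params), before)
})

test_that("communication accounting follows the payload arithmetic", {
  payload <- 27e6
  fed <- communicationLedger("fedavg", rounds = 1L, nNodes = 5L,
                             payloadBytes = payload)
  expect_equal(totalBytes(fed) / 1e6, 135)
  gos65 <- communicationLedger("gossip", rounds = 65L, nNodes = 5L,
                               payloadBytes = payload)
  expect_equal(totalBytes(gos65) / 1e6, 1755) # about 1.8 GB
  ## per-round ratio is exactly nNodes for any payload
  set.seed(43)
  for (rep in 1:10) {
    pay <- runif(1, 1e3, 1e8)
    nn <- sample(2:10, 1)
    f1 <- communicationLedger("fedavg", 1L, nn, pay)
    g1 <- communicationLedger("gossip", 1L, nn, pay)
    expect_equal(f1@entries$bytes[1] / g1@entries$bytes[1], nn)
  }
  ## zero rounds cost zero bytes
  expect_equal(totalBytes(communicationLedger("fedavg", 0L, 5L, payload)), 0)
})

test_that("gossip and fedavg runs are reproducible and ledgered", {
  set.seed(47)
  shards <- makeShards(3L, perNode = 9L)
  cfg <- tinyGat()
  tcfg <- tinyTrain()
  gcfg <- gossipConfig(nNodes = 3L, rounds = 2L, fineTuneEpochs = 1L,
                       seed = 51L)
  r1 <- runGossip(shards, cfg, tcfg, gcfg)
  r2 <- runGossip(shards, cfg, tcfg, gcfg)
  expect_identical(flattenParams(r1$model@params),
                   flattenParams(r2$model@params))
  expect_identical(r1$history, r2$history)
  expect_identical(nrow(r1$ledger@entries), 2L)
  ## scheduling reorders exchanges but never adds payloads
  rs <- runGossip(shards, cfg, tcfg,
                  gossipConfig(nNodes = 3L, rounds = 2L, scheduling = TRUE,
                               fineTuneEpochs = 1L, seed = 51L))
  expect_identical(totalBytes(rs$ledger), totalBytes(r1$ledger))
  ## fedavg: 0 rounds returns the seeded initial model (bias set to the
  ## prevalence log-odds) and an empty ledger
  f0 <- runFedAvg(shards, cfg, tcfg, rounds = 0L, seed = 53L)
  set.seed(53L)
  init <- initGatParams(cfg)
  flatInit <- flattenParams(init)
  flat0 <- flattenParams(f0$model@params)
  expect_identical(flat0[-length(flat0)], flatInit[-length(flatInit)])
  y <- unlist(lapply(shards, function(s) sapply(s$train, graphLabel)))
  expect_equal(flat0[length(flat0)], log(mean(y) / (1 - mean(y))))
  expect_identical(totalBytes(f0$ledger), 0)
  ## fedavg logs nNodes upload payloads per round
  f2 <- runFedAvg(shards, cfg, tcfg, rounds = 2L, seed = 53L)
  expect_identical(f2$ledger@entries$bytes,
                   rep(3 * 4 * parameterCount(f2$model@params), 2))
})

test_that("a one-node protocol collapses to centralized training bit-for-bit", {
  set.seed(59)
  graphs <- makeSeparableGraphs(16L, Tn = 4L)
  cfg <- tinyGat()
  epochs <- 3L
  tcfg <- trainConfig(lr = 0.01, epochs = epochs, batchSize = 8L, seed = 61L)
  gres <- runGossip(
    list(list(train = graphs, val = graphs[1:4])), cfg, tcfg,
    gossipConfig(nNodes = 1L, rounds = epochs, fineTuneEpochs = 0L,
                 seed = 61L)
  )
  cres <- trainCentralized(graphs, NULL, cfg, tcfg)
  expect_identical(flattenParams(gres$model@params),
                   flattenParams(cres$model@params))
  expect_identical(flattenParams(gres$nodes[[1]]@params),
                   flattenParams(cres$model@params))
})

test_that("training is seed-deterministic and inert at lr = 0", {
  graphs <- makeSeparableGraphs(12L, Tn = 4L)
  cfg <- tinyGat()
  tc <- trainConfig(lr = 0.01, epochs = 2L, batchSize = 6L, seed = 67L)
  f1 <- trainCentralized(graphs, graphs[1:4], cfg, tc)
  f2 <- trainCentralized(graphs, graphs[1:4], cfg, tc)
  expect_identical(flattenParams(f1$model@params),
                   flattenParams(f2$model@params))
  expect_identical(f1$history, f2$history)
  ## lr = 0: parameters frozen at initialization
  tc0 <- trainConfig(lr = 0, epochs = 2L, batchSize = 6L, seed = 67L)
  f0 <- trainCentralized(graphs, NULL, cfg, tc0)
  set.seed(67L)
  expect_identical(flattenParams(f0$model@params),
                   flattenParams(initGatParams(cfg)))
  ## single-class training is rejected
  onlyPos <- makeSeparableGraphs(6L, Tn = 4L)[1:3]
  expect_error(trainCentralized(onlyPos, NULL, cfg, tc), "both classes")
})

test_that("a trained model overfits a separable toy set to perfect accuracy", {
  set.seed(71)
  graphs <- makeSeparableGraphs(40L, Tn = 6L, shift = 2)
  cfg <- gatConfig(d0 = 3L, dh = 8L, heads = 2L, dropout = 0)
  fit <- trainCentralized(graphs, NULL, cfg,
                          trainConfig(lr = 0.005, epochs = 120L,
                                      batchSize = 40L, seed = 73L))
  p <- gatPredict(fit$model, graphs)
  y <- vapply(graphs, graphLabel, integer(1))
  expect_equal(mean((p >= 0.5) == (y == 1L)), 1)
  ## the loss history is finite and decreasing overall
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("an unreachable peer is skipped and the round continues", {
  set.seed(77)
  cfg <- tinyGat()
  shards <- makeShards(3L, perNode = 8L)
  nodes <- makeNodes(shards, cfg, gossipConfig(nNodes = 3L, seed = 79L))
  tcfg <- tinyTrain()
  set.seed(80)
  res <- gossipRound(nodes, cfg, tcfg, unreachable = 2L)
  expect_length(res$nodes, 3L)
  ## node 2 trained locally but took part in no exchange: its parameters
  ## equal plain local training from the shared start
  lone <- akigraph:::nodeLocalEpoch(nodes[[2]], cfg, tcfg)
  expect_identical(flattenParams(res$nodes[[2]]@params),
                   flattenParams(lone@params))
  ## with every peer unreachable the round degrades to local training only
  res2 <- gossipRound(nodes, cfg, tcfg, unreachable = c(1L, 2L, 3L))
  lone1 <- akigraph:::nodeLocalEpoch(nodes[[1]], cfg, tcfg)
  expect_identical(flattenParams(res2$nodes[[1]]@params),
                   flattenParams(lone1@params))
})
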