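test_that("the linear input transform is a plain matrix product", {
  expect_equal(linearTransform(c(1, 2, 3), diag(3)), c(1, 2, 3))
  expect_equal(linearTransform(c(1, 2, 3), matrix(0, 4, 3)), rep(0, 4))
  expect_equal(linearTransform(c(1.5, 1.2, 1.0), matrix(1, 1, 3)), 3.7)
  expect_error(linearTransform(c(1, 2), diag(3)), "shape")
})

test_that("attention scores apply the LeakyReLU with i-then-j concatenation", {
  dh <- 4L
  W <- diag(dh)
  ## null attention vector kills every score
  expect_equal(attentionScores(rnorm(dh), rnorm(dh), W, rep(0, 2 * dh)), 0)
  ## hand-built pre-activations
  a <- c(1, rep(0, 2 * dh - 1))
  expect_equal(attentionScores(c(2, 0, 0, 0), rep(0, dh), W, a), 2)
  expect_equal(attentionScores(c(-2, 0, 0, 0), rep(0, dh), W, a,
                               leakySlope = 0.2), -0.4)
  ## asymmetry: swapping i and j changes the score in general
  set.seed(3)
  W <- matrix(rnorm(dh * dh), dh)
  a <- rnorm(2 * dh)
  hi <- rnorm(dh)
  hj <- rnorm(dh)
  expect_false(isTRUE(all.equal(attentionScores(hi, hj, W, a),
                                attentionScores(hj, hi, W, a))))
})

test_that("the attention softmax is normalized, stable and handles edge cases", {
  expect_equal(attentionSoftmax(rep(1.7, 5)), rep(0.2, 5))
  expect_equal(attentionSoftmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  expect_equal(attentionSoftmax(42), 1)
  ## stability under large scores
  expect_equal(attentionSoftmax(c(1000, 1000)), c(0.5, 0.5))
  expect_error(attentionSoftmax(numeric(0)), "empty")
})

test_that("aggregation is the ReLU of the attention-weighted combination", {
  v <- c(1, -2, 3)
  ## convexity fixed point on identical neighbors
  nb <- cbind(v, v, v)
  expect_equal(aggregateNeighbors(rep(1 / 3, 3), nb), pmax(v, 0))
  ## all-negative pre-activations floor at zero
  expect_equal(aggregateNeighbors(c(0.5, 0.5), cbind(c(-1, -2), c(-3, -4))),
               c(0, 0))
  ## hand-computed weighted mean
  expect_equal(aggregateNeighbors(c(0.75, 0.25), cbind(c(4, 0), c(0, 4))),
               c(3, 1))
})

test_that("head concatenation preserves order and dimension", {
  expect_equal(concatHeads(list(c(1, 2))), c(1, 2))
  expect_equal(concatHeads(list(c(1, 2), c(3, 4))), c(1, 2, 3, 4))
  ## default architecture: 8 heads x 64 dims = 512
  expect_length(concatHeads(lapply(1:8, function(k) numeric(64))), 512L)
})

test_that("a null output head predicts exactly 0.5 and the sigmoid is exact", {
  set.seed(11)
  g <- makeRandomGraph()
  cfg <- gatConfig(d0 = 3L, dh = 6L, heads = 2L, dropout = 0)
  params <- initGatParams(cfg)
  params$Wfc[] <- 0
  params$b <- 0
  expect_equal(gatForwardReference(params, cfg, g), 0.5)
  ## logit ln 3 -> probability 0.75
  expect_equal(plogis(log(3)), 0.75)
  params$b <- log(3)
  expect_equal(gatForwardReference(params, cfg, g), 0.75)
})

test_that("the batched engine reproduces the primitive-op reference exactly", {
  set.seed(23)
  for (mode in c("average", "concat")) {
    graphs <- lapply(1:4, function(i) makeRandomGraph(i %% 2, Tn = 5L))
    cfg <- gatConfig(d0 = 3L, dh = 6L, heads = 3L, dropout = 0,
                     secondLayerMode = mode)
    params <- initGatParams(cfg)
    pBatch <- akigraph:::predictPrep(params, cfg, prepareGraphs(graphs))
    pRef <- vapply(graphs, function(g) gatForwardReference(params, cfg, g),
                   numeric(1))
    expect_equal(pBatch, pRef, tolerance = 1e-12)
  }
})

test_that("predictions are invariant under consistent node permutations", {
  set.seed(31)
  g <- makeRandomGraph(Tn = 6L)
  cfg <- gatConfig(d0 = 3L, dh = 8L, heads = 2L, dropout = 0)
  params <- initGatParams(cfg)
  p0 <- akigraph:::predictPrep(params, cfg, prepareGraphs(list(g)))
  for (rep in 1:3) {
    perm <- sample(12)
    gp <- g
    gp@adjacency <- g@adjacency[perm, perm]
    gp@nodeFeatures <- g@nodeFeatures[perm, , , drop = FALSE]
    pp <- akigraph:::predictPrep(params, cfg, prepareGraphs(list(gp)))
    expect_equal(pp, p0, tolerance = 1e-10)
  }
})

test_that("attention coefficients sum to one over every neighborhood", {
  set.seed(37)
  graphs <- lapply(1:3, function(i) makeRandomGraph(Tn = 4L))
  cfg <- gatConfig(d0 = 3L, dh = 6L, heads = 2L, dropout = 0)
  params <- initGatParams(cfg)
  prep <- prepareGraphs(graphs)
  batch <- akigraph:::makeBatch(prep, 1:3)
  fw <- akigraph:::gatBatchForward(params, cfg, batch, keepCache = TRUE)
  N <- batch$N
  for (layer in list(fw$cache$l1, fw$cache$l2)) {
    for (ch in layer) {
      ## row sums per receiver: fold the (i,j) pair axis back to i
      sums <- matrix(0, N, batch$S)
      for (j in seq_len(N)) {
        sums <- sums + ch$alpha[(j - 1L) * N + seq_len(N), , drop = FALSE]
      }
      expect_true(all(abs(sums - 1) < 1e-8))
    }
  }
})

test_that("the output is bounded in (0,1) and monotone in the final bias", {
  set.seed(41)
  g <- makeRandomGraph()
  cfg <- gatConfig(d0 = 3L, dh = 6L, heads = 2L, dropout = 0)
  params <- initGatParams(cfg)
  probs <- vapply(c(-3, -1, 0, 1, 3), function(b) {
    params$b <- b
    gatForwardReference(params, cfg, g)
  }, numeric(1))
  expect_true(all(probs > 0 & probs < 1))
  expect_true(all(diff(probs) > 0))
})

test_that("analytic gradients match central finite differences", {
  set.seed(47)
  graphs <- list(makeRandomGraph(1L, Tn = 3L), makeRandomGraph(0L, Tn = 3L))
  cfg <- gatConfig(d0 = 3L, dh = 4L, heads = 2L, dropout = 0)
  params <- initGatParams(cfg)
  prep <- prepareGraphs(graphs)
  batch <- akigraph:::makeBatch(prep, 1:2)
  fw <- akigraph:::gatBatchForward(params, cfg, batch, training = TRUE,
                                   keepCache = TRUE)
  grads <- akigraph:::gatBatchBackward(params, cfg, batch, fw,
                                       (fw$prob - batch$y) / 2)
  flatG <- flattenParams(grads)
  flatP <- flattenParams(params)
  lossAt <- function(v) {
    p <- unflattenParams(v, cfg)
    akigraph:::bceLoss(akigraph:::gatBatchForward(p, cfg, batch)$prob,
                       batch$y)
  }
  eps <- 1e-5
  idx <- sample(length(flatP), 50)
  for (i in idx) {
    e <- flatP
    e[i] <- flatP[i] + eps
    up <- lossAt(e)
    e[i] <- flatP[i] - eps
    dn <- lossAt(e)
    num <- (up - dn) / (2 * eps)
    denom <- max(1e-6, abs(num) + abs(flatG[i]))
    expect_lt(abs(num - flatG[i]) / denom, 1e-4)
  }
})

test_that("flatten/unflatten is an exact inverse pair with correct count", {
  set.seed(53)
  cfg <- gatConfig(d0 = 3L, dh = 5L, heads = 3L, dropout = 0.3)
  params <- initGatParams(cfg)
  flat <- flattenParams(params)
  expect_identical(unflattenParams(flat, cfg), params)
  expect_identical(length(flat), parameterCount(params))
  expect_error(unflattenParams(flat[-1], cfg), "length")
  ## payload: 4 bytes per FP32 parameter, or an explicit override
  model <- new("GatModel", params = params, config = cfg,
               payloadOverride = NA_real_)
  expect_equal(payloadBytes(model), 4 * length(flat))
  expect_equal(payloadBytes(model, overrideBytes = 27e6), 27e6)
  model@payloadOverride <- 27e6
  expect_equal(payloadBytes(model), 27e6)
})

test_that("the default architecture matches the published dimensioning", {
  cfg <- gatConfig()
  expect_identical(cfg@dh, 64L)
  expect_identical(cfg@heads, 8L)
  ## layer-1 concat output: 8 x 64 = 512
  params <- local({
    set.seed(1)
    initGatParams(cfg)
  })
  expect_identical(dim(params$layer2[[1]]$W), c(64L, 512L))
  expect_identical(dim(params$W1), c(64L, 3L))
  expect_length(params$layer1[[1]]$a, 128L)
})

test_that("model checkpoints round-trip losslessly through JSON", {
  set.seed(59)
  cfg <- gatConfig(d0 = 3L, dh = 4L, heads = 2L)
  model <- new("GatModel", params = initGatParams(cfg), config = cfg,
               payloadOverride = NA_real_)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(model, path)
  back <- loadModel(path)
  expect_equal(flattenParams(back@params), flattenParams(model@params))
  expect_identical(back@config@dh, cfg@dh)
})
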