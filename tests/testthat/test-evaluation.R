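test_that("threshold metrics reproduce hand-computed confusion counts", {
  ## TP=2, FP=1, FN=1, TN=2 -> MCC = 1/3
  y <- c(1, 1, 1, 0, 0, 0)
  p <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.3)
  m <- thresholdMetrics(predictionSet(y, p))
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(2L, 1L, 1L, 2L))
  expect_equal(m$mcc, 1 / 3)
  ## independent covariance-form oracle for the MCC
  pred <- as.integer(p >= 0.5)
  mccCov <- cov(pred, y) / sqrt(var(pred) * var(y))
  expect_equal(m$mcc, mccCov, tolerance = 1e-12)
  ## perfect predictions
  mp <- thresholdMetrics(predictionSet(c(0, 1), c(0.1, 0.9)))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$mcc, 1)
})

test_that("degenerate rates are reported as undefined, not zero", {
  ## all-positive predictor at prevalence pi
  y <- c(rep(1, 3), rep(0, 7))
  m <- thresholdMetrics(predictionSet(y, rep(1, 10)))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$accuracy, 0.3)
  ## no predicted positives: precision undefined
  m0 <- thresholdMetrics(predictionSet(y, rep(0, 10)))
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$mcc))
})

test_that("AUROC matches the worked example and exhaustive concordance", {
  ps <- predictionSet(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(auroc(ps), 0.75)
  expect_equal(auroc(predictionSet(c(0, 1), c(0.2, 0.9))), 1)
  expect_equal(auprc(predictionSet(c(0, 1), c(0.2, 0.9))), 1)
  ## tie convention: constant scores give exactly 0.5
  expect_equal(auroc(predictionSet(c(0, 1, 0, 1), rep(0.4, 4))), 0.5)
  expect_error(auroc(predictionSet(c(1, 1), c(0.2, 0.9))), "both classes")
  ## exhaustive pairwise concordance oracle on random sets
  set.seed(61)
  for (rep in 1:300) {
    n <- sample(8:40, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- round(runif(n), 2) # coarse grid forces ties
    conc <- 0
    tot <- 0
    for (i in which(y == 1)) {
      for (j in which(y == 0)) {
        tot <- tot + 1
        conc <- conc + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
      }
    }
    expect_equal(auroc(predictionSet(y, p)), conc / tot, tolerance = 1e-10)
  }
})

test_that("Brier score and log loss have their closed forms", {
  y <- rbinom(50, 1, 0.5)
  half <- predictionSet(y, rep(0.5, 50))
  expect_equal(brierScore(half), 0.25)
  expect_equal(logLoss(half), log(2))
  perf <- predictionSet(c(0, 1), c(0, 1))
  expect_equal(brierScore(perf), 0)
  ## definitional identity with mean squared error
  set.seed(67)
  p <- runif(50)
  expect_equal(brierScore(predictionSet(y, p)), mean((p - y)^2))
})

test_that("DeLong's test handles self-comparison, sign and order symmetry", {
  set.seed(71)
  y <- rbinom(120, 1, 0.3)
  y[1:2] <- c(0, 1)
  pA <- plogis(rnorm(120) + 1.2 * y)
  pB <- plogis(rnorm(120) + 0.4 * y)
  a <- predictionSet(y, pA, "A")
  b <- predictionSet(y, pB, "B")
  self <- delongTest(a, a)
  expect_equal(self$z, 0)
  expect_equal(self$pValue, 1)
  d <- delongTest(a, b)
  expect_equal(sign(d$z), sign(auroc(a) - auroc(b)))
  ## swapping the model order negates z exactly
  d2 <- delongTest(b, a)
  expect_equal(d2$z, -d$z)
  expect_equal(d2$pValue, d$pValue)
  expect_equal(d$aucA, auroc(a))
})

test_that("DeLong agrees with pROC and the bootstrap variance", {
  skip_if_not_installed("pROC")
  set.seed(73)
  y <- rbinom(200, 1, 0.35)
  y[1:2] <- c(0, 1)
  pA <- plogis(rnorm(200) + 1.5 * y)
  pB <- plogis(rnorm(200) + 0.5 * y)
  d <- delongTest(predictionSet(y, pA), predictionSet(y, pB))
  ref <- pROC::roc.test(
    pROC::roc(y, pA, quiet = TRUE), pROC::roc(y, pB, quiet = TRUE),
    method = "delong", paired = TRUE
  )
  expect_equal(unname(d$z), unname(ref$statistic), tolerance = 1e-8)
  expect_equal(d$pValue, ref$p.value, tolerance = 1e-8)
  ## bootstrap oracle for the variance of the AUC difference
  set.seed(74)
  boots <- vapply(1:5000, function(i) {
    idx <- sample(200, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auroc(predictionSet(y[idx], pA[idx])) -
      auroc(predictionSet(y[idx], pB[idx]))
  }, numeric(1))
  expect_lt(abs(sd(boots, na.rm = TRUE) - d$se) / d$se, 0.10)
})

test_that("Hosmer-Lemeshow vanishes on perfectly matched bins", {
  ## two hand-built bins with observed = expected
  p <- c(rep(0.2, 5), rep(0.8, 5))
  y <- c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0)
  hl <- hosmerLemeshow(predictionSet(y, p), bins = 2L)
  expect_equal(hl$statistic, 0)
  expect_identical(hl$df, 0L)
  ## degenerate constant probabilities cannot be binned
  expect_error(hosmerLemeshow(predictionSet(y, rep(0.5, 10)), bins = 2L),
               "degenerate")
})

test_that("the Hosmer-Lemeshow statistic follows its null distribution", {
  ## With externally specified probabilities (no fitting step) the statistic
  ## is chi-square with df = bins; the reported df = bins - 2 is the
  ## convention for internally fitted models. The null check therefore
  ## converts the statistic with the simulation's own df.
  set.seed(79)
  stats <- vapply(1:200, function(i) {
    p <- runif(400, 0.05, 0.95)
    y <- rbinom(400, 1, p)
    hosmerLemeshow(predictionSet(y, p), bins = 10L)$statistic
  }, numeric(1))
  pvals <- pchisq(stats, df = 10, lower.tail = FALSE)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})

test_that("the accuracy chi-square matches the textbook Pearson computation", {
  set.seed(83)
  y <- rbinom(200, 1, 0.3)
  pA <- runif(200)
  pB <- runif(200)
  a <- predictionSet(y, pA)
  b <- predictionSet(y, pB)
  cs <- chiSquareAccuracy(a, b)
  ref <- suppressWarnings(chisq.test(cs$table, correct = FALSE))
  expect_equal(cs$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cs$pValue, ref$p.value, tolerance = 1e-12)
  ## identical models: statistic 0, p = 1
  same <- chiSquareAccuracy(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)
  ## symmetric in model order
  expect_equal(chiSquareAccuracy(b, a)$statistic, cs$statistic)
  ## hand-checked counts [[90,10],[50,50]]
  yh <- rep(1, 100)
  ph1 <- c(rep(1, 90), rep(0, 10))
  ph2 <- c(rep(1, 50), rep(0, 50))
  h <- chiSquareAccuracy(predictionSet(yh, ph1), predictionSet(yh, ph2))
  expect_equal(h$statistic,
               unname(suppressWarnings(chisq.test(
                 rbind(c(90, 10), c(50, 50)), correct = FALSE))$statistic),
               tolerance = 1e-12)
})

test_that("net benefit follows its closed form and DCA bounds hold", {
  ## N=100, TP=18, FP=10, pt=0.2 -> 0.155
  y <- c(rep(1, 20), rep(0, 80))
  p <- c(rep(0.9, 18), rep(0.1, 2), rep(0.9, 10), rep(0.1, 70))
  ps <- predictionSet(y, p)
  expect_equal(netBenefit(ps, 0.2), 0.18 - 0.10 * 0.25)
  expect_error(netBenefit(ps, 1), "threshold")
  ## treat-none is 0; treat-all breaks even at pt = prevalence
  curve <- dcaCurve(ps, thresholds = c(0.2, exp(1) / (1 + exp(1))))
  expect_true(all(curve$treatNone == 0))
  prev <- 0.2
  expect_equal(curve$treatAll[1], prev - (1 - prev) * 0.2 / 0.8)
  ## model net benefit never exceeds the prevalence
  set.seed(89)
  for (rep in 1:20) {
    yr <- rbinom(60, 1, 0.3)
    pr <- runif(60)
    for (pt in c(0.1, 0.3, 0.5)) {
      expect_lte(netBenefit(predictionSet(yr, pr), pt), mean(yr))
    }
  }
  ## treat-all at pi = 0.15, pt = 0.15 is exactly zero
  y15 <- c(rep(1, 15), rep(0, 85))
  all15 <- predictionSet(y15, rep(1, 100))
  expect_equal(netBenefit(all15, 0.15), 0.15 - 0.85 * 0.15 / 0.85,
               tolerance = 1e-12)
})

test_that("MetricReport bounds hold on fuzzed inputs", {
  set.seed(97)
  for (rep in 1:30) {
    n <- sample(10:100, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- runif(n)
    m <- metricReport(predictionSet(y, p))
    rates <- unlist(m[c("accuracy", "sensitivity", "specificity",
                        "precision", "f1", "auroc", "auprc")])
    rates <- rates[!is.na(rates)]
    expect_true(all(rates >= 0 & rates <= 1))
    if (!is.na(m$mcc)) expect_true(abs(m$mcc) <= 1)
    expect_identical(m$tp + m$fp + m$tn + m$fn, n)
  }
})

test_that("attention importance is a normalized, symmetric-at-init score", {
  set.seed(101)
  ## identical features + full connectivity: neutral model is near-uniform
  A <- matrix(0.5, 12, 12)
  diag(A) <- 0
  feats <- array(rep(rnorm(4 * 3), each = 12), c(12, 4, 3))
  g <- new("FeatureGraph", nodeIds = akiFeatures(), adjacency = A,
           nodeFeatures = feats, label = 1L, patientId = "U", endHour = 4L)
  cfg <- gatConfig(d0 = 3L, dh = 6L, heads = 2L, dropout = 0)
  model <- new("GatModel", params = initGatParams(cfg), config = cfg,
               payloadOverride = NA_real_)
  sc <- attentionImportance(model, list(g))
  expect_equal(sum(sc), 1)
  expect_lt(max(abs(sc - 1 / 12)), 1e-9)
  ## general graphs still normalize to one
  gs <- lapply(1:3, function(i) makeRandomGraph(Tn = 4L))
  sc2 <- attentionImportance(model, gs)
  expect_equal(sum(sc2), 1)
  expect_named(sc2, akiFeatures())
})
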