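## Evaluation battery: threshold metrics, ranking metrics, calibration,
## paired model-comparison tests, decision-curve analysis, attention-based
## feature importance.

checkBothClasses <- function(y) {
  if (length(unique(y)) < 2L) stop("both classes must be present")
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Classifies at \code{probability >= threshold} and reports the standard
#' confusion-derived rates plus the Matthews correlation coefficient (MCC,
#' four-count closed form). Rates with a zero denominator are reported as
#' \code{NA} (undefined), never coerced to 0.
#'
#' @param preds A \code{\link{predictionSet}}.
#' @param threshold Classification threshold (default 0.5).
#' @return Named list: \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{precision}, \code{f1}, \code{mcc}.
#' @export
thresholdMetrics <- function(preds, threshold = 0.5) {
  y <- preds@labels
  pos <- preds@probabilities >= threshold
  tp <- sum(pos & y == 1L)
  fp <- sum(pos & y == 0L)
  tn <- sum(!pos & y == 0L)
  fn <- sum(!pos & y == 1L)
  safeDiv <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safeDiv(tp, tp + fn)
  spec <- safeDiv(tn, tn + fp)
  prec <- safeDiv(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  mccDen <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mccDen == 0) NA_real_
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mccDen)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y), sensitivity = sens,
       specificity = spec, precision = prec, f1 = f1, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outranks a random negative, ties counted one half.
#'
#' @param preds A \code{\link{predictionSet}}.
#' @return AUROC in [0, 1].
#' @export
#' @examples
#' auroc(predictionSet(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))) # 0.75
auroc <- function(preds) {
  y <- preds@labels
  checkBothClasses(y)
  p <- preds@probabilities
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration (average precision): thresholds sweep the distinct
#' predicted probabilities from high to low, and each recall increment is
#' weighted by the precision at that threshold — no linear interpolation
#' between operating points.
#'
#' @param preds A \code{\link{predictionSet}}.
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(preds) {
  y <- preds@labels
  checkBothClasses(y)
  p <- preds@probabilities
  ord <- order(p, decreasing = TRUE)
  yo <- y[ord]
  po <- p[ord]
  ## group ties: one operating point per distinct threshold
  grp <- cumsum(!duplicated(po))
  tpCum <- cumsum(yo)
  nCum <- seq_along(yo)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tpCum[last]
  n <- nCum[last]
  prec <- tp / n
  recall <- tp / sum(y == 1L)
  dRecall <- diff(c(0, recall))
  sum(dRecall * prec)
}

#' Brier score and log loss
#'
#' \code{brierScore}: mean squared difference between predicted probability
#' and outcome. \code{logLoss}: mean negative log-likelihood with
#' probabilities clipped to [eps, 1 - eps] (eps = 1e-15).
#'
#' @param preds A \code{\link{predictionSet}}.
#' @param eps Clipping constant for the log loss.
#' @return Numeric scalar.
#' @export
brierScore <- function(preds) {
  mean((preds@probabilities - preds@labels)^2)
}

#' @rdname brierScore
#' @export
logLoss <- function(preds, eps = 1e-15) {
  bceLoss(preds@probabilities, preds@labels, eps)
}

#' Combined metric report
#'
#' @param preds A \code{\link{predictionSet}}.
#' @param threshold Classification threshold.
#' @return Named list combining \code{\link{thresholdMetrics}},
#'   \code{\link{auroc}}, \code{\link{auprc}}, \code{\link{brierScore}} and
#'   \code{\link{logLoss}}.
#' @export
metricReport <- function(preds, threshold = 0.5) {
  c(thresholdMetrics(preds, threshold),
    list(auroc = auroc(preds), auprc = auprc(preds),
         brier = brierScore(preds), logLoss = logLoss(preds)))
}

#' DeLong's paired test for two correlated AUCs
#'
#' Computes placement values (mid-rank structural components) per observation
#' for both models on the shared labels, the covariance of the AUC
#' difference, and the normal z statistic
#' \code{z = (AUC_A - AUC_B) / se}.
#'
#' @param predsA,predsB \code{\link{predictionSet}}s over the same labels.
#' @return List: \code{aucA}, \code{aucB}, \code{z}, \code{pValue}, \code{se}.
#' @export
delongTest <- function(predsA, predsB) {
  y <- predsA@labels
  if (!identical(y, predsB@labels)) {
    stop("both prediction sets must share the same labels")
  }
  checkBothClasses(y)
  placements <- function(p) {
    x <- p[y == 1L]
    w <- p[y == 0L]
    n1 <- length(x)
    n0 <- length(w)
    rAll <- rank(c(x, w), ties.method = "average")
    v10 <- (rAll[seq_len(n1)] - rank(x, ties.method = "average")) / n0
    v01 <- 1 - (rAll[n1 + seq_len(n0)] - rank(w, ties.method = "average")) / n1
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- placements(predsA@probabilities)
  b <- placements(predsB@probabilities)
  n1 <- length(a$v10)
  n0 <- length(a$v01)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  dAuc <- a$auc - b$auc
  if (varDiff <= 0) {
    if (abs(dAuc) < 1e-12) {
      return(list(aucA = a$auc, aucB = b$auc, z = 0, pValue = 1, se = 0))
    }
    stop("zero variance of the AUC difference with unequal AUCs")
  }
  se <- sqrt(varDiff)
  z <- dAuc / se
  list(aucA = a$auc, aucB = b$auc, z = z,
       pValue = 2 * stats::pnorm(-abs(z)), se = se)
}

#' Hosmer-Lemeshow calibration test
#'
#' Equal-frequency bins by predicted probability (ties broken by original
#' index, i.e. \code{rank(..., ties.method = "first")}), with the statistic
#' \code{sum (O - E)^2 / (E (1 - E / n_g))} over bins and df = bins - 2.
#'
#' @param preds A \code{\link{predictionSet}}.
#' @param bins Number of bins (default 10).
#' @return List: \code{statistic}, \code{df}, \code{pValue}, \code{table}
#'   (per-bin n, expected and observed events).
#' @export
hosmerLemeshow <- function(preds, bins = 10L) {
  y <- preds@labels
  p <- preds@probabilities
  n <- length(y)
  if (n < bins) stop("need at least as many observations as bins")
  if (length(unique(p)) < 2L) {
    stop("degenerate predictions: all probabilities identical; cannot bin")
  }
  bin <- ceiling(rank(p, ties.method = "first") * bins / n)
  tab <- data.frame(
    bin = seq_len(bins),
    n = as.vector(tabulate(bin, bins)),
    observed = as.vector(rowsum(as.numeric(y), bin)[, 1]),
    expected = as.vector(rowsum(p, bin)[, 1])
  )
  if (any(tab$n == 0L)) stop("empty bin; use fewer bins")
  denom <- tab$expected * (1 - tab$expected / tab$n)
  if (any(denom <= 0)) {
    stop("bin with zero expected variance; use fewer bins")
  }
  stat <- sum((tab$observed - tab$expected)^2 / denom)
  df <- bins - 2L
  list(statistic = stat, df = df,
       pValue = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Chi-square test comparing two models' classification accuracy
#'
#' Builds the 2 x 2 contingency table of correct/incorrect counts per model
#' and applies the Pearson chi-square test with 1 degree of freedom, without
#' continuity correction.
#'
#' @param predsA,predsB \code{\link{predictionSet}}s over the same labels.
#' @param threshold Classification threshold (default 0.5).
#' @return List: \code{statistic}, \code{pValue}, \code{table}.
#' @export
chiSquareAccuracy <- function(predsA, predsB, threshold = 0.5) {
  y <- predsA@labels
  if (!identical(y, predsB@labels)) {
    stop("both prediction sets must share the same labels")
  }
  corrA <- (predsA@probabilities >= threshold) == (y == 1L)
  corrB <- (predsB@probabilities >= threshold) == (y == 1L)
  tab <- rbind(
    A = c(correct = sum(corrA), incorrect = sum(!corrA)),
    B = c(correct = sum(corrB), incorrect = sum(!corrB))
  )
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd == 0)) stop("empty cells in the accuracy contingency table")
  stat <- sum((tab - expd)^2 / expd)
  list(statistic = stat,
       pValue = stats::pchisq(stat, df = 1L, lower.tail = FALSE), table = tab)
}

#' Net benefit at a threshold probability
#'
#' \code{NB = TP/N - (FP/N) * p_t / (1 - p_t)}, classifying at
#' \code{probability >= p_t}. The treat-none strategy has net benefit 0 and
#' treat-all has \code{pi - (1 - pi) * p_t / (1 - p_t)} at prevalence pi.
#'
#' @param preds A \code{\link{predictionSet}}.
#' @param pt Threshold probability in (0, 1).
#' @return Numeric scalar.
#' @export
netBenefit <- function(preds, pt) {
  if (pt <= 0 || pt >= 1) stop("threshold probability must lie in (0, 1)")
  y <- preds@labels
  n <- length(y)
  pos <- preds@probabilities >= pt
  tp <- sum(pos & y == 1L)
  fp <- sum(pos & y == 0L)
  tp / n - (fp / n) * pt / (1 - pt)
}

#' Decision-curve analysis table
#'
#' Net benefit of the model, the treat-all strategy and the treat-none
#' strategy across threshold probabilities.
#'
#' @param preds A \code{\link{predictionSet}}.
#' @param thresholds Vector of threshold probabilities (default 0.1-0.6).
#' @return Data frame: threshold, netBenefit, treatAll, treatNone.
#' @export
dcaCurve <- function(preds, thresholds = seq(0.1, 0.6, by = 0.1)) {
  prev <- mean(preds@labels)
  data.frame(
    threshold = thresholds,
    netBenefit = vapply(thresholds, function(pt) netBenefit(preds, pt),
                        numeric(1)),
    treatAll = prev - (1 - prev) * thresholds / (1 - thresholds),
    treatNone = 0
  )
}

#' Attention-based feature importance
#'
#' Runs the model over the graphs in evaluation mode and, for every feature
#' node, averages the normalized attention coefficients it receives across
#' patients, time steps, heads and incident edges of the first attention
#' layer; scores are renormalized to sum to 1. Self-loops are excluded: they
#' are an attention convention rather than graph edges, and their
#' coefficients dominate low-degree nodes (an isolated node pays itself
#' attention 1), which would invert the ranking. Deterministic given model
#' and data.
#'
#' @param model A \code{GatModel}.
#' @param graphs List of \code{FeatureGraph}.
#' @param layer Attention layer to read (1 or 2; default 1).
#' @return Named numeric vector of length 12 summing to 1.
#' @export
attentionImportance <- function(model, graphs, layer = 1L) {
  prep <- prepareGraphs(graphs)
  N <- prep$N
  recvSum <- numeric(N)
  recvCnt <- numeric(N)
  chunk <- 128L
  nG <- length(prep$y)
  for (start in seq(1L, nG, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nG)
    batch <- makeBatch(prep, idx)
    fw <- gatBatchForward(model@params, model@config, batch,
                          training = FALSE, keepCache = TRUE)
    caches <- if (layer == 1L) fw$cache$l1 else fw$cache$l2
    for (ch in caches) {
      ## pair p = i + (j-1)N: attention paid by receiver i to sender j
      aSum <- .rowSums(ch$alpha, N * N, batch$S)
      mSum <- .rowSums(batch$M, N * N, batch$S)
      bySender <- matrix(aSum, N, N) # [i, j]
      cntSender <- matrix(mSum, N, N)
      ## drop self-loops: count only mass arriving over actual graph edges
      diag(bySender) <- 0
      diag(cntSender) <- 0
      recvSum <- recvSum + colSums(bySender)
      recvCnt <- recvCnt + colSums(cntSender)
    }
  }
  score <- ifelse(recvCnt > 0, recvSum / recvCnt, 0)
  score <- score / sum(score)
  names(score) <- graphs[[1]]@nodeIds
  score
}
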