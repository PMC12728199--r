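## Patient-specific feature graphs: windowing, imputation, thresholded
## Pearson edges, short temporal node features.

#' Extract the pre-prediction window from a record
#'
#' Returns the last \code{spec@windowHours} hours of the series ending at
#' \code{endHour}. Records shorter than the window are padded at the front by
#' repeating the first row inside the window (values and missingness alike),
#' so the output always has exactly \code{windowHours} rows.
#'
#' @param record A \code{PatientRecord}.
#' @param spec A \code{\link{windowSpec}}.
#' @param endHour Window end hour (1-based, inclusive).
#' @return List with \code{series} (windowHours x 12, \code{NA} at missing
#'   cells) and \code{padded} (number of padded leading rows).
#' @export
extractWindow <- function(record, spec, endHour) {
  L <- nrow(record@series)
  endHour <- as.integer(endHour)
  if (endHour < 1L) stop("endHour precedes the first observation")
  if (endHour > L) stop("endHour exceeds record length")
  start <- endHour - spec@windowHours + 1L
  rows <- max(1L, start):endHour
  W <- record@series[rows, , drop = FALSE]
  nPad <- spec@windowHours - length(rows)
  if (nPad > 0L) {
    W <- rbind(W[rep(1L, nPad), , drop = FALSE], W)
  }
  rownames(W) <- NULL
  list(series = W, padded = nPad)
}

#' Impute a windowed series
#'
#' Forward-fills each feature within the window, then replaces remaining
#' leading gaps by the supplied per-feature training means (or, when absent,
#' the window mean; an entirely missing feature falls back to 0, i.e. the
#' z-scored population mean).
#'
#' @param window Numeric matrix (hours x features) with \code{NA} gaps.
#' @param featureMeans Optional per-feature fallback means.
#' @return Numeric matrix with no missing entries.
#' @export
imputeWindow <- function(window, featureMeans = NULL) {
  out <- window
  for (f in seq_len(ncol(out))) {
    x <- out[, f]
    obs <- !is.na(x)
    if (any(obs)) {
      obsMean <- mean(x[obs])
      idx <- cummax(ifelse(obs, seq_along(x), 0L))
      x[idx > 0L] <- x[idx[idx > 0L]]
      if (any(idx == 0L)) {
        fb <- if (!is.null(featureMeans)) featureMeans[f] else obsMean
        x[idx == 0L] <- fb
      }
    } else {
      x[] <- if (!is.null(featureMeans)) featureMeans[f] else 0
    }
    out[, f] <- x
  }
  out
}

#' Thresholded Pearson correlation edges
#'
#' Computes the signed adjacency \code{w_ij = Pearson(x_i, x_j)} whenever
#' \code{|Pearson| > threshold} and 0 otherwise. Zero-variance features yield
#' zero rows/columns; the diagonal is zero (self-loops are a property of the
#' attention neighborhood, not of the adjacency).
#'
#' @param window Fully imputed numeric matrix (hours x features).
#' @param threshold Absolute correlation threshold in (0, 1).
#' @return Symmetric signed weight matrix.
#' @export
#' @examples
#' w <- computeEdges(cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3)), 0.3)
#' w["a", "b"] # 0.6
computeEdges <- function(window, threshold) {
  if (nrow(window) < 3L) stop("need at least 3 time points to estimate edges")
  if (nrow(unique(window)) < 2L) stop("fewer than 2 distinct time points")
  R <- suppressWarnings(stats::cor(window))
  R[is.na(R)] <- 0
  R[abs(R) <= threshold] <- 0
  diag(R) <- 0
  R
}

#' Short temporal node feature vectors
#'
#' Builds the initial node state \code{h_(i,t) = [x_(i,t), x_(i,t-1), ...,
#' x_(i,t-s+1)]} -- most recent value first -- for every node and time step.
#' The window is front-padded by repeating its first row, so every t in
#' 1..T is usable and T equals the window length.
#'
#' @param window Fully imputed numeric matrix (T x N).
#' @param historySteps Temporal depth s (default 3).
#' @return Array N x T x historySteps.
#' @export
temporalNodeFeatures <- function(window, historySteps = 3L) {
  Tn <- nrow(window)
  if (Tn < 1L) stop("empty window")
  N <- ncol(window)
  out <- array(0, dim = c(N, Tn, historySteps))
  for (s in seq_len(historySteps)) {
    rows <- pmax(seq_len(Tn) - (s - 1L), 1L)
    out[, , s] <- t(window[rows, , drop = FALSE])
  }
  out
}

## sample() that treats a length-1 vector as a single candidate
sampleOne <- function(v) if (length(v) == 1L) v else sample(v, 1L)

## Pick the window end hour: for positives, horizonMin..horizonMax hours
## before onset; for negatives, a seeded-random observed hour.
pickEndHour <- function(record, spec) {
  L <- nrow(record@series)
  if (record@label == 1L && !is.na(record@akiOnsetHour)) {
    horizon <- sampleOne(spec@horizonMin:spec@horizonMax)
    max(3L, record@akiOnsetHour - horizon)
  } else {
    ## start at hour 3 so the window always spans >= 3 observed rows
    sampleOne(min(3L, L):L)
  }
}

#' Build a patient's feature graph
#'
#' Composes window extraction, imputation, thresholded Pearson edges and
#' temporal node features into a \code{\link{FeatureGraph-class}}. The
#' adjacency is static within the window (one correlation estimate over the
#' whole window); node features vary over time. When \code{endHour} is
#' \code{NULL} it is chosen per the labeling contract: positive windows end
#' \code{horizonMin}-\code{horizonMax} hours before onset (horizon drawn from
#' the current RNG stream), negative windows end at a random hour.
#'
#' @param record A \code{PatientRecord}.
#' @param spec A \code{\link{windowSpec}}.
#' @param endHour Window end hour, or \code{NULL} to choose automatically.
#' @param featureMeans Optional per-feature imputation fallback means.
#' @return A \code{FeatureGraph}.
#' @export
buildGraph <- function(record, spec, endHour = NULL, featureMeans = NULL) {
  if (is.null(endHour)) endHour <- pickEndHour(record, spec)
  win <- extractWindow(record, spec, endHour)
  X <- imputeWindow(win$series, featureMeans)
  A <- computeEdges(X, spec@corrThreshold)
  H <- temporalNodeFeatures(X, spec@historySteps)
  new("FeatureGraph",
    nodeIds = colnames(record@series), adjacency = A, nodeFeatures = H,
    label = record@label, patientId = record@patientId,
    endHour = as.integer(endHour)
  )
}

#' Build feature graphs for a whole cohort
#'
#' @param cohort An \code{AkiCohort} (typically z-score normalized).
#' @param spec A \code{\link{windowSpec}}.
#' @param seed RNG seed for horizon and negative-window draws (per-cohort).
#' @param featureMeans Optional per-feature imputation fallback means.
#' @return List of \code{FeatureGraph}, one per usable record. Records
#'   shorter than 3 hours cannot support a correlation estimate and are
#'   dropped with a warning.
#' @export
buildGraphs <- function(cohort, spec = windowSpec(), seed = 1L,
                        featureMeans = NULL) {
  usable <- recordLengths(cohort) >= 3L
  if (any(!usable)) {
    warning(sprintf("dropping %d record(s) shorter than 3 hours",
                    sum(!usable)))
  }
  set.seed(seed)
  lapply(cohort@records[usable], buildGraph, spec = spec, endHour = NULL,
         featureMeans = featureMeans)
}

#' Mean per-window correlation structure of a cohort
#'
#' Averages the per-patient window Pearson correlation matrices (unit
#' diagonal; undefined correlations from zero-variance features counted as
#' 0), mirroring the population-level correlation maps used to interpret the
#' graph topology.
#'
#' @param cohort An \code{AkiCohort}.
#' @param spec A \code{\link{windowSpec}}.
#' @param seed Seed for window placement.
#' @return Symmetric 12 x 12 matrix with unit diagonal.
#' @export
correlationSummary <- function(cohort, spec = windowSpec(), seed = 1L) {
  set.seed(seed)
  mats <- lapply(cohort@records[recordLengths(cohort) >= 3L], function(r) {
    win <- extractWindow(r, spec, pickEndHour(r, spec))
    X <- imputeWindow(win$series)
    R <- suppressWarnings(stats::cor(X))
    R[is.na(R)] <- 0
    diag(R) <- 1
    R
  })
  out <- Reduce(`+`, mats) / length(mats)
  dimnames(out) <- list(akiFeatures(), akiFeatures())
  out
}
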