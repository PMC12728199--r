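## Synthetic ICU cohort generation, KDIGO labeling, normalization, splitting.

#' Default cross-feature correlation structure of the synthetic cohort
#'
#' Encodes the physiological dependence blocks the graph construction relies
#' on: the blood-pressure triplet (SBP/DBP/MAP), renal markers
#' (creatinine-BUN), perfusion (lactate against MAP/SBP/pH, lactate-HR),
#' infection/stress (HR-Temp, WBC-Temp) and respiration (Resp-O2Sat). The
#' matrix is verified symmetric positive definite at construction.
#'
#' @return A 12 x 12 correlation matrix with feature names as dimnames.
#' @export
defaultCorrelationSpec <- function() {
  f <- akiFeatures()
  R <- diag(12)
  dimnames(R) <- list(f, f)
  set2 <- function(R, a, b, r) {
    R[a, b] <- r; R[b, a] <- r; R
  }
  R <- set2(R, "SBP", "DBP", 0.60)
  R <- set2(R, "SBP", "MAP", 0.75)
  R <- set2(R, "DBP", "MAP", 0.75)
  R <- set2(R, "Creatinine", "BUN", 0.60)
  R <- set2(R, "Lactate", "MAP", -0.40)
  R <- set2(R, "Lactate", "SBP", -0.25)
  R <- set2(R, "Lactate", "pH", -0.45)
  R <- set2(R, "Lactate", "HR", 0.30)
  R <- set2(R, "HR", "Temp", 0.40)
  R <- set2(R, "WBC", "Temp", 0.35)
  R <- set2(R, "Resp", "O2Sat", -0.35)
  R <- set2(R, "O2Sat", "Lactate", -0.25)
  R
}

## Marginal scales of the 12 features: population mean, between-patient sd of
## the per-patient baseline, within-patient (hour-to-hour) sd, and floors/caps.
featureMarginals <- function() {
  data.frame(
    feature = akiFeatures(),
    mean = c(0.9, 120, 70, 87, 85, 37, 18, 1.6, 97, 18, 7.38, 9),
    betweenSd = c(0.18, 12, 8, 9, 12, 0.3, 3, 0.5, 1.5, 5, 0.03, 2.5),
    withinSd = c(0.05, 10, 7, 8, 8, 0.4, 3, 0.6, 2, 2, 0.04, 1.5),
    lower = c(0.2, 60, 30, 40, 30, 34, 5, 0.2, 70, 3, 6.9, 0.5),
    upper = c(15, 220, 140, 160, 200, 42, 60, 20, 100, 120, 7.8, 50),
    stringsAsFactors = FALSE
  )
}

## AR(1) innovation mixing: stationary cross-correlation of the latent process
## equals correlationSpec when all features share the same phi.
arPhi <- 0.6

#' Generate a synthetic ICU cohort
#'
#' Draws per-patient hourly series for the 12 physiological features from a
#' Gaussian-copula AR(1) process whose stationary cross-correlation matches
#' \code{config@correlationSpec}, with feature-wise marginal location/scale
#' transforms and physiological range clipping. Intended AKI-positive patients
#' (Bernoulli at the target prevalence) receive the planted pre-onset drift of
#' \code{config@plantedSignal}; every record is then labeled with the KDIGO
#' rule, so stored labels and onset hours are always rule-consistent. Positive
#' records are truncated at onset by default.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @param rule A \code{\link{kdigoRule}} used to label the generated records.
#' @param truncateAtOnset Truncate positive records at the intended onset hour
#'   (default \code{TRUE}).
#' @return An \code{\link{akiCohort}}.
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(nPatients = 50, seed = 1))
#' mean(akiLabels(cohort))
generateCohort <- function(config, rule = kdigoRule(), truncateAtOnset = TRUE) {
  validObject(config)
  set.seed(config@seed)
  marg <- featureMarginals()
  Rchol <- chol(config@correlationSpec)
  sig <- config@plantedSignal
  drift <- as.integer(sig$driftHours)
  records <- vector("list", config@nPatients)
  for (p in seq_len(config@nPatients)) {
    intendedPositive <- stats::rbinom(1, 1, config@prevalence) == 1
    L <- as.integer(round(stats::rnorm(1, config@lengthMean, config@lengthSd)))
    L <- max(1L, min(336L, L))
    if (intendedPositive) {
      L <- max(L, drift + 6L)
      onset <- if (L > drift + 2L) sample((drift + 2L):L, 1L) else (drift + 2L)
    } else {
      onset <- NA_integer_
    }
    len <- if (intendedPositive && truncateAtOnset) onset else L
    ## latent AR(1) with cross-correlated innovations
    E <- matrix(stats::rnorm(len * 12L), len, 12L) %*% Rchol
    Z <- E
    if (len > 1L) {
      w <- sqrt(1 - arPhi^2)
      for (t in 2:len) Z[t, ] <- arPhi * Z[t - 1L, ] + w * E[t, ]
    }
    base <- marg$mean + stats::rnorm(12L) * marg$betweenSd
    X <- sweep(Z, 2L, marg$withinSd, `*`)
    X <- sweep(X, 2L, base, `+`)
    if (intendedPositive) {
      X <- addPlantedDrift(X, onset, sig)
    }
    X <- pmin(pmax(X, rep(marg$lower, each = len)), rep(marg$upper, each = len))
    colnames(X) <- akiFeatures()
    ## missingness: MCAR, but keep admission creatinine (baseline) and the
    ## terminal creatinine rise observable so the planted label is decidable
    M <- matrix(stats::runif(len * 12L) < config@missingRate, len, 12L)
    M[1L, 1L] <- FALSE
    if (intendedPositive) {
      keep <- max(1L, onset - 1L):min(len, onset)
      M[keep, 1L] <- FALSE
    }
    X[M] <- NA_real_
    rec <- patientRecord(sprintf("P%05d", p), X)
    lab <- labelAki(rec, rule)
    rec@label <- lab$label
    rec@akiOnsetHour <- lab$onsetHour
    records[[p]] <- rec
  }
  akiCohort(records)
}

## Linear pre-onset drift: slow creatinine creep plus a steep terminal rise
## that makes the KDIGO absolute-rise branch fire at (about) the intended
## onset, with hemodynamic precursors over the whole drift window.
addPlantedDrift <- function(X, onset, sig) {
  len <- nrow(X)
  drift <- as.integer(sig$driftHours)
  t0 <- max(1L, onset - drift)
  hrs <- t0:min(len, onset)
  frac <- (hrs - t0) / max(1L, onset - t0)
  X[hrs, "Creatinine"] <- X[hrs, "Creatinine"] + sig$creatinineCreep * frac
  X[hrs, "Lactate"] <- X[hrs, "Lactate"] + sig$lactateRise * frac
  X[hrs, "MAP"] <- X[hrs, "MAP"] - sig$mapDrop * frac
  X[hrs, "HR"] <- X[hrs, "HR"] + sig$hrRise * frac
  jumpHrs <- intersect(max(1L, onset - 2L):onset, seq_len(len))
  jfrac <- seq_along(jumpHrs) / length(jumpHrs)
  X[jumpHrs, "Creatinine"] <- X[jumpHrs, "Creatinine"] + sig$creatinineJump * jfrac
  X
}

#' Back-calculate baseline creatinine from the MDRD equation
#'
#' Inverts the 4-variable MDRD equation
#' \code{eGFR = 175 * Scr^-1.154 * age^-0.203 * 0.742[female] * 1.212[black]}
#' at an assumed eGFR, yielding the baseline serum creatinine used when no
#' admission value is trusted. Defaults: age 60, female, race coefficient 1.
#'
#' @param egfr Assumed eGFR in mL/min/1.73m^2 (default 75).
#' @param age Age in years (default 60).
#' @param female Logical (default \code{TRUE}).
#' @param raceCoef Race coefficient (default 1).
#' @return Baseline creatinine in mg/dL.
#' @export
#' @examples
#' mdrdBaselineCreatinine() # about 0.78 mg/dL
mdrdBaselineCreatinine <- function(egfr = 75, age = 60, female = TRUE,
                                   raceCoef = 1) {
  k <- 175 * age^(-0.203) * (if (female) 0.742 else 1) * raceCoef
  (egfr / k)^(-1 / 1.154)
}

#' Label a record with the KDIGO creatinine rule
#'
#' Scans the observed creatinine series for (a) a rise of at least
#' \code{rule@absRise} mg/dL relative to any earlier observed value within
#' \code{rule@absWindow} hours, or (b) a value of at least
#' \code{rule@ratioRise} times baseline within \code{rule@ratioWindow} hours
#' of admission. The onset hour is the first hour at which either branch
#' fires. Baseline is the first observed creatinine under the
#' \code{"first_value"} policy, or the MDRD back-calculated value under
#' \code{"mdrd_backcalc"}.
#'
#' @param record A \code{PatientRecord}.
#' @param rule A \code{\link{kdigoRule}}.
#' @return List with \code{label} (integer 0/1) and \code{onsetHour} (integer,
#'   \code{NA} for negatives).
#' @export
labelAki <- function(record, rule = kdigoRule()) {
  creat <- record@series[, "Creatinine"]
  obs <- which(!is.na(creat))
  if (length(obs) == 0L) {
    stop(structure(
      class = c("akigraph_no_creatinine", "error", "condition"),
      list(message = sprintf(
        "record %s has no observed creatinine values and must be excluded",
        record@patientId
      ), call = sys.call())
    ))
  }
  baseline <- switch(rule@baselinePolicy,
    first_value = creat[obs[1L]],
    mdrd_backcalc = mdrdBaselineCreatinine(rule@mdrdEgfr)
  )
  vals <- creat[obs]
  nObs <- length(obs)
  ## running minimum of earlier observed values within the absolute window
  onset <- NA_integer_
  for (k in seq_len(nObs)) {
    t2 <- obs[k]
    fired <- FALSE
    if (k > 1L) {
      inWin <- obs[seq_len(k - 1L)] >= t2 - rule@absWindow
      if (any(inWin) && vals[k] - min(vals[seq_len(k - 1L)][inWin]) >= rule@absRise)
        fired <- TRUE
    }
    if (!fired && t2 <= rule@ratioWindow && vals[k] >= rule@ratioRise * baseline)
      fired <- TRUE
    if (fired) {
      onset <- t2
      break
    }
  }
  if (is.na(onset)) list(label = 0L, onsetHour = NA_integer_)
  else list(label = 1L, onsetHour = as.integer(onset))
}

#' @rdname labelAki
#' @param cohort An \code{AkiCohort}; every record is relabeled in place.
#' @return \code{labelCohort}: the cohort with labels and onset hours updated.
#' @export
labelCohort <- function(cohort, rule = kdigoRule()) {
  cohort@records <- lapply(cohort@records, function(r) {
    lab <- labelAki(r, rule)
    r@label <- lab$label
    r@akiOnsetHour <- lab$onsetHour
    r
  })
  cohort
}

#' Z-score normalize a cohort
#'
#' Standardizes every feature using the mean and sample standard deviation
#' (denominator n-1) over all non-missing values in the cohort, or applies
#' externally supplied reference statistics (the test-time contract: test data
#' are scaled by training statistics, never their own). Zero-variance features
#' map to zeros.
#'
#' @param cohort An \code{AkiCohort}.
#' @param referenceStats Optional list with numeric vectors \code{mean} and
#'   \code{sd} (length 12) from a training cohort.
#' @return List with \code{cohort} (normalized) and \code{stats} (the
#'   statistics applied).
#' @export
zscoreNormalize <- function(cohort, referenceStats = NULL) {
  if (length(cohort) == 0L) stop("cannot normalize an empty cohort")
  feats <- akiFeatures()
  if (is.null(referenceStats)) {
    all <- do.call(rbind, lapply(cohort@records, function(r) r@series))
    mu <- colMeans(all, na.rm = TRUE)
    sdv <- apply(all, 2L, stats::sd, na.rm = TRUE)
    nObs <- colSums(!is.na(all))
    if (any(nObs == 0L)) {
      stop(sprintf(
        "feature(s) entirely missing: %s",
        paste(feats[nObs == 0L], collapse = ", ")
      ))
    }
    sdv[is.na(sdv)] <- 0
    referenceStats <- list(mean = mu, sd = sdv)
  }
  mu <- referenceStats$mean
  sdv <- referenceStats$sd
  scaleRow <- ifelse(sdv > 0, 1 / sdv, 0)
  cohort@records <- lapply(cohort@records, function(r) {
    r@series <- sweep(sweep(r@series, 2L, mu, `-`), 2L, scaleRow, `*`)
    ## zero-variance features map to zeros, not (x - mu) * 0 + noise
    r@series[, sdv == 0] <- ifelse(is.na(r@series[, sdv == 0]), NA_real_, 0)
    r
  })
  list(cohort = cohort, stats = referenceStats)
}

#' Split arithmetic helpers
#'
#' \code{trainTestSizes} gives the train/test record counts of a
#' fraction-based split (train size rounded to the nearest integer);
#' \code{shardSizes} partitions a training set into near-equal node shards
#' (remainder spread over the first shards).
#'
#' @param n Total number of records.
#' @param trainFrac Training fraction.
#' @param nTrain Training-set size.
#' @param nNodes Number of decentralized nodes.
#' @return Named integer vector of sizes.
#' @export
#' @examples
#' trainTestSizes(40336, 0.85) # 34286 train, 6050 test
#' shardSizes(34285, 5) # 6857 per node
trainTestSizes <- function(n, trainFrac) {
  nTrain <- as.integer(round(n * trainFrac))
  c(train = nTrain, test = as.integer(n) - nTrain)
}

#' @rdname trainTestSizes
#' @export
shardSizes <- function(nTrain, nNodes) {
  base <- nTrain %/% nNodes
  extra <- nTrain %% nNodes
  as.integer(base + (seq_len(nNodes) <= extra))
}

#' Stratified train/test split with per-node shards
#'
#' Splits a cohort into training and held-out sets, stratified by AKI label so
#' that every partition's prevalence matches the cohort within rounding, and
#' further partitions the training set into \code{nNodes} near-equal disjoint
#' shards (stratified round-robin assignment).
#'
#' @param cohort An \code{AkiCohort}.
#' @param trainFrac Training fraction in (0, 1) (default 0.85).
#' @param nNodes Number of node shards (default 1).
#' @param seed RNG seed for the shuffles.
#' @return List with \code{train}, \code{test} (cohorts) and \code{shards}
#'   (list of cohorts, length \code{nNodes}).
#' @export
splitCohort <- function(cohort, trainFrac = 0.85, nNodes = 1L, seed = 1L) {
  stopifnot(trainFrac > 0, trainFrac < 1, nNodes >= 1L)
  n <- length(cohort)
  labs <- akiLabels(cohort)
  sizes <- trainTestSizes(n, trainFrac)
  if (sizes["test"] < 1L) stop("split leaves an empty test partition")
  set.seed(seed)
  pos <- sample(which(labs == 1L))
  neg <- sample(which(labs == 0L))
  nPosTrain <- as.integer(round(trainFrac * length(pos)))
  nNegTrain <- sizes[["train"]] - nPosTrain
  if (nNegTrain < 0L || nNegTrain > length(neg))
    stop("infeasible stratified split for this prevalence")
  trainIdx <- c(pos[seq_len(nPosTrain)], neg[seq_len(nNegTrain)])
  testIdx <- setdiff(seq_len(n), trainIdx)
  if (nNodes > length(trainIdx)) stop("more nodes than training records")
  ## stratified sharding: positives round-robin, negatives fill each shard up
  ## to its near-equal target size, keeping per-shard prevalence aligned
  shardOf <- integer(n)
  shardOf[pos[seq_len(nPosTrain)]] <- rep_len(seq_len(nNodes), nPosTrain)
  target <- shardSizes(length(trainIdx), nNodes)
  posCounts <- tabulate(shardOf[pos[seq_len(nPosTrain)]], nNodes)
  negAssign <- rep(seq_len(nNodes), pmax(target - posCounts, 0L))
  shardOf[neg[seq_len(nNegTrain)]] <- negAssign[seq_len(nNegTrain)]
  shards <- lapply(seq_len(nNodes), function(k) {
    akiCohort(cohort@records[sort(which(shardOf == k))])
  })
  list(
    train = akiCohort(cohort@records[sort(trainIdx)]),
    test = akiCohort(cohort@records[sort(testIdx)]),
    shards = shards
  )
}
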