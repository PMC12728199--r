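## Shared fixtures: tiny records, graphs and prediction sets built in code.

## A record with a fully specified creatinine trajectory and flat vitals.
makeRecord <- function(creatinine, patientId = "T1", label = 0L,
                       onset = NA_integer_) {
  L <- length(creatinine)
  X <- matrix(rep(c(1, 120, 70, 87, 85, 37, 18, 1.6, 97, 18, 7.38, 9),
                  each = L), L, 12)
  colnames(X) <- akiFeatures()
  X[, "Creatinine"] <- creatinine
  patientRecord(patientId, X, akiOnsetHour = onset, label = label)
}

## A random smooth multivariate record (no planted AKI signal).
makeNoiseRecord <- function(L, patientId = "N1", sd = 0.05) {
  X <- matrix(rnorm(L * 12), L, 12)
  for (f in seq_len(12)) X[, f] <- cumsum(X[, f]) * sd + f
  colnames(X) <- akiFeatures()
  patientRecord(patientId, X)
}

## A random FeatureGraph with the package's node set.
makeRandomGraph <- function(label = 1L, Tn = 6L, steps = 3L, nEdges = 20L,
                            patientId = "G1") {
  A <- matrix(0, 12, 12)
  on <- sample(which(upper.tri(A)), nEdges)
  A[on] <- runif(nEdges, -1, 1)
  A <- A + t(A)
  diag(A) <- 0
  new("FeatureGraph",
    nodeIds = akiFeatures(), adjacency = pmax(pmin(A, 1), -1),
    nodeFeatures = array(rnorm(12 * Tn * steps), c(12, Tn, steps)),
    label = as.integer(label), patientId = patientId, endHour = as.integer(Tn)
  )
}

## Linearly separable toy graphs: positives have node-1 features shifted.
makeSeparableGraphs <- function(n = 40L, Tn = 6L, shift = 2) {
  lapply(seq_len(n), function(i) {
    lab <- as.integer(i <= n / 2)
    g <- makeRandomGraph(lab, Tn = Tn, patientId = sprintf("S%02d", i))
    if (lab == 1L) g@nodeFeatures[1, , ] <- g@nodeFeatures[1, , ] + shift
    g
  })
}

## A small labeled cohort for pipeline tests.
makeSmallCohort <- function(n = 60L, seed = 7L, prevalence = 0.2) {
  generateCohort(cohortConfig(nPatients = n, prevalence = prevalence,
                              seed = seed))
}

randomPredictionSet <- function(n = 100L, id = "m") {
  y <- rbinom(n, 1, 0.3)
  p <- plogis(rnorm(n) + y)
  predictionSet(y, p, id)
}
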