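## S4 classes for cohorts, graphs, models, protocol state and evaluation.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PatientRecord: one patient's hourly multivariate physiological series
#'
#' @slot patientId Character scalar identifier.
#' @slot series Numeric matrix, L hours x 12 features (canonical column order,
#'   see \code{\link{akiFeatures}}); missing measurements are \code{NA}.
#' @slot missingMask Logical matrix of the same shape; \code{TRUE} = missing.
#' @slot akiOnsetHour Integer hour of AKI onset (\code{NA} for negatives).
#' @slot label Integer 0/1 AKI annotation.
#' @export
setClass("PatientRecord",
  representation(
    patientId = "character",
    series = "matrix",
    missingMask = "matrix",
    akiOnsetHour = "integer",
    label = "integer"
  )
)

setValidity("PatientRecord", function(object) {
  L <- nrow(object@series)
  msg <- character(0)
  if (length(object@patientId) != 1L) msg <- c(msg, "patientId must be a scalar")
  if (L < 1L) msg <- c(msg, "series must have at least one hour (L >= 1)")
  if (L > 336L) msg <- c(msg, "series longer than 336 hours")
  if (ncol(object@series) != 12L) msg <- c(msg, "series must have 12 feature columns")
  if (!identical(colnames(object@series), akiFeatures()))
    msg <- c(msg, "series columns must be the canonical feature set, in order")
  if (!identical(dim(object@series), dim(object@missingMask)))
    msg <- c(msg, "missingMask shape must match series")
  if (!object@label %in% c(0L, 1L)) msg <- c(msg, "label must be 0 or 1")
  if (object@label == 1L && (is.na(object@akiOnsetHour) || object@akiOnsetHour > L))
    msg <- c(msg, "positive records need akiOnsetHour <= L")
  if (length(msg)) msg else TRUE
})

#' Construct a PatientRecord
#'
#' @param patientId Scalar identifier.
#' @param series L x 12 numeric matrix with \code{NA} at missing cells.
#'   Columns must be (or be renameable to) the canonical feature set.
#' @param akiOnsetHour Onset hour (integer) or \code{NA}.
#' @param label 0/1 AKI label.
#' @return A \code{PatientRecord}.
#' @export
patientRecord <- function(patientId, series, akiOnsetHour = NA_integer_, label = 0L) {
  series <- as.matrix(series)
  storage.mode(series) <- "double"
  colnames(series) <- akiFeatures()
  new("PatientRecord",
    patientId = as.character(patientId),
    series = series,
    missingMask = is.na(series),
    akiOnsetHour = as.integer(akiOnsetHour),
    label = as.integer(label)
  )
}

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf(
    "PatientRecord %s: %d h x %d features, label=%d%s\n",
    object@patientId, nrow(object@series), ncol(object@series), object@label,
    if (!is.na(object@akiOnsetHour)) sprintf(", onset=%dh", object@akiOnsetHour) else ""
  ))
})

#' AkiCohort: an ordered collection of PatientRecord objects
#'
#' @slot records List of \code{PatientRecord}.
#' @export
setClass("AkiCohort", representation(records = "list"))

setValidity("AkiCohort", function(object) {
  ok <- vapply(object@records, is, logical(1), class2 = "PatientRecord")
  if (!all(ok)) "all records must be PatientRecord objects" else TRUE
})

#' @export
akiCohort <- function(records) new("AkiCohort", records = records)

#' @describeIn akiCohort number of patients in the cohort
#' @param x,object An \code{AkiCohort}.
#' @export
setMethod("length", "AkiCohort", function(x) length(x@records))

setMethod("show", "AkiCohort", function(object) {
  labs <- akiLabels(object)
  cat(sprintf(
    "AkiCohort: %d patients, %.1f%% AKI-positive\n",
    length(labs), if (length(labs)) 100 * mean(labs) else 0
  ))
})

#' Extract per-record vectors from a cohort
#'
#' @param cohort An \code{AkiCohort}.
#' @return \code{akiLabels}: integer 0/1 vector; \code{recordLengths}: integer
#'   vector of record durations in hours.
#' @export
akiLabels <- function(cohort) {
  vapply(cohort@records, function(r) r@label, integer(1))
}

#' @rdname akiLabels
#' @export
recordLengths <- function(cohort) {
  vapply(cohort@records, function(r) nrow(r@series), integer(1))
}

## ---- configuration classes -------------------------------------------------

#' CohortConfig: parameters of the synthetic ICU cohort generator
#'
#' @slot nPatients Number of patients.
#' @slot prevalence Target AKI fraction (0, 1).
#' @slot lengthMean,lengthSd Record-length distribution in hours.
#' @slot correlationSpec 12 x 12 target cross-feature correlation matrix
#'   (symmetric positive semidefinite).
#' @slot missingRate Per-cell missingness probability.
#' @slot plantedSignal Named list describing the pre-onset physiological drift
#'   (see \code{\link{plantedSignalDefaults}}).
#' @slot seed Integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    nPatients = "integer", prevalence = "numeric",
    lengthMean = "numeric", lengthSd = "numeric",
    correlationSpec = "matrix", missingRate = "numeric",
    plantedSignal = "list", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (object@prevalence < 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must be in [0, 1)")
  if (object@lengthMean <= 0 || object@lengthSd <= 0)
    msg <- c(msg, "lengthMean and lengthSd must be positive")
  R <- object@correlationSpec
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    msg <- c(msg, "correlationSpec must be symmetric")
  else if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    msg <- c(msg, "correlationSpec is not positive semidefinite")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Default pre-onset drift parameters for AKI-positive patients
#'
#' Positives carry a slow creatinine creep over the \code{driftHours} before
#' onset, a steep terminal creatinine rise that triggers the KDIGO rule at the
#' intended onset hour, and hemodynamic precursors (lactate rise, MAP drop,
#' HR rise) ramping linearly over the same pre-onset window.
#'
#' @return Named list: \code{creatinineCreep} (mg/dL over the drift window),
#'   \code{creatinineJump} (mg/dL over the final 2 h), \code{lactateRise}
#'   (mmol/L), \code{mapDrop} (mmHg), \code{hrRise} (bpm), \code{driftHours}.
#' @export
plantedSignalDefaults <- function() {
  list(
    creatinineCreep = 0.12, creatinineJump = 0.45,
    lactateRise = 2.0, mapDrop = 15, hrRise = 12,
    driftHours = 24L
  )
}

#' Construct a CohortConfig
#'
#' @param nPatients Number of patients (default 2000).
#' @param prevalence Target AKI prevalence (default 0.15).
#' @param lengthMean,lengthSd Record-length mean/sd in hours (default 24 / 10).
#' @param correlationSpec Target correlation matrix (default
#'   \code{\link{defaultCorrelationSpec}}).
#' @param missingRate Per-cell missingness probability (default 0.1).
#' @param plantedSignal Drift parameters (default
#'   \code{\link{plantedSignalDefaults}}).
#' @param seed RNG seed.
#' @return A \code{CohortConfig}.
#' @export
cohortConfig <- function(nPatients = 2000L, prevalence = 0.15,
                         lengthMean = 24, lengthSd = 10,
                         correlationSpec = defaultCorrelationSpec(),
                         missingRate = 0.1,
                         plantedSignal = plantedSignalDefaults(),
                         seed = 1L) {
  sig <- plantedSignalDefaults()
  sig[names(plantedSignal)] <- plantedSignal
  new("CohortConfig",
    nPatients = as.integer(nPatients), prevalence = prevalence,
    lengthMean = lengthMean, lengthSd = lengthSd,
    correlationSpec = correlationSpec, missingRate = missingRate,
    plantedSignal = sig, seed = as.integer(seed)
  )
}

#' KdigoRule: creatinine-based AKI labeling rule
#'
#' A record is AKI-positive when serum creatinine rises by at least
#' \code{absRise} mg/dL within \code{absWindow} hours of any earlier value, or
#' reaches \code{ratioRise} times baseline within \code{ratioWindow} hours of
#' admission. Baseline is the first observed creatinine, or a back-calculated
#' MDRD value at \code{mdrdEgfr} mL/min/1.73m^2 under the
#' \code{"mdrd_backcalc"} policy.
#'
#' @slot absRise,absWindow Absolute-rise branch: mg/dL within hours.
#' @slot ratioRise,ratioWindow Ratio branch: fold-change within hours.
#' @slot baselinePolicy \code{"first_value"} or \code{"mdrd_backcalc"}.
#' @slot mdrdEgfr Assumed eGFR for the MDRD back-calculation.
#' @export
setClass("KdigoRule",
  representation(
    absRise = "numeric", absWindow = "integer",
    ratioRise = "numeric", ratioWindow = "integer",
    baselinePolicy = "character", mdrdEgfr = "numeric"
  )
)

setValidity("KdigoRule", function(object) {
  msg <- character(0)
  if (object@absRise <= 0) msg <- c(msg, "absRise must be positive")
  if (object@ratioRise <= 1) msg <- c(msg, "ratioRise must exceed 1")
  if (object@absWindow <= 0L || object@ratioWindow <= 0L)
    msg <- c(msg, "windows must be positive")
  if (!object@baselinePolicy %in% c("first_value", "mdrd_backcalc"))
    msg <- c(msg, "unknown baselinePolicy")
  if (length(msg)) msg else TRUE
})

#' @rdname KdigoRule-class
#' @param absRise,absWindow,ratioRise,ratioWindow,baselinePolicy,mdrdEgfr See
#'   slots.
#' @return A \code{KdigoRule}.
#' @export
kdigoRule <- function(absRise = 0.3, absWindow = 48L, ratioRise = 1.5,
                      ratioWindow = 168L, baselinePolicy = "first_value",
                      mdrdEgfr = 75) {
  new("KdigoRule",
    absRise = absRise, absWindow = as.integer(absWindow),
    ratioRise = ratioRise, ratioWindow = as.integer(ratioWindow),
    baselinePolicy = baselinePolicy, mdrdEgfr = mdrdEgfr
  )
}

#' WindowSpec: pre-prediction window and graph-construction settings
#'
#' @slot windowHours Window length in hours (default 48; sensitivity grid
#'   24/48/72).
#' @slot historySteps Temporal depth of node features (default 3).
#' @slot corrThreshold Absolute Pearson threshold for edges (default 0.30).
#' @slot horizonMin,horizonMax Prediction-horizon bounds: positive windows end
#'   between \code{horizonMin} and \code{horizonMax} hours before onset
#'   (default 6-12).
#' @export
setClass("WindowSpec",
  representation(
    windowHours = "integer", historySteps = "integer",
    corrThreshold = "numeric", horizonMin = "integer", horizonMax = "integer"
  )
)

setValidity("WindowSpec", function(object) {
  msg <- character(0)
  if (object@historySteps < 1L) msg <- c(msg, "historySteps must be >= 1")
  if (object@corrThreshold <= 0 || object@corrThreshold >= 1)
    msg <- c(msg, "corrThreshold must be in (0, 1)")
  if (object@windowHours < object@historySteps)
    msg <- c(msg, "windowHours must be >= historySteps")
  if (object@horizonMin < 0L || object@horizonMax < object@horizonMin)
    msg <- c(msg, "need 0 <= horizonMin <= horizonMax")
  if (length(msg)) msg else TRUE
})

#' @rdname WindowSpec-class
#' @param windowHours,historySteps,corrThreshold,horizonMin,horizonMax See
#'   slots.
#' @return A \code{WindowSpec}.
#' @export
windowSpec <- function(windowHours = 48L, historySteps = 3L,
                       corrThreshold = 0.30, horizonMin = 6L,
                       horizonMax = 12L) {
  new("WindowSpec",
    windowHours = as.integer(windowHours),
    historySteps = as.integer(historySteps),
    corrThreshold = corrThreshold,
    horizonMin = as.integer(horizonMin), horizonMax = as.integer(horizonMax)
  )
}

#' FeatureGraph: a patient's windowed physiological feature graph
#'
#' Nodes are the 12 physiological features; the adjacency holds signed Pearson
#' correlation weights, zeroed below the threshold; node features are the
#' short temporal history vectors \code{[x_t, x_(t-1), ..., x_(t-s+1)]}.
#'
#' @slot nodeIds Ordered feature names (length N).
#' @slot adjacency N x N symmetric signed weight matrix (0 = no edge).
#' @slot nodeFeatures Array N x T x historySteps.
#' @slot label Integer 0/1.
#' @slot patientId Character.
#' @slot endHour Window end hour within the source record.
#' @export
setClass("FeatureGraph",
  representation(
    nodeIds = "character", adjacency = "matrix", nodeFeatures = "array",
    label = "integer", patientId = "character", endHour = "integer"
  )
)

setValidity("FeatureGraph", function(object) {
  msg <- character(0)
  N <- length(object@nodeIds)
  A <- object@adjacency
  if (!identical(dim(A), c(N, N))) msg <- c(msg, "adjacency must be N x N")
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10)))
    msg <- c(msg, "adjacency must be symmetric")
  if (any(abs(A) > 1 + 1e-10)) msg <- c(msg, "edge weights must lie in [-1, 1]")
  d <- dim(object@nodeFeatures)
  if (length(d) != 3L || d[1] != N) msg <- c(msg, "nodeFeatures must be N x T x steps")
  if (d[2] < 1L) msg <- c(msg, "need at least one usable time step (T >= 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureGraph", function(object) {
  d <- dim(object@nodeFeatures)
  nE <- sum(object@adjacency[upper.tri(object@adjacency)] != 0)
  cat(sprintf(
    "FeatureGraph %s: %d nodes, %d edges, T=%d, steps=%d, label=%d\n",
    object@patientId, length(object@nodeIds), nE, d[2], d[3], object@label
  ))
})

#' Accessors for FeatureGraph
#'
#' @param graph A \code{FeatureGraph}.
#' @return \code{graphAdjacency}: the signed weight matrix;
#'   \code{graphNodeFeatures}: the N x T x steps feature array;
#'   \code{graphLabel}: the 0/1 label.
#' @export
graphAdjacency <- function(graph) graph@adjacency

#' @rdname graphAdjacency
#' @export
graphNodeFeatures <- function(graph) graph@nodeFeatures

#' @rdname graphAdjacency
#' @export
graphLabel <- function(graph) graph@label

#' GatConfig: architecture of the two-layer multi-head GAT classifier
#'
#' @slot d0 Input feature dimension per node per step (= historySteps).
#' @slot dh Hidden dimension per head (default 64).
#' @slot heads Number of attention heads K (default 8).
#' @slot dropout Dropout rate on attention coefficients and the hidden layer
#'   during training (default 0.3).
#' @slot leakySlope Negative slope of the LeakyReLU in the attention scores
#'   (default 0.2).
#' @slot secondLayerMode \code{"average"} (head-averaged second layer, pooled
#'   dimension dh) or \code{"concat"} (pooled dimension K*dh).
#' @export
setClass("GatConfig",
  representation(
    d0 = "integer", dh = "integer", heads = "integer",
    dropout = "numeric", leakySlope = "numeric", secondLayerMode = "character"
  )
)

setValidity("GatConfig", function(object) {
  msg <- character(0)
  if (object@heads < 1L) msg <- c(msg, "heads must be >= 1")
  if (object@dh < 1L) msg <- c(msg, "dh must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (!object@secondLayerMode %in% c("average", "concat"))
    msg <- c(msg, "secondLayerMode must be 'average' or 'concat'")
  if (length(msg)) msg else TRUE
})

#' @rdname GatConfig-class
#' @param d0,dh,heads,dropout,leakySlope,secondLayerMode See slots.
#' @return A \code{GatConfig}.
#' @export
gatConfig <- function(d0 = 3L, dh = 64L, heads = 8L, dropout = 0.3,
                      leakySlope = 0.2, secondLayerMode = "average") {
  new("GatConfig",
    d0 = as.integer(d0), dh = as.integer(dh), heads = as.integer(heads),
    dropout = dropout, leakySlope = leakySlope,
    secondLayerMode = secondLayerMode
  )
}

#' TrainConfig: optimization settings
#'
#' @slot lr Adam learning rate (default 0.001).
#' @slot epochs Training epochs (default 50).
#' @slot batchSize Mini-batch size in graphs (default 128).
#' @slot seed RNG seed for initialization, shuffling and dropout.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", epochs = "integer", batchSize = "integer",
                 seed = "integer")
)

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@lr < 0) msg <- c(msg, "lr must be non-negative")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param lr,epochs,batchSize,seed See slots.
#' @return A \code{TrainConfig}.
#' @export
trainConfig <- function(lr = 0.001, epochs = 50L, batchSize = 128L, seed = 1L) {
  new("TrainConfig",
    lr = lr, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), seed = as.integer(seed)
  )
}

#' GatModel: a trained (or initialized) GAT classifier
#'
#' @slot params Named parameter list (\code{W1}, per-head layer-1/2 weights and
#'   attention vectors, \code{Wfc}, \code{b}).
#' @slot config The \code{GatConfig} the parameters belong to.
#' @slot payloadOverride Optional explicit per-message payload in bytes for
#'   communication accounting (\code{NA} = 4 bytes per parameter).
#' @export
setClass("GatModel",
  representation(params = "list", config = "GatConfig",
                 payloadOverride = "numeric")
)

setMethod("show", "GatModel", function(object) {
  cat(sprintf(
    "GatModel: dh=%d, K=%d, %s second layer, %s parameters (%.2f MB FP32)\n",
    object@config@dh, object@config@heads, object@config@secondLayerMode,
    format(parameterCount(object), big.mark = ","),
    payloadBytes(object) / 1e6
  ))
})

#' GossipConfig: decentralized protocol settings
#'
#' @slot nNodes Number of participants (default 5).
#' @slot rounds Gossip rounds; one local epoch plus one exchange per node per
#'   round (default 18).
#' @slot scheduling Order exchanges by local validation accuracy (default
#'   \code{FALSE}: uniformly random peers).
#' @slot fineTuneLr Learning rate eta of post-distribution local fine-tuning
#'   (default 1e-4, plain gradient descent).
#' @slot fineTuneEpochs Fine-tuning epochs (default 5).
#' @slot aggregationMode \code{"adaptive"} (softmax of validation accuracies)
#'   or \code{"equal"} (uniform weights).
#' @slot temperature Softmax temperature for adaptive weights (default 1).
#' @slot seed Integer RNG seed.
#' @export
setClass("GossipConfig",
  representation(
    nNodes = "integer", rounds = "integer", scheduling = "logical",
    fineTuneLr = "numeric", fineTuneEpochs = "integer",
    aggregationMode = "character", temperature = "numeric", seed = "integer"
  )
)

setValidity("GossipConfig", function(object) {
  msg <- character(0)
  if (object@nNodes < 1L) msg <- c(msg, "nNodes must be >= 1")
  if (object@rounds < 0L) msg <- c(msg, "rounds must be >= 0")
  if (!object@aggregationMode %in% c("adaptive", "equal"))
    msg <- c(msg, "aggregationMode must be 'adaptive' or 'equal'")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname GossipConfig-class
#' @param nNodes,rounds,scheduling,fineTuneLr,fineTuneEpochs,aggregationMode,temperature,seed
#'   See slots.
#' @return A \code{GossipConfig}.
#' @export
gossipConfig <- function(nNodes = 5L, rounds = 18L, scheduling = FALSE,
                         fineTuneLr = 1e-4, fineTuneEpochs = 5L,
                         aggregationMode = "adaptive", temperature = 1,
                         seed = 1L) {
  new("GossipConfig",
    nNodes = as.integer(nNodes), rounds = as.integer(rounds),
    scheduling = scheduling, fineTuneLr = fineTuneLr,
    fineTuneEpochs = as.integer(fineTuneEpochs),
    aggregationMode = aggregationMode, temperature = temperature,
    seed = as.integer(seed)
  )
}

#' NodeState: one decentralized participant
#'
#' @slot nodeId Integer identifier.
#' @slot params Current local parameters (named list, as in
#'   \code{GatModel@params}).
#' @slot prevParams Parameters at the previous epoch (empty list before the
#'   first local epoch).
#' @slot valAccuracy Local validation accuracy in [0, 1] (\code{NA} before the
#'   first evaluation).
#' @slot adamState Optimizer state carried across rounds.
#' @slot rngState The node's private RNG state (\code{.Random.seed} vector).
#' @slot trainPrep,valPrep Prepared local graph tensors (see
#'   \code{\link{prepareGraphs}}).
#' @export
setClass("NodeState",
  representation(
    nodeId = "integer", params = "list", prevParams = "list",
    valAccuracy = "numeric", adamState = "list", rngState = "integer",
    trainPrep = "list", valPrep = "list"
  )
)

setValidity("NodeState", function(object) {
  acc <- object@valAccuracy
  if (length(acc) == 1L && !is.na(acc) && (acc < 0 || acc > 1))
    "valAccuracy must lie in [0, 1]" else TRUE
})

setMethod("show", "NodeState", function(object) {
  cat(sprintf(
    "NodeState %d: %d training graphs, valAccuracy=%s\n",
    object@nodeId, length(object@trainPrep$y),
    ifelse(is.na(object@valAccuracy), "NA", sprintf("%.3f", object@valAccuracy))
  ))
})

#' CommLedger: per-round communication accounting
#'
#' Accounting is per participant per round: one model payload per gossip round
#' (each node talks to a single peer), \code{nNodes} upload payloads per
#' federated-averaging round (broadcast bytes are not counted by default).
#'
#' @slot entries Data frame with columns \code{round}, \code{protocol}
#'   (\code{"gossip"} or \code{"fedavg"}), \code{bytes}.
#' @slot payloadBytes Per-message payload size in bytes.
#' @export
setClass("CommLedger",
  representation(entries = "data.frame", payloadBytes = "numeric")
)

setValidity("CommLedger", function(object) {
  if (!all(c("round", "protocol", "bytes") %in% names(object@entries)))
    return("entries needs columns round, protocol, bytes")
  if (!all(object@entries$protocol %in% c("gossip", "fedavg")))
    return("protocol must be 'gossip' or 'fedavg'")
  TRUE
})

setMethod("show", "CommLedger", function(object) {
  cat(sprintf(
    "CommLedger: %d rounds, payload %.2f MB, total %.2f MB\n",
    nrow(object@entries), object@payloadBytes / 1e6, totalBytes(object) / 1e6
  ))
})

#' Total bytes recorded in a communication ledger
#'
#' @param ledger A \code{CommLedger}.
#' @return Numeric scalar, the sum of all per-round byte entries.
#' @export
totalBytes <- function(ledger) sum(ledger@entries$bytes)

#' PredictionSet: paired labels and predicted probabilities
#'
#' @slot labels Integer 0/1 outcome vector.
#' @slot probabilities Predicted probabilities in [0, 1].
#' @slot modelId Character tag naming the model.
#' @export
setClass("PredictionSet",
  representation(labels = "integer", probabilities = "numeric",
                 modelId = "character")
)

setValidity("PredictionSet", function(object) {
  msg <- character(0)
  if (length(object@labels) != length(object@probabilities))
    msg <- c(msg, "labels and probabilities must have equal length")
  if (any(!object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
  if (any(object@probabilities < 0 | object@probabilities > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname PredictionSet-class
#' @param labels 0/1 outcomes.
#' @param probabilities Predicted probabilities.
#' @param modelId Model tag.
#' @return A \code{PredictionSet}.
#' @export
predictionSet <- function(labels, probabilities, modelId = "model") {
  new("PredictionSet",
    labels = as.integer(labels), probabilities = as.numeric(probabilities),
    modelId = as.character(modelId)
  )
}

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf(
    "PredictionSet '%s': n=%d, prevalence=%.3f\n",
    object@modelId, length(object@labels), mean(object@labels)
  ))
})
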