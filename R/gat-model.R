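## Batched two-layer multi-head GAT: forward, manual backpropagation, Adam
## training loop, parameter (un)flattening. All graphs in a batch share the
## node count N and window length T, so node/time/graph dimensions are folded
## into one column axis and every attention operation is vectorized over it.

#' Initialize GAT parameters
#'
#' Glorot-uniform weight matrices and attention vectors, zero output bias.
#' Layer 1 has K heads of shape dh x dh acting on the transformed input;
#' layer 2 heads act on the concatenated K*dh layer-1 output. Draws from the
#' current RNG stream (seed before calling for reproducibility).
#'
#' @param config A \code{\link{gatConfig}}.
#' @return Named parameter list: \code{W1} (dh x d0), \code{layer1},
#'   \code{layer2} (lists of \code{list(W, a)} per head), \code{Wfc}
#'   (1 x pooled dim), \code{b}.
#' @export
initGatParams <- function(config) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  dh <- config@dh
  K <- config@heads
  poolDim <- if (config@secondLayerMode == "concat") K * dh else dh
  list(
    W1 = glorot(dh, config@d0),
    layer1 = lapply(seq_len(K), function(k) {
      list(W = glorot(dh, dh), a = as.vector(glorot(2L * dh, 1L)))
    }),
    layer2 = lapply(seq_len(K), function(k) {
      list(W = glorot(dh, K * dh), a = as.vector(glorot(2L * dh, 1L)))
    }),
    Wfc = glorot(1L, poolDim),
    b = 0
  )
}

## Output-bias initialization at the log-odds of the training prevalence,
## so optimization starts at the base-rate prediction instead of spending
## early epochs learning it.
priorLogit <- function(y) {
  p <- min(max(mean(y), 0.01), 0.99)
  log(p / (1 - p))
}

#' Flatten GAT parameters to a single vector and back
#'
#' The flat view concatenates, in fixed order: \code{W1}, per-head layer-1
#' \code{W} then \code{a}, per-head layer-2 \code{W} then \code{a},
#' \code{Wfc}, \code{b}. \code{unflattenParams} is its exact inverse given
#' the architecture.
#'
#' @param params Parameter list.
#' @param flat Numeric vector of length \code{parameterCount}.
#' @param config A \code{\link{gatConfig}}.
#' @return \code{flattenParams}: numeric vector; \code{unflattenParams}: a
#'   parameter list.
#' @export
flattenParams <- function(params) {
  c(
    as.vector(params$W1),
    unlist(lapply(params$layer1, function(h) c(as.vector(h$W), h$a)),
           use.names = FALSE),
    unlist(lapply(params$layer2, function(h) c(as.vector(h$W), h$a)),
           use.names = FALSE),
    as.vector(params$Wfc),
    params$b
  )
}

#' @rdname flattenParams
#' @export
unflattenParams <- function(flat, config) {
  dh <- config@dh
  K <- config@heads
  d0 <- config@d0
  poolDim <- if (config@secondLayerMode == "concat") K * dh else dh
  expected <- dh * d0 + K * (dh * dh + 2L * dh) +
    K * (dh * K * dh + 2L * dh) + poolDim + 1L
  if (length(flat) != expected) {
    stop(sprintf("flat vector length %d does not match architecture (%d)",
                 length(flat), expected))
  }
  pos <- 0L
  takeMat <- function(nr, nc) {
    v <- flat[pos + seq_len(nr * nc)]
    pos <<- pos + nr * nc
    matrix(v, nr, nc)
  }
  takeVec <- function(n) {
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  list(
    W1 = takeMat(dh, d0),
    layer1 = lapply(seq_len(K), function(k) {
      list(W = takeMat(dh, dh), a = takeVec(2L * dh))
    }),
    layer2 = lapply(seq_len(K), function(k) {
      list(W = takeMat(dh, K * dh), a = takeVec(2L * dh))
    }),
    Wfc = takeMat(1L, poolDim),
    b = takeVec(1L)
  )
}

#' Parameter count and communication payload of a model
#'
#' @param model A \code{GatModel} or a bare parameter list.
#' @param overrideBytes Optional explicit payload in bytes (e.g. a reported
#'   message size); when the model carries a \code{payloadOverride}, that is
#'   used. Default payload is 4 bytes per parameter (FP32).
#' @return Integer parameter count / numeric payload in bytes.
#' @export
parameterCount <- function(model) {
  params <- if (is(model, "GatModel")) model@params else model
  length(flattenParams(params))
}

#' @rdname parameterCount
#' @export
payloadBytes <- function(model, overrideBytes = NULL) {
  if (!is.null(overrideBytes)) return(as.numeric(overrideBytes))
  if (is(model, "GatModel") && !is.na(model@payloadOverride)) {
    return(model@payloadOverride)
  }
  4 * parameterCount(model)
}

## ---- batched tensors -------------------------------------------------------

#' Prepare graphs for the batched GAT engine
#'
#' Precomputes, per graph, the d0 x (N*T) input feature matrix (columns
#' ordered node-fast within time) and the flattened self-loop-augmented
#' neighborhood mask. All graphs must share N and T.
#'
#' @param graphs List of \code{FeatureGraph}.
#' @return Prepared list consumed by the training and prediction routines.
#' @export
prepareGraphs <- function(graphs) {
  if (length(graphs) == 0L) stop("no graphs to prepare")
  d <- dim(graphs[[1]]@nodeFeatures)
  N <- d[1]; Tn <- d[2]; d0 <- d[3]
  H0 <- vector("list", length(graphs))
  maskMat <- vector("list", length(graphs))
  for (g in seq_along(graphs)) {
    gr <- graphs[[g]]
    dg <- dim(gr@nodeFeatures)
    if (!identical(dg, d)) stop("all graphs in a batch must share N, T, steps")
    h <- aperm(gr@nodeFeatures, c(3L, 1L, 2L))
    dim(h) <- c(d0, N * Tn)
    H0[[g]] <- h
    m <- gr@adjacency != 0
    diag(m) <- TRUE # self-loops: i is always in its own neighborhood
    maskMat[[g]] <- matrix(as.numeric(m), N * N, Tn)
  }
  list(
    H0 = H0, maskMat = maskMat,
    y = vapply(graphs, function(g) g@label, integer(1)),
    N = N, T = Tn, d0 = d0
  )
}

makeBatch <- function(prep, idx) {
  N <- prep$N; Tn <- prep$T
  B <- length(idx)
  S <- B * Tn
  H0 <- do.call(cbind, prep$H0[idx])
  M <- do.call(cbind, prep$maskMat[idx])
  list(H0 = H0, M = M, y = prep$y[idx], N = N, T = Tn, B = B, S = S)
}

## One attention layer over the batched column axis. The per-slice score /
## softmax / dropout / aggregation kernel runs in C++; the large linear
## products stay in R's BLAS. Returns output and, when keepCache, everything
## backward needs.
attnLayerForward <- function(Hin, headPars, batch, slope, dropout, training,
                             combine, keepCache = FALSE) {
  N <- batch$N
  K <- length(headPars)
  dh <- nrow(headPars[[1]]$W)
  outs <- vector("list", K)
  caches <- if (keepCache) vector("list", K) else NULL
  for (k in seq_len(K)) {
    W <- headPars[[k]]$W
    a <- headPars[[k]]$a
    Z <- W %*% Hin
    u <- as.vector(a[seq_len(dh)] %*% Z)
    v <- as.vector(a[dh + seq_len(dh)] %*% Z)
    kern <- .attnHeadForwardCpp(Z, u, v, batch$M, N, batch$T, slope, dropout,
                                training, !keepCache)
    outs[[k]] <- kern$Hrelu
    if (keepCache) {
      caches[[k]] <- list(
        Z = Z, u = u, v = v, alpha = kern$alpha,
        dmask = kern$dmask, Hrelu = kern$Hrelu
      )
    }
  }
  Hout <- if (combine == "concat") do.call(rbind, outs)
          else Reduce(`+`, outs) / K
  list(H = Hout, caches = caches)
}

## Backward through one attention layer. dHout: gradient w.r.t. the combined
## output. Returns per-head parameter grads and the gradient w.r.t. Hin.
attnLayerBackward <- function(dHout, Hin, headPars, caches, batch, combine,
                              slope) {
  N <- batch$N
  K <- length(headPars)
  dh <- nrow(headPars[[1]]$W)
  dHin <- matrix(0, nrow(Hin), ncol(Hin))
  gradHeads <- vector("list", K)
  for (k in seq_len(K)) {
    ch <- caches[[k]]
    W <- headPars[[k]]$W
    a <- headPars[[k]]$a
    dHrelu <- if (combine == "concat") {
      dHout[(k - 1L) * dh + seq_len(dh), , drop = FALSE]
    } else {
      dHout / K
    }
    kern <- .attnHeadBackwardCpp(ch$Z, dHrelu, ch$Hrelu, ch$alpha, ch$dmask,
                                 ch$u, ch$v, batch$M, N, batch$T, slope,
                                 a[seq_len(dh)], a[dh + seq_len(dh)])
    gradHeads[[k]] <- list(W = tcrossprod(kern$dZ, Hin),
                           a = c(as.vector(kern$daSrc),
                                 as.vector(kern$daDst)))
    dHin <- dHin + crossprod(W, kern$dZ)
  }
  list(gradHeads = gradHeads, dHin = dHin)
}

## Full forward pass over a batch. Returns probabilities and (optionally)
## the cache needed for backward / attention extraction.
gatBatchForward <- function(params, config, batch, training = FALSE,
                            keepCache = FALSE) {
  N <- batch$N; Tn <- batch$T; B <- batch$B
  H1 <- params$W1 %*% batch$H0
  l1 <- attnLayerForward(H1, params$layer1, batch, config@leakySlope,
                         config@dropout, training, "concat", keepCache)
  H2 <- l1$H
  hmask <- NULL
  if (training && config@dropout > 0) {
    hmask <- matrix(
      (stats::runif(length(H2)) >= config@dropout) / (1 - config@dropout),
      nrow(H2), ncol(H2)
    )
    H2 <- H2 * hmask
  }
  l2 <- attnLayerForward(H2, params$layer2, batch, config@leakySlope,
                         config@dropout, training, config@secondLayerMode,
                         keepCache)
  H3 <- l2$H
  NT <- N * Tn
  G <- matrix(0, nrow(H3), B)
  for (g in seq_len(B)) {
    G[, g] <- .rowMeans(H3[, (g - 1L) * NT + seq_len(NT), drop = FALSE],
                        nrow(H3), NT)
  }
  logit <- as.vector(params$Wfc %*% G) + params$b
  prob <- stats::plogis(logit)
  out <- list(prob = prob, logit = logit)
  if (keepCache) {
    out$cache <- list(H1 = H1, l1 = l1$caches, hmask = hmask, H2 = H2,
                      l2 = l2$caches, G = G)
  }
  out
}

## Backward pass: returns the full parameter gradient (same structure as
## params) given dLoss/dLogit.
gatBatchBackward <- function(params, config, batch, fw, dLogit) {
  N <- batch$N; Tn <- batch$T; B <- batch$B
  NT <- N * Tn
  cache <- fw$cache
  dWfc <- matrix(dLogit, 1L) %*% t(cache$G)
  db <- sum(dLogit)
  dG <- t(params$Wfc) %*% matrix(dLogit, 1L)
  dH3 <- dG[, rep(seq_len(B), each = NT), drop = FALSE] / NT
  bl2 <- attnLayerBackward(dH3, cache$H2, params$layer2, cache$l2, batch,
                           config@secondLayerMode, config@leakySlope)
  dH2 <- bl2$dHin
  if (!is.null(cache$hmask)) dH2 <- dH2 * cache$hmask
  bl1 <- attnLayerBackward(dH2, cache$H1, params$layer1, cache$l1, batch,
                           "concat", config@leakySlope)
  dH1 <- bl1$dHin
  dW1 <- tcrossprod(dH1, batch$H0)
  list(W1 = dW1, layer1 = bl1$gradHeads, layer2 = bl2$gradHeads,
       Wfc = dWfc, b = db)
}

## ---- loss and optimizer ----------------------------------------------------

bceLoss <- function(prob, y, eps = 1e-15) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adamInit <- function(nParams) {
  list(m = numeric(nParams), v = numeric(nParams), t = 0L)
}

adamStep <- function(state, flatParams, flatGrad, lr, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * flatGrad
  state$v <- beta2 * state$v + (1 - beta2) * flatGrad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(params = flatParams - lr * mh / (sqrt(vh) + eps), state = state)
}

## One optimization epoch (shuffle + mini-batches) over prepared graphs.
## optimizer = "adam" carries state across calls; "sgd" takes plain steps
## (used for post-distribution fine-tuning). Consumes the current RNG stream.
trainOneEpoch <- function(prep, params, adamState, config, lr, batchSize,
                          optimizer = "adam") {
  nG <- length(prep$y)
  ord <- sample.int(nG)
  losses <- numeric(0)
  for (start in seq(1L, nG, by = batchSize)) {
    idx <- ord[start:min(start + batchSize - 1L, nG)]
    batch <- makeBatch(prep, idx)
    fw <- gatBatchForward(params, config, batch, training = TRUE,
                          keepCache = TRUE)
    losses <- c(losses, bceLoss(fw$prob, batch$y))
    dLogit <- (fw$prob - batch$y) / length(idx)
    grads <- gatBatchBackward(params, config, batch, fw, dLogit)
    flatG <- flattenParams(grads)
    flatP <- flattenParams(params)
    if (optimizer == "adam") {
      upd <- adamStep(adamState, flatP, flatG, lr)
      adamState <- upd$state
      flatP <- upd$params
    } else {
      flatP <- flatP - lr * flatG
    }
    params <- unflattenParams(flatP, config)
  }
  list(params = params, adamState = adamState, loss = mean(losses))
}

## ---- public training / prediction -----------------------------------------

#' Train the centralized GAT classifier
#'
#' Minimizes mean binary cross-entropy by mini-batch Adam over the training
#' graphs, logging per-epoch training loss and (when a validation set is
#' given) validation accuracy and log loss. Fully reproducible from
#' \code{trainCfg@seed}, which drives initialization, shuffling and dropout.
#'
#' @param trainGraphs List of \code{FeatureGraph} (both classes present).
#' @param valGraphs Optional validation graphs.
#' @param config A \code{\link{gatConfig}}.
#' @param trainCfg A \code{\link{trainConfig}}.
#' @return List with \code{model} (a \code{GatModel}) and \code{history}
#'   (data frame: epoch, loss, valAccuracy, valLogLoss).
#' @export
trainCentralized <- function(trainGraphs, valGraphs = NULL,
                             config = gatConfig(), trainCfg = trainConfig()) {
  prep <- prepareGraphs(trainGraphs)
  if (length(unique(prep$y)) < 2L) {
    stop("training set must contain both classes")
  }
  if (prep$d0 != config@d0) {
    stop(sprintf("config d0=%d but graphs carry %d history steps",
                 config@d0, prep$d0))
  }
  valPrep <- if (!is.null(valGraphs)) prepareGraphs(valGraphs) else NULL
  set.seed(trainCfg@seed)
  params <- initGatParams(config)
  params$b <- priorLogit(prep$y)
  adamState <- adamInit(length(flattenParams(params)))
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     valAccuracy = numeric(0), valLogLoss = numeric(0))
  for (epoch in seq_len(trainCfg@epochs)) {
    res <- trainOneEpoch(prep, params, adamState, config, trainCfg@lr,
                         trainCfg@batchSize)
    params <- res$params
    adamState <- res$adamState
    valAcc <- NA_real_
    valLL <- NA_real_
    if (!is.null(valPrep)) {
      vp <- predictPrep(params, config, valPrep)
      valAcc <- mean((vp >= 0.5) == (valPrep$y == 1L))
      valLL <- bceLoss(vp, valPrep$y)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = res$loss,
                                   valAccuracy = valAcc, valLogLoss = valLL))
  }
  list(
    model = new("GatModel", params = params, config = config,
                payloadOverride = NA_real_),
    history = hist
  )
}

## Prediction on prepared graphs, chunked to bound memory. No RNG use.
predictPrep <- function(params, config, prep, chunk = 256L) {
  nG <- length(prep$y)
  out <- numeric(nG)
  for (start in seq(1L, nG, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nG)
    batch <- makeBatch(prep, idx)
    out[idx] <- gatBatchForward(params, config, batch)$prob
  }
  out
}

#' Predict AKI probabilities for graphs
#'
#' @param model A \code{GatModel}.
#' @param graphs List of \code{FeatureGraph}.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
gatPredict <- function(model, graphs) {
  predictPrep(model@params, model@config, prepareGraphs(graphs))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a JSON file holding the architecture manifest and the
#' flat parameter vector at full precision; the round trip is loss-free.
#'
#' @param model A \code{GatModel}.
#' @param path File path.
#' @return \code{loadModel}: the restored \code{GatModel}.
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  obj <- list(
    format = "akigraph-checkpoint-v1",
    payloadOverride = if (is.na(model@payloadOverride)) NULL
                      else model@payloadOverride,
    config = list(d0 = cfg@d0, dh = cfg@dh, heads = cfg@heads,
                  dropout = cfg@dropout, leakySlope = cfg@leakySlope,
                  secondLayerMode = cfg@secondLayerMode),
    flat = flattenParams(model@params)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- gatConfig(d0 = obj$config$d0, dh = obj$config$dh,
                   heads = obj$config$heads, dropout = obj$config$dropout,
                   leakySlope = obj$config$leakySlope,
                   secondLayerMode = obj$config$secondLayerMode)
  new("GatModel", params = unflattenParams(obj$flat, cfg), config = cfg,
      payloadOverride = if (is.null(obj$payloadOverride)) NA_real_
                        else as.numeric(obj$payloadOverride))
}
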