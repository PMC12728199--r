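## Reference (single-node / single-pair) graph-attention primitives. These
## are the readable, equation-level definitions; training and prediction use
## the batched engine in gat-model.R, which is cross-checked against a
## composition of these primitives in the test suite.

#' Linear input transform of a node feature vector
#'
#' Lifts the raw temporal node feature vector into the hidden space:
#' \code{h1 = W1 h0}.
#'
#' @param h0 Input vector (length d0).
#' @param W1 Weight matrix dh x d0.
#' @return Hidden vector of length dh.
#' @export
linearTransform <- function(h0, W1) {
  if (ncol(W1) != length(h0)) stop("shape mismatch: ncol(W1) != length(h0)")
  as.vector(W1 %*% h0)
}

#' Unnormalized attention score between two nodes
#'
#' \code{e_ij = LeakyReLU(a . [W h_i || W h_j])}, with the receiver's
#' transformed vector concatenated first.
#'
#' @param h1i,h1j Hidden vectors of receiver i and neighbor j.
#' @param W Per-head transform matrix dh x dh.
#' @param a Attention vector of length 2*dh.
#' @param leakySlope Negative slope of the LeakyReLU (default 0.2).
#' @return Scalar attention score.
#' @export
attentionScores <- function(h1i, h1j, W, a, leakySlope = 0.2) {
  zi <- W %*% h1i
  zj <- W %*% h1j
  if (length(a) != 2L * nrow(W)) stop("shape mismatch: length(a) != 2*dh")
  pre <- sum(a * c(zi, zj))
  if (pre > 0) pre else leakySlope * pre
}

#' Softmax-normalized attention coefficients over a neighborhood
#'
#' \code{alpha_ij = exp(e_ij) / sum_m exp(e_im)}, numerically stabilized by
#' max subtraction. Self-loops guarantee a non-empty neighborhood.
#'
#' @param scores Numeric vector of attention scores over the neighborhood.
#' @return Coefficients summing to 1.
#' @export
attentionSoftmax <- function(scores) {
  if (length(scores) == 0L) stop("empty neighborhood")
  z <- exp(scores - max(scores))
  z / sum(z)
}

#' Attention-weighted neighborhood aggregation
#'
#' \code{h'_i = ReLU(sum_j alpha_ij W h_j)} for one head.
#'
#' @param alpha Normalized coefficients (length m).
#' @param neighborH Matrix of neighbor hidden vectors, dh x m (already
#'   transformed by W when \code{W} is \code{NULL}).
#' @param W Optional per-head transform applied to the columns first.
#' @return Updated node vector of length dh.
#' @export
aggregateNeighbors <- function(alpha, neighborH, W = NULL) {
  if (!is.null(W)) neighborH <- W %*% neighborH
  pmax(as.vector(neighborH %*% alpha), 0)
}

#' Concatenate per-head outputs
#'
#' Stacks K head outputs of dimension dh into a single K*dh vector, in head
#' order.
#'
#' @param headOutputs List of K vectors.
#' @return Vector of length K*dh.
#' @export
concatHeads <- function(headOutputs) {
  unlist(headOutputs, use.names = FALSE)
}

#' Reference forward pass on a single graph
#'
#' A direct, loop-based composition of the primitive operations: input
#' transform, two multi-head attention layers (first concatenated, second
#' averaged or concatenated per the config), global mean pooling over nodes
#' and time, and the sigmoid output head. Slow by construction; used as the
#' independent cross-check of the batched engine.
#'
#' @param params Parameter list (see \code{\link{initGatParams}}).
#' @param config A \code{\link{gatConfig}}.
#' @param graph A \code{FeatureGraph}.
#' @return Predicted AKI probability in (0, 1).
#' @export
gatForwardReference <- function(params, config, graph) {
  H0 <- graph@nodeFeatures
  N <- dim(H0)[1]
  Tn <- dim(H0)[2]
  K <- config@heads
  nbrs <- lapply(seq_len(N), function(i) {
    sort(union(i, which(graph@adjacency[i, ] != 0)))
  })
  attnLayer <- function(Hin, headPars, combine) {
    out <- vector("list", K)
    for (k in seq_len(K)) {
      W <- headPars[[k]]$W
      a <- headPars[[k]]$a
      Hk <- array(0, dim = c(nrow(W), N, Tn))
      for (t in seq_len(Tn)) {
        Z <- W %*% Hin[, , t]
        for (i in seq_len(N)) {
          js <- nbrs[[i]]
          e <- vapply(js, function(j) {
            pre <- sum(a * c(Z[, i], Z[, j]))
            if (pre > 0) pre else config@leakySlope * pre
          }, numeric(1))
          alpha <- attentionSoftmax(e)
          Hk[, i, t] <- aggregateNeighbors(alpha, Z[, js, drop = FALSE])
        }
      }
      out[[k]] <- Hk
    }
    if (combine == "concat") {
      res <- array(0, dim = c(K * nrow(headPars[[1]]$W), N, Tn))
      for (k in seq_len(K)) {
        rows <- (k - 1L) * nrow(headPars[[k]]$W) + seq_len(nrow(headPars[[k]]$W))
        res[rows, , ] <- out[[k]]
      }
      res
    } else {
      Reduce(`+`, out) / K
    }
  }
  ## input transform: d0 x N x T -> dh x N x T
  H0p <- aperm(H0, c(3, 1, 2)) # d0 x N x T
  H1 <- array(0, dim = c(config@dh, N, Tn))
  for (t in seq_len(Tn)) H1[, , t] <- params$W1 %*% H0p[, , t]
  H2 <- attnLayer(H1, params$layer1, "concat")
  H3 <- attnLayer(H2, params$layer2, config@secondLayerMode)
  hGlobal <- apply(H3, 1, mean)
  logit <- sum(params$Wfc * hGlobal) + params$b
  stats::plogis(logit)
}
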