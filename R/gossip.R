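## Decentralized training: gossip exchange, accuracy-ranked task scheduling,
## adaptive aggregation, global distribution with local fine-tuning, and a
## federated-averaging baseline with communication accounting.

## Private per-node RNG streams: each node owns a .Random.seed vector so
## local training draws (shuffles, dropout) are independent of protocol
## draws (peer selection), which keeps the one-node protocol bit-identical
## to centralized training.
getRngState <- function() {
  if (!exists(".Random.seed", envir = .GlobalEnv)) set.seed(NULL)
  get(".Random.seed", envir = .GlobalEnv)
}

setRngState <- function(state) {
  assign(".Random.seed", state, envir = .GlobalEnv)
}

#' Build node states for a decentralized run
#'
#' All nodes start from a common parameter initialization drawn under
#' \code{gossipCfg@seed}; node 1 inherits the post-initialization RNG stream
#' (so a single-node protocol reproduces centralized training exactly) and
#' the remaining nodes get derived private streams.
#'
#' @param shards List (length nNodes) of \code{list(train = , val = )} graph
#'   lists — disjoint local data.
#' @param config A \code{\link{gatConfig}}.
#' @param gossipCfg A \code{\link{gossipConfig}}.
#' @return List of \code{NodeState}.
#' @export
makeNodes <- function(shards, config, gossipCfg) {
  if (length(shards) != gossipCfg@nNodes) {
    stop("number of shards must equal gossipCfg@nNodes")
  }
  set.seed(gossipCfg@seed)
  params0 <- initGatParams(config)
  ## shared bias initialization at the pooled training prevalence
  allY <- unlist(lapply(shards, function(s) {
    vapply(s$train, function(g) g@label, integer(1))
  }))
  params0$b <- priorLogit(allY)
  nP <- length(flattenParams(params0))
  firstState <- getRngState()
  lapply(seq_along(shards), function(n) {
    if (n == 1L) {
      setRngState(firstState)
    } else {
      set.seed(deriveSeed(gossipCfg@seed, 100L + n))
    }
    new("NodeState",
      nodeId = as.integer(n), params = params0, prevParams = list(),
      valAccuracy = NA_real_, adamState = adamInit(nP),
      rngState = getRngState(),
      trainPrep = prepareGraphs(shards[[n]]$train),
      valPrep = if (length(shards[[n]]$val)) prepareGraphs(shards[[n]]$val)
                else list()
    )
  })
}

#' Parameter update of a node since its previous epoch
#'
#' \code{delta = theta^(t) - theta^(t-1)} on the flat parameter view — the
#' quantity a delta-payload gossip message would carry.
#'
#' @param node A \code{NodeState}.
#' @return Numeric vector of length \code{parameterCount}.
#' @export
computeDelta <- function(node) {
  if (length(node@prevParams) == 0L) {
    stop("node has no recorded previous parameters")
  }
  flattenParams(node@params) - flattenParams(node@prevParams)
}

## One local training epoch on the node's private RNG stream.
nodeLocalEpoch <- function(node, config, trainCfg, lr = trainCfg@lr,
                           optimizer = "adam") {
  node@prevParams <- node@params
  setRngState(node@rngState)
  res <- trainOneEpoch(node@trainPrep, node@params, node@adamState, config,
                       lr, trainCfg@batchSize, optimizer)
  node@rngState <- getRngState()
  node@params <- res$params
  if (optimizer == "adam") node@adamState <- res$adamState
  node
}

## Local validation accuracy at threshold 0.5 (no RNG use).
nodeValAccuracy <- function(node, config) {
  if (length(node@valPrep) == 0L) return(NA_real_)
  p <- predictPrep(node@params, config, node@valPrep)
  mean((p >= 0.5) == (node@valPrep$y == 1L))
}

#' Accuracy-ranked exchange schedule
#'
#' Orders nodes by local validation accuracy, highest first (ties broken by
#' node id ascending), so the most accurate node's update propagates earliest
#' in the round.
#'
#' @param nodes List of \code{NodeState} with validation accuracies set.
#' @return Integer vector of node ids in exchange order.
#' @export
scheduleExchanges <- function(nodes) {
  if (length(nodes) < 2L) return(integer(0))
  accs <- vapply(nodes, function(n) n@valAccuracy, numeric(1))
  ids <- vapply(nodes, function(n) n@nodeId, integer(1))
  ids[order(-accs, ids)]
}

## Merge a pair by element-wise parameter averaging (the default payload is
## the full parameter vector; both peers end up at the midpoint).
mergePair <- function(nodes, i1, i2, config) {
  avg <- (flattenParams(nodes[[i1]]@params) +
            flattenParams(nodes[[i2]]@params)) / 2
  p <- unflattenParams(avg, config)
  nodes[[i1]]@params <- p
  nodes[[i2]]@params <- p
  nodes
}

#' One gossip round: local epochs plus peer exchanges
#'
#' Every node trains one local epoch; each node then initiates one exchange.
#' Without scheduling, initiators run in id order and pick a uniformly random
#' distinct peer. With scheduling, initiators run in accuracy-ranked order
#' and pick a uniformly random strictly-lower-ranked peer (the last-ranked
#' node falls back to any other node), so either mode performs exactly one
#' exchange per node per round. Exchanged parameters are merged by
#' element-wise averaging. Peer draws come from \code{protocolState} (a
#' \code{.Random.seed} vector), not the node streams.
#'
#' @param nodes List of \code{NodeState}.
#' @param config A \code{\link{gatConfig}}.
#' @param trainCfg A \code{\link{trainConfig}}.
#' @param scheduling Logical; accuracy-ranked exchange order.
#' @param protocolState RNG state for peer selection (\code{NULL}: continue
#'   the current stream).
#' @param unreachable Integer node ids that cannot be contacted this round:
#'   they still train locally but neither initiate exchanges nor serve as
#'   peers — the round skips them and continues (simple dropout tolerance).
#' @return List with \code{nodes} and \code{protocolState}.
#' @export
gossipRound <- function(nodes, config, trainCfg, scheduling = FALSE,
                        protocolState = NULL, unreachable = integer(0)) {
  nodes <- lapply(nodes, nodeLocalEpoch, config = config, trainCfg = trainCfg)
  for (k in seq_along(nodes)) {
    nodes[[k]]@valAccuracy <- nodeValAccuracy(nodes[[k]], config)
  }
  if (length(nodes) >= 2L) {
    if (!is.null(protocolState)) setRngState(protocolState)
    ids <- vapply(nodes, function(n) n@nodeId, integer(1))
    down <- match(intersect(unreachable, ids), ids)
    order <- if (scheduling) scheduleExchanges(nodes) else ids
    idOf <- match(order, ids)
    for (r in seq_along(order)) {
      initiator <- idOf[r]
      if (initiator %in% down) next
      candidates <- if (scheduling && r < length(order)) {
        idOf[(r + 1L):length(order)]
      } else {
        setdiff(seq_along(nodes), initiator)
      }
      candidates <- setdiff(candidates, down)
      if (length(candidates) == 0L) next # no reachable peer: skip, continue
      peer <- if (length(candidates) == 1L) candidates else
        candidates[sample.int(length(candidates), 1L)]
      nodes <- mergePair(nodes, initiator, peer, config)
    }
    protocolState <- getRngState()
  }
  list(nodes = nodes, protocolState = protocolState)
}

#' Softmax aggregation weights from validation accuracies
#'
#' \code{p_n = exp(acc_n / temperature) / sum_m exp(acc_m / temperature)};
#' \code{mode = "equal"} returns uniform weights. Accuracies in [0, 1] at
#' temperature 1 yield near-uniform weights by construction.
#'
#' @param accs Numeric vector of validation accuracies.
#' @param mode \code{"adaptive"} or \code{"equal"}.
#' @param temperature Softmax temperature (default 1).
#' @return Weights summing to 1.
#' @export
aggregationWeights <- function(accs, mode = c("adaptive", "equal"),
                               temperature = 1) {
  mode <- match.arg(mode)
  n <- length(accs)
  if (mode == "equal") return(rep(1 / n, n))
  z <- accs / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Adaptive aggregation of node models into a global model
#'
#' Builds \code{theta_global = sum_n p_n theta_n} with accuracy-softmax
#' weights (or uniform weights under \code{mode = "equal"}).
#'
#' @param nodes List of \code{NodeState} (accuracies set for adaptive mode).
#' @param config A \code{\link{gatConfig}}.
#' @param mode \code{"adaptive"} or \code{"equal"}.
#' @param temperature Softmax temperature.
#' @return List with \code{params} (global parameter list) and
#'   \code{weights}.
#' @export
adaptiveAggregate <- function(nodes, config, mode = c("adaptive", "equal"),
                              temperature = 1) {
  mode <- match.arg(mode)
  accs <- vapply(nodes, function(n) n@valAccuracy, numeric(1))
  w <- aggregationWeights(accs, mode, temperature)
  flats <- lapply(nodes, function(n) flattenParams(n@params))
  glob <- Reduce(`+`, Map(`*`, flats, as.list(w)))
  list(params = unflattenParams(glob, config), weights = w)
}

#' Distribute the global model and fine-tune locally
#'
#' Sets every node's parameters to \code{globalParams}, then runs
#' \code{gossipCfg@fineTuneEpochs} epochs of plain gradient descent at the
#' fine-tuning rate eta on each node's local shard. Zero epochs or eta = 0
#' leave the global model intact.
#'
#' @param nodes List of \code{NodeState}.
#' @param globalParams Global parameter list.
#' @param config A \code{\link{gatConfig}}.
#' @param trainCfg A \code{\link{trainConfig}} (for the batch size).
#' @param gossipCfg A \code{\link{gossipConfig}}.
#' @return Updated node list.
#' @export
distributeAndFinetune <- function(nodes, globalParams, config, trainCfg,
                                  gossipCfg) {
  nodes <- lapply(nodes, function(n) {
    n@prevParams <- n@params
    n@params <- globalParams
    n
  })
  if (gossipCfg@fineTuneEpochs > 0L && gossipCfg@fineTuneLr > 0) {
    for (e in seq_len(gossipCfg@fineTuneEpochs)) {
      nodes <- lapply(nodes, nodeLocalEpoch, config = config,
                      trainCfg = trainCfg, lr = gossipCfg@fineTuneLr,
                      optimizer = "sgd")
    }
  }
  for (k in seq_along(nodes)) {
    nodes[[k]]@valAccuracy <- nodeValAccuracy(nodes[[k]], config)
  }
  nodes
}

#' Analytic communication ledger
#'
#' Per-participant per-round accounting: a gossip round costs one model
#' payload (each node exchanges with a single peer), a federated-averaging
#' round costs \code{nNodes} upload payloads (the server broadcast is not
#' counted by default).
#'
#' @param protocol \code{"gossip"} or \code{"fedavg"}.
#' @param rounds Number of rounds.
#' @param nNodes Number of participants.
#' @param payloadBytes Per-message payload in bytes.
#' @return A \code{CommLedger}.
#' @export
#' @examples
#' totalBytes(communicationLedger("fedavg", 1, 5, 27e6)) / 1e6 # 135 MB
communicationLedger <- function(protocol = c("gossip", "fedavg"), rounds,
                                nNodes, payloadBytes) {
  protocol <- match.arg(protocol)
  perRound <- if (protocol == "gossip") payloadBytes else nNodes * payloadBytes
  entries <- if (rounds > 0) {
    data.frame(round = seq_len(rounds), protocol = protocol,
               bytes = rep(perRound, rounds), stringsAsFactors = FALSE)
  } else {
    data.frame(round = integer(0), protocol = character(0),
               bytes = numeric(0), stringsAsFactors = FALSE)
  }
  new("CommLedger", entries = entries, payloadBytes = payloadBytes)
}

#' Run the decentralized gossip protocol
#'
#' Alternates local epochs and gossip exchanges for \code{gossipCfg@rounds}
#' rounds (scheduled or random peers), then performs one adaptive aggregation,
#' distributes the global model and fine-tunes it locally. With a single node
#' the protocol collapses to centralized training. All randomness is seeded;
#' the history records the per-round mean local validation accuracy and log
#' loss.
#'
#' @param shards List (length nNodes) of \code{list(train = , val = )} graph
#'   lists.
#' @param config A \code{\link{gatConfig}}.
#' @param trainCfg A \code{\link{trainConfig}}.
#' @param gossipCfg A \code{\link{gossipConfig}}.
#' @param payloadOverride Optional explicit payload bytes for the ledger.
#' @return List with \code{nodes}, \code{model} (global \code{GatModel}),
#'   \code{weights} (aggregation weights), \code{ledger}, \code{history}.
#' @export
runGossip <- function(shards, config = gatConfig(), trainCfg = trainConfig(),
                      gossipCfg = gossipConfig(), payloadOverride = NULL) {
  nodes <- makeNodes(shards, config, gossipCfg)
  payload <- if (is.null(payloadOverride)) {
    4 * length(flattenParams(nodes[[1]]@params))
  } else {
    payloadOverride
  }
  set.seed(deriveSeed(gossipCfg@seed, 999L))
  protocolState <- getRngState()
  hist <- data.frame(round = integer(0), meanValAccuracy = numeric(0),
                     meanValLogLoss = numeric(0))
  for (r in seq_len(gossipCfg@rounds)) {
    res <- gossipRound(nodes, config, trainCfg,
                       scheduling = gossipCfg@scheduling,
                       protocolState = protocolState)
    nodes <- res$nodes
    protocolState <- res$protocolState
    hist <- rbind(hist, data.frame(
      round = r,
      meanValAccuracy = mean(vapply(nodes, function(n) n@valAccuracy,
                                    numeric(1)), na.rm = TRUE),
      meanValLogLoss = meanValLogLoss(nodes, config)
    ))
  }
  agg <- adaptiveAggregate(nodes, config, mode = gossipCfg@aggregationMode,
                           temperature = gossipCfg@temperature)
  nodes <- distributeAndFinetune(nodes, agg$params, config, trainCfg,
                                 gossipCfg)
  ledger <- communicationLedger("gossip", gossipCfg@rounds,
                                gossipCfg@nNodes, payload)
  list(
    nodes = nodes,
    model = new("GatModel", params = agg$params, config = config,
                payloadOverride = if (is.null(payloadOverride)) NA_real_
                                  else payloadOverride),
    weights = agg$weights,
    ledger = ledger,
    history = hist
  )
}

meanValLogLoss <- function(nodes, config) {
  lls <- vapply(nodes, function(n) {
    if (length(n@valPrep) == 0L) return(NA_real_)
    bceLoss(predictPrep(n@params, config, n@valPrep), n@valPrep$y)
  }, numeric(1))
  mean(lls, na.rm = TRUE)
}

#' Run the federated-averaging baseline
#'
#' Per round, every node trains one local epoch starting from the current
#' global model (fresh optimizer state each round), uploads its parameters to
#' a virtual server that averages them uniformly, and receives the broadcast
#' back. The ledger counts \code{nNodes} upload payloads per round.
#'
#' @param shards List of \code{list(train = , val = )} graph lists.
#' @param config A \code{\link{gatConfig}}.
#' @param trainCfg A \code{\link{trainConfig}}.
#' @param rounds Number of communication rounds.
#' @param seed RNG seed.
#' @param payloadOverride Optional explicit payload bytes for the ledger.
#' @return List with \code{model}, \code{ledger}, \code{history}.
#' @export
runFedAvg <- function(shards, config = gatConfig(), trainCfg = trainConfig(),
                      rounds = 18L, seed = 1L, payloadOverride = NULL) {
  set.seed(seed)
  global <- initGatParams(config)
  global$b <- priorLogit(unlist(lapply(shards, function(s) {
    vapply(s$train, function(g) g@label, integer(1))
  })))
  nP <- length(flattenParams(global))
  preps <- lapply(shards, function(s) prepareGraphs(s$train))
  payload <- if (is.null(payloadOverride)) 4 * nP else payloadOverride
  hist <- data.frame(round = integer(0), meanLoss = numeric(0))
  for (r in seq_len(rounds)) {
    flats <- vector("list", length(shards))
    losses <- numeric(length(shards))
    for (n in seq_along(shards)) {
      set.seed(deriveSeed(seed, 1000L * r + n))
      res <- trainOneEpoch(preps[[n]], global, adamInit(nP), config,
                           trainCfg@lr, trainCfg@batchSize)
      flats[[n]] <- flattenParams(res$params)
      losses[n] <- res$loss
    }
    global <- unflattenParams(Reduce(`+`, flats) / length(flats), config)
    hist <- rbind(hist, data.frame(round = r, meanLoss = mean(losses)))
  }
  ledger <- communicationLedger("fedavg", rounds, length(shards), payload)
  list(
    model = new("GatModel", params = global, config = config,
                payloadOverride = if (is.null(payloadOverride)) NA_real_
                                  else payloadOverride),
    ledger = ledger,
    history = hist
  )
}
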