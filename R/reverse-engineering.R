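## ---- exact integer helpers -------------------------------------------
## Counts of consistent topologies overflow 2^53 (e.g. 3^36 for a 6-node
## enumeration), so exact values are carried as base-1e4 digit vectors
## (little-endian) and only multiplied by moderate scalars (< 2^31).

.bigFromScalar <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^31)
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) { d <- c(d, x %% 1e4); x <- x %/% 1e4 }
  d
}

.bigTimesScalar <- function(d, m) {
  stopifnot(m >= 0, m == floor(m), m < 2^31)
  if (m == 0) return(0)
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] * m + carry
    d[i] <- v %% 1e4
    carry <- v %/% 1e4
  }
  while (carry > 0) { d <- c(d, carry %% 1e4); carry <- carry %/% 1e4 }
  d
}

.bigProd <- function(xs) {
  d <- .bigFromScalar(1)
  for (x in xs) d <- .bigTimesScalar(d, x)
  d
}

.bigToString <- function(d) {
  d <- rev(d)
  paste0(d[1L], paste(sprintf("%04d", d[-1L]), collapse = ""))
}

#' Total number of signed topologies on N nodes
#'
#' Each ordered node pair independently carries activation, inhibition or
#' nothing, giving \code{3^(N^2)} topologies (self-edges included). The
#' exact value is computed in arbitrary precision since it exceeds
#' \code{2^53} already at N = 6.
#'
#' @param nNodes node count.
#' @param exact if \code{TRUE} return the exact value as a character
#'   string, otherwise a double.
#' @return character (exact) or double.
#' @examples
#' topologyCount(6)          # 1.500946e+17
#' topologyCount(6, TRUE)    # "150094635296999121"
#' @export
topologyCount <- function(nNodes, exact = FALSE) {
  d <- .bigProd(rep(3, nNodes^2))
  if (exact) .bigToString(d) else 3^(nNodes^2)
}

## ---- per-node consistency enumeration --------------------------------

## All 3^n regulation vectors over n sources, one row each.
.allConfigs <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), n),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

## Next bit of target node i for every config row, given current state s.
## Same dominant-inhibition semantics as .booleanStepRaw, evaluated per
## candidate regulation vector.
.configNext <- function(cfg, s, i) {
  n <- length(s)
  on <- which(s == 1L)
  onOther <- setdiff(on, i)
  if (length(onOther)) {
    sub <- cfg[, onOther, drop = FALSE]
    extAct <- rowSums(sub == 1L) > 0L
    extInh <- rowSums(sub == -1L) > 0L
  } else {
    extAct <- extInh <- rep(FALSE, nrow(cfg))
  }
  first <- if (s[i] == 1L) extAct | (cfg[, i] != -1L)
           else extAct | (cfg[, i] == 1L)
  as.integer(first & !extInh)
}

## Transition pairs of a trajectory: consecutive rows; the fixed point's
## self-transition is present because the terminal row is duplicated.
.transitions <- function(trajectory) {
  st <- booleanStates(trajectory)
  list(from = st[-nrow(st), , drop = FALSE],
       to = st[-1L, , drop = FALSE])
}

#' Regulator configurations of one node consistent with a trajectory
#'
#' Enumerates all \code{3^N} assignments of \{activation, inhibition,
#' none\} from every source node to the target node and keeps exactly
#' those that reproduce the target's bit at every transition of the
#' trajectory under the dominant-inhibition update. When the target is
#' the input node and \code{allowInputSelfLoop} is \code{FALSE},
#' assignments with a self-edge are discarded.
#'
#' @param trajectory a [BooleanTrajectory-class] with at least 2 states.
#' @param node target node index.
#' @param inputNode input node index (used only for the self-loop
#'   exclusion); \code{NA} to skip.
#' @param allowInputSelfLoop admit self-edges on the input node?
#' @return integer matrix, one row per consistent configuration, one
#'   column per source node, entries in \{-1, 0, +1\}.
#' @export
consistentConfigsForNode <- function(trajectory, node,
                                     inputNode = NA_integer_,
                                     allowInputSelfLoop = TRUE) {
  st <- booleanStates(trajectory)
  if (nrow(st) < 2L) stop("trajectory must have at least 2 states")
  n <- ncol(st)
  cfg <- .allConfigs(n)
  if (!is.na(inputNode) && node == inputNode && !allowInputSelfLoop)
    cfg <- cfg[cfg[, node] == 0L, , drop = FALSE]
  tr <- .transitions(trajectory)
  keep <- rep(TRUE, nrow(cfg))
  for (t in seq_len(nrow(tr$from))) {
    if (!any(keep)) break
    keep[keep] <- .configNext(cfg[keep, , drop = FALSE], tr$from[t, ], node) ==
      tr$to[t, node]
  }
  cfg[keep, , drop = FALSE]
}

#' Reverse-engineer all topologies consistent with a trajectory
#'
#' Runs [consistentConfigsForNode()] for every node. Because the update
#' of each node depends only on its own incoming regulation, the full
#' solution space factorises: any combination of per-node consistent
#' configurations yields a network that reproduces the trajectory.
#'
#' @param trajectory a [BooleanTrajectory-class].
#' @param inputNode input node index or name.
#' @param allowInputSelfLoop admit self-edges on the input node during
#'   enumeration? (The minimal-network step always excludes them.)
#' @param nodeNames optional labels; defaults to the trajectory's column
#'   names.
#' @return A [ConsistentSolutionSet-class].
#' @examples
#' fix <- loadSOSFixture()
#' sol <- reverseEngineer(fix$trajectory, inputNode = 1)
#' countConsistentNetworks(sol)    # 7104000
#' @export
reverseEngineer <- function(trajectory, inputNode,
                            allowInputSelfLoop = TRUE, nodeNames = NULL) {
  st <- booleanStates(trajectory)
  n <- ncol(st)
  if (is.null(nodeNames))
    nodeNames <- if (!is.null(colnames(st))) colnames(st)
                 else paste0("n", seq_len(n))
  if (is.character(inputNode)) {
    inputNode <- match(inputNode, nodeNames)
    if (is.na(inputNode)) stop("inputNode name not found")
  }
  perNode <- lapply(seq_len(n), function(i)
    consistentConfigsForNode(trajectory, i, inputNode = inputNode,
                             allowInputSelfLoop = allowInputSelfLoop))
  new("ConsistentSolutionSet", perNode = perNode, trajectory = trajectory,
      inputNode = as.integer(inputNode), nodeNames = as.character(nodeNames),
      allowInputSelfLoop = isTRUE(allowInputSelfLoop))
}

setMethod("show", "ConsistentSolutionSet", function(object) {
  k <- vapply(object@perNode, nrow, integer(1))
  cat(sprintf("ConsistentSolutionSet: %d nodes, per-node counts [%s]\n",
              length(k), paste(k, collapse = ", ")))
  cat(sprintf("  total consistent networks: %s (input self-loops %s)\n",
              countConsistentNetworks(object, exact = TRUE),
              if (object@allowInputSelfLoop) "allowed" else "excluded"))
})

#' Count all consistent networks
#'
#' The total is the product over nodes of the per-node consistent
#' configuration counts (the solution space is a Cartesian product).
#'
#' @param solutions a [ConsistentSolutionSet-class].
#' @param exact return the exact count as a character string instead of a
#'   double?
#' @return double, or character when \code{exact = TRUE}.
#' @export
countConsistentNetworks <- function(solutions, exact = FALSE) {
  k <- vapply(solutions@perNode, nrow, integer(1))
  if (exact) .bigToString(.bigProd(k)) else prod(as.numeric(k))
}

## Assemble a full network from one configuration row index per node.
.assembleNetwork <- function(solutions, idx) {
  n <- length(solutions@perNode)
  a <- matrix(0L, n, n)
  for (i in seq_len(n))
    a[, i] <- solutions@perNode[[i]][idx[i], ]
  SignedNetwork(a, inputNode = solutions@inputNode,
                nodeNames = solutions@nodeNames)
}

#' Minimal consistent networks
#'
#' For every node only the consistent configurations with the fewest
#' edges (non-zero entries) are kept — all ties at the minimum are
#' retained — and their Cartesian product is assembled into full
#' networks. Networks with a self-loop on the input node are then
#' discarded. The result is returned in a deterministic order
#' (lexicographic by the flattened adjacency matrix).
#'
#' @param solutions a [ConsistentSolutionSet-class].
#' @return list of [SignedNetwork-class] objects.
#' @examples
#' fix <- loadSOSFixture()
#' sol <- reverseEngineer(fix$trajectory, inputNode = 1)
#' length(minimalNetworks(sol))    # 48
#' @export
minimalNetworks <- function(solutions) {
  n <- length(solutions@perNode)
  kept <- lapply(solutions@perNode, function(m) {
    ec <- rowSums(m != 0L)
    m[ec == min(ec), , drop = FALSE]
  })
  counts <- vapply(kept, nrow, integer(1))
  combos <- as.matrix(expand.grid(lapply(counts, seq_len),
                                  KEEP.OUT.ATTRS = FALSE))
  inp <- solutions@inputNode
  nets <- list()
  for (r in seq_len(nrow(combos))) {
    a <- matrix(0L, n, n)
    for (i in seq_len(n)) a[, i] <- kept[[i]][combos[r, i], ]
    if (a[inp, inp] != 0L) next
    nets[[length(nets) + 1L]] <- a
  }
  if (!length(nets)) return(list())
  vecs <- do.call(rbind, lapply(nets, as.vector))
  ord <- do.call(order, lapply(seq_len(ncol(vecs)), function(j) vecs[, j]))
  lapply(nets[ord], function(a)
    SignedNetwork(a, inputNode = inp, nodeNames = solutions@nodeNames))
}

#' Sample candidate networks uniformly from the consistent set
#'
#' Draws each network by choosing, independently and uniformly, one
#' consistent configuration per node — uniform over the full Cartesian
#' product. Duplicate draws are discarded and redrawn, so the returned
#' networks are distinct.
#'
#' @param solutions a [ConsistentSolutionSet-class].
#' @param n number of distinct networks to draw.
#' @param seed integer seed (the draw is reproducible).
#' @return list of [SignedNetwork-class] objects, length \code{n}.
#' @export
sampleCandidateNetworks <- function(solutions, n, seed) {
  stopifnot(n >= 1)
  counts <- vapply(solutions@perNode, nrow, integer(1))
  total <- prod(as.numeric(counts))
  if (n > total)
    stop("requested ", n, " networks but only ", total, " distinct ones exist")
  set.seed(as.integer(seed))
  chosen <- character(0)
  nets <- vector("list", n)
  got <- 0L
  while (got < n) {
    idx <- vapply(counts, function(k) sample.int(k, 1L), integer(1))
    key <- paste(idx, collapse = ".")
    if (key %in% chosen) next
    chosen <- c(chosen, key)
    got <- got + 1L
    nets[[got]] <- .assembleNetwork(solutions, idx)
  }
  nets
}
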