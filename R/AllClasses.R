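#' @import methods
NULL

#' Signed directed regulatory network
#'
#' An N-node network is stored as a signed adjacency matrix \code{a[i, j]}
#' with \code{+1} meaning activation from node \code{i} to node \code{j},
#' \code{-1} inhibition, and \code{0} no regulation. A single signed entry
#' per ordered pair enforces that activation and inhibition are mutually
#' exclusive. One node is designated the input node (the signal, e.g. ssDNA
#' in the SOS response); by convention its clearance is modelled as
#' inhibition by downstream repair nodes.
#'
#' @slot adjacency integer matrix, entries in \{-1, 0, +1\};
#'   \code{adjacency[i, j]} is the regulation from node i to node j.
#' @slot inputNode integer scalar, index of the input (signal) node.
#' @slot nodeNames character vector of node labels, one per node.
#'
#' @seealso [SignedNetwork()] for the constructor, [booleanStep()],
#'   [simulateBoolean()].
#' @export
setClass("SignedNetwork",
  slots = c(adjacency = "matrix", inputNode = "integer",
            nodeNames = "character"))

setValidity("SignedNetwork", function(object) {
  a <- object@adjacency
  if (!is.numeric(a) || nrow(a) != ncol(a))
    return("adjacency must be a square numeric matrix")
  if (nrow(a) < 1L)
    return("network needs at least one node")
  if (!all(a %in% c(-1L, 0L, 1L)))
    return("adjacency entries must be -1, 0 or +1")
  n <- nrow(a)
  if (length(object@inputNode) != 1L || is.na(object@inputNode) ||
      object@inputNode < 1L || object@inputNode > n)
    return("inputNode must be a single valid node index")
  if (length(object@nodeNames) != n)
    return("nodeNames length must equal the number of nodes")
  if (anyDuplicated(object@nodeNames))
    return("nodeNames must be unique")
  TRUE
})

#' Create a SignedNetwork
#'
#' @param adjacency square matrix with entries in \{-1, 0, +1\};
#'   \code{adjacency[i, j]} is the regulation from node i to node j
#'   (+1 activation, -1 inhibition).
#' @param inputNode index (or name) of the input/signal node.
#' @param nodeNames optional character labels; defaults to the matrix
#'   dimnames or \code{"n1"..."nN"}.
#' @return A [SignedNetwork-class] object.
#' @examples
#' a <- matrix(0L, 2, 2); a[1, 2] <- 1L; a[2, 1] <- -1L
#' net <- SignedNetwork(a, inputNode = 1, nodeNames = c("sig", "rep"))
#' nNodes(net)
#' @export
SignedNetwork <- function(adjacency, inputNode = 1L, nodeNames = NULL) {
  a <- as.matrix(adjacency)
  storage.mode(a) <- "integer"
  if (nrow(a) != ncol(a))
    stop("adjacency must be a square matrix")
  n <- nrow(a)
  if (is.null(nodeNames))
    nodeNames <- if (!is.null(rownames(a))) rownames(a) else paste0("n", seq_len(n))
  if (is.character(inputNode)) {
    inputNode <- match(inputNode, nodeNames)
    if (is.na(inputNode)) stop("inputNode name not found in nodeNames")
  }
  dimnames(a) <- list(nodeNames, nodeNames)
  new("SignedNetwork", adjacency = a, inputNode = as.integer(inputNode),
      nodeNames = as.character(nodeNames))
}

#' Boolean state trajectory
#'
#' An ordered sequence of 0/1 network states, one row per discrete time
#' step. When the dynamics reach a fixed point the repeated terminal state
#' is kept as the last row and \code{terminalFixedPoint} is set, so that
#' consecutive row pairs enumerate every transition constraint including
#' the fixed point's self-transition (the system returns to its normal
#' state and stays there).
#'
#' @slot states integer matrix of 0/1 values, rows = time steps,
#'   columns = nodes.
#' @slot terminalFixedPoint logical; the last state maps to itself.
#' @slot cycleStart integer; if a limit cycle was detected, the row index
#'   where the cycle re-enters, otherwise \code{NA}.
#' @export
setClass("BooleanTrajectory",
  slots = c(states = "matrix", terminalFixedPoint = "logical",
            cycleStart = "integer"))

setValidity("BooleanTrajectory", function(object) {
  s <- object@states
  if (nrow(s) < 2L) return("a trajectory needs at least 2 states")
  if (!all(s %in% c(0L, 1L))) return("states must be 0/1")
  if (length(object@terminalFixedPoint) != 1L)
    return("terminalFixedPoint must be a single flag")
  if (isTRUE(object@terminalFixedPoint) &&
      !identical(s[nrow(s), ], s[nrow(s) - 1L, ]))
    return("terminalFixedPoint set but last state is not repeated")
  TRUE
})

#' Create a BooleanTrajectory
#'
#' @param states 0/1 matrix (rows = time steps) or list of 0/1 vectors.
#' @param terminalFixedPoint logical; if \code{TRUE} and the last row is
#'   not already a repeat of the previous one, the terminal row is
#'   duplicated so the self-transition is explicit.
#' @param cycleStart row index at which a detected limit cycle re-enters,
#'   or \code{NA} (default).
#' @return A [BooleanTrajectory-class] object.
#' @export
BooleanTrajectory <- function(states, terminalFixedPoint = FALSE,
                              cycleStart = NA_integer_) {
  if (is.list(states)) states <- do.call(rbind, states)
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (isTRUE(terminalFixedPoint) && nrow(states) >= 1L &&
      (nrow(states) < 2L ||
       !identical(states[nrow(states), ], states[nrow(states) - 1L, ])))
    states <- rbind(states, states[nrow(states), , drop = FALSE])
  new("BooleanTrajectory", states = states,
      terminalFixedPoint = isTRUE(terminalFixedPoint),
      cycleStart = as.integer(cycleStart))
}

#' Per-node sets of trajectory-consistent regulator configurations
#'
#' The result of reverse engineering: for every target node, the list of
#' regulation vectors (one signed entry per source node) that reproduce
#' the node's bit at every transition of the constraining trajectory.
#' The full solution space is the Cartesian product over nodes, so the
#' total network count is the product of the per-node list lengths.
#'
#' @slot perNode list of integer matrices; element i has one row per
#'   consistent configuration of node i, columns = source nodes,
#'   entries in \{-1, 0, +1\}.
#' @slot trajectory the constraining [BooleanTrajectory-class].
#' @slot inputNode integer, index of the input node.
#' @slot nodeNames character labels.
#' @slot allowInputSelfLoop logical; whether self-edges on the input node
#'   were admitted during enumeration.
#' @export
setClass("ConsistentSolutionSet",
  slots = c(perNode = "list", trajectory = "BooleanTrajectory",
            inputNode = "integer", nodeNames = "character",
            allowInputSelfLoop = "logical"))

setValidity("ConsistentSolutionSet", function(object) {
  n <- ncol(object@trajectory@states)
  if (length(object@perNode) != n)
    return("perNode must have one element per node")
  for (i in seq_len(n)) {
    m <- object@perNode[[i]]
    if (!is.matrix(m) || ncol(m) != n)
      return("each perNode element must be a matrix with one column per source")
    if (nrow(m) < 1L)
      return(sprintf("node %d has no consistent configuration", i))
  }
  TRUE
})

#' Continuous (ODE) trajectory
#'
#' Concentrations over time from numerical integration of the
#' Hill-kinetics model.
#'
#' @slot times increasing numeric vector of report times.
#' @slot values numeric matrix, rows = times, columns = nodes;
#'   finite and non-negative.
#' @export
setClass("ContinuousTrajectory",
  slots = c(times = "numeric", values = "matrix"))

setValidity("ContinuousTrajectory", function(object) {
  if (length(object@times) != nrow(object@values))
    return("times length must match number of value rows")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (!all(is.finite(object@values)))
    return("values must be finite")
  if (any(object@values < 0))
    return("values must be non-negative")
  TRUE
})
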