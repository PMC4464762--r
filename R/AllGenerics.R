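#' Number of nodes
#' @param x a [SignedNetwork-class] or [BooleanTrajectory-class].
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Signed adjacency matrix
#' @param x a [SignedNetwork-class].
#' @return integer matrix, entries in \{-1, 0, +1\}.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Input (signal) node index
#' @param x a [SignedNetwork-class] or [ConsistentSolutionSet-class].
#' @return integer index.
#' @export
setGeneric("inputNode", function(x) standardGeneric("inputNode"))

#' Node labels
#' @param x an object carrying node labels.
#' @return character vector.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Matrix of 0/1 states (rows = time steps)
#' @param x a [BooleanTrajectory-class].
#' @return integer matrix.
#' @export
setGeneric("booleanStates", function(x) standardGeneric("booleanStates"))

#' Did the discrete dynamics reach a fixed point?
#' @param x a [BooleanTrajectory-class].
#' @return logical flag.
#' @export
setGeneric("terminalFixedPoint",
           function(x) standardGeneric("terminalFixedPoint"))

#' One synchronous update of the Boolean dynamics
#'
#' Applies the dominant-inhibition update rule: a node with at least one
#' active inhibitor (other than itself) switches OFF regardless of its
#' activators; otherwise it switches ON if any activator is active; with
#' zero net input it keeps its state. Self-edges follow the constraint
#' form of the update: an ON node stays ON unless self-inhibited, and an
#' OFF self-activated node switches ON when uninhibited. The input node
#' obeys the same rule (its clearance is inhibition by repair nodes).
#'
#' @param network a [SignedNetwork-class].
#' @param state 0/1 vector, one entry per node.
#' @return integer 0/1 vector: the next state.
#' @examples
#' sos <- sosNetwork()
#' booleanStep(sos, c(1, 0, 1, 0, 0, 0))
#' @export
setGeneric("booleanStep", function(network, state)
  standardGeneric("booleanStep"))

#' Simulate the discrete dynamics to an attractor
#'
#' Iterates [booleanStep()] from an initial state until the first repeated
#' state (fixed point or limit cycle) or until \code{maxSteps} updates.
#' Non-convergence is reported in the result, never raised.
#'
#' @param network a [SignedNetwork-class].
#' @param initial 0/1 vector.
#' @param maxSteps maximum number of updates (default \code{2^N + 1},
#'   enough to guarantee a repeat).
#' @return A [BooleanTrajectory-class]; for a fixed point the repeated
#'   terminal state is the last row and \code{terminalFixedPoint(x)} is
#'   \code{TRUE}; for a cycle the first revisited state closes the matrix
#'   and the cycle entry row is recorded.
#' @export
setGeneric("simulateBoolean", function(network, initial, maxSteps = NULL)
  standardGeneric("simulateBoolean"))

#' Basin size of a Boolean fixed point
#'
#' Exhaustively enumerates all \code{2^N} initial states and counts how
#' many converge to the given attractor.
#'
#' @param network a [SignedNetwork-class].
#' @param attractor 0/1 vector that must be a fixed point of the update.
#' @return integer count in \code{[1, 2^N]}.
#' @export
setGeneric("booleanBasinSize", function(network, attractor)
  standardGeneric("booleanBasinSize"))
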