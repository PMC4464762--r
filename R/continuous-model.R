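#' Free parameters of the Hill-kinetics model for a topology
#'
#' Every activation edge j -> i contributes a kinetic constant \code{a}
#' and a dissociation constant \code{b}; every inhibition edge
#' contributes saturation/weight constants \code{c} and \code{d}; three
#' global parameters \code{Wp}, \code{Wn} (relative weights of
#' activation and inhibition) and \code{delta} (promoter leakage,
#' scaling every \code{b}) complete the set. The Hill coefficient is
#' fixed at 2, basal production at 0.1 and the degradation rate at 1.
#'
#' @param network a [SignedNetwork-class].
#' @return data.frame with columns \code{name}, \code{type} (one of
#'   \code{a, b, c, d, Wp, Wn, delta}), \code{from}, \code{to}
#'   (\code{NA} for globals); edges ordered by target then source.
#' @export
parameterInfo <- function(network) {
  a <- adjacency(network)
  ord <- function(m) m[order(m[, 2L], m[, 1L]), , drop = FALSE]
  actE <- ord(which(a == 1L, arr.ind = TRUE))
  inhE <- ord(which(a == -1L, arr.ind = TRUE))
  rows <- list()
  for (k in seq_len(nrow(actE)))
    for (tp in c("a", "b"))
      rows[[length(rows) + 1L]] <-
        data.frame(name = sprintf("%s_%d_%d", tp, actE[k, 1L], actE[k, 2L]),
                   type = tp, from = actE[k, 1L], to = actE[k, 2L])
  for (k in seq_len(nrow(inhE)))
    for (tp in c("c", "d"))
      rows[[length(rows) + 1L]] <-
        data.frame(name = sprintf("%s_%d_%d", tp, inhE[k, 1L], inhE[k, 2L]),
                   type = tp, from = inhE[k, 1L], to = inhE[k, 2L])
  for (tp in c("Wp", "Wn", "delta"))
    rows[[length(rows) + 1L]] <-
      data.frame(name = tp, type = tp, from = NA_integer_, to = NA_integer_)
  do.call(rbind, rows)
}

#' Default parameter sampling ranges
#'
#' Log-uniform two-decade spans around 1 for the per-edge constants and
#' \code{[0.5, 5]} for the global weights and leakage. Q values are only
#' meaningful relative to a declared range; override per type to probe a
#' different regime.
#'
#' @return named list of \code{c(lo, hi)} ranges for types
#'   \code{a, b, c, d, Wp, Wn, delta}.
#' @export
defaultParameterRanges <- function() {
  list(a = c(0.1, 10), b = c(0.1, 10), c = c(0.1, 10), d = c(0.1, 10),
       Wp = c(0.5, 5), Wn = c(0.5, 5), delta = c(0.5, 5))
}

#' Latin hypercube sample of kinetic parameter sets
#'
#' One Latin hypercube over all free dimensions of the topology (every
#' per-edge \code{a, b, c, d} plus \code{Wp, Wn, delta}), with
#' \code{nSets} strata per dimension, mapped onto the configured ranges
#' either log-uniformly (default) or uniformly.
#'
#' @param network a [SignedNetwork-class].
#' @param nSets number of parameter sets (default 1000).
#' @param ranges per-type ranges, see [defaultParameterRanges()].
#' @param seed integer seed; a fixed seed gives a bit-identical sample.
#' @param distribution \code{"log-uniform"} or \code{"uniform"} mapping
#'   of the unit hypercube onto the ranges.
#' @return numeric matrix \code{nSets x nParameters} with parameter
#'   names as column names.
#' @export
sampleParameters <- function(network, nSets = 1000,
                             ranges = defaultParameterRanges(), seed = 1L,
                             distribution = c("log-uniform", "uniform")) {
  stopifnot(nSets >= 1)
  distribution <- match.arg(distribution)
  info <- parameterInfo(network)
  for (tp in unique(info$type)) {
    rg <- ranges[[tp]]
    if (is.null(rg) || length(rg) != 2L || any(rg <= 0) || rg[1L] >= rg[2L])
      stop("ranges must contain positive c(lo, hi) for type '", tp, "'")
  }
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(nSets, nrow(info))
  out <- matrix(NA_real_, nSets, nrow(info),
                dimnames = list(NULL, info$name))
  for (j in seq_len(nrow(info))) {
    rg <- ranges[[info$type[j]]]
    out[, j] <- if (distribution == "log-uniform")
      exp(log(rg[1L]) + u[, j] * (log(rg[2L]) - log(rg[1L])))
    else rg[1L] + u[, j] * (rg[2L] - rg[1L])
  }
  out
}

## Packed parameter vector for the compiled right-hand side. Returns the
## template plus the positions where each named parameter lands, so the
## per-set fill in scoring loops is a single assignment.
.parmTemplate <- function(network) {
  n <- nNodes(network)
  if (n > 64L) stop("compiled model supports at most 64 nodes")
  info <- parameterInfo(network)
  edges <- info[info$type %in% c("a", "b", "c", "d"), ]
  nAct <- sum(edges$type == "a")
  nInh <- sum(edges$type == "c")
  p <- numeric(4096)
  p[1:4] <- c(n, inputNode(network), nAct, nInh)
  slot <- integer(nrow(info))
  names(slot) <- info$name
  pos <- 8L                     # 1-based R index just past the header
  for (k in which(info$type %in% c("a", "c"))) {
    p[pos] <- info$from[k]
    p[pos + 1L] <- info$to[k]
    slot[k] <- pos + 2L         # a or c
    slot[k + 1L] <- pos + 3L    # paired b or d
    pos <- pos + 4L
  }
  slot[info$type == "Wp"] <- 5L
  slot[info$type == "Wn"] <- 6L
  slot[info$type == "delta"] <- 7L
  list(template = p, slot = slot)
}

.fillParms <- function(tmpl, params) {
  p <- tmpl$template
  p[tmpl$slot] <- params[names(tmpl$slot)]
  p
}

#' Build the ODE right-hand side as an R function
#'
#' Readable reference implementation of the Hill-kinetics model used for
#' scoring. For every non-input node i,
#' \deqn{dx_i/dt = \Big[\sum_{j \in act(i)} W_p a_j x_j^2 /(\delta b_j + x_j^2)\Big]
#'   \prod_{j \in inh(i)} \frac{1}{c_j + W_n d_j x_j^2} + 0.1 - x_i,}
#' a node with no activators is driven only by the basal 0.1, a node
#' with no inhibitors has product 1. The input node carries no
#' production and decays by the unweighted sum of its inhibitors' Hill
#' terms,
#' \deqn{dx_{in}/dt = -\sum_{j \in inh(in)} x_j^2/(c_j + x_j^2),}
#' scaled near zero by a continuous ramp (full decay above 1e-3,
#' linearly vanishing below) so the cleared signal is absorbing instead
#' of drifting negative.
#' Activation edges onto the input node are ignored. [simulateODE()]
#' integrates the equivalent compiled version by default.
#'
#' @param network a [SignedNetwork-class].
#' @param params named numeric vector covering every name of
#'   [parameterInfo()].
#' @return function \code{(t, y)} returning the derivative vector.
#' @export
buildODE <- function(network, params) {
  info <- parameterInfo(network)
  missing <- setdiff(info$name, names(params))
  if (length(missing))
    stop("missing parameters for edges: ", paste(missing, collapse = ", "))
  a <- adjacency(network)
  n <- nNodes(network)
  inp <- inputNode(network)
  Wp <- params[["Wp"]]; Wn <- params[["Wn"]]; del <- params[["delta"]]
  act <- lapply(seq_len(n), function(i) which(a[, i] == 1L))
  inh <- lapply(seq_len(n), function(i) which(a[, i] == -1L))
  pget <- function(tp, j, i) params[[sprintf("%s_%d_%d", tp, j, i)]]
  function(t, y) {
    x <- pmax(y, 0)
    dy <- numeric(n)
    for (i in seq_len(n)) {
      if (i == inp) {
        s <- 0
        for (j in inh[[i]]) s <- s + x[j]^2 / (pget("c", j, i) + x[j]^2)
        dy[i] <- -s * min(max(y[i] / 1e-3, 0), 1)
      } else {
        s <- 0
        for (j in act[[i]]) s <- s + Wp * pget("a", j, i) * x[j]^2 /
            (del * pget("b", j, i) + x[j]^2)
        pr <- 1
        for (j in inh[[i]]) pr <- pr / (pget("c", j, i) + Wn * pget("d", j, i) * x[j]^2)
        dy[i] <- s * pr + 0.1 - y[i]
      }
    }
    dy
  }
}

#' Integrate the continuous model
#'
#' Solves the Hill-kinetics ODEs with \code{deSolve}'s \code{lsoda} from
#' time 0 to \code{tEnd}, reporting \code{nReport} evenly spaced times.
#' Negative undershoots larger than \code{negTol} in magnitude, missing
#' report rows or non-finite values are raised as an integration error
#' (condition class \code{"integrationError"}); smaller undershoots are
#' clamped to zero.
#'
#' @param network a [SignedNetwork-class].
#' @param params named parameter vector (one row of [sampleParameters()]).
#' @param initial non-negative initial concentrations.
#' @param tEnd integration horizon (dimensionless time, default 50).
#' @param nReport number of report times (default 501).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param engine \code{"compiled"} (default) or \code{"R"} (the
#'   [buildODE()] closure; identical dynamics, much slower).
#' @param negTol negative-undershoot tolerance.
#' @return A [ContinuousTrajectory-class].
#' @export
simulateODE <- function(network, params, initial, tEnd = 50, nReport = 501,
                        rtol = 1e-6, atol = 1e-8,
                        engine = c("compiled", "R"), negTol = 1e-6) {
  engine <- match.arg(engine)
  stopifnot(tEnd > 0, nReport >= 2, all(initial >= 0),
            length(initial) == nNodes(network))
  times <- seq(0, tEnd, length.out = nReport)
  if (engine == "compiled") {
    tmpl <- .parmTemplate(network)
    .odeRunCompiled(.fillParms(tmpl, params), as.numeric(initial), times,
                    rtol, atol, negTol, nodeNames(network))
  } else {
    f <- buildODE(network, params)
    .odeFinish(tryCatch(suppressWarnings(
      deSolve::lsoda(as.numeric(initial), times,
                     func = function(t, y, parms) list(f(t, y)),
                     parms = NULL, rtol = rtol, atol = atol)),
      error = function(e) .odeFail(paste("solver failure:",
                                         conditionMessage(e)))),
      times, negTol, nodeNames(network))
  }
}

.odeFail <- function(msg) stop(structure(
  class = c("integrationError", "error", "condition"),
  list(message = msg, call = NULL)))

## hot path: packed parameter vector already built
.odeRunCompiled <- function(p, y0, times, rtol, atol, negTol, nodeNames) {
  out <- tryCatch(suppressWarnings(
    deSolve::lsoda(y0, times, func = "cd_derivs", parms = p,
                   dllname = "CircuitDesign", initfunc = "cd_initmod",
                   rtol = rtol, atol = atol)),
    error = function(e) .odeFail(paste("solver failure:",
                                       conditionMessage(e))))
  .odeFinish(out, times, negTol, nodeNames)
}

.odeFinish <- function(out, times, negTol, nodeNames) {
  if (nrow(out) < length(times)) .odeFail("integration stopped early")
  v <- out[, -1L, drop = FALSE]
  if (!all(is.finite(v))) .odeFail("non-finite state reached")
  if (min(v) < -negTol)
    .odeFail(sprintf("negative undershoot %.3g beyond tolerance", min(v)))
  v[v < 0] <- 0
  dimnames(v) <- list(NULL, nodeNames)
  new("ContinuousTrajectory", times = times, values = v)
}

setMethod("show", "ContinuousTrajectory", function(object) {
  cat(sprintf("ContinuousTrajectory: %d times in [%g, %g], %d nodes\n",
              length(object@times), min(object@times), max(object@times),
              ncol(object@values)))
  cat("  final state:", paste(sprintf("%.3g", object@values[nrow(object@values), ]),
                              collapse = ", "), "\n")
})

#' Report times of a continuous trajectory
#' @param traj a [ContinuousTrajectory-class].
#' @return numeric vector.
#' @export
odeTimes <- function(traj) traj@times

#' Concentration matrix of a continuous trajectory
#' @param traj a [ContinuousTrajectory-class].
#' @return numeric matrix, rows = times, columns = nodes.
#' @export
odeValues <- function(traj) traj@values

#' Map a Boolean state to continuous initial concentrations
#'
#' ON maps to 1.0 and OFF to the basal level 0.1, e.g. (1,0,1,0,0,1)
#' becomes (1.0, 0.1, 1.0, 0.1, 0.1, 1.0).
#'
#' @param state 0/1 vector.
#' @return numeric vector.
#' @export
booleanToContinuous <- function(state) ifelse(state == 1, 1.0, 0.1)

#' Standard initial state of the response simulation
#'
#' The input (signal) node and the designated normal-state node start at
#' 1.0; every other node starts at the basal level 0.1. For the SOS
#' fixture this is (1.0, 0.1, 1.0, 0.1, 0.1, 0.1): ssDNA present, LexA
#' constitutively expressed.
#'
#' @param network a [SignedNetwork-class].
#' @param normalNode index (or name) of the node that defines the normal
#'   state (e.g. LexA); may be omitted when \code{onNodes} is given.
#' @param onNodes explicit set of nodes starting at 1.0 (overrides the
#'   default input + normal-state set).
#' @return numeric vector of initial concentrations.
#' @export
standardInitialState <- function(network, normalNode = NULL, onNodes = NULL) {
  n <- nNodes(network)
  if (is.null(onNodes)) {
    if (is.null(normalNode))
      stop("supply normalNode or an explicit onNodes set")
    if (is.character(normalNode))
      normalNode <- match(normalNode, nodeNames(network))
    onNodes <- unique(c(inputNode(network), normalNode))
  } else if (is.character(onNodes)) {
    onNodes <- match(onNodes, nodeNames(network))
  }
  if (any(is.na(onNodes)) || any(onNodes < 1L) || any(onNodes > n))
    stop("unknown node roles for the initial state")
  y <- rep(0.1, n)
  y[onNodes] <- 1.0
  names(y) <- nodeNames(network)
  y
}
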