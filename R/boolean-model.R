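#' @describeIn nNodes node count of a network
#' @export
setMethod("nNodes", "SignedNetwork", function(x) nrow(x@adjacency))

#' @describeIn nNodes node count of a trajectory
#' @export
setMethod("nNodes", "BooleanTrajectory", function(x) ncol(x@states))

#' @describeIn adjacency adjacency of a network
#' @export
setMethod("adjacency", "SignedNetwork", function(x) x@adjacency)

#' @describeIn inputNode input node of a network
#' @export
setMethod("inputNode", "SignedNetwork", function(x) x@inputNode)

#' @describeIn inputNode input node recorded in a solution set
#' @export
setMethod("inputNode", "ConsistentSolutionSet", function(x) x@inputNode)

#' @describeIn nodeNames labels of a network
#' @export
setMethod("nodeNames", "SignedNetwork", function(x) x@nodeNames)

#' @describeIn nodeNames labels recorded in a solution set
#' @export
setMethod("nodeNames", "ConsistentSolutionSet", function(x) x@nodeNames)

#' @describeIn booleanStates state matrix of a trajectory
#' @export
setMethod("booleanStates", "BooleanTrajectory", function(x) x@states)

#' @describeIn terminalFixedPoint flag of a trajectory
#' @export
setMethod("terminalFixedPoint", "BooleanTrajectory",
          function(x) x@terminalFixedPoint)

#' Edge list of a network
#'
#' @param network a [SignedNetwork-class].
#' @return data.frame with columns \code{from}, \code{sign} (\code{"+"} or
#'   \code{"-"}) and \code{to} (node names), one row per edge, ordered by
#'   target then source.
#' @export
edgeList <- function(network) {
  a <- adjacency(network)
  idx <- which(a != 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  nm <- nodeNames(network)
  data.frame(from = nm[idx[, 1L]],
             sign = ifelse(a[idx] > 0L, "+", "-"),
             to = nm[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Number of edges
#' @param network a [SignedNetwork-class].
#' @return integer edge count.
#' @export
edgeCount <- function(network) sum(adjacency(network) != 0L)

setMethod("show", "SignedNetwork", function(object) {
  n <- nNodes(object)
  cat(sprintf("SignedNetwork: %d nodes, %d edges; input node: %s\n",
              n, edgeCount(object), nodeNames(object)[inputNode(object)]))
  el <- edgeList(object)
  if (nrow(el) > 0L) {
    arrows <- ifelse(el$sign == "+", "->", "-|")
    cat("  ", paste(el$from, arrows, el$to, collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "BooleanTrajectory", function(object) {
  cat(sprintf("BooleanTrajectory: %d states x %d nodes; %s\n",
              nrow(object@states), ncol(object@states),
              if (object@terminalFixedPoint) "ends at a fixed point"
              else if (!is.na(object@cycleStart))
                sprintf("limit cycle entering at step %d", object@cycleStart)
              else "no attractor detected"))
  print(object@states)
})

## Core synchronous update, vectorised over nodes. `a` is the signed
## adjacency (a[j, i] = regulation from j to i), `s` a 0/1 integer vector.
.booleanStepRaw <- function(a, s) {
  g <- a == 1L
  r <- a == -1L
  actIn <- as.vector(crossprod(g, s))   # active activators incl. self
  inhIn <- as.vector(crossprod(r, s))
  gd <- diag(g)
  rd <- diag(r)
  extAct <- (actIn - gd * s) > 0
  extInh <- (inhIn - rd * s) > 0
  # first bracket: any active non-self activator, OR an ON node not
  # self-inhibited, OR an OFF self-activated node; then dominant
  # inhibition by any active non-self inhibitor
  as.integer((extAct | (s == 1L & !rd) | (s == 0L & gd)) & !extInh)
}

.checkState <- function(network, state) {
  if (length(state) != nNodes(network))
    stop("state length (", length(state), ") does not match network size (",
         nNodes(network), ")")
  if (!all(state %in% c(0, 1)))
    stop("state entries must be 0 or 1")
  as.integer(state)
}

#' @rdname booleanStep
#' @export
setMethod("booleanStep", "SignedNetwork", function(network, state) {
  s <- .checkState(network, state)
  .booleanStepRaw(network@adjacency, s)
})

#' @rdname simulateBoolean
#' @export
setMethod("simulateBoolean", "SignedNetwork",
          function(network, initial, maxSteps = NULL) {
  s <- .checkState(network, initial)
  n <- nNodes(network)
  if (is.null(maxSteps)) maxSteps <- 2L^n + 1L
  if (maxSteps < 1L) stop("maxSteps must be >= 1")
  a <- network@adjacency
  states <- list(s)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(s, collapse = ""), 1L, envir = seen)
  fixed <- FALSE
  cycleStart <- NA_integer_
  for (k in seq_len(maxSteps)) {
    s2 <- .booleanStepRaw(a, s)
    states[[length(states) + 1L]] <- s2
    key <- paste(s2, collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      if (identical(s2, s)) fixed <- TRUE else cycleStart <- prev
      break
    }
    assign(key, length(states), envir = seen)
    s <- s2
  }
  st <- do.call(rbind, states)
  colnames(st) <- nodeNames(network)
  BooleanTrajectory(st, terminalFixedPoint = fixed, cycleStart = cycleStart)
})

## Encode/decode 0/1 states as integers 0..2^n-1 (node 1 = least
## significant bit).
.encodeStates <- function(m) as.vector(m %*% 2L^(seq_len(ncol(m)) - 1L))
.decodeState <- function(code, n) as.integer(bitwAnd(code %/% 2L^(0:(n - 1L)), 1L))

#' All attractors and their basin sizes
#'
#' Enumerates the full \code{2^N} state space, applies the synchronous
#' update once per state to build the transition map, and partitions all
#' states by the attractor (fixed point or limit cycle) they flow into.
#' Basin sizes over all attractors always sum to \code{2^N}.
#'
#' @param network a [SignedNetwork-class] with a modest node count
#'   (exhaustive in \code{2^N}).
#' @return list with \code{attractors} (list of 0/1 state matrices; a
#'   fixed point is a 1-row matrix) and \code{basinSizes} (integer
#'   vector, parallel to \code{attractors}).
#' @export
booleanAttractors <- function(network) {
  n <- nNodes(network)
  nState <- 2L^n
  a <- network@adjacency
  codes <- 0:(nState - 1L)
  allStates <- t(vapply(codes, .decodeState, integer(n), n = n))
  nxt <- integer(nState)
  for (c0 in codes)
    nxt[c0 + 1L] <- sum(.booleanStepRaw(a, allStates[c0 + 1L, ]) *
                        2L^(0:(n - 1L)))
  # attractor id per state by pointer-following with memoisation
  attrId <- rep(NA_integer_, nState)
  attractors <- list()
  for (c0 in codes) {
    if (!is.na(attrId[c0 + 1L])) next
    path <- integer(0)
    cur <- c0
    while (is.na(attrId[cur + 1L]) && !(cur %in% path)) {
      path <- c(path, cur)
      cur <- nxt[cur + 1L]
    }
    if (is.na(attrId[cur + 1L])) {
      # new cycle (possibly length 1): extract it from the path tail
      cyc <- path[which(path == cur):length(path)]
      id <- length(attractors) + 1L
      attractors[[id]] <- allStates[cyc + 1L, , drop = FALSE]
      attrId[cyc + 1L] <- id
      id0 <- id
    } else {
      id0 <- attrId[cur + 1L]
    }
    attrId[path + 1L] <- id0
  }
  sizes <- tabulate(attrId, nbins = length(attractors))
  for (i in seq_along(attractors))
    colnames(attractors[[i]]) <- nodeNames(network)
  list(attractors = attractors, basinSizes = sizes)
}

#' @rdname booleanBasinSize
#' @export
setMethod("booleanBasinSize", "SignedNetwork", function(network, attractor) {
  s <- .checkState(network, attractor)
  if (!identical(.booleanStepRaw(network@adjacency, s), s))
    stop("attractor is not a fixed point of the Boolean update")
  res <- booleanAttractors(network)
  for (i in seq_along(res$attractors)) {
    m <- res$attractors[[i]]
    if (nrow(m) == 1L && identical(as.integer(m[1L, ]), s))
      return(res$basinSizes[i])
  }
  stop("fixed point not found among attractors")  # unreachable
})
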