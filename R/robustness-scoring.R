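#' Q value: fraction of parameter sets giving a successful response
#'
#' Integrates the continuous model from the standard initial state once
#' per parameter set and evaluates all success criteria (signal cleared,
#' relaxation to the normal state, pattern accordance, expression
#' floor). Parameter sets whose integration fails count as failures —
#' a set that cannot be integrated is not demonstrably functional.
#'
#' @param network a [SignedNetwork-class].
#' @param paramSets matrix from [sampleParameters()] for this network.
#' @param expected pattern mapping from [expectedPatterns()].
#' @param normalNode index of the normal-state node.
#' @param initial initial state; defaults to
#'   [standardInitialState()] with the given normal node.
#' @param tEnd,nReport,rtol,atol integration settings, see
#'   [simulateODE()].
#' @param ... further criteria settings passed to [evaluateResponse()].
#' @return list with \code{Q} (= \code{nPass / nSets}), \code{nSets},
#'   \code{nPass}, logical \code{passMask} over sets, and
#'   \code{nIntegrationFailures}.
#' @export
qValue <- function(network, paramSets, expected, normalNode,
                   initial = standardInitialState(network, normalNode),
                   tEnd = 50, nReport = 501, rtol = 1e-6, atol = 1e-8, ...) {
  stopifnot(nrow(paramSets) >= 1)
  nSets <- nrow(paramSets)
  pass <- logical(nSets)
  nFail <- 0L
  inp <- inputNode(network)
  tmpl <- .parmTemplate(network)
  times <- seq(0, tEnd, length.out = nReport)
  y0 <- as.numeric(initial)
  nm <- nodeNames(network)
  for (k in seq_len(nSets)) {
    traj <- tryCatch(
      .odeRunCompiled(.fillParms(tmpl, paramSets[k, ]), y0, times,
                      rtol, atol, 1e-6, nm),
      integrationError = function(e) NULL)
    if (is.null(traj)) { nFail <- nFail + 1L; next }
    rep <- evaluateResponse(traj, expected, normalNode, inp,
                            checkPatterns = TRUE, ...)
    pass[k] <- rep$overallPass
  }
  list(Q = mean(pass), nSets = nSets, nPass = sum(pass), passMask = pass,
       nIntegrationFailures = nFail)
}

#' Enumerate perturbed initial states for the continuous basin
#'
#' All initial states with the input node pinned at 1.0 (the signal is
#' present) and every other node independently at the basal 0.1 or the
#' expressed 1.0 level: \code{2^(N-1)} states, i.e. 32 for a 6-node
#' network.
#'
#' @param network a [SignedNetwork-class].
#' @return numeric matrix, one row per initial state.
#' @export
enumerateBasinStates <- function(network) {
  n <- nNodes(network)
  inp <- inputNode(network)
  others <- setdiff(seq_len(n), inp)
  grid <- as.matrix(expand.grid(rep(list(c(0.1, 1.0)), length(others)),
                                KEEP.OUT.ATTRS = FALSE))
  out <- matrix(NA_real_, nrow(grid), n)
  out[, inp] <- 1.0
  out[, others] <- grid
  colnames(out) <- nodeNames(network)
  out
}

#' Continuous basin size of the normal state
#'
#' For each functional parameter set (a set that passed [qValue()]),
#' every enumerated perturbed initial state is integrated and counted if
#' the system flows into the normal state — criteria (i), (ii) and the
#' expression floor; the pattern criterion is dropped because altered
#' starts legitimately change the transient shapes. The network's basin
#' size is the mean count over its functional sets (the maximum and the
#' first set's count are also reported). With no functional sets the
#' basin is undefined and reported as missing, not zero.
#'
#' @param network a [SignedNetwork-class].
#' @param paramSets the parameter matrix scored by [qValue()].
#' @param passMask logical vector marking the functional sets.
#' @param normalNode index of the normal-state node.
#' @param maxFunctionalSets cap on how many functional sets are averaged
#'   (the leading ones are used; \code{Inf} = all).
#' @param tEnd,nReport,rtol,atol integration settings.
#' @param ... criteria settings forwarded to [evaluateResponse()].
#' @return list with \code{basinMean}, \code{basinMax},
#'   \code{basinNominal} (first functional set), \code{perSetCounts},
#'   \code{nFunctional}; all \code{NA} when no set is functional.
#' @export
basinSizeContinuous <- function(network, paramSets, passMask, normalNode,
                                maxFunctionalSets = Inf, tEnd = 50,
                                nReport = 501, rtol = 1e-6, atol = 1e-8,
                                ...) {
  idx <- which(passMask)
  if (!length(idx))
    return(list(basinMean = NA_real_, basinMax = NA_real_,
                basinNominal = NA_real_, perSetCounts = numeric(0),
                nFunctional = 0L))
  if (length(idx) > maxFunctionalSets)
    idx <- idx[seq_len(maxFunctionalSets)]
  states <- enumerateBasinStates(network)
  inp <- inputNode(network)
  tmpl <- .parmTemplate(network)
  times <- seq(0, tEnd, length.out = nReport)
  nm <- nodeNames(network)
  counts <- integer(length(idx))
  for (s in seq_along(idx)) {
    p <- .fillParms(tmpl, paramSets[idx[s], ])
    cnt <- 0L
    for (r in seq_len(nrow(states))) {
      traj <- tryCatch(
        .odeRunCompiled(p, states[r, ], times, rtol, atol, 1e-6, nm),
        integrationError = function(e) NULL)
      if (is.null(traj)) next
      rep <- evaluateResponse(traj, expected = NULL, normalNode, inp,
                              checkPatterns = FALSE, ...)
      if (rep$overallPass) cnt <- cnt + 1L
    }
    counts[s] <- cnt
  }
  list(basinMean = mean(counts), basinMax = max(counts),
       basinNominal = counts[1L], perSetCounts = counts,
       nFunctional = length(idx))
}

## Fixed-width histogram with the last bin closed on the right.
.binCounts <- function(values, lo, hi, width) {
  nb <- round((hi - lo) / width)
  idx <- pmin(pmax(floor((values - lo) / width) + 1L, 1L), nb)
  tabulate(idx, nbins = nb)
}

#' Jensen-Shannon divergence of two histograms
#'
#' Both count vectors are normalised to probabilities and
#' \eqn{JSD(p, q) = H(m) - (H(p) + H(q))/2} with \eqn{m = (p+q)/2} is
#' evaluated with base-2 logarithms (\eqn{0 \log 0 := 0}), so the value
#' lies in \code{[0, 1]}, is symmetric, and is zero iff the histograms
#' are identical.
#'
#' @param p,q non-negative count (or probability) vectors on the same
#'   bins, each summing to more than zero.
#' @return divergence in bits, in \code{[0, 1]}.
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("histograms must share bin edges")
  if (sum(p) <= 0 || sum(q) <= 0) stop("each histogram must have mass")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  h(m) - (h(p) + h(q)) / 2
}

#' Permutation test on the JSD between two score samples
#'
#' The two samples are histogrammed on shared fixed-width bins and their
#' JSD computed; the null distribution is generated by shuffling the
#' group labels \code{nPerm} times, giving
#' \eqn{p = (1 + \#\{JSD^* \ge JSD\}) / (nPerm + 1)}.
#'
#' @param scoresA,scoresB numeric score vectors (e.g. Q values of the
#'   minimal and candidate network groups); missing values are dropped.
#' @param nPerm number of permutations (default 10000).
#' @param binWidth histogram bin width (0.05 for Q values; 1 for basin
#'   sizes).
#' @param lo,hi histogram support (defaults \code{[0, 1]}; use
#'   \code{c(0, 33)} style bounds for basin counts).
#' @param seed integer seed for the permutations.
#' @return list with \code{jsd}, \code{pValue}, \code{binEdges},
#'   \code{nA}, \code{nB}.
#' @export
jsdPermutationTest <- function(scoresA, scoresB, nPerm = 10000,
                               binWidth = 0.05, lo = 0, hi = 1, seed = 1L) {
  scoresA <- scoresA[!is.na(scoresA)]
  scoresB <- scoresB[!is.na(scoresB)]
  if (!length(scoresA) || !length(scoresB))
    stop("both score vectors must be non-empty")
  if (nPerm < 100) stop("nPerm must be at least 100")
  obs <- jsd(.binCounts(scoresA, lo, hi, binWidth),
             .binCounts(scoresB, lo, hi, binWidth))
  pool <- c(scoresA, scoresB)
  nA <- length(scoresA)
  set.seed(as.integer(seed))
  ge <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(length(pool), nA)
    j <- jsd(.binCounts(pool[idx], lo, hi, binWidth),
             .binCounts(pool[-idx], lo, hi, binWidth))
    if (j >= obs - 1e-12) ge <- ge + 1L
  }
  list(jsd = obs, pValue = (1 + ge) / (nPerm + 1),
       binEdges = seq(lo, hi, by = binWidth),
       nA = nA, nB = length(scoresB))
}

#' Rank scored networks by robustness
#'
#' Orders score records by (Q, basin) lexicographically, annotates the
#' Pareto front, and reports which networks strictly dominate a
#' designated reference (typically the biological network) on both
#' scores.
#'
#' @param records data.frame with at least columns \code{id}, \code{Q}
#'   and \code{basin} (e.g. from [scoreNetworks()]).
#' @param referenceId id of the reference network (optional).
#' @return list with \code{table} (records, ranked, plus a
#'   \code{pareto} flag), \code{dominatingReference} (ids strictly
#'   better than the reference on both Q and basin), and
#'   \code{referenceId}.
#' @export
rankNetworks <- function(records, referenceId = NULL) {
  stopifnot(all(c("id", "Q", "basin") %in% names(records)))
  ord <- order(-records$Q, -records$basin)
  tab <- records[ord, , drop = FALSE]
  b <- ifelse(is.na(tab$basin), -Inf, tab$basin)
  q <- tab$Q
  nr <- nrow(tab)
  pareto <- logical(nr)
  for (i in seq_len(nr))
    pareto[i] <- !any(q >= q[i] & b >= b[i] & (q > q[i] | b > b[i]))
  tab$pareto <- pareto
  dominating <- character(0)
  if (!is.null(referenceId)) {
    ref <- records[records$id == referenceId, , drop = FALSE]
    if (nrow(ref) != 1L) stop("referenceId must match exactly one record")
    refB <- ifelse(is.na(ref$basin), -Inf, ref$basin)
    hit <- records$Q > ref$Q &
      ifelse(is.na(records$basin), -Inf, records$basin) > refB
    dominating <- records$id[hit & records$id != referenceId]
  }
  list(table = tab, dominatingReference = dominating,
       referenceId = referenceId)
}

#' Score a list of networks (Q value and continuous basin size)
#'
#' Samples a Latin hypercube of parameter sets per network (each
#' network's dimensionality differs with its edge count), computes the Q
#' value, then the basin size over the functional sets.
#'
#' @param networks named list of [SignedNetwork-class] objects.
#' @param trajectory constraining [BooleanTrajectory-class] (supplies
#'   the expected patterns).
#' @param normalNode index of the normal-state node.
#' @param nSets parameter sets per network (default 1000).
#' @param ranges sampling ranges, see [defaultParameterRanges()].
#' @param seed base seed; each network uses a distinct stream derived
#'   from it.
#' @param classes optional character vector labelling each network
#'   (e.g. minimal / candidate / biological).
#' @param maxFunctionalSets cap forwarded to [basinSizeContinuous()].
#' @param verbose print one line per network?
#' @param ... integration / criteria settings forwarded to [qValue()]
#'   and [basinSizeContinuous()].
#' @return data.frame with one row per network: \code{id}, \code{class},
#'   \code{Q}, \code{nPass}, \code{basin} (mean), \code{basinMax},
#'   \code{basinNominal}, \code{nFunctional},
#'   \code{nIntegrationFailures}, \code{seed}.
#' @export
scoreNetworks <- function(networks, trajectory, normalNode, nSets = 1000,
                          ranges = defaultParameterRanges(), seed = 1L,
                          classes = NULL, maxFunctionalSets = Inf,
                          verbose = FALSE, ...) {
  ids <- names(networks)
  if (is.null(ids)) ids <- sprintf("net%03d", seq_along(networks))
  if (is.null(classes)) classes <- rep("candidate", length(networks))
  expected <- expectedPatterns(trajectory)
  rows <- vector("list", length(networks))
  for (i in seq_along(networks)) {
    net <- networks[[i]]
    netSeed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    ps <- sampleParameters(net, nSets = nSets, ranges = ranges,
                           seed = netSeed)
    qv <- qValue(net, ps, expected, normalNode, ...)
    bs <- basinSizeContinuous(net, ps, qv$passMask, normalNode,
                              maxFunctionalSets = maxFunctionalSets, ...)
    rows[[i]] <- data.frame(
      id = ids[i], class = classes[i], Q = qv$Q, nPass = qv$nPass,
      basin = bs$basinMean, basinMax = bs$basinMax,
      basinNominal = bs$basinNominal, nFunctional = bs$nFunctional,
      nIntegrationFailures = qv$nIntegrationFailures, seed = netSeed)
    if (verbose)
      message(sprintf("%s [%s]: Q = %.3f, basin = %s", ids[i], classes[i],
                      qv$Q, format(bs$basinMean, digits = 3)))
  }
  do.call(rbind, rows)
}
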