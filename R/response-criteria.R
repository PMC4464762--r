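#' Expected dynamic pattern of each node from the Boolean trajectory
#'
#' A node that starts ON and ends OFF with no intermediate rise is a
#' \code{"decline"}; OFF -> (ON ...) -> OFF is a \code{"peak"};
#' ON -> (OFF ...) -> ON a \code{"valley"}; a constant node is
#' \code{"other"} and exempt from pattern matching. When a node pulses
#' more than once the first excursion governs (a flagged convention;
#' shapes the discrete model cannot express map to \code{"other"}).
#'
#' @param trajectory a [BooleanTrajectory-class].
#' @return named character vector over nodes with values in
#'   \code{c("peak", "valley", "decline", "other")}.
#' @examples
#' fix <- loadSOSFixture()
#' expectedPatterns(fix$trajectory)
#' # ssDNA declines, LexA dips (valley), the SOS genes pulse (peak)
#' @export
expectedPatterns <- function(trajectory) {
  st <- booleanStates(trajectory)
  out <- apply(st, 2L, function(s) {
    s0 <- s[1L]; sT <- s[length(s)]
    if (all(s == s0)) return("other")
    rises <- any(diff(s) == 1L)
    if (s0 == 0L && sT == 0L) "peak"
    else if (s0 == 1L && sT == 1L) "valley"
    else if (s0 == 1L && sT == 0L && !rises) "decline"
    else "other"
  })
  names(out) <- colnames(st)
  out
}

#' Classify the shape of a continuous time course
#'
#' \code{"peak"} if an interior maximum exceeds both endpoints by the
#' margin; \code{"valley"} if an interior minimum undercuts both
#' endpoints by the margin; if both qualify, the extremum occurring
#' first in time decides. Otherwise \code{"decline"} when the final
#' value is below the initial by the margin, else \code{"other"}.
#' The classification is invariant to uniform time rescaling and to
#' adding a constant smaller than the margin.
#'
#' @param series numeric vector of at least 3 samples.
#' @param margin absolute classification margin on the concentration
#'   scale (default 0.05).
#' @return one of \code{"peak"}, \code{"valley"}, \code{"decline"},
#'   \code{"other"}.
#' @export
classifyPattern <- function(series, margin = 0.05) {
  x <- as.numeric(series)
  k <- length(x)
  if (k < 3L) stop("need at least 3 samples")
  if (!all(is.finite(x))) stop("non-finite values in series")
  interior <- x[2:(k - 1L)]
  iMax <- which.max(interior); vMax <- interior[iMax]
  iMin <- which.min(interior); vMin <- interior[iMin]
  isPeak <- vMax > x[1L] + margin && vMax > x[k] + margin
  isValley <- vMin < x[1L] - margin && vMin < x[k] - margin
  if (isPeak && isValley) {
    if (iMax <= iMin) "peak" else "valley"
  } else if (isPeak) "peak"
  else if (isValley) "valley"
  else if (x[k] < x[1L] - margin) "decline"
  else "other"
}

#' Judge a continuous trajectory against the success criteria
#'
#' A successful response must (i) clear the signal: the input node's
#' final value falls below \code{epsClear}; (ii) relax to the normal
#' state: the normal node's final value strictly exceeds every other
#' node's, and every non-normal, non-input node ends below
#' \code{epsLow}; (iii) when \code{checkPatterns} is set, reproduce each
#' non-constant node's expected dynamic pattern; and keep every node's
#' maximum expression above the floor of 0.1 (each gene must actually
#' express). Failures are reported, never raised.
#'
#' @param traj a [ContinuousTrajectory-class].
#' @param expected pattern mapping from [expectedPatterns()].
#' @param normalNode index of the normal-state node.
#' @param inputNode index of the input node.
#' @param checkPatterns evaluate criterion (iii)? Dropped when scanning
#'   basin states, whose altered starts change the transient shapes.
#' @param epsClear signal-cleared threshold (default 0.01).
#' @param epsLow relaxed-state ceiling for non-normal nodes (default 0.2).
#' @param margin pattern-classification margin (default 0.05).
#' @param floorThreshold minimum peak expression (default 0.1); compared
#'   with a tiny exceedance tolerance so a node pinned at the basal
#'   level never passes through solver noise.
#' @return list with flags \code{c1SignalCleared},
#'   \code{c2ReturnsToNormal}, \code{c3PatternsMatch} (\code{NA} when
#'   not checked), \code{floorOk}, \code{overallPass}, and the
#'   \code{observedPatterns} vector.
#' @export
evaluateResponse <- function(traj, expected, normalNode, inputNode,
                             checkPatterns = TRUE, epsClear = 0.01,
                             epsLow = 0.2, margin = 0.05,
                             floorThreshold = 0.1) {
  v <- odeValues(traj)
  n <- ncol(v)
  finals <- v[nrow(v), ]
  maxima <- apply(v, 2L, max)
  c1 <- finals[inputNode] < epsClear
  others <- setdiff(seq_len(n), normalNode)
  relaxed <- setdiff(others, inputNode)
  c2 <- all(finals[normalNode] > finals[others]) &&
    (length(relaxed) == 0L || all(finals[relaxed] < epsLow))
  floorOk <- all(maxima > floorThreshold + 1e-9)
  observed <- rep(NA_character_, n)
  c3 <- NA
  if (checkPatterns) {
    observed <- vapply(seq_len(n), function(i)
      classifyPattern(v[, i], margin = margin), character(1))
    active <- which(expected != "other")
    c3 <- all(observed[active] == expected[active])
  }
  overall <- isTRUE(c1) && isTRUE(c2) && isTRUE(floorOk) &&
    (!checkPatterns || isTRUE(c3))
  list(c1SignalCleared = c1, c2ReturnsToNormal = c2,
       c3PatternsMatch = c3, floorOk = floorOk,
       overallPass = overall, observedPatterns = observed)
}
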