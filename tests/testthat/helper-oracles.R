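# Independent oracles, written as literal scalar translations of the
# update rule and of graph/enumeration definitions. They share no code
# with the package internals they check.

# Literal term-by-term evaluation of the constraint form of the update:
# next_i = (OR_{j!=i} s_j g_ji  OR  s_i !r_ii  OR  !s_i g_ii)
#          AND AND_{j!=i} !(s_j r_ji)
bruteStep <- function(a, s) {
  n <- length(s)
  out <- integer(n)
  for (i in seq_len(n)) {
    first <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (s[j] == 1L && a[j, i] == 1L) first <- TRUE
    }
    if (s[i] == 1L && a[i, i] != -1L) first <- TRUE
    if (s[i] == 0L && a[i, i] == 1L) first <- TRUE
    inhibited <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (s[j] == 1L && a[j, i] == -1L) inhibited <- TRUE
    }
    out[i] <- as.integer(first && !inhibited)
  }
  out
}

randomAdjacency <- function(n) {
  matrix(sample(c(-1L, 0L, 1L), n * n, replace = TRUE,
                prob = c(0.3, 0.4, 0.3)), n, n)
}

# All 3^(n^2) signed topologies, one adjacency per iteration.
forEachTopology <- function(n, fn) {
  total <- 3^(n * n)
  for (k in 0:(total - 1)) {
    digits <- integer(n * n)
    kk <- k
    for (d in seq_len(n * n)) {
      digits[d] <- kk %% 3
      kk <- kk %/% 3
    }
    fn(matrix(as.integer(digits) - 1L, n, n))
  }
  invisible(total)
}

# Does a full network reproduce a trajectory (every consecutive row pair,
# including the duplicated fixed-point row) by brute-force stepping?
reproducesTrajectory <- function(a, stateMatrix) {
  for (t in seq_len(nrow(stateMatrix) - 1L)) {
    if (!identical(bruteStep(a, unname(stateMatrix[t, ])),
                   unname(stateMatrix[t + 1L, ])))
      return(FALSE)
  }
  TRUE
}

# Basin of a fixed point by breadth-first search on the reversed
# transition graph of all 2^n states.
bfsBasinSize <- function(a, attractor) {
  n <- length(attractor)
  codeOf <- function(s) sum(s * 2L^(seq_len(n) - 1L)) + 1L
  stateOf <- function(code) as.integer(bitwAnd((code - 1L) %/% 2L^(0:(n - 1L)), 1L))
  nxt <- integer(2^n)
  for (c0 in seq_len(2^n)) nxt[c0] <- codeOf(bruteStep(a, stateOf(c0)))
  target <- codeOf(attractor)
  reached <- rep(FALSE, 2^n)
  reached[target] <- TRUE
  queue <- target
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    preds <- which(nxt == cur & !reached)
    reached[preds] <- TRUE
    queue <- c(queue, preds)
  }
  sum(reached)
}
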