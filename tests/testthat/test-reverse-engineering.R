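# Oracle strategy: for 3-node problems the whole topology space
# (3^9 = 19683 networks) is enumerable, so per-node enumeration can be
# checked against brute-force forward simulation of every full network.

toy <- makeToyProblem(3, seed = 404)

test_that("per-node consistent sets equal the forward-simulation oracle", {
  st <- booleanStates(toy$trajectory)
  sol <- reverseEngineer(toy$trajectory, inputNode = 1)
  for (i in 1:3) {
    cfg <- sol@perNode[[i]]
    # oracle: all 27 single-node configs, each checked by literal
    # stepping of a network whose only regulated node is i
    cfgGrid <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), 3),
                                     KEEP.OUT.ATTRS = FALSE))
    good <- list()
    for (k in seq_len(nrow(cfgGrid))) {
      a <- matrix(0L, 3, 3)
      a[, i] <- cfgGrid[k, ]
      consistent <- TRUE
      for (t in seq_len(nrow(st) - 1L)) {
        if (bruteStep(a, st[t, ])[i] != st[t + 1L, i]) {
          consistent <- FALSE
          break
        }
      }
      if (consistent) good[[length(good) + 1L]] <- cfgGrid[k, ]
    }
    oracle <- do.call(rbind, good)
    expect_identical(unname(cfg[order(cfg[, 1], cfg[, 2], cfg[, 3]), ]),
                     unname(oracle[order(oracle[, 1], oracle[, 2],
                                         oracle[, 3]), ]))
  }
})

test_that("the product count matches exhaustive enumeration of all 3^9", {
  st <- booleanStates(toy$trajectory)
  sol <- reverseEngineer(toy$trajectory, inputNode = 1)
  oracleCount <- 0L
  forEachTopology(3, function(a) {
    if (reproducesTrajectory(a, st)) oracleCount <<- oracleCount + 1L
  })
  expect_identical(countConsistentNetworks(sol), as.numeric(oracleCount))
  expect_identical(countConsistentNetworks(sol, exact = TRUE),
                   as.character(oracleCount))
})

test_that("minimal networks equal the brute-force minimality filter", {
  st <- booleanStates(toy$trajectory)
  sol <- reverseEngineer(toy$trajectory, inputNode = 1)
  mins <- minimalNetworks(sol)
  # oracle: consistent networks where every node's in-edge count equals
  # the smallest in-edge count over all consistent configs of that node,
  # excluding input-node self-loops
  perNodeMin <- vapply(sol@perNode, function(m) min(rowSums(m != 0L)),
                       numeric(1))
  oracle <- list()
  forEachTopology(3, function(a) {
    if (a[1, 1] != 0L) return(invisible())
    if (!reproducesTrajectory(a, st)) return(invisible())
    if (all(colSums(a != 0L) == perNodeMin))
      oracle[[length(oracle) + 1L]] <<- a
  })
  expect_identical(length(mins), length(oracle))
  minKeys <- sort(vapply(mins, function(n) paste(adjacency(n), collapse = ","),
                         character(1)))
  oracleKeys <- sort(vapply(oracle, function(a) paste(a, collapse = ","),
                            character(1)))
  expect_identical(minKeys, oracleKeys)
})

test_that("each minimal network is edge-minimal per node and consistent", {
  fix <- loadSOSFixture()
  sol <- reverseEngineer(fix$trajectory, inputNode = 1)
  mins <- minimalNetworks(sol)
  perNodeMin <- vapply(sol@perNode, function(m) min(rowSums(m != 0L)),
                       numeric(1))
  st <- booleanStates(fix$trajectory)
  for (net in mins) {
    a <- adjacency(net)
    expect_identical(unname(colSums(a != 0L)), unname(perNodeMin))
    expect_identical(a[1, 1], 0L)  # no self-loop on the input node
    sim <- simulateBoolean(net, st[1, ])
    expect_identical(unname(booleanStates(sim)), unname(st))
  }
})

test_that("a unique minimal config per node gives exactly one network", {
  # constant all-OFF two-node trajectory: the only minimal (0-edge)
  # config per node is "no regulation"
  tr <- BooleanTrajectory(rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L)),
                          terminalFixedPoint = TRUE)
  sol <- reverseEngineer(tr, inputNode = 1)
  mins <- minimalNetworks(sol)
  expect_identical(length(mins), 1L)
  expect_identical(unname(adjacency(mins[[1]])), matrix(0L, 2, 2))
})

test_that("constant all-zero trajectories admit any non-forcing config", {
  # a config is consistent iff it never switches the node ON from the
  # all-zero state: no self-activation (sources are all OFF, so other
  # edges never fire)
  tr <- BooleanTrajectory(rbind(c(0L, 0L, 0L), c(0L, 0L, 0L)),
                          terminalFixedPoint = TRUE)
  cfg <- consistentConfigsForNode(tr, 2)
  expect_identical(nrow(cfg), 18L)       # 27 minus 9 with g_self = +1
  expect_true(all(cfg[, 2] != 1L))
})

test_that("the biological SOS column is consistent for every node", {
  fix <- loadSOSFixture()
  sol <- reverseEngineer(fix$trajectory, inputNode = 1)
  a <- adjacency(fix$network)
  for (i in 1:6) {
    hits <- apply(sol@perNode[[i]], 1L, function(r) all(r == a[, i]))
    expect_true(any(hits))
  }
})

test_that("one node fixed and k elsewhere multiplies to k^(N-1)", {
  sol <- reverseEngineer(toy$trajectory, inputNode = 1)
  k <- vapply(sol@perNode, nrow, integer(1))
  sol2 <- sol
  sol2@perNode <- lapply(seq_along(k), function(i)
    if (i == 1L) sol@perNode[[1]][1L, , drop = FALSE] else sol@perNode[[i]])
  expect_identical(countConsistentNetworks(sol2), prod(as.numeric(k[-1])))
})

test_that("input self-loop exclusion drops exactly the self-edge configs", {
  fix <- loadSOSFixture()
  with_sl <- consistentConfigsForNode(fix$trajectory, 1, inputNode = 1,
                                      allowInputSelfLoop = TRUE)
  without <- consistentConfigsForNode(fix$trajectory, 1, inputNode = 1,
                                      allowInputSelfLoop = FALSE)
  expect_identical(nrow(without), sum(with_sl[, 1] == 0L))
  expect_true(all(without[, 1] == 0L))
})

test_that("sampled candidates are reproducible, distinct and sound", {
  fix <- loadSOSFixture()
  sol <- reverseEngineer(fix$trajectory, inputNode = 1,
                         allowInputSelfLoop = FALSE)
  s1 <- sampleCandidateNetworks(sol, 20, seed = 99)
  s2 <- sampleCandidateNetworks(sol, 20, seed = 99)
  keys <- vapply(s1, function(n) paste(adjacency(n), collapse = ","),
                 character(1))
  expect_identical(keys,
                   vapply(s2, function(n) paste(adjacency(n), collapse = ","),
                          character(1)))
  expect_identical(anyDuplicated(keys), 0L)
  st <- booleanStates(fix$trajectory)
  for (net in s1) {
    sim <- simulateBoolean(net, st[1, ])
    expect_identical(unname(booleanStates(sim)), unname(st))
  }
})

test_that("sampling is uniform over the solution-space product", {
  # small 2-node solution space so frequencies are testable
  tr <- BooleanTrajectory(rbind(c(1L, 0L), c(1L, 1L), c(1L, 1L)),
                          terminalFixedPoint = TRUE)
  sol <- reverseEngineer(tr, inputNode = 1)
  total <- countConsistentNetworks(sol)
  expect_lt(total, 60)
  draws <- vapply(1:3000, function(k) {
    net <- sampleCandidateNetworks(sol, 1, seed = 10000L + k)[[1]]
    paste(adjacency(net), collapse = ",")
  }, character(1))
  tab <- table(draws)
  expect_identical(length(tab), as.integer(total))  # every network seen
  chi <- suppressWarnings(stats::chisq.test(as.vector(tab)))
  expect_gt(chi$p.value, 0.001)
})

test_that("capacity errors are raised when n exceeds the solution count", {
  tr <- BooleanTrajectory(rbind(c(1L, 0L), c(1L, 1L), c(1L, 1L)),
                          terminalFixedPoint = TRUE)
  sol <- reverseEngineer(tr, inputNode = 1)
  expect_error(
    sampleCandidateNetworks(sol, countConsistentNetworks(sol) + 1, seed = 1),
    "distinct")
})

test_that("exact big-integer products agree with double arithmetic", {
  expect_identical(topologyCount(2, exact = TRUE), as.character(3^4))
  expect_identical(topologyCount(3, exact = TRUE), as.character(3^9))
  expect_equal(as.numeric(topologyCount(6, exact = TRUE)),
               topologyCount(6), tolerance = 1e-15)
})
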