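sosFix <- loadSOSFixture()

test_that("a network whose input has no inhibitor scores Q = 0", {
  a <- matrix(0L, 2, 2)
  a[1, 2] <- 1L
  net <- SignedNetwork(a, inputNode = 1L)
  ps <- sampleParameters(net, nSets = 20, seed = 1)
  qv <- qValue(net, ps, expected = c("decline", "peak"), normalNode = 2,
               initial = c(1.0, 0.1))
  expect_identical(qv$Q, 0)
  expect_identical(qv$nPass, 0L)
  # and its basin is then undefined (missing, not zero)
  bs <- basinSizeContinuous(net, ps, qv$passMask, normalNode = 2)
  expect_true(is.na(bs$basinMean))
  expect_identical(bs$nFunctional, 0L)
})

test_that("Q estimates at 200 and 1000 sets agree within sampling error", {
  expected <- expectedPatterns(sosFix$trajectory)
  ps1 <- sampleParameters(sosFix$network, nSets = 1000, seed = 51)
  qv1 <- qValue(sosFix$network, ps1, expected, normalNode = 3)
  ps2 <- sampleParameters(sosFix$network, nSets = 200, seed = 52)
  qv2 <- qValue(sosFix$network, ps2, expected, normalNode = 3)
  p <- qv1$Q
  se <- sqrt(p * (1 - p) / 1000 + max(p, 0.005) * (1 - p) / 200)
  expect_lt(abs(qv1$Q - qv2$Q), 3 * se + 1e-9)
  # splitting one sample in half leaves the expectation unchanged
  qa <- mean(qv1$passMask[1:500]); qb <- mean(qv1$passMask[501:1000])
  expect_lt(abs(qa - qb), 4 * sqrt(2 * max(p, 0.005) * (1 - p) / 500) + 1e-9)
})

test_that("basin states enumerate the input-pinned lattice", {
  st <- enumerateBasinStates(sosFix$network)
  expect_identical(nrow(st), 32L)
  expect_true(all(st[, 1] == 1.0))
  expect_true(all(st[, -1] %in% c(0.1, 1.0)))
  expect_identical(anyDuplicated(st), 0L)
  # the worked-example state is among them
  key <- apply(st, 1, paste, collapse = ",")
  expect_true("1,0.1,1,0.1,0.1,1" %in% key)
  # N = 2 gives two states
  net2 <- SignedNetwork(matrix(0L, 2, 2), inputNode = 1L)
  expect_identical(nrow(enumerateBasinStates(net2)), 2L)
})

test_that("basin counting matches an explicit loop over the 32 states", {
  expected <- expectedPatterns(sosFix$trajectory)
  ps <- sampleParameters(sosFix$network, nSets = 500, seed = 2)
  qv <- qValue(sosFix$network, ps, expected, normalNode = 3)
  k <- which(qv$passMask)[1]
  expect_false(is.na(k))
  mask1 <- seq_len(nrow(ps)) == k
  bs <- basinSizeContinuous(sosFix$network, ps, mask1, normalNode = 3)
  # independent loop with the public one-shot integrator
  states <- enumerateBasinStates(sosFix$network)
  cnt <- 0L
  for (r in seq_len(nrow(states))) {
    tr <- tryCatch(simulateODE(sosFix$network, ps[k, ], states[r, ]),
                   integrationError = function(e) NULL)
    if (is.null(tr)) next
    rp <- evaluateResponse(tr, NULL, normalNode = 3, inputNode = 1,
                           checkPatterns = FALSE)
    if (rp$overallPass) cnt <- cnt + 1L
  }
  expect_identical(bs$basinNominal, cnt)
  expect_identical(bs$basinMean, as.numeric(cnt))
  # the standard initial state is one of the counted states for a
  # functional set: it already passed criteria (i) and (ii)
  expect_gte(cnt, 1L)
})

test_that("jsd satisfies the metric axioms on histograms", {
  set.seed(9)
  for (rep in 1:50) {
    p <- stats::rpois(12, 4); q <- stats::rpois(12, 4)
    if (sum(p) == 0 || sum(q) == 0) next
    expect_identical(jsd(p, p), 0)
    v <- jsd(p, q)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(jsd(p, q), jsd(q, p), tolerance = 1e-12)
    # alternative formula: mean of the two KL divergences to the mixture
    pp <- p / sum(p); qq <- q / sum(q); m <- (pp + qq) / 2
    kl <- function(x, y) sum(ifelse(x > 0, x * log2(x / y), 0))
    expect_equal(v, (kl(pp, m) + kl(qq, m)) / 2, tolerance = 1e-12)
  }
  # disjoint point masses are maximally divergent
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  expect_error(jsd(c(1, 2), c(1, 2, 3)), "share")
  expect_error(jsd(c(0, 0), c(1, 2)), "mass")
})

test_that("the permutation test behaves at the two extremes", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.45, 0.5)
  same <- jsdPermutationTest(x, x, nPerm = 200, binWidth = 0.05, seed = 1)
  expect_identical(same$jsd, 0)
  expect_identical(same$pValue, 1)
  a <- rep(0.01, 20); b <- rep(0.99, 20)
  far <- jsdPermutationTest(a, b, nPerm = 400, binWidth = 0.05, seed = 2)
  expect_equal(far$jsd, 1)
  expect_lte(far$pValue, 1 / 401 + 1e-9)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(2024)
  pvals <- vapply(1:300, function(r) {
    a <- stats::runif(25); b <- stats::runif(25)
    jsdPermutationTest(a, b, nPerm = 199, binWidth = 0.1,
                       seed = 5000L + r)$pValue
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pvals) - 0.5), 0.1)
})

test_that("ranking dominance matches a quadratic brute-force check", {
  set.seed(17)
  rec <- data.frame(id = sprintf("n%02d", 1:40),
                    Q = round(stats::runif(40), 2),
                    basin = sample(0:32, 40, replace = TRUE))
  rk <- rankNetworks(rec, referenceId = "n01")
  brute <- rec$id[vapply(seq_len(40), function(i)
    rec$Q[i] > rec$Q[1] && rec$basin[i] > rec$basin[1], logical(1))]
  expect_setequal(rk$dominatingReference, brute)
  # pareto front: no member is dominated by any record
  tab <- rk$table
  for (i in which(tab$pareto)) {
    dominated <- any(tab$Q >= tab$Q[i] & tab$basin >= tab$basin[i] &
                     (tab$Q > tab$Q[i] | tab$basin > tab$basin[i]))
    expect_false(dominated)
  }
  # a reference that tops both scores is dominated by nothing
  rec2 <- rbind(rec, data.frame(id = "best", Q = 1, basin = 33))
  expect_identical(rankNetworks(rec2, "best")$dominatingReference,
                   character(0))
})

test_that("scoreNetworks is reproducible and respects score bounds", {
  nets <- list(bio = sosFix$network)
  sc1 <- scoreNetworks(nets, sosFix$trajectory, normalNode = 3, nSets = 60,
                       seed = 77, classes = "biological")
  sc2 <- scoreNetworks(nets, sosFix$trajectory, normalNode = 3, nSets = 60,
                       seed = 77, classes = "biological")
  expect_identical(sc1, sc2)
  expect_gte(sc1$Q, 0); expect_lte(sc1$Q, 1)
  if (!is.na(sc1$basin)) {
    expect_gte(sc1$basin, 0); expect_lte(sc1$basin, 32)
  }
})
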