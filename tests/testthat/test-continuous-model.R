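sosFix <- loadSOSFixture()

allOnesParams <- function(network) {
  info <- parameterInfo(network)
  stats::setNames(rep(1, nrow(info)), info$name)
}

test_that("an isolated node at the basal level has zero derivative", {
  net <- SignedNetwork(matrix(0L, 1, 1))
  f <- buildODE(net, allOnesParams(net))
  # input node with no inhibitors: derivative identically zero
  expect_identical(f(0, 0.7), 0)
  net2 <- SignedNetwork(matrix(0L, 2, 2), inputNode = 1L)
  f2 <- buildODE(net2, allOnesParams(net2))
  expect_equal(f2(0, c(0.5, 0.1)), c(0, 0), tolerance = 1e-12)
})

test_that("the SOS derivative with unit parameters matches hand evaluation", {
  # worked out term by term from the rate law with
  # a = b = c = d = Wp = Wn = delta = 1 at x = (1, .1, 1, .1, .1, .1):
  # ssDNA: -2 * (0.01/1.01)
  # RecA:  1*(1/2) * 1/(1.01^2) + 0.1 - 0.1
  # LexA:  (0.01/1.01) * (1/1.01) + 0.1 - 1.0
  # sigma70/UmuDC/SSB: (0.01/1.01) * (1/2) + 0.1 - 0.1
  x <- c(1.0, 0.1, 1.0, 0.1, 0.1, 0.1)
  hand <- c(-2 * 0.01 / 1.01,
            0.5 / 1.01^2,
            (0.01 / 1.01) * (1 / 1.01) + 0.1 - 1.0,
            rep((0.01 / 1.01) * 0.5, 3))
  f <- buildODE(sosFix$network, allOnesParams(sosFix$network))
  expect_equal(f(0, x), hand, tolerance = 1e-12)
})

test_that("compiled and R engines integrate to the same trajectory", {
  set.seed(21)
  for (rep in 1:4) {
    a <- randomAdjacency(4)
    a[1, 1] <- 0L
    net <- SignedNetwork(a, inputNode = 1L)
    ps <- sampleParameters(net, nSets = 1, seed = 100 + rep)
    y0 <- booleanToContinuous(sample(0:1, 4, replace = TRUE))
    trC <- simulateODE(net, ps[1, ], y0, tEnd = 20, nReport = 101)
    trR <- simulateODE(net, ps[1, ], y0, tEnd = 20, nReport = 101,
                       engine = "R")
    expect_equal(odeValues(trC), odeValues(trR), tolerance = 1e-4)
  }
})

test_that("an unregulated node relaxes exponentially to the basal level", {
  a <- matrix(0L, 2, 2)
  a[2, 1] <- -1L           # give the input an inhibitor; node 2 is free
  net <- SignedNetwork(a, inputNode = 1L)
  tr <- simulateODE(net, allOnesParams(net), c(1.0, 1.0), tEnd = 1,
                    nReport = 11)
  # closed form of dx/dt = 0.1 - x from x(0) = 1: x(1) = 0.1 + 0.9 e^-1
  expect_equal(unname(odeValues(tr)[11, 2]), 0.1 + 0.9 * exp(-1),
               tolerance = 1e-5)
  # and it settles within 1e-4 of 0.1 by t = 20
  tr2 <- simulateODE(net, allOnesParams(net), c(1.0, 1.0), tEnd = 20,
                     nReport = 21)
  expect_equal(unname(odeValues(tr2)[21, 2]), 0.1, tolerance = 1e-4)
})

test_that("halving the tolerance barely changes the SOS solution", {
  ps <- sampleParameters(sosFix$network, nSets = 1, seed = 8)
  y0 <- standardInitialState(sosFix$network, normalNode = 3)
  t1 <- simulateODE(sosFix$network, ps[1, ], y0, rtol = 1e-6, atol = 1e-8)
  t2 <- simulateODE(sosFix$network, ps[1, ], y0, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(odeValues(t1) - odeValues(t2))), 1e-5)
})

test_that("trajectories are non-negative, bounded, with decreasing input", {
  ps <- sampleParameters(sosFix$network, nSets = 12, seed = 31)
  y0 <- standardInitialState(sosFix$network, normalNode = 3)
  info <- parameterInfo(sosFix$network)
  for (k in seq_len(nrow(ps))) {
    tr <- simulateODE(sosFix$network, ps[k, ], y0)
    v <- odeValues(tr)
    expect_true(all(v >= 0))
    # input never rises (its derivative is a negative sum)
    expect_true(all(diff(v[, 1]) <= 1e-7))
    # production is bounded: each activation term is at most Wp * a and
    # each inhibition factor at most max(1, 1/c)
    for (i in 2:6) {
      aNames <- info$name[info$type == "a" & info$to == i]
      cNames <- info$name[info$type == "c" & info$to == i]
      bound <- ps[k, "Wp"] * sum(ps[k, aNames]) *
        prod(pmax(1, 1 / ps[k, cNames])) + 0.1 + y0[i]
      expect_lt(max(v[, i]), bound)
    }
  }
})

test_that("Latin hypercube sampling stratifies every marginal", {
  ps <- sampleParameters(sosFix$network, nSets = 50, seed = 5)
  info <- parameterInfo(sosFix$network)
  rng <- defaultParameterRanges()
  for (j in seq_len(ncol(ps))) {
    r <- rng[[info$type[j]]]
    u <- log(ps[, j] / r[1]) / log(r[2] / r[1])
    expect_true(all(u >= 0 & u <= 1))
    strata <- floor(u * 50)
    strata[strata == 50] <- 49
    expect_identical(sort(strata), as.numeric(0:49))  # one per stratum
  }
  # fixed seed reproduces bit-identically
  expect_identical(ps, sampleParameters(sosFix$network, nSets = 50, seed = 5))
})

test_that("log-uniform marginals match their law at large n", {
  net <- SignedNetwork(matrix(0L, 2, 2), inputNode = 1L)  # 3 globals only
  ps <- sampleParameters(net, nSets = 10000, seed = 77)
  u <- log(ps[, "Wp"] / 0.5) / log(5 / 0.5)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("missing edge parameters raise a configuration error", {
  p <- allOnesParams(sosFix$network)
  expect_error(buildODE(sosFix$network, p[-1]), "missing parameters")
  expect_error(sampleParameters(sosFix$network, 5, ranges = list(a = c(-1, 2)),
                                seed = 1),
               "positive")
})

test_that("the standard initial state follows the node roles", {
  expect_equal(unname(standardInitialState(sosFix$network, normalNode = 3)),
               c(1.0, 0.1, 1.0, 0.1, 0.1, 0.1))
  expect_equal(unname(standardInitialState(sosFix$network, onNodes = 1)),
               c(1.0, 0.1, 0.1, 0.1, 0.1, 0.1))
  expect_equal(booleanToContinuous(c(1, 0, 1, 0, 0, 1)),
               c(1.0, 0.1, 1.0, 0.1, 0.1, 1.0))
  expect_error(standardInitialState(sosFix$network), "normalNode")
  expect_error(standardInitialState(sosFix$network, onNodes = 99), "unknown")
})
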