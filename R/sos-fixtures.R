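#' The E. coli SOS DNA-damage response network
#'
#' Reconstruction of the six-node SOS regulatory network: the ssDNA
#' damage signal (input, node 1) activates RecA (2); RecA relieves
#' repression by promoting self-cleavage of LexA (3, modelled as
#' inhibition of LexA); sigma70 (4) activates LexA, itself (a
#' self-activation loop) and the repair genes UmuDC (5) and SSB (6);
#' LexA represses sigma70, UmuDC and SSB; the repair genes clear the
#' signal and shut down RecA (UmuDC and SSB each inhibit both ssDNA and
#' RecA — the variant that is encoded here; which repair gene hits which
#' target is not separable from the trajectory, as all assignments give
#' identical discrete dynamics). There is no self-loop on the input
#' node.
#'
#' @return A [SignedNetwork-class] with nodes ssDNA, RecA, LexA,
#'   sigma70, UmuDC, SSB and input node ssDNA.
#' @export
sosNetwork <- function() {
  nm <- c("ssDNA", "RecA", "LexA", "sigma70", "UmuDC", "SSB")
  a <- matrix(0L, 6, 6, dimnames = list(nm, nm))
  a["ssDNA", "RecA"] <- 1L
  a["RecA", "LexA"] <- -1L
  a["sigma70", "LexA"] <- 1L
  a["LexA", "sigma70"] <- -1L
  a["sigma70", "sigma70"] <- 1L
  a["sigma70", "UmuDC"] <- 1L
  a["sigma70", "SSB"] <- 1L
  a["LexA", "UmuDC"] <- -1L
  a["LexA", "SSB"] <- -1L
  a["UmuDC", "ssDNA"] <- -1L
  a["SSB", "ssDNA"] <- -1L
  a["UmuDC", "RecA"] <- -1L
  a["SSB", "RecA"] <- -1L
  SignedNetwork(a, inputNode = "ssDNA", nodeNames = nm)
}

#' Load and validate the packaged SOS fixture
#'
#' Reads the network (TSV edge list) and Boolean trajectory (CSV) from
#' the package's \code{extdata} and validates them against each other:
#' the network, simulated from the damage state (ssDNA and LexA ON),
#' must reproduce the packaged trajectory exactly and terminate at the
#' normal state (only LexA ON); the input node must carry no self-loop.
#' Any mismatch raises an integrity error — the fixture is never
#' silently patched.
#'
#' @return list with \code{network} ([SignedNetwork-class]),
#'   \code{trajectory} ([BooleanTrajectory-class], terminal fixed point
#'   explicit), \code{initialState}, \code{normalState} (0/1 vectors),
#'   \code{inputNode} = 1 and \code{normalNode} = 3 (LexA).
#' @export
loadSOSFixture <- function() {
  nm <- c("ssDNA", "RecA", "LexA", "sigma70", "UmuDC", "SSB")
  netPath <- system.file("extdata", "sos_network.tsv",
                         package = "CircuitDesign", mustWork = TRUE)
  trajPath <- system.file("extdata", "sos_trajectory.csv",
                          package = "CircuitDesign", mustWork = TRUE)
  network <- readNetworkTSV(netPath, nodeNames = nm, inputNode = "ssDNA")
  trajectory <- readTrajectoryCSV(trajPath, terminalFixedPoint = TRUE)
  initial <- c(1L, 0L, 1L, 0L, 0L, 0L)
  normal <- c(0L, 0L, 1L, 0L, 0L, 0L)
  a <- adjacency(network)
  if (a[inputNode(network), inputNode(network)] != 0L)
    stop("SOS fixture integrity: self-loop on the input node")
  sim <- simulateBoolean(network, initial)
  if (!terminalFixedPoint(sim))
    stop("SOS fixture integrity: simulation does not reach a fixed point")
  simStates <- booleanStates(sim)
  fixStates <- booleanStates(trajectory)
  if (!identical(unname(simStates), unname(fixStates)))
    stop("SOS fixture integrity: simulated trajectory differs from the ",
         "packaged one")
  if (!identical(as.integer(simStates[nrow(simStates), ]), normal))
    stop("SOS fixture integrity: terminal state is not the normal state")
  list(network = network, trajectory = trajectory, initialState = initial,
       normalState = normal, inputNode = inputNode(network), normalNode = 3L)
}

#' Random small test problem (network + trajectory)
#'
#' Samples a random signed network (each ordered pair is activation,
#' nothing or inhibition with probability 1/4, 1/2, 1/4) and a random
#' initial state, simulates to a fixed point, and returns the pair.
#' Sized for exhaustive oracles: all \code{3^(N^2)} topologies are
#' enumerable for N up to 3-4. Degenerate draws (no fixed point, or no
#' transition at all) are resampled a bounded number of times.
#'
#' @param nNodes node count, between 2 and 4.
#' @param seed integer seed; fixed seed gives an identical problem.
#' @param maxTries resampling bound.
#' @return list with \code{network}, \code{trajectory},
#'   \code{initialState}.
#' @export
makeToyProblem <- function(nNodes, seed, maxTries = 100L) {
  stopifnot(nNodes >= 2, nNodes <= 4)
  set.seed(as.integer(seed))
  for (try in seq_len(maxTries)) {
    a <- matrix(sample(c(-1L, 0L, 1L), nNodes^2, replace = TRUE,
                       prob = c(0.25, 0.5, 0.25)), nNodes, nNodes)
    net <- SignedNetwork(a, inputNode = 1L)
    s0 <- sample(0:1, nNodes, replace = TRUE)
    traj <- simulateBoolean(net, s0)
    st <- booleanStates(traj)
    if (terminalFixedPoint(traj) && nrow(st) >= 3L &&
        !identical(st[1L, ], st[2L, ]))
      return(list(network = net, trajectory = traj, initialState = s0))
  }
  stop("no non-degenerate toy problem found in ", maxTries, " tries")
}
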