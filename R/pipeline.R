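#' End-to-end circuit-design pipeline
#'
#' Runs the full two-step procedure on a Boolean trajectory:
#' reverse-engineer the consistent topology space (with and without
#' input-node self-loops), extract the minimal networks, sample
#' candidate networks uniformly from the consistent set, score minimal +
#' candidate (+ optionally the biological reference) networks by Q value
#' and continuous basin size, compare the minimal and candidate score
#' distributions by JSD with a permutation test, and rank all networks.
#'
#' @param trajectory a [BooleanTrajectory-class].
#' @param inputNode input node index or name.
#' @param normalNode normal-state node index or name.
#' @param biologicalNetwork optional [SignedNetwork-class] reference
#'   scored alongside and used as the ranking reference.
#' @param nCandidates number of candidate networks to sample (default
#'   100).
#' @param nSets Latin-hypercube parameter sets per network (default
#'   1000).
#' @param ranges parameter ranges, see [defaultParameterRanges()].
#' @param seed master seed; every stochastic stage derives its own
#'   stream from it and all derived seeds are reported.
#' @param nPerm permutations for the JSD test (default 10000).
#' @param qBinWidth histogram bin width for Q values (default 0.05).
#' @param maxFunctionalSets cap forwarded to [basinSizeContinuous()].
#' @param outDir optional directory; when given, the score table,
#'   comparison table, minimal-network edge lists with a manifest, and a
#'   JSON log (stage counts and seeds) are written there.
#' @param verbose print progress?
#' @param ... integration / criteria settings forwarded to
#'   [scoreNetworks()].
#' @return list with \code{solutions}, \code{countWithSelfLoops},
#'   \code{countNoSelfLoops}, \code{minimal}, \code{candidates},
#'   \code{scores}, \code{comparisonQ}, \code{comparisonBasin},
#'   \code{ranking}, \code{seeds}.
#' @export
runPipeline <- function(trajectory, inputNode, normalNode,
                        biologicalNetwork = NULL, nCandidates = 100,
                        nSets = 1000, ranges = defaultParameterRanges(),
                        seed = 1L, nPerm = 10000, qBinWidth = 0.05,
                        maxFunctionalSets = Inf, outDir = NULL,
                        verbose = FALSE, ...) {
  seed <- as.integer(seed)
  seeds <- c(candidates = seed + 1L, scoring = seed + 2L,
             permutation = seed + 3L)
  stage <- function(name, expr) {
    if (verbose) message("[", name, "]")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  solAll <- stage("reverse-engineer",
    reverseEngineer(trajectory, inputNode, allowInputSelfLoop = TRUE))
  solNoSL <- stage("reverse-engineer",
    reverseEngineer(trajectory, inputNode, allowInputSelfLoop = FALSE))
  if (is.character(normalNode))
    normalNode <- match(normalNode, solAll@nodeNames)
  minimal <- stage("minimal", minimalNetworks(solAll))
  candidates <- stage("sample-candidates",
    sampleCandidateNetworks(solNoSL, nCandidates, seed = seeds["candidates"]))
  networks <- c(minimal, candidates)
  names(networks) <- c(sprintf("minimal%03d", seq_along(minimal)),
                       sprintf("candidate%03d", seq_along(candidates)))
  classes <- c(rep("minimal", length(minimal)),
               rep("candidate", length(candidates)))
  refId <- NULL
  if (!is.null(biologicalNetwork)) {
    networks <- c(networks, list(biological = biologicalNetwork))
    classes <- c(classes, "biological")
    refId <- "biological"
  }
  scores <- stage("score",
    scoreNetworks(networks, trajectory, normalNode, nSets = nSets,
                  ranges = ranges, seed = seeds["scoring"],
                  classes = classes, maxFunctionalSets = maxFunctionalSets,
                  verbose = verbose, ...))
  qM <- scores$Q[scores$class == "minimal"]
  qC <- scores$Q[scores$class == "candidate"]
  bM <- scores$basin[scores$class == "minimal"]
  bC <- scores$basin[scores$class == "candidate"]
  basinHi <- 2^(ncol(booleanStates(trajectory)) - 1L) + 1L
  cmpQ <- stage("compare",
    jsdPermutationTest(qM, qC, nPerm = nPerm, binWidth = qBinWidth,
                       lo = 0, hi = 1, seed = seeds["permutation"]))
  cmpB <- if (all(is.na(bM)) || all(is.na(bC))) {
    # basins are undefined for a group with no functional network
    list(jsd = NA_real_, pValue = NA_real_,
         binEdges = seq(0, basinHi, by = 1),
         nA = sum(!is.na(bM)), nB = sum(!is.na(bC)))
  } else stage("compare",
    jsdPermutationTest(bM, bC, nPerm = nPerm, binWidth = 1,
                       lo = 0, hi = basinHi, seed = seeds["permutation"]))
  ranking <- stage("rank", rankNetworks(scores, referenceId = refId))
  res <- list(solutions = solAll,
              countWithSelfLoops = countConsistentNetworks(solAll),
              countNoSelfLoops = countConsistentNetworks(solNoSL),
              minimal = minimal, candidates = candidates, scores = scores,
              comparisonQ = cmpQ, comparisonBasin = cmpB,
              ranking = ranking, seeds = seeds)
  if (!is.null(outDir)) stage("write", .writePipelineOutputs(res, outDir))
  res
}

.writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$scores, file.path(outDir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp <- data.frame(
    comparison = c("Q", "basin"),
    jsd = c(res$comparisonQ$jsd, res$comparisonBasin$jsd),
    p_value = c(res$comparisonQ$pValue, res$comparisonBasin$pValue),
    n_minimal = c(res$comparisonQ$nA, res$comparisonBasin$nA),
    n_candidate = c(res$comparisonQ$nB, res$comparisonBasin$nB))
  utils::write.table(cmp, file.path(outDir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mdir <- file.path(outDir, "minimal_networks")
  dir.create(mdir, showWarnings = FALSE)
  manifest <- data.frame(id = character(0), edges = integer(0))
  for (i in seq_along(res$minimal)) {
    id <- sprintf("minimal%03d", i)
    writeNetworkTSV(res$minimal[[i]], file.path(mdir, paste0(id, ".tsv")))
    manifest <- rbind(manifest,
                      data.frame(id = id, edges = edgeCount(res$minimal[[i]])))
  }
  utils::write.table(manifest, file.path(mdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- list(count_with_self_loops = res$countWithSelfLoops,
              count_no_self_loops = res$countNoSelfLoops,
              n_minimal = length(res$minimal),
              n_candidates = length(res$candidates),
              seeds = as.list(res$seeds),
              dominating_reference = res$ranking$dominatingReference)
  jsonlite::write_json(log, file.path(outDir, "pipeline_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Recognised fields: \code{n_candidates}, \code{n_sets}, \code{seed},
#' \code{n_perm}, \code{q_bin_width}, \code{t_end}, \code{rtol},
#' \code{distribution}, and a \code{ranges} block of per-type
#' \code{[lo, hi]} pairs (types \code{a, b, c, d, Wp, Wn, delta}).
#' Missing fields fall back to package defaults.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return list of settings suitable for splicing into [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$ranges))
    cfg$ranges <- lapply(cfg$ranges, as.numeric)
  cfg
}
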