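#' Read / write signed networks and Boolean trajectories
#'
#' Networks travel in two dialects that round-trip losslessly:
#' a SIF-like tab-separated edge list (`source<TAB>sign<TAB>target`,
#' sign `+` or `-`) and a JSON file that additionally carries the node
#' names and the input node. Trajectories are CSV with one column per
#' node (header = node names) and one row per time step, cells 0/1.
#'
#' @param network a [SignedNetwork-class].
#' @param path file path.
#' @param nodeNames node labels; for the TSV reader, supplies nodes and
#'   their order (required when some nodes have no edges).
#' @param inputNode input node name or index (TSV reader only; the JSON
#'   dialect stores it).
#' @return Readers return a [SignedNetwork-class] or
#'   [BooleanTrajectory-class]; writers return the path, invisibly.
#' @name network-io
NULL

#' @rdname network-io
#' @export
writeNetworkTSV <- function(network, path) {
  el <- edgeList(network)
  utils::write.table(el[, c("from", "sign", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
readNetworkTSV <- function(path, nodeNames = NULL, inputNode = 1L) {
  el <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("from", "sign", "to"),
                          colClasses = "character")
  if (is.null(nodeNames))
    nodeNames <- unique(c(el$from, el$to))
  bad <- setdiff(c(el$from, el$to), nodeNames)
  if (length(bad))
    stop("edge list mentions unknown nodes: ", paste(bad, collapse = ", "))
  n <- length(nodeNames)
  a <- matrix(0L, n, n, dimnames = list(nodeNames, nodeNames))
  if (!all(el$sign %in% c("+", "-")))
    stop("sign column must be '+' or '-'")
  a[cbind(match(el$from, nodeNames), match(el$to, nodeNames))] <-
    ifelse(el$sign == "+", 1L, -1L)
  SignedNetwork(a, inputNode = inputNode, nodeNames = nodeNames)
}

#' @rdname network-io
#' @export
writeNetworkJSON <- function(network, path) {
  el <- edgeList(network)
  obj <- list(nodes = nodeNames(network),
              input_node = nodeNames(network)[inputNode(network)],
              edges = el)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname network-io
#' @export
readNetworkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodeNames <- as.character(obj$nodes)
  n <- length(nodeNames)
  a <- matrix(0L, n, n, dimnames = list(nodeNames, nodeNames))
  el <- obj$edges
  if (!is.null(el) && NROW(el) > 0L)
    a[cbind(match(el$from, nodeNames), match(el$to, nodeNames))] <-
      ifelse(el$sign == "+", 1L, -1L)
  SignedNetwork(a, inputNode = obj$input_node, nodeNames = nodeNames)
}

#' @rdname network-io
#' @param trajectory a [BooleanTrajectory-class] (writer). The CSV holds
#'   the distinct visited states; a duplicated terminal fixed-point row is
#'   collapsed on write and restored by the reader flag.
#' @param terminalFixedPoint logical; whether the trajectory being read
#'   ends at a fixed point (restores the explicit self-transition row).
#' @export
writeTrajectoryCSV <- function(trajectory, path) {
  st <- booleanStates(trajectory)
  k <- nrow(st)
  if (terminalFixedPoint(trajectory) && k >= 2L &&
      identical(st[k, ], st[k - 1L, ]))
    st <- st[-k, , drop = FALSE]
  utils::write.csv(as.data.frame(st), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
readTrajectoryCSV <- function(path, terminalFixedPoint = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  st <- as.matrix(df)
  storage.mode(st) <- "integer"
  BooleanTrajectory(st, terminalFixedPoint = terminalFixedPoint)
}
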