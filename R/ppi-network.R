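#' Protein-protein interaction network
#'
#' A `ppi_network` is an undirected simple graph (no self-loops, no
#' multi-edges) on canonical protein accessions.  Node order is fixed
#' lexicographically at construction time and shared by every downstream
#' matrix and probability vector, so indexing is reproducible.
#'
#' @param edges two-column matrix or data frame of accession pairs.
#' @return An object of class `ppi_network` wrapping an igraph graph.
#' @examples
#' net <- ppi_network(cbind(c("A", "B"), c("B", "C")))
#' network_nodes(net)
#' @export
ppi_network <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L || nrow(edges) == 0L)
    stopf("edges must be a non-empty two-column table of accession pairs")
  mode(edges) <- "character"
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) stopf("no edges remain after self-loop removal")
  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L]),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, nodes = nodes), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n",
              length(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node accessions of a network, in the fixed lexicographic order
#' @param net a `ppi_network`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  net$nodes
}

#' Merge interaction edge lists into one canonical network
#'
#' Integrates several raw edge tables (e.g. exports of different interaction
#' databases) into a single undirected simple graph.  Raw identifiers are
#' optionally translated to canonical accessions through `id_map`; rows with
#' an unmappable endpoint are dropped and counted, never guessed.
#' Duplicate edges (including reversed duplicates) and self-loops are
#' removed.
#'
#' @param sources a single two-column edge table or a list of them.
#' @param id_map optional named character vector or two-column data frame
#'   (`raw`, `canonical`) used to translate identifiers.
#' @return A `ppi_network` with attribute `n_dropped`, the number of source
#'   rows removed because an endpoint could not be mapped.
#' @export
merge_edge_lists <- function(sources, id_map = NULL) {
  if (is.data.frame(sources) || is.matrix(sources)) sources <- list(sources)
  if (!length(sources)) stopf("no edge sources given")
  rows <- do.call(rbind, lapply(sources, function(s) {
    s <- as.matrix(s)
    if (ncol(s) < 2L) stopf("each edge source needs at least two columns")
    mode(s) <- "character"
    s[, 1:2, drop = FALSE]
  }))
  n_dropped <- 0L
  if (!is.null(id_map)) {
    if (is.data.frame(id_map)) {
      map <- stats::setNames(as.character(id_map[[2L]]),
                             as.character(id_map[[1L]]))
    } else {
      map <- id_map
    }
    a <- unname(map[rows[, 1L]])
    b <- unname(map[rows[, 2L]])
    ok <- !is.na(a) & !is.na(b)
    n_dropped <- sum(!ok)
    if (n_dropped > 0L)
      message(n_dropped, " edge row(s) dropped: unmappable identifier")
    rows <- cbind(a[ok], b[ok])
  }
  rows <- rows[rows[, 1L] != rows[, 2L], , drop = FALSE]
  if (nrow(rows) == 0L) stopf("merged edge list is empty")
  net <- ppi_network(rows)
  attr(net, "n_dropped") <- n_dropped
  net
}

#' Restrict a network to its largest connected component
#'
#' Network diffusion requires a connected graph, so analyses are restricted
#' to the largest connected component of the merged interactome.  Ties in
#' component size are broken towards the component containing the
#' lexicographically smallest accession.
#'
#' @param net a `ppi_network`.
#' @return The induced `ppi_network` on the largest component.
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  comp <- igraph::components(net$graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # first vertex is the lexicographically smallest name by construction
    firsts <- vapply(best, function(k) {
      min(net$nodes[comp$membership == k])
    }, character(1))
    best <- best[firsts == min(firsts)][1L]
  }
  keep <- net$nodes[comp$membership == best]
  sub <- igraph::induced_subgraph(net$graph, keep)
  el <- igraph::as_edgelist(sub, names = TRUE)
  ppi_network(el)
}

#' Build the diffusion matrix of a network
#'
#' Derives the transition matrix P driving the random walk with restart
#' from the network adjacency structure.  The default column-stochastic
#' normalization (`P[u, v] = 1/deg(v)` for each edge u-v) conserves total
#' probability mass under the iteration, so diffusion limits remain genuine
#' probability distributions over the proteins.  Row normalization and the
#' symmetric normalization `D^{-1/2} A D^{-1/2}` are available as variants.
#'
#' @param net a connected `ppi_network` with at least one edge.
#' @param normalization one of `"column"`, `"row"`, `"symmetric"`.
#' @return An object of class `diffusion_matrix`: a sparse matrix `P`
#'   indexed by `network_nodes(net)` plus its normalization mode.
#' @export
build_diffusion_matrix <- function(net,
                                   normalization = c("column", "row",
                                                     "symmetric")) {
  stopifnot(inherits(net, "ppi_network"))
  normalization <- match.arg(normalization)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  A <- A[net$nodes, net$nodes]
  deg <- Matrix::colSums(A)
  if (any(deg == 0))
    stopf("network has isolated node(s); restrict to a connected component")
  P <- switch(normalization,
    column    = A %*% Matrix::Diagonal(x = 1 / deg),
    row       = Matrix::Diagonal(x = 1 / deg) %*% A,
    symmetric = Matrix::Diagonal(x = 1 / sqrt(deg)) %*% A %*%
                Matrix::Diagonal(x = 1 / sqrt(deg))
  )
  P <- methods::as(P, "CsparseMatrix")
  dimnames(P) <- list(net$nodes, net$nodes)
  structure(list(P = P, nodes = net$nodes, normalization = normalization),
            class = "diffusion_matrix")
}

#' @export
print.diffusion_matrix <- function(x, ...) {
  cat(sprintf("<diffusion_matrix> %d x %d, %s-normalized\n",
              length(x$nodes), length(x$nodes), x$normalization))
  invisible(x)
}

#' Read / write two-column edge list TSV
#' @param path file path.
#' @rdname edge_list_io
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stopf("edge list not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          comment.char = "#")
  ppi_network(df[, 1:2])
}

#' @param net a `ppi_network`.
#' @rdname edge_list_io
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
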