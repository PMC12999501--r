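#' Gene interaction networks
#'
#' A `gene_network` is a weighted, undirected, simple graph over gene
#' identifiers, together with the column-stochastic transition matrix `W`
#' used by random-walk-with-restart propagation. Gene identifiers are
#' opaque, case-sensitive strings; no symbol/ID mapping is performed.
#'
#' Construction enforces the container invariants: no self-loops, no
#' duplicate undirected edges (duplicates resolved by keeping the maximum
#' weight), strictly positive weights, and no isolated nodes (a node exists
#' only by incidence to an edge, so every column of `W` sums to 1).
#'
#' @param edges a data.frame with columns `from`, `to`, `weight`
#'   (character, character, positive numeric). Extra columns are ignored.
#' @return an object of class `gene_network` with elements
#'   \describe{
#'     \item{genes}{ordered character vector of unique gene ids}
#'     \item{edges}{canonicalized edge data.frame (`from` < `to`)}
#'     \item{W}{sparse column-stochastic transition matrix (`dgCMatrix`)}
#'     \item{report}{load report: counts of self-loops and duplicates dropped}
#'   }
#' @examples
#' net <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                weight = 1))
#' Matrix::colSums(net$W) # all 1
#' @export
gene_network <- function(edges) {
  if (!is.data.frame(edges) || !all(c("from", "to", "weight") %in% names(edges)))
    dd_param_error("'edges' must be a data.frame with columns from, to, weight")
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (anyNA(from) || anyNA(to) || anyNA(w))
    dd_format_error("edge list contains missing values")
  if (any(w <= 0))
    dd_format_error("edge weights must be strictly positive")

  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]; w <- w[!self]
  if (length(from) == 0L)
    dd_format_error("network has no edges after removing self-loops")

  # canonical undirected orientation, then keep-max-weight dedup
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  ord <- order(key, -w)
  keep <- !duplicated(key[ord])
  n_dup <- sum(!keep)
  idx <- ord[keep]
  edge_df <- data.frame(from = from[idx], to = to[idx], weight = w[idx],
                        stringsAsFactors = FALSE)
  edge_df <- edge_df[order(edge_df$from, edge_df$to), , drop = FALSE]
  rownames(edge_df) <- NULL

  genes <- sort(unique(c(edge_df$from, edge_df$to)))
  W <- normalize_adjacency(edge_df, genes)

  structure(list(
    genes = genes,
    edges = edge_df,
    W = W,
    report = list(n_genes = length(genes), n_edges = nrow(edge_df),
                  self_loops_dropped = n_self, duplicates_dropped = n_dup)
  ), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d undirected weighted edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Column-stochastic normalization of a weighted adjacency matrix
#'
#' Divides each column of the symmetric weighted adjacency matrix by its
#' column sum (the node's weighted degree), giving the transition matrix
#' `W` of a random walk on the network. For symmetric input every column
#' of `W` sums to 1, which is what makes propagation conserve heat.
#'
#' @param edges canonical edge data.frame (`from`, `to`, `weight`)
#' @param genes ordered gene ids defining row/column order
#' @return sparse `dgCMatrix`, columns summing to 1
#' @export
normalize_adjacency <- function(edges, genes = sort(unique(c(edges$from, edges$to)))) {
  if (nrow(edges) == 0L) dd_param_error("at least one edge is required")
  if (any(edges$weight <= 0)) dd_param_error("weights must be positive")
  i <- match(edges$from, genes)
  j <- match(edges$to, genes)
  if (anyNA(i) || anyNA(j))
    dd_param_error("edge endpoints missing from the gene universe")
  n <- length(genes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$weight, 2L), dims = c(n, n),
                            dimnames = list(genes, genes))
  csums <- Matrix::colSums(A)
  if (any(csums == 0))
    dd_param_error("isolated node in adjacency; drop isolated nodes first")
  W <- A %*% Matrix::Diagonal(n, 1 / csums)
  dimnames(W) <- list(genes, genes)
  W
}

#' Weighted degree (strength) of every gene
#' @param network a `gene_network`
#' @return named numeric vector of summed incident edge weights
#' @export
node_strength <- function(network) {
  s <- stats::setNames(numeric(length(network$genes)), network$genes)
  tab_f <- tapply(network$edges$weight, network$edges$from, sum)
  tab_t <- tapply(network$edges$weight, network$edges$to, sum)
  s[names(tab_f)] <- s[names(tab_f)] + tab_f
  s[names(tab_t)] <- s[names(tab_t)] + tab_t
  s
}

#' Unweighted degree of every gene
#' @param network a `gene_network`
#' @return named integer vector
#' @export
node_degree <- function(network) {
  d <- stats::setNames(integer(length(network$genes)), network$genes)
  tab <- table(c(network$edges$from, network$edges$to))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Convert a gene_network to an igraph graph
#' @param network a `gene_network`
#' @return an undirected weighted `igraph` graph
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = data.frame(name = network$genes))
}

#' Induced subnetwork on a gene subset
#'
#' Keeps the edges with both endpoints in `genes`; genes left isolated by
#' the restriction are dropped (and reported), preserving the no-isolated-
#' node invariant.
#'
#' @param network a `gene_network`
#' @param genes character vector of gene ids to retain
#' @return a `gene_network`; its `report` records genes dropped as isolated
#' @export
induced_subnetwork <- function(network, genes) {
  genes <- unique(as.character(genes))
  keep <- network$edges$from %in% genes & network$edges$to %in% genes
  if (!any(keep))
    dd_param_error("induced subnetwork has no edges")
  sub <- gene_network(network$edges[keep, , drop = FALSE])
  sub$report$isolated_dropped <- setdiff(genes, sub$genes)
  sub
}

#' Read a gene network from an edge-list TSV
#'
#' Accepts the common functional-network edge-list dialect: tab-separated
#' `geneA geneB weight`, `#`-prefixed comment lines, an optional header
#' line, and extra columns (ignored). The weight column can be selected by
#' name (when a header is present) or by index; it defaults to the third
#' column. Self-loops are dropped and duplicate undirected edges resolved
#' by keeping the maximum weight; both counts appear in the load report.
#'
#' @param path path to the TSV file
#' @param weight_column column name or index holding the edge weight
#' @return a `gene_network`
#' @export
read_edge_list <- function(path, weight_column = 3L) {
  if (!file.exists(path)) dd_param_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) dd_format_error(sprintf("empty network file: %s", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[[3L]])))
  header <- if (has_header) first else NULL
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) dd_format_error(sprintf("no data rows in %s", path))

  wcol <- weight_column
  if (is.character(wcol)) {
    if (is.null(header)) dd_param_error("weight column named but file has no header")
    wcol <- match(weight_column, header)
    if (is.na(wcol))
      dd_format_error(sprintf("weight column '%s' not in header of %s",
                              weight_column, path))
  }
  wcol <- as.integer(wcol)

  nf <- lengths(fields)
  bad <- which(nf < max(3L, wcol))
  if (length(bad)) {
    line_no <- bad[1L] + if (has_header) 1L else 0L
    dd_format_error(sprintf("malformed line %d in %s: expected >= %d tab-separated fields",
                            line_no, path, max(3L, wcol)))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", wcol)))
  if (anyNA(w)) {
    line_no <- which(is.na(w))[1L] + if (has_header) 1L else 0L
    dd_format_error(sprintf("non-numeric weight at line %d in %s", line_no, path))
  }
  if (any(w < 0)) {
    line_no <- which(w < 0)[1L] + if (has_header) 1L else 0L
    dd_format_error(sprintf("negative weight at line %d in %s", line_no, path))
  }
  if (any(w == 0)) {
    line_no <- which(w == 0)[1L] + if (has_header) 1L else 0L
    dd_format_error(sprintf("zero weight at line %d in %s", line_no, path))
  }
  gene_network(data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE))
}

#' Write a gene network as an edge-list TSV
#' @param network a `gene_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(network, path) {
  write_tsv_plain(network$edges, path)
}
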