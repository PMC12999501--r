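# Multiscale community hierarchy: partition the proximal subnetwork over
# a sweep of modularity resolutions, keep the communities that persist
# (Jaccard-matched) across consecutive resolutions, and assemble a DAG
# whose edges are containment-index relations after transitive reduction.

#' Partition a network at one modularity resolution
#'
#' A seeded modularity-maximizing partition (Leiden local-moving
#' heuristic with a linear resolution parameter). Higher resolutions
#' favour smaller communities; nodes in different connected components
#' never share a block.
#'
#' @param network a `gene_network` (typically the NPS-selected subnetwork
#'   plus seeds)
#' @param resolution positive modularity resolution parameter
#' @param partition_seed integer seed making the heuristic deterministic
#' @return named integer vector: block id per gene
#' @export
partition_at_resolution <- function(network, resolution = 1,
                                    partition_seed = 1L) {
  assert_scalar(resolution, "resolution", lower = 0, strict_lower = TRUE)
  if (length(network$genes) == 0L) dd_param_error("empty subnetwork")
  g <- as_igraph(network)
  with_seed(partition_seed, {
    cl <- igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution,
      weights = igraph::E(g)$weight,
      n_iterations = 5L
    )
    stats::setNames(as.integer(igraph::membership(cl)), network$genes)
  })
}

#' Sweep a grid of resolutions
#'
#' @param network a `gene_network`
#' @param resolution_grid increasing positive resolutions (default 10
#'   steps from 0.5 to 5, the sweep maximum used throughout)
#' @param partition_seed integer seed reused at every resolution
#' @return named list (by resolution) of membership vectors
#' @export
sweep_resolutions <- function(network, resolution_grid = seq(0.5, 5, by = 0.5),
                              partition_seed = 1L) {
  if (length(resolution_grid) == 0L || any(diff(resolution_grid) <= 0))
    dd_param_error("resolution_grid must be nonempty and strictly increasing")
  out <- lapply(resolution_grid, function(r)
    partition_at_resolution(network, r, partition_seed))
  names(out) <- as.character(resolution_grid)
  out
}

#' Jaccard similarity of two gene sets
#' @param a,b character vectors; at least one nonempty
#' @return |a n b| / |a u b|
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) dd_param_error("jaccard undefined for two empty sets")
  length(intersect(a, b)) / u
}

#' Containment index: fraction of v contained in w
#' @param v,w character vectors; `v` nonempty
#' @return |v n w| / |v|
#' @export
containment_index <- function(v, w) {
  v <- unique(v); w <- unique(w)
  if (length(v) == 0L) dd_param_error("containment index undefined for empty v")
  length(intersect(v, w)) / length(v)
}

#' Communities that persist across the resolution sweep
#'
#' Blocks at consecutive resolutions are chained by greedy best Jaccard
#' match (requiring similarity >= `jaccard_threshold`; ties broken by
#' larger overlap then lexicographically smaller block id). Chains at
#' least `persistence_min` resolutions long become communities; the
#' community's gene set is the block at the chain's first resolution,
#' and each block joins at most one chain.
#'
#' @param sweep named list of membership vectors from [sweep_resolutions()]
#' @param jaccard_threshold minimal similarity to continue a chain
#'   (default 0.75)
#' @param persistence_min minimal chain length in sweep steps (default 5)
#' @param min_size smallest block treated as a community (default 2;
#'   singleton blocks carry no modular structure and are never chained)
#' @return data.frame: `community_id`, `genes` (list column),
#'   `size`, `resolution_first`, `resolution_last`, `persistence`
#' @export
persistent_communities <- function(sweep, jaccard_threshold = 0.75,
                                   persistence_min = 5L, min_size = 2L) {
  if (length(sweep) == 0L) dd_param_error("empty resolution sweep")
  assert_scalar(jaccard_threshold, "jaccard_threshold", 0, 1, strict_lower = TRUE)
  persistence_min <- assert_count(persistence_min, "persistence_min", min = 1L)
  min_size <- assert_count(min_size, "min_size", min = 1L)
  resolutions <- as.numeric(names(sweep))

  blocks_at <- lapply(sweep, function(m) {
    bl <- split(names(m), m)
    bl <- bl[order(as.integer(names(bl)))]
    bl[lengths(bl) >= min_size]
  })

  # active chains: list(genes_first, res_first, res_last, length, current)
  chains <- list()
  done <- list()
  for (s in seq_along(blocks_at)) {
    blocks <- blocks_at[[s]]
    taken <- rep(FALSE, length(blocks))
    if (length(chains) > 0L) {
      extended <- logical(length(chains))
      for (ci in seq_along(chains)) {
        cur <- chains[[ci]]$current
        sims <- vapply(blocks, function(b) jaccard(cur, b), numeric(1))
        ovl <- vapply(blocks, function(b) length(intersect(cur, b)), numeric(1))
        sims[taken] <- -1
        ok <- which(sims >= jaccard_threshold)
        if (length(ok) > 0L) {
          best <- ok[order(-sims[ok], -ovl[ok], ok)][1L]
          taken[best] <- TRUE
          chains[[ci]]$current <- blocks[[best]]
          chains[[ci]]$res_last <- resolutions[s]
          chains[[ci]]$length <- chains[[ci]]$length + 1L
          extended[ci] <- TRUE
        }
      }
      done <- c(done, chains[!extended])
      chains <- chains[extended]
    }
    for (bi in which(!taken)) {
      chains <- c(chains, list(list(genes_first = blocks[[bi]],
                                    res_first = resolutions[s],
                                    res_last = resolutions[s],
                                    length = 1L,
                                    current = blocks[[bi]])))
    }
  }
  done <- c(done, chains)

  keep <- Filter(function(ch) ch$length >= persistence_min, done)
  if (length(keep) == 0L) {
    return(data.frame(community_id = character(0), genes = I(list()),
                      size = integer(0), resolution_first = numeric(0),
                      resolution_last = numeric(0), persistence = integer(0)))
  }
  ord <- order(-vapply(keep, function(ch) length(ch$genes_first), integer(1)),
               vapply(keep, function(ch) ch$res_first, numeric(1)),
               vapply(keep, function(ch) paste(sort(ch$genes_first), collapse = ","),
                      character(1)))
  keep <- keep[ord]
  data.frame(
    community_id = sprintf("C%03d", seq_along(keep)),
    genes = I(lapply(keep, function(ch) sort(ch$genes_first))),
    size = vapply(keep, function(ch) length(ch$genes_first), integer(1)),
    resolution_first = vapply(keep, function(ch) ch$res_first, numeric(1)),
    resolution_last = vapply(keep, function(ch) ch$res_last, numeric(1)),
    persistence = vapply(keep, function(ch) ch$length, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Assemble the community DAG with containment-index edges
#'
#' For every ordered pair with `|v| < |w|`, a candidate edge `w -> v`
#' (parent w, child v) is added when `CI(v, w) > ci_threshold`; the
#' strict size condition makes cycles impossible. Equal-size communities
#' with mutual containment above the threshold (i.e. identical gene
#' sets) are merged with a notice. Redundant edges implied by longer
#' paths are removed by transitive reduction, and a synthetic root
#' holding all input genes is added when more than one top-level
#' community remains.
#'
#' @param communities data.frame from [persistent_communities()]
#' @param ci_threshold containment-index threshold in (0, 1], default 0.75
#' @param universe optional gene vector for the synthetic root (default:
#'   union of all community genes)
#' @return a `community_hierarchy`: list with `nodes` (community
#'   data.frame, plus the root if synthesized) and `edges`
#'   (`parent`, `child`, `ci`)
#' @export
build_hierarchy <- function(communities, ci_threshold = 0.75,
                            universe = NULL) {
  if (nrow(communities) == 0L) dd_param_error("no communities to organize")
  assert_scalar(ci_threshold, "ci_threshold", 0, 1, strict_lower = TRUE)

  # merge duplicated gene sets (equal size, mutual containment = 1)
  key <- vapply(communities$genes, function(g) paste(sort(g), collapse = ","),
                character(1))
  if (anyDuplicated(key)) {
    merged <- sum(duplicated(key))
    message(sprintf("merged %d duplicate community gene set(s)", merged))
    first <- !duplicated(key)
    agg_last <- tapply(communities$resolution_last, key, max)
    agg_pers <- tapply(communities$persistence, key, sum)
    communities <- communities[first, , drop = FALSE]
    k2 <- key[first]
    communities$resolution_last <- as.numeric(agg_last[k2])
    communities$persistence <- as.integer(agg_pers[k2])
  }

  nodes <- communities
  n <- nrow(nodes)
  parent <- character(0); child <- character(0); civ <- numeric(0)
  for (vi in seq_len(n)) for (wi in seq_len(n)) {
    if (vi == wi) next
    v <- nodes$genes[[vi]]; w <- nodes$genes[[wi]]
    if (length(v) >= length(w)) next
    ci <- containment_index(v, w)
    if (ci > ci_threshold) {
      parent <- c(parent, nodes$community_id[wi])
      child <- c(child, nodes$community_id[vi])
      civ <- c(civ, ci)
    }
  }
  edges <- data.frame(parent = parent, child = child, ci = civ,
                      stringsAsFactors = FALSE)
  edges <- transitive_reduction(edges)

  # synthetic root if needed
  roots <- setdiff(nodes$community_id, edges$child)
  universe <- sort(unique(universe %||% unlist(nodes$genes, use.names = FALSE)))
  root_id <- NULL
  if (length(roots) > 1L ||
      (length(roots) == 1L &&
       !setequal(nodes$genes[[match(roots, nodes$community_id)]], universe))) {
    root_id <- "root"
    root_row <- data.frame(
      community_id = root_id, genes = I(list(universe)),
      size = length(universe),
      resolution_first = min(nodes$resolution_first),
      resolution_last = max(nodes$resolution_last),
      persistence = max(nodes$persistence),
      stringsAsFactors = FALSE)
    top <- setdiff(nodes$community_id, edges$child)
    add <- data.frame(
      parent = root_id, child = top,
      ci = vapply(top, function(id)
        containment_index(nodes$genes[[match(id, nodes$community_id)]],
                          universe), numeric(1)),
      stringsAsFactors = FALSE)
    nodes <- rbind(root_row, nodes)
    edges <- rbind(add, edges)
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, root = root_id %||% roots),
            class = "community_hierarchy")
}

#' Transitive reduction of a DAG edge list
#'
#' Removes every edge (p, c) for which another directed path from p to c
#' exists; reachability is preserved and the operation is idempotent.
#'
#' @param edges data.frame with columns `parent`, `child` (extra columns
#'   carried through)
#' @return the reduced edge data.frame
#' @export
transitive_reduction <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  ids <- unique(c(edges$parent, edges$child))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  adj[cbind(edges$parent, edges$child)] <- TRUE
  # reachability via repeated squaring of the boolean adjacency
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  if (any(diag(reach))) dd_param_error("edge list contains a cycle")
  # edge p->c is redundant if p reaches some m with m -> ... -> c
  keep <- vapply(seq_len(nrow(edges)), function(i) {
    p <- edges$parent[i]; c_ <- edges$child[i]
    mids <- ids[adj[p, ] & ids != c_]
    !any(reach[mids, c_])
  }, logical(1))
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full hierarchy stage on a propagation result
#'
#' Induces the subnetwork on the NPS-selected genes plus seeds, sweeps
#' resolutions, keeps persistent communities, and builds the DAG.
#'
#' @param network the full `gene_network`
#' @param selected_genes NPS-selected gene ids
#' @param seed_genes seed gene ids (always included in the subnetwork)
#' @param resolution_grid sweep grid (default 0.5..5 by 0.5)
#' @param jaccard_threshold chain-matching similarity threshold
#' @param persistence_min minimal chain length
#' @param ci_threshold containment edge threshold
#' @param partition_seed partitioner seed
#' @return a `community_hierarchy` (with the induced subnetwork attached
#'   as attribute `subnetwork`)
#' @export
build_systems_map <- function(network, selected_genes, seed_genes = character(0),
                              resolution_grid = seq(0.5, 5, by = 0.5),
                              jaccard_threshold = 0.75, persistence_min = 5L,
                              ci_threshold = 0.75, partition_seed = 1L) {
  genes <- unique(c(selected_genes, intersect(seed_genes, network$genes)))
  sub <- induced_subnetwork(network, genes)
  sweep <- sweep_resolutions(sub, resolution_grid, partition_seed)
  comms <- persistent_communities(sweep, jaccard_threshold, persistence_min)
  if (nrow(comms) == 0L)
    dd_stop("no persistent communities found", "ddnetmap_stage_error")
  h <- build_hierarchy(comms, ci_threshold, universe = sub$genes)
  attr(h, "subnetwork") <- sub
  h
}

#' @export
print.community_hierarchy <- function(x, ...) {
  cat(sprintf("community_hierarchy: %d communities, %d containment edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Check a hierarchy's structural invariants
#'
#' Verifies acyclicity, the strict child-smaller-than-parent rule,
#' containment above threshold on every edge, and reachability of every
#' node from the root. Used by tests and the pipeline's output
#' validation.
#'
#' @param hierarchy a `community_hierarchy`
#' @param ci_threshold the threshold the edges were built with
#' @return TRUE invisibly; stops on violation
#' @export
validate_hierarchy <- function(hierarchy, ci_threshold = 0.75) {
  nodes <- hierarchy$nodes; edges <- hierarchy$edges
  sizes <- stats::setNames(nodes$size, nodes$community_id)
  gsets <- stats::setNames(nodes$genes, nodes$community_id)
  if (nrow(edges) > 0L) {
    if (!all(sizes[edges$child] < sizes[edges$parent]))
      dd_stop("edge with child not smaller than parent", "ddnetmap_invariant_error")
    ci_re <- mapply(function(p, c_) containment_index(gsets[[c_]], gsets[[p]]),
                    edges$parent, edges$child)
    if (!all(ci_re > ci_threshold))
      dd_stop("edge below containment threshold", "ddnetmap_invariant_error")
    g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) dd_stop("hierarchy contains a cycle",
                                    "ddnetmap_invariant_error")
  }
  invisible(TRUE)
}
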