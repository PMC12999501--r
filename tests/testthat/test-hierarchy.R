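# Multiscale partitions, persistence, containment DAG.

test_that("partitioner matches exhaustive modularity maximization on small graphs", {
  tri <- net_triangles()
  part <- partition_at_resolution(tri, 1, partition_seed = 1)
  oracle <- best_partition_oracle(tri, 1)
  expect_equal(partition_signature(part),
               partition_signature(stats::setNames(oracle, tri$genes)))
  # exactly the two triangles
  expect_equal(partition_signature(part), "a,b,c|x,y,z")

  # a single clique stays one block at low resolution
  v <- paste0("k", 1:6)
  p <- utils::combn(v, 2L)
  clique <- gene_network(edge_df(p[1L, ], p[2L, ]))
  part_c <- partition_at_resolution(clique, 0.5, partition_seed = 1)
  expect_equal(length(unique(part_c)), 1L)
  oracle_c <- best_partition_oracle(clique, 0.5)
  expect_equal(partition_signature(part_c),
               partition_signature(stats::setNames(oracle_c, clique$genes)))
})

test_that("partitions are deterministic under the partition seed", {
  net <- gen_network(60, 3, p_within = 0.4, p_between = 0.03, rng_seed = 6)
  a <- partition_at_resolution(net, 1.5, partition_seed = 11)
  b <- partition_at_resolution(net, 1.5, partition_seed = 11)
  expect_identical(a, b)
})

test_that("resolution sweep yields one partition per grid point and keeps components apart", {
  tri <- net_triangles()
  sw <- sweep_resolutions(tri, seq(0.5, 5, by = 0.5), partition_seed = 1)
  expect_length(sw, 10L)
  for (m in sw) {
    # disjoint components never share a block
    expect_false(any(m[c("a", "b", "c")] %in% m[c("x", "y", "z")]))
  }
  expect_error(sweep_resolutions(tri, c(2, 1)), class = "ddnetmap_parameter_error")
})

test_that("jaccard and containment behave on the boundary cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard(character(0), character(0)),
               class = "ddnetmap_parameter_error")
  expect_equal(containment_index(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(containment_index(c("a", "b"), c("c")), 0)
  expect_equal(containment_index(c("a", "b", "c", "d"), c("a", "b")), 0.5)
  expect_equal(containment_index(c("a", "b"), c("a", "b")), 1)
  expect_error(containment_index(character(0), "a"),
               class = "ddnetmap_parameter_error")
})

test_that("persistence counts consecutive matched resolutions", {
  # hand-built sweep: block {a,b,c} present at all 10 steps, {x,y} only at one
  grid <- seq(0.5, 5, by = 0.5)
  sweep <- lapply(seq_along(grid), function(i) {
    if (i == 4) c(a = 1, b = 1, c = 1, x = 2, y = 2, z = 4)
    else c(a = 1, b = 1, c = 1, x = 2, y = 3, z = 4)
  })
  names(sweep) <- as.character(grid)
  pc <- persistent_communities(sweep, 0.75, persistence_min = 5)
  expect_equal(nrow(pc), 1L)
  expect_equal(sort(pc$genes[[1]]), c("a", "b", "c"))
  expect_equal(pc$persistence, 10L)
  expect_equal(pc$resolution_first, 0.5)
  expect_equal(pc$resolution_last, 5)
})

test_that("two disjoint triangles persist as exactly two communities", {
  tri <- net_triangles()
  sw <- sweep_resolutions(tri, seq(0.5, 5, by = 0.5), partition_seed = 1)
  pc <- persistent_communities(sw, 0.75, persistence_min = 5)
  expect_equal(nrow(pc), 2L)
  sig <- sort(vapply(pc$genes, function(g) paste(sort(g), collapse = ","),
                     character(1)))
  expect_equal(sig, c("a,b,c", "x,y,z"))
  h <- build_hierarchy(pc, 0.75)
  expect_equal(sort(setdiff(h$nodes$community_id, "root")),
               sort(pc$community_id))
  expect_true(all(h$edges$parent == "root"))
})

test_that("containment edges chain with transitive reduction", {
  comms <- data.frame(
    community_id = c("big", "mid", "leaf"),
    genes = I(list(c("a", "b", "c", "d"), c("a", "b"), "a")),
    size = c(4L, 2L, 1L),
    resolution_first = c(1, 2, 3), resolution_last = c(5, 5, 5),
    persistence = c(5L, 5L, 5L), stringsAsFactors = FALSE)
  h <- build_hierarchy(comms, 0.75)
  expect_equal(nrow(h$edges[h$edges$parent != "root", ]), 2L)
  expect_true(any(h$edges$parent == "big" & h$edges$child == "mid"))
  expect_true(any(h$edges$parent == "mid" & h$edges$child == "leaf"))
  # the direct big -> leaf edge was reduced away
  expect_false(any(h$edges$parent == "big" & h$edges$child == "leaf"))
  validate_hierarchy(h, 0.75)
})

test_that("transitive reduction is idempotent and preserves reachability", {
  reach_set <- function(edges) {
    if (nrow(edges) == 0L) return(character(0))
    g <- igraph::graph_from_data_frame(edges[, c("parent", "child")])
    d <- igraph::distances(g, mode = "out")
    out <- apply(d, 1L, function(row) sort(names(which(is.finite(row) & row > 0))),
                 simplify = FALSE)
    out[order(names(out))]
  }
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    ids <- sprintf("c%02d", seq_len(n))
    # random DAG respecting the index order
    pairs <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(pairs)) < 0.15
    if (!any(keep)) next
    edges <- data.frame(parent = ids[pairs[1L, keep]],
                        child = ids[pairs[2L, keep]],
                        stringsAsFactors = FALSE)
    red <- transitive_reduction(edges)
    expect_identical(transitive_reduction(red), red)
    expect_equal(reach_set(red), reach_set(edges))
    g <- igraph::graph_from_data_frame(red[, c("parent", "child")])
    expect_true(igraph::is_dag(g))
  }
})

test_that("nested two-scale fixture recovers the planted containment DAG", {
  net <- net_nested()
  h <- build_systems_map(net, net$genes,
                         resolution_grid = seq(0.2, 5, by = 0.2),
                         jaccard_threshold = 0.75, persistence_min = 5,
                         ci_threshold = 0.75, partition_seed = 1)
  validate_hierarchy(h, 0.75)
  sigs <- vapply(h$nodes$genes, function(g) paste(sort(g), collapse = ","),
                 character(1))
  sub <- function(tag) paste(sort(paste0(tag, 1:6)), collapse = ",")
  super <- function(t1, t2) paste(sort(paste0(rep(c(t1, t2), each = 6), 1:6)),
                                  collapse = ",")
  # both planted scales are present
  for (s in c(sub("a"), sub("b"), sub("c"), sub("d"),
              super("a", "b"), super("c", "d")))
    expect_true(s %in% sigs)
  # sub-cliques hang under their super-group, not under the root
  id_of <- function(sig) h$nodes$community_id[sigs == sig]
  for (pair in list(c("a", "b"), c("c", "d"))) {
    pid <- id_of(super(pair[1], pair[2]))
    for (tag in pair) {
      cid <- id_of(sub(tag))
      expect_true(any(h$edges$parent == pid & h$edges$child == cid))
    }
  }
})

test_that("hierarchies are byte-identical under a fixed seed", {
  with_tmpdir(function(d) {
    net <- gen_network(80, 4, p_within = 0.5, p_between = 0.02, rng_seed = 4)
    h1 <- build_systems_map(net, net$genes, partition_seed = 3)
    h2 <- build_systems_map(net, net$genes, partition_seed = 3)
    d1 <- file.path(d, "h1"); d2 <- file.path(d, "h2")
    dir.create(d1); dir.create(d2)
    write_hierarchy(h1, d1); write_hierarchy(h2, d2)
    for (f in c("hierarchy_nodes.tsv", "hierarchy_edges.tsv"))
      expect_identical(readLines(file.path(d1, f)),
                       readLines(file.path(d2, f)))
  })
})
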