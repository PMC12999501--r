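# Degree-matched null ensembles and Network Proximity Scores.

test_that("null sets match the seed set in size and avoid exact reproduction", {
  net <- gen_network(100, 4, p_within = c(0.8, 0.5, 0.3, 0.15),
                     p_between = 0.02, rng_seed = 3)
  seeds <- net$genes[1:5]
  sets <- sample_degree_matched_sets(net, seeds, n_null = 50, rng_seed = 1)
  expect_length(sets, 50L)
  expect_true(all(lengths(sets) == 5L))
  expect_true(all(vapply(sets, function(s) !anyDuplicated(s), logical(1))))
  expect_false(any(vapply(sets, function(s) setequal(s, seeds), logical(1))))
  # deterministic under the seed
  sets2 <- sample_degree_matched_sets(net, seeds, n_null = 50, rng_seed = 1)
  expect_identical(sets, sets2)
})

test_that("on a regular graph the null is a uniform size-matched draw", {
  n <- 12L
  ring <- gene_network(edge_df(sprintf("v%02d", 1:n),
                               sprintf("v%02d", c(2:n, 1L))))
  bins <- degree_bin_assignment(ring, 10L)
  expect_equal(length(unique(bins)), 1L)
  sets <- sample_degree_matched_sets(ring, ring$genes[1:3], n_null = 200,
                                     rng_seed = 2)
  drawn <- table(unlist(sets))
  # every gene is reachable by the sampler
  expect_equal(length(drawn), n)
})

test_that("null sets preserve the seed set's mean degree on heterogeneous graphs", {
  net <- gen_network(120, 3, p_within = c(0.9, 0.4, 0.1), p_between = 0.02,
                     rng_seed = 5)
  deg <- node_degree(net)
  set.seed(8)
  seeds <- c(sample(net$genes[deg > stats::quantile(deg, 0.8)], 5),
             sample(net$genes[deg < stats::quantile(deg, 0.3)], 5))
  sets <- sample_degree_matched_sets(net, seeds, n_null = 1000, rng_seed = 9)
  null_mean <- mean(vapply(sets, function(s) mean(deg[s]), numeric(1)))
  expect_lt(abs(null_mean - mean(deg[seeds])) / mean(deg[seeds]), 0.10)
})

test_that("proximity scores are z-scores of log heats with exclusions flagged", {
  # observed log-heat equal to the null log-mean gives NPS 0
  f_obs <- c(g1 = exp(-3), g2 = exp(-1), g3 = 0.5, g4 = 0.1)
  nulls <- rbind(c(exp(-2), exp(-2), 0.5, 0),
                 c(exp(-4), exp(-4), 0.5, 0.2))
  colnames(nulls) <- names(f_obs)
  rec <- compute_nps(f_obs, nulls)
  expect_equal(rec$nps[rec$gene == "g1"], 0)
  # null log-heats {-2,-4}: mean -3, population sd 1; observed -1 -> NPS 2
  expect_equal(rec$nps[rec$gene == "g2"], 2)
  # zero spread in the null is flagged, not scored
  expect_true(is.na(rec$nps[rec$gene == "g3"]))
  expect_equal(rec$flags[rec$gene == "g3"], "degenerate_null")
  # zero heat anywhere excludes the gene
  expect_true(is.na(rec$nps[rec$gene == "g4"]))
  expect_equal(rec$flags[rec$gene == "g4"], "zero_heat")
})

test_that("selection uses a strict threshold", {
  rec <- data.frame(gene = c("a", "b", "c"), nps = c(3, 3.0001, NA))
  expect_equal(filter_nps(rec, 3), "b")
  rec2 <- data.frame(gene = c("a", "b"), nps = c(-5, 0))
  expect_equal(filter_nps(rec2, -Inf), c("a", "b"))
})

test_that("held-out null seed sets score approximately standard normal", {
  net <- gen_network(200, 4, p_within = 0.15, p_between = 0.01, rng_seed = 42)
  seeds <- gen_seed_set(net, 1, 10, purity = 1, rng_seed = 7)
  nulls <- sample_degree_matched_sets(net, seeds, n_null = 100, rng_seed = 5)
  held <- sample_degree_matched_sets(net, seeds, n_null = 10, rng_seed = 1234)
  null_heats <- propagate_ensemble(net, nulls, 0.5)
  held_heats <- propagate_ensemble(net, held, 0.5)
  pooled <- unlist(lapply(seq_len(nrow(held_heats)), function(i) {
    rec <- compute_nps(held_heats[i, ], null_heats)
    rec$nps[!is.na(rec$nps)]
  }))
  expect_gt(mean(pooled), -0.25)
  expect_lt(mean(pooled), 0.25)
  expect_gt(stats::sd(pooled), 0.75)
  expect_lt(stats::sd(pooled), 1.3)
})

test_that("proximity ranking separates the seeded community", {
  net <- gen_network(200, 4, p_within = 0.15, p_between = 0.01, rng_seed = 42)
  seeds <- gen_seed_set(net, 1, 10, purity = 1, rng_seed = 7)
  pr <- netprop(net, seeds, rng_seed = 5)
  nonseed <- setdiff(net$genes, seeds)
  lab <- net$membership[nonseed] == 1
  sc <- pr$nps$nps[match(nonseed, pr$nps$gene)]
  expect_gte(auroc(sc, lab), 0.9)
  # the selected set, where nonempty, is enriched for the planted block
  sel_nonseed <- setdiff(pr$selected, seeds)
  if (length(sel_nonseed) > 0)
    expect_gt(mean(net$membership[sel_nonseed] == 1), 0.5)
})

test_that("relabeling genes permutes proximity scores identically", {
  net <- gen_network(60, 3, p_within = 0.4, p_between = 0.03, rng_seed = 2)
  seeds <- net$genes[1:4]
  pr <- netprop(net, seeds, n_null = 20, rng_seed = 3)
  relabel <- stats::setNames(sprintf("z%03d", seq_along(net$genes)), net$genes)
  edges2 <- net$edges
  edges2$from <- unname(relabel[edges2$from])
  edges2$to <- unname(relabel[edges2$to])
  net2 <- gene_network(edges2)
  pr2 <- netprop(net2, unname(relabel[seeds]), n_null = 20, rng_seed = 3)
  m <- match(unname(relabel[pr$nps$gene]), pr2$nps$gene)
  expect_equal(pr2$nps$heat[m], pr$nps$heat, tolerance = 1e-12)
  expect_equal(pr2$nps$nps[m], pr$nps$nps, tolerance = 1e-10)
})
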