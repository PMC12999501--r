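# Discounting-rate scoring: implied rates, consistency, estimation, QC.

test_that("implied indifference rate follows the hyperbolic closed form", {
  it <- function(imm, del, d) data.frame(item_id = "x", immediate_amount = imm,
                                         delayed_amount = del, delay_days = d)
  expect_equal(implied_k(it(50, 100, 50)), 0.02)
  expect_equal(implied_k(it(99, 100, 1)), 1 / 99)
  # halving the delay doubles the implied rate
  expect_equal(implied_k(it(50, 100, 25)), 0.04)
  expect_equal(implied_k(it(50, 100, 25)), 2 * implied_k(it(50, 100, 50)))
})

test_that("consistency is 1 for rate-concordant profiles and 0 when reversed", {
  items <- mcq_item_bank()
  n <- nrow(items)
  ik <- implied_k(items)
  all_delayed <- choice_profile("p", rep(1L, n), items)
  all_immediate <- choice_profile("p", rep(0L, n), items)
  expect_equal(consistency_at_k(all_delayed, items, min(ik) / 10), 1)
  expect_equal(consistency_at_k(all_immediate, items, max(ik) * 10), 1)
  expect_equal(consistency_at_k(all_delayed, items, max(ik) * 10), 0)
  # boundary tie counts as consistent in either direction
  one <- items[1, , drop = FALSE]
  k_tie <- implied_k(one)
  expect_equal(consistency_at_k(0L, one, k_tie), 1)
  expect_equal(consistency_at_k(1L, one, k_tie), 1)
  expect_error(consistency_at_k(rep(NA_integer_, n), items, 0.01),
               class = "ddnetmap_empty_input")
})

test_that("noiseless on-grid choosers are recovered within half a grid step", {
  items <- mcq_item_bank()
  grid <- candidate_grid(items)
  half_step <- max(diff(log10(grid))) / 2
  for (k in grid) {
    prof <- gen_mcq_responses(log10(k), items)
    res <- estimate_k(prof, items)
    expect_lte(abs(res$log10_k - log10(k)), half_step + 1e-12)
    expect_equal(res$consistency, 1)
    expect_equal(10^res$log10_k, res$k_overall, tolerance = 1e-12)
  }
})

test_that("estimates are monotone in the generating rate", {
  items <- mcq_item_bank()
  grid <- candidate_grid(items)
  est <- vapply(grid, function(k)
    estimate_k(gen_mcq_responses(log10(k), items), items)$k_overall, numeric(1))
  expect_true(all(diff(est) >= 0))
})

test_that("boundary profiles are flagged as floor/ceiling estimates", {
  items <- mcq_item_bank()
  n <- nrow(items)
  grid <- candidate_grid(items)
  res_floor <- estimate_k(choice_profile("p", rep(1L, n), items), items)
  expect_equal(res_floor$k_overall, min(grid))
  expect_true("floor_estimate" %in% res_floor$qc_reasons)
  res_ceil <- estimate_k(choice_profile("p", rep(0L, n), items), items)
  expect_equal(res_ceil$k_overall, max(grid))
  expect_true("ceiling_estimate" %in% res_ceil$qc_reasons)
})

test_that("scoring is invariant to a joint permutation of items and choices", {
  items <- mcq_item_bank()
  prof <- gen_mcq_responses(-1.7, items)
  res <- estimate_k(prof, items)
  set.seed(1)
  perm <- sample(nrow(items))
  prof_p <- choice_profile(prof$participant_id, prof$choices[perm],
                           items[perm, , drop = FALSE])
  res_p <- estimate_k(prof_p, items[perm, , drop = FALSE])
  expect_equal(res_p$k_overall, res$k_overall)
  expect_equal(res_p$consistency, res$consistency)
  expect_equal(sort(names(res_p$k_by_bin)), sort(names(res$k_by_bin)))
})

test_that("QC flags fire on low concordance, missingness, and uniform response", {
  items <- mcq_item_bank()
  n <- nrow(items)
  # perfect profile passes
  good <- gen_mcq_responses(-2, items)
  expect_true(estimate_k(good, items)$qc_pass)
  # anti-concordant profile: answers opposite to a mid-grid rate
  ik <- implied_k(items)
  anti <- choice_profile("p", as.integer(ik <= 0.01), items)
  res_anti <- estimate_k(anti, items)
  expect_lt(res_anti$consistency, 0.75)
  expect_true("low_concordance" %in% res_anti$qc_reasons)
  # missing answers
  miss <- good$choices; miss[1:3] <- NA
  res_miss <- estimate_k(choice_profile("p", miss, items), items)
  expect_false(res_miss$qc_pass)
  expect_true("missing_items" %in% res_miss$qc_reasons)
  # uniform response
  unif <- estimate_k(choice_profile("p", rep(1L, n), items), items)
  expect_false(unif$qc_pass)
  expect_true("uniform_response" %in% unif$qc_reasons)
  # thresholds are configurable
  relaxed <- qc_flags(choice_profile("p", miss, items), res_miss,
                      max_missing = 5L)
  expect_true(relaxed$qc_pass)
})

test_that("cohort scoring returns one row per participant and a QC tally", {
  items <- mcq_item_bank()
  truth <- c(-3.2, -2.1, -1.2)
  mat <- gen_mcq_cohort(truth, items, noise_temperature = 0, rng_seed = 1)
  # append one uniform responder
  u <- mat[1, ]; u$participant_id <- "unif"; u[, -1] <- 1L
  mat <- rbind(mat, u)
  scored <- score_cohort(mat, items)
  expect_equal(nrow(scored), 4L)
  expect_true(all(scored$qc_pass[1:3]))
  expect_false(scored$qc_pass[4])
  expect_equal(attr(scored, "qc_summary")$n_excluded, 1L)
  expect_equal(scored$log10_k, log10(scored$k_overall))
  # per-bin columns populated for the standard three-bin bank
  expect_true(all(is.finite(scored$k_small)))
  # malformed entries name the row
  bad <- mat; bad[2, 3] <- 7L
  expect_error(score_cohort(bad, items), "row 2",
               class = "ddnetmap_format_error")
})

test_that("item and response CSVs round-trip", {
  with_tmpdir(function(d) {
    items <- mcq_item_bank()
    fi <- file.path(d, "items.csv")
    utils::write.csv(items, fi, row.names = FALSE, quote = FALSE)
    expect_equal(read_mcq_items(fi), items)
    mat <- gen_mcq_cohort(c(-2, -1), items, rng_seed = 1)
    fr <- file.path(d, "resp.csv")
    utils::write.csv(mat, fr, row.names = FALSE, quote = FALSE)
    expect_equal(read_mcq_responses(fr), mat)
  })
})
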