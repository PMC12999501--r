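# Monetary Choice Questionnaire scoring: derive each participant's
# hyperbolic discounting rate k (and log10 k) from 27 binary choices
# between a smaller-immediate and a larger-delayed reward, with QC flags.
#
# Scoring follows the consistency-maximization convention: each candidate
# rate k predicts "delayed" exactly when the item's implied indifference
# rate exceeds k; the estimate is the geometric mean of the candidates
# that agree with the largest fraction of observed choices.

#' Default 27-item questionnaire bank (synthetic Kirby-style ladder)
#'
#' Nine implied-k ranks spanning about 1.6e-4 to 0.25 per day in a
#' geometric ladder, crossed with three reward-magnitude bins. The same
#' (amount-ratio, delay) pairs are reused across bins — medium and large
#' items scale the small-bin amounts by 2 and 3 — so all three bins share
#' an identical implied-k ladder. The bank is a constructed instrument
#' with the standard questionnaire's statistical shape, not its item text;
#' any bank can be supplied as a CSV with the same columns.
#'
#' @return data.frame with columns `item_id`, `immediate_amount`,
#'   `delayed_amount`, `delay_days`, `magnitude_bin`
#' @export
mcq_item_bank <- function() {
  base <- data.frame(
    immediate_amount = c(34, 28, 22, 25, 19, 24, 14, 15, 11),
    delayed_amount   = c(35, 30, 25, 30, 25, 35, 25, 35, 30),
    delay_days       = c(186, 179, 136, 80, 53, 29, 19, 13, 7)
  )
  bins <- c(small = 1, medium = 2, large = 3)
  out <- do.call(rbind, lapply(names(bins), function(b) {
    data.frame(
      immediate_amount = base$immediate_amount * bins[[b]],
      delayed_amount = base$delayed_amount * bins[[b]],
      delay_days = base$delay_days,
      magnitude_bin = b,
      stringsAsFactors = FALSE
    )
  }))
  out <- cbind(item_id = sprintf("i%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' @noRd
validate_items <- function(items) {
  req <- c("item_id", "immediate_amount", "delayed_amount", "delay_days")
  if (!is.data.frame(items) || !all(req %in% names(items)))
    dd_param_error(paste("items must contain columns:", paste(req, collapse = ", ")))
  if (nrow(items) == 0L) dd_param_error("item bank is empty")
  if (any(items$immediate_amount <= 0) || any(items$delayed_amount <= 0))
    dd_param_error("amounts must be positive")
  if (any(items$delayed_amount <= items$immediate_amount))
    dd_param_error("delayed_amount must exceed immediate_amount")
  if (any(items$delay_days < 1))
    dd_param_error("delay_days must be >= 1")
  if (anyDuplicated(items$item_id))
    dd_param_error("duplicate item_id in item bank")
  invisible(items)
}

#' @noRd
item_bins <- function(items) {
  if ("magnitude_bin" %in% names(items)) return(as.character(items$magnitude_bin))
  # no bin column: tertiles of delayed amount, the instrument's convention
  q <- stats::quantile(items$delayed_amount, c(1 / 3, 2 / 3), type = 1)
  ifelse(items$delayed_amount <= q[1], "small",
         ifelse(items$delayed_amount <= q[2], "medium", "large"))
}

#' Construct a choice profile
#'
#' @param participant_id id string
#' @param choices integer vector aligned to `items`; 1 = delayed,
#'   0 = immediate, NA = missing
#' @param items the item bank the choices are aligned to
#' @return a `choice_profile` list
#' @export
choice_profile <- function(participant_id, choices, items = mcq_item_bank()) {
  validate_items(items)
  choices <- as.integer(choices)
  if (length(choices) != nrow(items))
    dd_param_error(sprintf("profile has %d choices; item bank has %d items",
                           length(choices), nrow(items)))
  if (!all(choices %in% c(0L, 1L) | is.na(choices)))
    dd_param_error("choices must be 0, 1, or NA")
  structure(list(participant_id = as.character(participant_id),
                 choices = choices, n_missing = sum(is.na(choices))),
            class = "choice_profile")
}

#' Indifference discounting rate implied by an item
#'
#' The per-day rate k at which the hyperbolically discounted delayed
#' reward equals the immediate reward: solving
#' `immediate = delayed / (1 + k * delay)` gives
#' `k = (delayed/immediate - 1) / delay`. A respondent with a steeper rate
#' than this prefers the immediate option.
#'
#' @param items item bank data.frame (one or more rows)
#' @return numeric vector of per-day rates, one per item
#' @examples
#' implied_k(data.frame(item_id = "x", immediate_amount = 50,
#'                      delayed_amount = 100, delay_days = 50)) # 0.02
#' @export
implied_k <- function(items) {
  validate_items(items)
  (items$delayed_amount / items$immediate_amount - 1) / items$delay_days
}

#' Candidate rate grid for consistency scoring
#'
#' The only decision-relevant rates are those between consecutive implied
#' indifference rates of the bank: the grid holds the geometric midpoints
#' of the sorted unique implied-k values plus one candidate below the
#' minimum and one above the maximum (extended at the same geometric
#' spacing as the nearest interior step, or by a factor of 2 for a
#' single-item bank).
#'
#' @param items item bank data.frame
#' @return increasing numeric vector of candidate per-day rates
#' @export
candidate_grid <- function(items) {
  ks <- sort(unique(implied_k(items)))
  if (length(ks) == 1L) return(c(ks / 2, ks * 2))
  mids <- sqrt(ks[-length(ks)] * ks[-1L])
  below <- ks[1L] * sqrt(ks[1L] / ks[2L])
  above <- ks[length(ks)] * sqrt(ks[length(ks)] / ks[length(ks) - 1L])
  c(below, mids, above)
}

#' Fraction of choices consistent with a candidate rate
#'
#' A rate k predicts "delayed" exactly when the item's implied rate
#' exceeds k; boundary ties (choice at exact indifference) count as
#' consistent, and missing responses are excluded from the denominator.
#'
#' @param profile a `choice_profile` (or bare 0/1/NA vector)
#' @param items item bank data.frame
#' @param k candidate per-day rate
#' @return fraction in [0, 1]
#' @export
consistency_at_k <- function(profile, items, k) {
  choices <- if (inherits(profile, "choice_profile")) profile$choices
             else as.integer(profile)
  if (length(choices) != nrow(items))
    dd_param_error("profile length does not match item bank")
  ok <- !is.na(choices)
  if (!any(ok)) dd_stop("profile has no answered items", "ddnetmap_empty_input")
  ik <- implied_k(items)
  consistent <- ifelse(ik == k, TRUE,                       # tie: consistent
                       choices == as.integer(ik > k))
  mean(consistent[ok])
}

#' Estimate the hyperbolic discounting rate from one profile
#'
#' Per magnitude bin, the bin estimate is the geometric mean of every
#' grid candidate achieving the bin's maximal consistency; the overall
#' rate is the geometric mean of the per-bin estimates, and the reported
#' consistency is evaluated at the overall rate across all answered
#' items. Profiles whose estimate sits on the grid boundary (all-delayed
#' or all-immediate response patterns) are flagged.
#'
#' @param profile a `choice_profile`
#' @param items item bank data.frame
#' @param grid candidate rates; defaults to [candidate_grid()] of `items`
#' @return a `discount_result` list: `participant_id`, `k_by_bin`,
#'   `k_overall`, `log10_k`, `consistency`, `qc_pass`, `qc_reasons`
#'   (QC fields filled by [qc_flags()] with default thresholds)
#' @export
estimate_k <- function(profile, items = mcq_item_bank(),
                       grid = candidate_grid(items)) {
  if (!inherits(profile, "choice_profile"))
    dd_param_error("profile must be a choice_profile")
  validate_items(items)
  if (length(grid) == 0L) dd_param_error("candidate grid is empty")
  grid <- sort(grid)
  bins <- item_bins(items)
  answered <- !is.na(profile$choices)
  if (!any(answered)) dd_stop("profile has no answered items", "ddnetmap_empty_input")

  reasons <- character(0)
  k_by_bin <- numeric(0)
  for (b in unique(bins)) {
    sel <- bins == b & answered
    if (!any(sel)) next
    sub_items <- items[bins == b, , drop = FALSE]
    sub_choices <- profile$choices[bins == b]
    cons <- vapply(grid, function(k)
      consistency_at_k(sub_choices, sub_items, k), numeric(1))
    best <- grid[cons == max(cons)]
    k_by_bin[b] <- geomean(best)
  }
  k_overall <- geomean(k_by_bin)
  if (k_overall <= grid[1L] * (1 + 1e-9))
    reasons <- c(reasons, "floor_estimate")
  if (k_overall >= grid[length(grid)] * (1 - 1e-9))
    reasons <- c(reasons, "ceiling_estimate")
  res <- structure(list(
    participant_id = profile$participant_id,
    k_by_bin = k_by_bin,
    k_overall = k_overall,
    log10_k = log10(k_overall),
    consistency = consistency_at_k(profile, items, k_overall),
    n_missing = profile$n_missing,
    qc_pass = NA,
    qc_reasons = reasons
  ), class = "discount_result")
  qc_flags(profile, res)
}

#' Apply quality-control exclusion rules to a discount result
#'
#' Participants with low response concordance or inappropriate response
#' patterns are excluded: the result fails if consistency at the estimate
#' falls below `min_consistency`, if more than `max_missing` items are
#' unanswered, or (with `flag_uniform`) if every answered choice is
#' identical. Flags accumulate in `qc_reasons`; `qc_pass` is their
#' conjunction. Boundary-estimate flags set by [estimate_k()] are
#' informational and do not fail QC by themselves.
#'
#' @param profile the scored `choice_profile`
#' @param result the `discount_result` to annotate
#' @param min_consistency minimum consistency fraction (default 0.75)
#' @param max_missing maximum unanswered items (default 0)
#' @param flag_uniform fail all-identical response patterns (default TRUE)
#' @return the annotated `discount_result`
#' @export
qc_flags <- function(profile, result, min_consistency = 0.75,
                     max_missing = 0L, flag_uniform = TRUE) {
  reasons <- setdiff(result$qc_reasons, c("low_concordance", "missing_items",
                                          "uniform_response"))
  if (result$consistency < min_consistency)
    reasons <- c(reasons, "low_concordance")
  if (profile$n_missing > max_missing)
    reasons <- c(reasons, "missing_items")
  answered <- profile$choices[!is.na(profile$choices)]
  if (flag_uniform && length(answered) > 0L && length(unique(answered)) == 1L)
    reasons <- c(reasons, "uniform_response")
  result$qc_reasons <- reasons
  result$qc_pass <- !any(reasons %in% c("low_concordance", "missing_items",
                                        "uniform_response"))
  result
}

#' Score a whole cohort of questionnaire responses
#'
#' @param choice_matrix data.frame: `participant_id` column followed by one
#'   0/1/NA column per item, aligned to `items` rows by position (or by
#'   name when column names match item ids)
#' @param items item bank data.frame
#' @param min_consistency,max_missing,flag_uniform QC thresholds, see
#'   [qc_flags()]
#' @return data.frame with one row per participant: `participant_id`,
#'   `k_small`, `k_medium`, `k_large` (NA for bins absent from the bank),
#'   `k_overall`, `log10_k`, `consistency`, `n_missing`, `qc_pass`,
#'   `qc_reasons` (comma-joined). QC-failed participants are retained
#'   with `qc_pass = FALSE`. The exclusion tally is attached as
#'   `attr(, "qc_summary")`.
#' @export
score_cohort <- function(choice_matrix, items = mcq_item_bank(),
                         min_consistency = 0.75, max_missing = 0L,
                         flag_uniform = TRUE) {
  if (!is.data.frame(choice_matrix) || names(choice_matrix)[1L] != "participant_id")
    dd_format_error("choice matrix must start with a participant_id column")
  validate_items(items)
  resp <- choice_matrix[, -1L, drop = FALSE]
  if (ncol(resp) != nrow(items))
    dd_format_error(sprintf("choice matrix has %d item columns; bank has %d items",
                            ncol(resp), nrow(items)))
  if (all(items$item_id %in% names(resp)))
    resp <- resp[, items$item_id, drop = FALSE]
  grid <- candidate_grid(items)

  rows <- lapply(seq_len(nrow(resp)), function(i) {
    raw <- suppressWarnings(as.integer(unlist(resp[i, ], use.names = FALSE)))
    if (!all(raw %in% c(0L, 1L) | is.na(raw)))
      dd_format_error(sprintf("row %d: choices must be 0, 1, or missing", i))
    prof <- choice_profile(choice_matrix$participant_id[i], raw, items)
    res <- estimate_k(prof, items, grid)
    res <- qc_flags(prof, res, min_consistency, max_missing, flag_uniform)
    data.frame(
      participant_id = res$participant_id,
      k_small = unname(res$k_by_bin["small"])[1],
      k_medium = unname(res$k_by_bin["medium"])[1],
      k_large = unname(res$k_by_bin["large"])[1],
      k_overall = res$k_overall,
      log10_k = res$log10_k,
      consistency = res$consistency,
      n_missing = res$n_missing,
      qc_pass = res$qc_pass,
      qc_reasons = paste(res$qc_reasons, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "qc_summary") <- list(
    n_total = nrow(out),
    n_pass = sum(out$qc_pass),
    n_excluded = sum(!out$qc_pass),
    reasons = table(unlist(strsplit(out$qc_reasons[!out$qc_pass], ",")))
  )
  out
}

#' Read an item bank CSV
#' @param path CSV with columns item_id, immediate_amount, delayed_amount,
#'   delay_days and optional magnitude_bin
#' @return validated item data.frame
#' @export
read_mcq_items <- function(path) {
  if (!file.exists(path)) dd_param_error(sprintf("file not found: %s", path))
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_items(items)
  items
}

#' Read a participant choice-matrix CSV
#' @param path CSV: participant_id plus one 0/1 column per item
#' @return data.frame suitable for [score_cohort()]
#' @export
read_mcq_responses <- function(path) {
  if (!file.exists(path)) dd_param_error(sprintf("file not found: %s", path))
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(out)[1L] != "participant_id")
    dd_format_error(sprintf("%s: first column must be participant_id", path))
  out
}
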