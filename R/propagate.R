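# Random-walk-with-restart propagation and Network Proximity Scores.
#
# Heat spreads from seed genes over the column-stochastic transition
# matrix W; at every step a constant fraction (1 - alpha) of each gene's
# heat returns to the seeds, so the steady state solves
#   F = (I - alpha * W)^{-1} (1 - alpha) * Y0 .
# Observed heats are z-scored (on the log scale) against an ensemble of
# random seed sets matched to the real seeds in size and degree
# distribution; genes with NPS above the threshold form the proximal set.

#' Uniform seed indicator vector
#'
#' Mass 1/|seeds| on each seed gene and 0 elsewhere, so total injected
#' heat is exactly 1.
#'
#' @param network a `gene_network`
#' @param seed_genes character vector of seed ids; genes absent from the
#'   network are dropped with a warning (count retained in
#'   `attr(, "dropped")`)
#' @return named numeric vector over `network$genes`, summing to 1
#' @export
seed_vector <- function(network, seed_genes) {
  seed_genes <- unique(as.character(seed_genes))
  present <- intersect(seed_genes, network$genes)
  dropped <- setdiff(seed_genes, network$genes)
  if (length(present) == 0L)
    dd_param_error("no seed genes present in the network")
  if (length(dropped) > 0L)
    warning(sprintf("%d seed gene(s) absent from the network were dropped",
                    length(dropped)), call. = FALSE)
  y0 <- stats::setNames(numeric(length(network$genes)), network$genes)
  y0[present] <- 1 / length(present)
  attr(y0, "dropped") <- dropped
  y0
}

#' Propagate seed heat to steady state (direct linear solve)
#'
#' Solves `(I - alpha W) F = (1 - alpha) Y0` exactly with a sparse
#' direct solver. Because W is column-stochastic the solution conserves
#' heat: `sum(F) = sum(Y0)`.
#'
#' @param network a `gene_network`
#' @param seed_genes seed ids, or a precomputed seed vector from
#'   [seed_vector()]
#' @param alpha restart-complement in (0, 1): the fraction of heat that
#'   keeps diffusing each step (default 0.5)
#' @return named numeric heat vector `F` over `network$genes`
#' @examples
#' net <- gene_network(data.frame(from = "a", to = "b", weight = 1))
#' propagate(net, "a", alpha = 0.5) # (2/3, 1/3)
#' @export
propagate <- function(network, seed_genes, alpha = 0.5) {
  assert_scalar(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  y0 <- if (is.numeric(seed_genes) && length(seed_genes) == length(network$genes))
    seed_genes else seed_vector(network, seed_genes)
  n <- length(network$genes)
  A <- Matrix::Diagonal(n) - alpha * network$W
  f <- as.numeric(Matrix::solve(A, (1 - alpha) * y0))
  stats::setNames(f, network$genes)
}

#' Propagate by fixed-point iteration (independent oracle)
#'
#' Iterates `F <- (1 - alpha) Y0 + alpha W F` from `F = Y0` until the
#' max-norm update falls below `tol`. The iteration contracts for
#' `alpha < 1`, so it converges to the same steady state as the direct
#' solve and serves as its independent cross-check.
#'
#' @inheritParams propagate
#' @param tol max-norm convergence tolerance
#' @param max_iter iteration cap
#' @return named numeric heat vector
#' @export
propagate_power_iteration <- function(network, seed_genes, alpha = 0.5,
                                      tol = 1e-12, max_iter = 10000L) {
  assert_scalar(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  y0 <- if (is.numeric(seed_genes) && length(seed_genes) == length(network$genes))
    seed_genes else seed_vector(network, seed_genes)
  f <- as.numeric(y0)
  base <- (1 - alpha) * as.numeric(y0)
  for (it in seq_len(max_iter)) {
    f_new <- base + alpha * as.numeric(network$W %*% f)
    if (max(abs(f_new - f)) < tol) {
      return(stats::setNames(f_new, network$genes))
    }
    f <- f_new
  }
  dd_stop("power iteration failed to converge (alpha too close to 1?)",
          "ddnetmap_convergence_error")
}

#' Assign genes to log-degree bins for null sampling
#'
#' Equal-width bins in log10(degree + 1); bins left with fewer than two
#' members are merged into the nearest (by bin centre) nonempty bin so
#' every bin supports sampling without replacement.
#'
#' @param network a `gene_network`
#' @param degree_bins requested number of bins (default 10)
#' @return named integer vector of bin ids per gene
#' @export
degree_bin_assignment <- function(network, degree_bins = 10L) {
  degree_bins <- assert_count(degree_bins, "degree_bins", min = 1L)
  ld <- log10(node_degree(network) + 1)
  rng <- range(ld)
  if (diff(rng) == 0) {
    bin <- rep.int(1L, length(ld))
  } else {
    brk <- seq(rng[1], rng[2], length.out = degree_bins + 1L)
    bin <- as.integer(cut(ld, brk, include.lowest = TRUE))
  }
  names(bin) <- names(ld)
  # merge undersized bins into the nearest occupied neighbour
  repeat {
    tab <- table(bin)
    small <- as.integer(names(tab)[tab < 2L])
    if (length(small) == 0L || length(tab) == 1L) break
    b <- small[1L]
    others <- as.integer(names(tab))[as.integer(names(tab)) != b]
    nearest <- others[which.min(abs(others - b))]
    bin[bin == b] <- nearest
  }
  bin
}

#' Sample random seed sets matched in size and degree distribution
#'
#' Each null set replaces every seed gene with a gene drawn uniformly
#' (without replacement within the set) from the same log10-degree bin,
#' preserving the size and the degree profile of the original seed set.
#' Null sets may contain original seed genes but never reproduce the
#' exact seed set.
#'
#' @param network a `gene_network`
#' @param seed_set character vector of seed ids (present in the network)
#' @param n_null number of null sets (default 100)
#' @param degree_bins number of log-degree bins (default 10)
#' @param rng_seed integer seed; the ensemble order is deterministic
#' @return list of `n_null` character vectors, each of length
#'   `length(seed_set)`
#' @export
sample_degree_matched_sets <- function(network, seed_set, n_null = 100L,
                                       degree_bins = 10L, rng_seed = 1L) {
  n_null <- assert_count(n_null, "n_null", min = 1L)
  seed_set <- unique(as.character(seed_set))
  if (!all(seed_set %in% network$genes))
    dd_param_error("seed_set contains genes absent from the network")
  bin <- degree_bin_assignment(network, degree_bins)
  seed_bins <- bin[seed_set]
  by_bin <- split(names(bin), bin)
  need <- table(seed_bins)
  for (b in names(need))
    if (length(by_bin[[b]]) < need[[b]])
      dd_param_error(sprintf("degree bin %s has %d genes but %d seeds need replacements",
                             b, length(by_bin[[b]]), need[[b]]))
  seed_sorted <- sort(seed_set)
  with_seed(rng_seed, {
    lapply(seq_len(n_null), function(i) {
      for (try in 1:100) {
        out <- character(length(seed_set))
        for (b in names(need))
          out[seed_bins == as.integer(b)] <- sample(by_bin[[b]], need[[b]])
        if (!identical(sort(out), seed_sorted)) return(out)
      }
      dd_param_error("could not sample a null set distinct from the seed set")
    })
  })
}

#' Network Proximity Scores from observed and null heats
#'
#' Per gene, the z-score of the log observed heat against the mean and
#' population standard deviation of the log null heats:
#' `NPS = (log F_obs - mean(log F_null)) / sd_pop(log F_null)`. Natural
#' logs are used (z-scores are base-invariant). Genes with zero heat in
#' the observed run or any null run are excluded from scoring and flagged
#' `zero_heat`; genes whose null log-heats have zero spread are flagged
#' `degenerate_null`.
#'
#' @param f_obs named observed heat vector
#' @param null_heats matrix, one row per null run, columns aligned to
#'   `f_obs` (n_null x n_genes)
#' @param threshold selection threshold on NPS (strict `>`, default 3)
#' @return data.frame: `gene`, `heat`, `null_log_mean`, `null_log_sd`,
#'   `nps`, `selected`, `flags`
#' @export
compute_nps <- function(f_obs, null_heats, threshold = 3) {
  if (is.null(dim(null_heats)) || nrow(null_heats) < 2L)
    dd_param_error("null_heats must be a matrix with >= 2 rows")
  if (ncol(null_heats) != length(f_obs))
    dd_param_error("null_heats columns must align with f_obs")
  genes <- names(f_obs) %||% colnames(null_heats) %||%
    sprintf("g%d", seq_along(f_obs))

  zero <- f_obs <= 0 | apply(null_heats <= 0, 2L, any)
  log_null <- log(null_heats)
  log_null[, zero] <- NA_real_
  mu <- colMeans(log_null)
  sdv <- apply(log_null, 2L, sd_pop)
  degen <- !zero & sdv == 0
  nps <- ifelse(zero | degen, NA_real_, (log(f_obs) - mu) / sdv)

  flags <- character(length(f_obs))
  flags[zero] <- "zero_heat"
  flags[degen] <- "degenerate_null"
  data.frame(
    gene = genes,
    heat = as.numeric(f_obs),
    null_log_mean = ifelse(zero, NA_real_, mu),
    null_log_sd = ifelse(zero, NA_real_, sdv),
    nps = nps,
    selected = !is.na(nps) & nps > threshold,
    flags = flags,
    stringsAsFactors = FALSE
  )
}

#' Select proximal genes by NPS threshold
#'
#' @param nps_records data.frame from [compute_nps()]
#' @param threshold strict lower bound on NPS (default 3)
#' @return character vector of genes with `NPS > threshold`
#' @export
filter_nps <- function(nps_records, threshold = 3) {
  nps_records$gene[!is.na(nps_records$nps) & nps_records$nps > threshold]
}

#' Run the full propagation + NPS stage
#'
#' Propagates the observed seed set, builds the degree-matched null
#' ensemble (all null runs share one multi-right-hand-side linear solve),
#' scores every gene, and applies the selection threshold.
#'
#' @param network a `gene_network`
#' @param seed_genes character vector of seed ids; ids absent from the
#'   network are dropped with a warning
#' @param alpha diffusion fraction in (0, 1), default 0.5
#' @param n_null size of the null ensemble, default 100
#' @param nps_threshold strict NPS selection threshold, default 3
#' @param degree_bins log-degree bins for null sampling, default 10
#' @param rng_seed integer seed for the null ensemble
#' @return a `propagation_result`: list with `f_obs`, `null_heats`
#'   (n_null x n_genes), `nps` (records data.frame), `selected` (gene
#'   vector), `seeds_used`, `seeds_dropped`, and the configuration
#' @export
netprop <- function(network, seed_genes, alpha = 0.5, n_null = 100L,
                    nps_threshold = 3, degree_bins = 10L, rng_seed = 1L) {
  y0 <- seed_vector(network, seed_genes)
  seeds_used <- names(y0)[y0 > 0]
  f_obs <- propagate(network, y0, alpha)

  null_sets <- sample_degree_matched_sets(network, seeds_used, n_null,
                                          degree_bins, rng_seed)
  null_heats <- propagate_ensemble(network, null_sets, alpha)
  nps <- compute_nps(f_obs, null_heats, nps_threshold)
  structure(list(
    f_obs = f_obs,
    null_heats = null_heats,
    nps = nps,
    selected = filter_nps(nps, nps_threshold),
    seeds_used = seeds_used,
    seeds_dropped = attr(y0, "dropped"),
    config = list(alpha = alpha, n_null = n_null,
                  nps_threshold = nps_threshold,
                  degree_bins = degree_bins, rng_seed = rng_seed)
  ), class = "propagation_result")
}

#' Propagate many seed sets in one factorized solve
#'
#' @param network a `gene_network`
#' @param seed_sets list of character vectors
#' @param alpha diffusion fraction
#' @return matrix, one row per seed set, columns = `network$genes`
#' @export
propagate_ensemble <- function(network, seed_sets, alpha = 0.5) {
  n <- length(network$genes)
  Y <- matrix(0, n, length(seed_sets))
  for (j in seq_along(seed_sets)) {
    idx <- match(seed_sets[[j]], network$genes)
    if (anyNA(idx)) dd_param_error("seed set contains genes absent from the network")
    Y[idx, j] <- 1 / length(idx)
  }
  A <- Matrix::Diagonal(n) - alpha * network$W
  Fm <- as.matrix(Matrix::solve(A, (1 - alpha) * Y))
  out <- t(Fm)
  colnames(out) <- network$genes
  out
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "propagation_result: %d genes, %d seeds, %d null sets, %d selected (NPS > %g)\n",
    length(x$f_obs), length(x$seeds_used), nrow(x$null_heats),
    length(x$selected), x$config$nps_threshold))
  invisible(x)
}
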