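# Synthetic-data generators: planted-partition networks, seed/trait gene
# sets concentrated in chosen communities, and simulated questionnaire
# responses from a known discounting rate. These define the conditions the
# downstream tests and the acceptance checks run under.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are
#' deterministic under their own seed without disturbing the session.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a planted-partition (stochastic block model) gene network
#'
#' The minimal generative model with community structure and tunable edge
#' density: `n_genes` genes are split into `n_communities` near-equal
#' blocks; each within-block gene pair is connected independently with
#' probability `p_within` (scalar, or one value per block for heterogeneous
#' degree distributions) and each between-block pair with probability
#' `p_between`. Edge weights are drawn uniformly from `weight_range` —
#' propagation only requires positive weights, so no heavier-tailed weight
#' model is claimed.
#'
#' Genes that receive no edge are dropped (a `gene_network` has no isolated
#' nodes); the planted block membership of the retained genes is kept in
#' the `membership` element.
#'
#' @param n_genes total number of genes
#' @param n_communities number of planted blocks (>= 1)
#' @param p_within within-block edge probability; scalar or length
#'   `n_communities`
#' @param p_between between-block edge probability; must satisfy
#'   `0 <= p_between < min(p_within) <= 1`
#' @param weight_range length-2 positive numeric, uniform weight bounds
#' @param rng_seed integer seed; same seed, same spec => identical network
#' @param p_matrix optional symmetric `n_communities` x `n_communities`
#'   matrix of block-pair edge probabilities (diagonal = within-block);
#'   overrides `p_within`/`p_between` and allows nested multi-scale
#'   structure
#' @return a `gene_network` with extra element `membership` (named integer
#'   vector: planted block of each retained gene)
#' @examples
#' net <- gen_network(30, 3, p_within = 1, p_between = 0, rng_seed = 1)
#' nrow(net$edges) # 3 * choose(10, 2) = 135
#' @export
gen_network <- function(n_genes, n_communities, p_within, p_between,
                        weight_range = c(0.1, 1), rng_seed = 1L,
                        p_matrix = NULL) {
  n_genes <- assert_count(n_genes, "n_genes", min = 2L)
  n_communities <- assert_count(n_communities, "n_communities", min = 1L)
  if (n_genes < n_communities)
    dd_param_error("n_genes must be >= n_communities")
  if (is.null(p_matrix)) {
    if (!length(p_within) %in% c(1L, n_communities))
      dd_param_error("p_within must be scalar or one value per community")
    for (p in p_within) assert_scalar(p, "p_within", 0, 1)
    assert_scalar(p_between, "p_between", 0, 1)
    if (p_between >= min(p_within) && p_between > 0)
      dd_param_error("p_between must be < p_within (planted structure)")
    p_within <- rep_len(p_within, n_communities)
    p_matrix <- matrix(p_between, n_communities, n_communities)
    diag(p_matrix) <- p_within
  } else {
    if (!is.matrix(p_matrix) || !all(dim(p_matrix) == n_communities) ||
        !isSymmetric(p_matrix) || any(p_matrix < 0 | p_matrix > 1))
      dd_param_error("p_matrix must be a symmetric probability matrix")
  }
  if (length(weight_range) != 2L || any(weight_range <= 0) ||
      weight_range[1] > weight_range[2])
    dd_param_error("weight_range must be positive (min, max)")

  block <- sort(rep_len(seq_len(n_communities), n_genes))
  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))

  with_seed(rng_seed, {
    pairs <- utils::combn(n_genes, 2L)
    i <- pairs[1L, ]; j <- pairs[2L, ]
    p <- p_matrix[cbind(block[i], block[j])]
    keep <- stats::runif(length(p)) < p
    if (!any(keep)) dd_param_error("generated network has no edges; raise densities")
    w <- stats::runif(sum(keep), weight_range[1], weight_range[2])
    net <- gene_network(data.frame(from = genes[i[keep]], to = genes[j[keep]],
                                   weight = w, stringsAsFactors = FALSE))
    dropped <- setdiff(genes, net$genes)
    net$membership <- stats::setNames(block, genes)[net$genes]
    net$report$isolated_dropped <- dropped
    net
  })
}

#' Sample a seed gene-set concentrated in one planted community
#'
#' Stands in for a trait-associated gene list: `ceiling(purity * size)`
#' genes are drawn from the target community and the remainder from the
#' rest of the network, without duplicates.
#'
#' @param network a `gene_network` with a `membership` element (or supply
#'   `membership` explicitly)
#' @param community_id planted block id to concentrate in
#' @param size total number of seed genes
#' @param purity fraction (0..1) of seeds that must come from the community
#' @param rng_seed integer seed
#' @param membership optional named block vector overriding
#'   `network$membership`
#' @return character vector of seed gene ids
#' @export
gen_seed_set <- function(network, community_id, size, purity = 1,
                         rng_seed = 1L, membership = network$membership) {
  size <- assert_count(size, "size", min = 1L)
  assert_scalar(purity, "purity", 0, 1)
  if (is.null(membership))
    dd_param_error("network has no community membership")
  if (size > length(network$genes))
    dd_param_error("size exceeds number of network genes")
  inside <- names(membership)[membership == community_id]
  outside <- setdiff(network$genes, inside)
  n_in <- as.integer(ceiling(purity * size))
  n_out <- size - n_in
  if (n_in > length(inside))
    dd_param_error(sprintf("community %s has %d genes; %d requested",
                           as.character(community_id), length(inside), n_in))
  if (n_out > length(outside))
    dd_param_error("not enough genes outside the target community")
  with_seed(rng_seed, {
    c(sample(inside, n_in), if (n_out > 0L) sample(outside, n_out))
  })
}

#' Generate trait gene-sets with controlled community overlap
#'
#' Builds one gene-set per trait; for trait t and community c, the set
#' contains `ceiling(overlap_matrix[t, c] * sizes[t])` genes sampled from
#' community c, with any remainder sampled from genes outside all listed
#' communities (or, if none exist, from genes not yet chosen).
#'
#' @param network a `gene_network`
#' @param communities named list of gene-id vectors (the planted or
#'   detected communities to overlap with)
#' @param overlap_matrix numeric matrix, traits x communities, entries in
#'   [0, 1]; rownames are trait names, colnames must match `communities`
#' @param sizes integer vector of trait-set sizes (recycled to traits)
#' @param rng_seed integer seed
#' @return named list of character vectors (GMT-style gene sets)
#' @export
gen_trait_sets <- function(network, communities, overlap_matrix, sizes,
                           rng_seed = 1L) {
  if (!is.matrix(overlap_matrix) || is.null(rownames(overlap_matrix)))
    dd_param_error("overlap_matrix must be a matrix with trait rownames")
  if (any(overlap_matrix < 0 | overlap_matrix > 1))
    dd_param_error("overlap_matrix entries must be in [0, 1]")
  cn <- colnames(overlap_matrix) %||% names(communities)
  if (!all(cn %in% names(communities)))
    dd_param_error("overlap_matrix columns must name entries of 'communities'")
  sizes <- rep_len(as.integer(sizes), nrow(overlap_matrix))
  pool_outside <- setdiff(network$genes, unlist(communities, use.names = FALSE))

  with_seed(rng_seed, {
    out <- vector("list", nrow(overlap_matrix))
    names(out) <- rownames(overlap_matrix)
    for (t in seq_len(nrow(overlap_matrix))) {
      counts <- as.integer(ceiling(overlap_matrix[t, ] * sizes[t]))
      if (sum(counts) > sizes[t])
        dd_param_error(sprintf(
          "trait '%s': requested community overlaps exceed set size %d",
          rownames(overlap_matrix)[t], sizes[t]))
      chosen <- character(0)
      for (ci in seq_along(counts)) {
        avail <- setdiff(communities[[cn[ci]]], chosen)
        if (counts[ci] > length(avail))
          dd_param_error(sprintf(
            "trait '%s': community '%s' too small for requested overlap",
            rownames(overlap_matrix)[t], cn[ci]))
        chosen <- c(chosen, sample(avail, counts[ci]))
      }
      rem <- sizes[t] - length(chosen)
      if (rem > 0L) {
        pool <- setdiff(pool_outside, chosen)
        if (rem > length(pool))
          dd_param_error(sprintf("trait '%s': not enough genes outside the listed communities for the remainder",
                                 rownames(overlap_matrix)[t]))
        chosen <- c(chosen, sample(pool, rem))
      }
      out[[t]] <- chosen
    }
    out
  })
}

#' Simulate questionnaire choices from a known discounting rate
#'
#' For each item the delayed option's present value is the hyperbolic
#' `V_delayed = delayed_amount / (1 + k * delay_days)` against
#' `V_immediate = immediate_amount`. With `noise_temperature > 0` the
#' delayed option is chosen with probability
#' `plogis((V_delayed - V_immediate) / noise_temperature)`; at temperature
#' 0 the chooser is the deterministic argmax, with value ties resolved to
#' "delayed" (a fixed convention that keeps the noiseless output
#' deterministic).
#'
#' @param true_log10_k log10 of the generating per-day discounting rate
#' @param items item bank data.frame (see [mcq_item_bank()])
#' @param noise_temperature nonnegative softmax temperature in currency
#'   units; 0 = noiseless
#' @param rng_seed integer seed (unused at temperature 0)
#' @param participant_id id string for the profile
#' @return a `choice_profile`: list with `participant_id`, `choices`
#'   (integer vector aligned to `items`, 1 = delayed, 0 = immediate,
#'   NA = missing), `n_missing`
#' @export
gen_mcq_responses <- function(true_log10_k, items = mcq_item_bank(),
                              noise_temperature = 0, rng_seed = 1L,
                              participant_id = "sim") {
  assert_scalar(true_log10_k, "true_log10_k")
  assert_scalar(noise_temperature, "noise_temperature", lower = 0)
  validate_items(items)
  k <- 10^true_log10_k
  v_del <- items$delayed_amount / (1 + k * items$delay_days)
  v_imm <- items$immediate_amount
  choices <- if (noise_temperature == 0) {
    as.integer(v_del >= v_imm)
  } else {
    p <- stats::plogis((v_del - v_imm) / noise_temperature)
    with_seed(rng_seed, as.integer(stats::runif(length(p)) < p))
  }
  choice_profile(participant_id, choices, items)
}

#' Simulate a cohort of questionnaire respondents
#'
#' @param true_log10_k numeric vector, one generating log10(k) per
#'   participant
#' @param items item bank data.frame
#' @param noise_temperature shared softmax temperature
#' @param rng_seed integer seed governing all participants
#' @return data.frame: `participant_id` followed by one 0/1 column per item
#' @export
gen_mcq_cohort <- function(true_log10_k, items = mcq_item_bank(),
                           noise_temperature = 0, rng_seed = 1L) {
  n <- length(true_log10_k)
  rows <- lapply(seq_len(n), function(i) {
    p <- gen_mcq_responses(true_log10_k[i], items, noise_temperature,
                           rng_seed = derive_seed(rng_seed, i),
                           participant_id = sprintf("p%04d", i))
    p$choices
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- items$item_id
  cbind(data.frame(participant_id = sprintf("p%04d", seq_len(n)),
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}
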