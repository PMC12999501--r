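# Hypergeometric trait enrichment of hierarchy communities, with odds
# ratios for the heatmap and Benjamini-Hochberg FDR over the whole
# community x trait family.

#' Upper-tail hypergeometric over-representation p-value
#'
#' The probability of drawing at least `overlap` trait genes when
#' `community_size` genes are sampled without replacement from a
#' universe of `universe_size` genes containing `trait_size` trait
#' genes: `P(X >= overlap)` for X hypergeometric.
#'
#' @param overlap observed overlap count a
#' @param community_size community (sample) size
#' @param trait_size trait-set size within the universe
#' @param universe_size total universe size N
#' @return p-value in [0, 1]
#' @examples
#' hypergeom_test(4, 5, 4, 10) # 6/252
#' @export
hypergeom_test <- function(overlap, community_size, trait_size, universe_size) {
  overlap <- assert_count(overlap, "overlap")
  community_size <- assert_count(community_size, "community_size")
  trait_size <- assert_count(trait_size, "trait_size")
  universe_size <- assert_count(universe_size, "universe_size", min = 1L)
  if (community_size > universe_size || trait_size > universe_size)
    dd_param_error("community and trait sizes must not exceed the universe")
  if (overlap > min(community_size, trait_size))
    dd_param_error("overlap exceeds min(community_size, trait_size)")
  if (overlap < community_size + trait_size - universe_size)
    dd_param_error("overlap below the margin-forced minimum")
  stats::phyper(overlap - 1L, trait_size, universe_size - trait_size,
                community_size, lower.tail = FALSE)
}

#' Odds ratio of the community x trait 2x2 table
#'
#' From the table (a = overlap, b = community \\ trait, c = trait \\
#' community, d = remainder), OR = (a d)/(b c). With `haldane = TRUE`
#' (the default) 0.5 is added to every cell whenever any cell is zero,
#' keeping heatmap values finite.
#'
#' @inheritParams hypergeom_test
#' @param haldane apply the Haldane-Anscombe 0.5 correction on zero cells
#' @return nonnegative odds ratio (possibly `Inf` when `haldane = FALSE`)
#' @export
odds_ratio <- function(overlap, community_size, trait_size, universe_size,
                       haldane = TRUE) {
  a <- overlap
  b <- community_size - overlap
  c_ <- trait_size - overlap
  d <- universe_size - community_size - trait_size + overlap
  if (min(a, b, c_, d) < 0) dd_param_error("inconsistent 2x2 table")
  if (haldane && any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` in sorted order, mapped
#' back to the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1]
#' @return q-values aligned to the input
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    dd_param_error("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric enrichment of every community for every trait set
#'
#' One test per (community, trait) pair against a shared gene universe;
#' trait sets are intersected with the universe first, and the FDR
#' correction is applied across the full family of pairs in one pass.
#'
#' @param hierarchy a `community_hierarchy`, or a data.frame of
#'   communities with `community_id` and `genes` (list column)
#' @param trait_sets named list of gene vectors (e.g. from [read_gmt()])
#' @param universe character vector of universe genes (default: all
#'   network genes should be supplied by the caller; falls back to the
#'   union of community genes)
#' @param fdr_level significance level on q (default 0.05)
#' @param haldane zero-cell correction for the odds ratio
#' @param include_root score the synthetic root node too (default FALSE)
#' @return data.frame: `community_id`, `trait`, `overlap`,
#'   `community_size`, `trait_size`, `universe_size`, `odds_ratio`,
#'   `p_value`, `q_value`, `significant`
#' @export
enrich_hierarchy <- function(hierarchy, trait_sets, universe = NULL,
                             fdr_level = 0.05, haldane = TRUE,
                             include_root = FALSE) {
  nodes <- if (inherits(hierarchy, "community_hierarchy")) hierarchy$nodes
           else hierarchy
  if (!is.data.frame(nodes) || nrow(nodes) == 0L)
    dd_param_error("no communities to test")
  if (!include_root) nodes <- nodes[nodes$community_id != "root", , drop = FALSE]
  if (is.null(names(trait_sets)) || anyDuplicated(names(trait_sets)))
    dd_param_error("trait_sets must be uniquely named")
  universe <- unique(as.character(
    universe %||% unlist(nodes$genes, use.names = FALSE)))
  N <- length(universe)
  if (N == 0L) dd_param_error("empty gene universe")

  rows <- list()
  for (ci in seq_len(nrow(nodes))) {
    comm <- intersect(nodes$genes[[ci]], universe)
    for (tn in names(trait_sets)) {
      trait <- intersect(unique(trait_sets[[tn]]), universe)
      a <- length(intersect(comm, trait))
      rows[[length(rows) + 1L]] <- data.frame(
        community_id = nodes$community_id[ci],
        trait = tn,
        overlap = a,
        community_size = length(comm),
        trait_size = length(trait),
        universe_size = N,
        odds_ratio = odds_ratio(a, length(comm), length(trait), N, haldane),
        p_value = hypergeom_test(a, length(comm), length(trait), N),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < fdr_level
  rownames(out) <- NULL
  out
}

#' Annotate communities with their top enriched term
#'
#' Reuses the enrichment machinery on an annotation term GMT (e.g.
#' biological-process term sets): each community is labelled with its
#' smallest-q term, ties broken by larger overlap then term name. A
#' manual-override column can replace labels downstream.
#'
#' @param hierarchy a `community_hierarchy`
#' @param term_sets named list of gene vectors
#' @param universe gene universe
#' @param fdr_level q threshold for assigning a label at all
#' @return data.frame: `community_id`, `annotation`, `q_value`
#' @export
annotate_communities <- function(hierarchy, term_sets, universe = NULL,
                                 fdr_level = 0.05) {
  tab <- enrich_hierarchy(hierarchy, term_sets, universe, fdr_level)
  by_comm <- split(tab, tab$community_id)
  rows <- lapply(by_comm, function(d) {
    d <- d[order(d$q_value, -d$overlap, d$trait), , drop = FALSE]
    top <- d[1L, ]
    data.frame(community_id = top$community_id,
               annotation = if (top$significant) top$trait else NA_character_,
               q_value = top$q_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member genes.
#' Duplicate genes within a set are removed with a warning; duplicate
#' set names are an error. Trailing empty fields are tolerated.
#'
#' @param path GMT file path
#' @return named list of character vectors; descriptions kept in
#'   `attr(, "description")`
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) dd_param_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) dd_format_error(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    dd_format_error(sprintf("malformed GMT line %d in %s", bad[1L], path))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    dd_format_error(sprintf("duplicate gene-set name '%s' in %s",
                            nm[duplicated(nm)][1L], path))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g))
      warning(sprintf("duplicate genes within set '%s' deduplicated", f[[1L]]),
              call. = FALSE)
    unique(g)
  })
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output path
#' @param description per-set description (recycled; default "na")
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets))) dd_param_error("sets must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
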