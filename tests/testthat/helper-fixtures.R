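# Shared fixtures and small independent oracles, all built in code.

edge_df <- function(from, to, weight = 1) {
  data.frame(from = from, to = to, weight = weight, stringsAsFactors = FALSE)
}

net_two <- function(w = 1) gene_network(edge_df("a", "b", w))

net_path3 <- function() gene_network(edge_df(c("a", "b"), c("b", "c")))

net_star <- function(leaves = 3L) {
  gene_network(edge_df(rep("h", leaves), paste0("l", seq_len(leaves))))
}

# two disjoint triangles {a,b,c} and {x,y,z}
net_triangles <- function() {
  gene_network(edge_df(c("a", "a", "b", "x", "x", "y"),
                       c("b", "c", "c", "y", "z", "z")))
}

# Erdos-Renyi random network for oracle-equivalence sweeps
net_random <- function(n, p = 0.3, seed = 1L) {
  set.seed(seed)
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[1L] <- TRUE
  # guarantee no isolated node: chain all nodes
  chain <- cbind(seq_len(n - 1L), 2:n)
  from <- c(pairs[1L, keep], chain[, 1L])
  to <- c(pairs[2L, keep], chain[, 2L])
  w <- stats::runif(length(from), 0.2, 1)
  gene_network(edge_df(sprintf("n%02d", from), sprintf("n%02d", to), w))
}

# nested two-scale fixture: four 6-cliques; sibling cliques coupled by 12
# bridge edges (two chained matchings); two edges join the super-groups
net_nested <- function() {
  clique <- function(tag) {
    v <- paste0(tag, 1:6)
    p <- utils::combn(v, 2L)
    edge_df(p[1L, ], p[2L, ])
  }
  bridge <- function(ta, tb) {
    i <- 1:6
    edge_df(c(paste0(ta, i), paste0(ta, i)),
            c(paste0(tb, i), paste0(tb, c(2:6, 1))))
  }
  gene_network(rbind(
    clique("a"), clique("b"), clique("c"), clique("d"),
    bridge("a", "b"), bridge("c", "d"),
    edge_df(c("a1", "b4"), c("c1", "d4"))
  ))
}

# rank-based AUROC of scores for binary labels
auroc <- function(scores, labels) {
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- independent oracles -------------------------------------------------

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (b in seq_len(mx + 1L)) rec(c(prefix, b), max(mx, b))
  }
  rec(integer(0), 0L)
  out
}

# resolution-parameterized weighted modularity of a membership vector
modularity_oracle <- function(network, membership, resolution = 1) {
  stopifnot(length(membership) == length(network$genes))
  names(membership) <- network$genes
  w <- network$edges$weight
  m <- sum(w)
  strength <- node_strength(network)
  same <- membership[network$edges$from] == membership[network$edges$to]
  e_in <- tapply(w[same], membership[network$edges$from][same], sum)
  q <- sum(e_in) / m
  for (b in unique(membership)) {
    d <- sum(strength[membership == b])
    q <- q - resolution * (d / (2 * m))^2
  }
  q
}

# exhaustive modularity-maximizing partition (n small)
best_partition_oracle <- function(network, resolution = 1) {
  parts <- all_partitions(length(network$genes))
  qs <- vapply(parts, function(p) modularity_oracle(network, p, resolution),
               numeric(1))
  parts[[which.max(qs)]]
}

# exact upper-tail hypergeometric by direct enumeration of overlap counts
hyper_oracle <- function(a, k, K, N) {
  lo <- max(a, k + K - N)
  hi <- min(k, K)
  if (a > hi) return(0)
  sum(vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, k - x), numeric(1))) / choose(N, k)
}

# canonical block signature of a partition (label-invariant comparison)
partition_signature <- function(membership, genes = names(membership)) {
  blocks <- split(genes, membership)
  paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = ","),
                    character(1))), collapse = "|")
}

with_tmpdir <- function(code) {
  d <- tempfile("ddnm")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  force(code(d))
}
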