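# Independent oracles and graph fixtures used across the suite.

# brute-force HRR: for each gene sort partners by |r| (ties by index) with an
# explicit double loop, then take the max of the two one-sided ranks
oracle_hrr <- function(r) {
  n <- nrow(r)
  a <- abs(r)
  rank_of <- function(i, j) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-a[i, others], others)]
    match(j, ord)
  }
  out <- matrix(NA_integer_, n, n, dimnames = dimnames(r))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- max(rank_of(i, j), rank_of(j, i))
  out
}

# exact hypergeometric upper tail by explicit binomial-coefficient summation
oracle_hyper_tail <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition: sort, p(i)*m/i, cumulative
# minimum from the largest rank down, cap at 1, restore input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# random symmetric correlation-like matrix with unit diagonal
random_cor <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * 8), n, 8)
  r <- cor(t(x))
  dimnames(r) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  r
}

# planted-partition graph: k blocks, intra-block edge prob 0.9, inter 0.02
make_block_graph <- function(k, seed, size_range = 8:20,
                             p_in = 0.9, p_out = 0.02) {
  set.seed(seed)
  sizes <- sample(size_range, k, replace = TRUE)
  n <- sum(sizes)
  lab <- rep(seq_len(k), sizes)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < (if (lab[i] == lab[j]) p_in else p_out))
      A[i, j] <- A[j, i] <- 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::E(g)$weight <- 1
  list(graph = g, labels = stats::setNames(lab, igraph::V(g)$name))
}

# three cliques (5, 6, 7) joined by two single bridges of weight 0.1
bridged_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(6),
                              igraph::make_full_graph(7))
  igraph::V(g)$name <- paste0("n", 1:18)
  igraph::E(g)$weight <- 1
  igraph::add_edges(g, c(1, 6, 6, 12), attr = list(weight = c(0.1, 0.1)))
}

# small expression set with explicit stage means (one value per stage,
# replicated with optional jitter)
toy_expression <- function(stage_means, replicates = 3, jitter = 0, seed = 1) {
  set.seed(seed)
  stages <- colnames(stage_means)
  vals <- do.call(cbind, lapply(stages, function(s)
    matrix(rep(stage_means[, s], replicates), ncol = replicates) +
      matrix(rnorm(nrow(stage_means) * replicates, 0, jitter), ncol = replicates)))
  vals <- pmax(vals, 0)
  colnames(vals) <- paste0(rep(stages, each = replicates), "_",
                           rep(seq_len(replicates), length(stages)))
  rownames(vals) <- rownames(stage_means)
  expression_set(vals, stage_order = stages)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# shared default synthetic dataset + fit (computed once per test run)
default_fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_gcn_dataset(seed = 1)
      fit <- hrr_gcn(ds$expression, deg = ds$deg, annotation = ds$annotation,
                     tf = ds$tf)
      cache <<- list(ds = ds, fit = fit)
    }
    cache
  }
})
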