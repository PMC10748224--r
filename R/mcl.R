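#' Markov Cluster Algorithm (MCL)
#'
#' Clusters a weighted undirected graph by simulating flow: the column-
#' stochastic transition matrix is alternately expanded (matrix power,
#' strengthening flow along long walks) and inflated (entrywise power
#' followed by column renormalisation, sharpening strong flow), with small
#' entries pruned each iteration.  At convergence the remaining flow defines
#' attractor nodes (nonzero diagonal); each attractor system — attractors
#' connected through residual flow — forms one cluster, and every other node
#' joins the system it sends most flow to.  The inflation parameter `I`
#' controls granularity (larger I, finer clusters); 3.0 is the value commonly
#' used for co-expression networks of this kind.
#'
#' @param g igraph graph with positive edge weights (attribute `weight`;
#'   weight 1 assumed if absent).
#' @param inflation inflation exponent I > 1 (default 3).
#' @param expansion expansion power e >= 2 (default 2).
#' @param edge_weights `"attribute"` (default) clusters on the graph's
#'   `weight` attribute; `"uniform"` clusters on structure alone (every edge
#'   weight 1).  Uniform weighting reproduces the convention of giving every
#'   edge of a network one constant weight tied to its HRR cutoff (1/5, 1/15,
#'   1/25 at cutoffs 10, 20, 30): MCL is invariant to that constant once
#'   self-loops scale with it.
#' @param self_loops rule for the self-loop weight added to each node before
#'   normalisation: `"max"` (default; the node's maximum incident edge
#'   weight, at least 1) or `"one"`.
#' @param prune entries below this value are zeroed each iteration (1e-5).
#' @param max_iter iteration cap (200); hitting it yields a warning and
#'   `converged = FALSE`.
#' @param tol convergence tolerance on the largest entry change (1e-8).
#' @return object of class `"mcl_clusters"`: list with `clusters` (named list
#'   of gene-id vectors; ids ordered by decreasing size, ties by smallest
#'   member), `assignment` (named integer vector), `unassigned`,
#'   `iterations`, `converged`, and `max_col_dev` (worst deviation of any
#'   column sum from 1 across iterates, a numerical health check).
#' @export
mcl <- function(g, inflation = 3, expansion = 2,
                edge_weights = c("attribute", "uniform"),
                self_loops = c("max", "one"), prune = 1e-5,
                max_iter = 200, tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2, prune > 0, tol > 0)
  self_loops <- match.arg(self_loops)
  edge_weights <- match.arg(edge_weights)
  n <- igraph::vcount(g)
  if (n == 0) stopf("graph has no nodes")
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  if (edge_weights == "uniform" ||
      (is.null(igraph::E(g)$weight) && igraph::ecount(g) > 0))
    g <- igraph::set_edge_attr(g, "weight", value = 1)
  if (igraph::ecount(g) > 0 && any(igraph::E(g)$weight <= 0))
    stopf("edge weights must be positive")
  A <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "weight" else NULL,
                                   sparse = FALSE)
  dimnames(A) <- list(nodes, nodes)
  loop <- switch(self_loops,
                 max = pmax(apply(A, 1, max), 1),
                 one = rep(1, n))
  diag(A) <- loop
  normalize <- function(M) {
    cs <- colSums(M)
    dead <- cs == 0
    if (any(dead)) { diag(M)[dead] <- 1; cs[dead] <- 1 }
    sweep(M, 2, cs, "/")
  }
  M <- normalize(A)
  converged <- FALSE
  it <- 0
  delta <- Inf
  max_col_dev <- 0  # worst deviation of any column sum from 1 across iterates
  while (it < max_iter) {
    it <- it + 1
    Mx <- M
    for (k in seq_len(expansion - 1)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    Mx[Mx < prune] <- 0
    Mx <- normalize(Mx)
    max_col_dev <- max(max_col_dev, abs(colSums(Mx) - 1))
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("MCL did not converge within %d iterations (last change %.3g)",
          max_iter, delta)

  # attractor systems: attractors are nodes retaining flow on the diagonal;
  # two attractors share a system if residual flow links them
  attract <- which(diag(M) > 0)
  if (length(attract) == 0) attract <- seq_len(n)  # degenerate safeguard
  sub <- (M[attract, attract, drop = FALSE] > 0) |
         t(M[attract, attract, drop = FALSE] > 0)
  ga <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected", diag = FALSE)
  comp <- igraph::components(ga)$membership  # system id per attractor
  systems <- split(attract, comp)

  assignment <- integer(n)
  for (j in seq_len(n)) {
    flow <- M[attract, j]
    if (all(flow == 0)) { assignment[j] <- NA_integer_; next }
    cand <- unique(comp[flow == max(flow)])
    if (length(cand) > 1) {  # deterministic overlap resolution
      sizes <- vapply(systems[as.character(cand)], length, integer(1))
      cand <- cand[order(-sizes, cand)][1]
    }
    assignment[j] <- cand
  }
  clusters <- split(nodes[!is.na(assignment)], assignment[!is.na(assignment)])
  unassigned <- nodes[is.na(assignment)]
  structure(list(clusters = order_clusters(clusters),
                 assignment = cluster_assignment(order_clusters(clusters)),
                 unassigned = unassigned, iterations = it, converged = converged,
                 max_col_dev = max_col_dev),
            class = "mcl_clusters")
}

# stable ids: decreasing size, ties by lexicographically smallest member
order_clusters <- function(clusters) {
  clusters <- lapply(clusters, function(x) sort(as.character(x)))
  if (!length(clusters)) return(setNames(list(), character(0)))
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[`, character(1), 1))
  out <- clusters[ord]
  names(out) <- as.character(seq_along(out))
  out
}

cluster_assignment <- function(clusters) {
  if (!length(clusters)) return(setNames(integer(0), character(0)))
  ids <- rep(as.integer(names(clusters)), lengths(clusters))
  setNames(ids, unlist(clusters, use.names = FALSE))
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat(sprintf("MCL clustering: %d clusters over %d genes (%d unassigned), %d iterations%s\n",
              length(x$clusters), length(x$assignment), length(x$unassigned),
              x$iterations, if (x$converged) "" else " [not converged]"))
  if (length(x$clusters)) {
    sz <- lengths(x$clusters)
    cat(sprintf("  sizes: %s\n", paste(sz, collapse = ", ")))
  }
  invisible(x)
}

#' Drop meaningless clusters
#'
#' Removes clusters that are too small or lack any significantly enriched
#' annotation term.  The default rule keeps a cluster only if it has at least
#' `min_size` genes AND at least one significant term (removal on either
#' failure); `rule = "and"` removes only clusters failing both conditions.
#'
#' @param cs an [mcl()] result.
#' @param verdicts logical vector named by cluster id: does the cluster have
#'   any significant enriched term?  `NA` is treated as `FALSE`.
#' @param min_size minimum cluster size (default 3).
#' @param rule `"or"` (default): remove if small OR unenriched; `"and"`:
#'   remove only if small AND unenriched.
#' @return a new `"mcl_clusters"` object with ids recomputed and removed
#'   genes moved to `unassigned`.
#' @export
drop_meaningless <- function(cs, verdicts, min_size = 3, rule = c("or", "and")) {
  stopifnot(inherits(cs, "mcl_clusters"))
  rule <- match.arg(rule)
  ids <- names(cs$clusters)
  if (!all(ids %in% names(verdicts)))
    stopf("missing enrichment verdict for cluster(s): %s",
          paste(setdiff(ids, names(verdicts)), collapse = ", "))
  v <- !is.na(verdicts[ids]) & verdicts[ids]
  small <- lengths(cs$clusters) < min_size
  remove <- if (rule == "or") small | !v else small & !v
  kept <- order_clusters(cs$clusters[!remove])
  structure(list(clusters = kept, assignment = cluster_assignment(kept),
                 unassigned = sort(c(cs$unassigned,
                                     unlist(cs$clusters[remove], use.names = FALSE))),
                 iterations = cs$iterations, converged = cs$converged),
            class = "mcl_clusters")
}

#' Read or write a cluster assignment TSV
#'
#' Two columns, `gene` and `cluster_id`; lets users export an MCL result or
#' substitute an external clustering (e.g. Cytoscape clusterMaker output).
#'
#' @param cs an `"mcl_clusters"` object.
#' @param path file path.
#' @return `write_clusters()`: invisibly `path`; `read_clusters()`: an
#'   `"mcl_clusters"` object (iterations 0, converged `NA`).
#' @export
write_clusters <- function(cs, path) {
  df <- data.frame(gene = names(cs$assignment), cluster_id = unname(cs$assignment))
  df <- df[order(df$cluster_id, df$gene), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "cluster_id") %in% names(df)))
    stopf("%s: expected columns gene, cluster_id", path)
  cl <- order_clusters(split(df$gene, df$cluster_id))
  structure(list(clusters = cl, assignment = cluster_assignment(cl),
                 unassigned = character(0), iterations = 0L, converged = NA),
            class = "mcl_clusters")
}
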