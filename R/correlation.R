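#' Pearson correlation matrix over samples
#'
#' Correlates genes across replicate-level samples (or stage means with
#' `stage_level = TRUE`).  Genes with zero variance have undefined
#' correlations; their rows/columns are stored as 0 and flagged, and they are
#' excluded later at network construction.
#'
#' @param es an [expression_set()].
#' @param genes optional gene subset (must be present in `es`).
#' @param stage_level correlate stage means instead of raw samples.
#' @return object of class `"cor_mat"`: list with `r` (symmetric matrix,
#'   unit diagonal) and `zero_var` (logical flag per gene).
#' @export
pearson_matrix <- function(es, genes = NULL, stage_level = FALSE) {
  stopifnot(inherits(es, "expr_set"))
  genes <- genes %||% rownames(es$values)
  missing <- setdiff(genes, rownames(es$values))
  if (length(missing))
    stopf("gene(s) not in matrix: %s", paste(head(missing, 5), collapse = ", "))
  x <- if (stage_level) stage_means(subset_genes(es, genes))$mean
       else es$values[genes, , drop = FALSE]
  if (ncol(x) < 3) stopf("need >=3 samples to correlate")
  zv <- apply(x, 1, sd) == 0
  r <- suppressWarnings(cor(t(x)))
  r[zv, ] <- 0; r[, zv] <- 0
  diag(r) <- 1
  structure(list(r = r, zero_var = zv), class = "cor_mat")
}

#' Highest reciprocal rank transform
#'
#' For each gene, all other genes are ranked by descending absolute
#' correlation (rank 1 = strongest partner; ties broken deterministically by
#' gene-id order).  HRR(A, B) is the larger of B's rank in A's list and A's
#' rank in B's list, so a low HRR marks mutually top co-expression partners.
#'
#' @param cm a [pearson_matrix()] result (or a plain symmetric correlation
#'   matrix).
#' @return symmetric integer matrix of HRR values in `[1, n - 1]`; diagonal
#'   is `NA`.
#' @export
hrr_transform <- function(cm) {
  r <- if (inherits(cm, "cor_mat")) cm$r else cm
  n <- nrow(r)
  if (n < 3) stopf("need >=3 genes for reciprocal ranking")
  a <- abs(r)
  ranks <- matrix(NA_integer_, n, n, dimnames = dimnames(r))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-a[i, others], others)]
    ranks[i, ord] <- seq_len(n - 1)
  }
  hrr <- pmax(ranks, t(ranks))
  diag(hrr) <- NA_integer_
  hrr
}

#' Build the HRR co-expression network
#'
#' Keeps an undirected edge between genes A and B when both the absolute
#' correlation and the reciprocal-rank criteria hold:
#' `|r(A,B)| >= r_min` and `HRR(A,B) <= hrr_max` (both cutoffs inclusive).
#' Edges carry the signed correlation, the HRR, a weight (default `1/HRR`)
#' and a sign label; genes flagged as zero-variance are excluded, and only
#' genes incident to at least one retained edge become nodes.
#'
#' @param cm a [pearson_matrix()] result.
#' @param hrr matrix from [hrr_transform()]; computed from `cm` if missing.
#' @param r_min absolute-correlation cutoff (default 0.8).
#' @param hrr_max HRR cutoff (default 30, the loosest conventional choice).
#' @param weight_fun function mapping HRR to edge weight (default `1/HRR`).
#' @param tf_genes optional character vector; matching nodes get `tf = TRUE`.
#' @return an [igraph::graph] with vertex attribute `tf` and edge attributes
#'   `r`, `hrr`, `weight`, `sign`.
#' @export
build_network <- function(cm, hrr = NULL, r_min = 0.8, hrr_max = 30,
                          weight_fun = function(h) 1 / h, tf_genes = character()) {
  stopifnot(inherits(cm, "cor_mat"), r_min > 0, r_min <= 1, hrr_max >= 1)
  hrr <- hrr %||% hrr_transform(cm)
  r <- cm$r
  ok <- !cm$zero_var
  keep <- abs(r) >= r_min & hrr <= hrr_max & outer(ok, ok, "&")
  keep[upper.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warnf("no edges pass |r| >= %g and HRR <= %g; returning an empty network",
          r_min, hrr_max)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  genes <- rownames(r)
  edges <- data.frame(from = genes[idx[, 2]], to = genes[idx[, 1]],
                      r = r[idx], hrr = as.integer(hrr[idx]),
                      stringsAsFactors = FALSE)
  edges$weight <- weight_fun(edges$hrr)
  edges$sign <- ifelse(edges$r > 0, "positive", "negative")
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes,
                                                           tf = nodes %in% tf_genes))
  g
}

#' Simple topology report of a network
#'
#' Reports the descriptive graph statistics conventionally printed for a
#' co-expression network: node/edge counts, average neighbours `2E/N`,
#' density `2E/(N(N-1))`, mean local clustering coefficient (nodes with
#' degree < 2 contribute 0), diameter and characteristic path length over
#' connected pairs only, degree heterogeneity `sd(degree)/mean(degree)`
#' (population sd), degree centralization
#' `(N/(N-2)) * (max_degree/(N-1) - density)`, and the number of connected
#' components.
#'
#' @param g an igraph graph as from [build_network()].
#' @return object of class `"topology_report"` (a named list of numbers).
#' @export
topology_report <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) stopf("graph is empty")
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  density <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[!is.finite(loc)] <- 0
  dmean <- mean(deg)
  het <- if (dmean > 0) sqrt(mean((deg - dmean)^2)) / dmean else 0
  centr <- if (n > 2) (n / (n - 2)) * (max(deg) / (n - 1) - density) else 0
  if (n == 1 || e == 0) {
    diam <- 0; cpl <- 0
  } else {
    diam <- igraph::diameter(g, weights = NA)
    cpl <- igraph::mean_distance(g, weights = NA, unconnected = TRUE)
  }
  structure(list(
    n_nodes = n, n_edges = e,
    avg_neighbors = if (n > 0) 2 * e / n else 0,
    diameter = diam, characteristic_path_length = cpl,
    clustering_coefficient = mean(loc), density = density,
    heterogeneity = het, centralization = centr,
    connected_components = igraph::count_components(g)),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  lbl <- c(n_nodes = "Number of nodes", n_edges = "Number of edges",
           avg_neighbors = "Avg. number of neighbors",
           diameter = "Network diameter",
           characteristic_path_length = "Characteristic path length",
           clustering_coefficient = "Clustering coefficient",
           density = "Network density", heterogeneity = "Network heterogeneity",
           centralization = "Network centralization",
           connected_components = "Connected components")
  for (k in names(lbl))
    cat(sprintf("%-28s %s\n", lbl[[k]], format(x[[k]], digits = 4)))
  invisible(x)
}

#' Write a network in SIF format
#'
#' One line per edge: `geneA co-expr geneB` (Cytoscape-compatible).
#'
#' @param g igraph graph.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  writeLines(if (nrow(el)) paste(el[, 1], "co-expr", el[, 2]) else character(0), path)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' Keeps the `r`, `hrr`, `weight`, `sign` edge attributes and the `tf` vertex
#' flag (Cytoscape-compatible).
#'
#' @param g igraph graph.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
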