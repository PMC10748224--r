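#' Fit an HRR gene co-expression network model
#'
#' End-to-end estimator for staged bulk RNA-seq: filters expressed genes,
#' screens DEG-based candidates, computes the Pearson correlation matrix over
#' replicate-level samples, transforms it to highest reciprocal ranks, builds
#' the thresholded network, clusters it with MCL, drops meaningless clusters
#' using hypergeometric enrichment verdicts, merges similar clusters into
#' stage-associated modules, ranks intramodular connectivity to call hub and
#' key genes, and extracts the key-gene/TF subnetwork.
#'
#' @param es an [expression_set()].
#' @param deg optional DEG table ([read_deg_table()] layout); if `NULL`, all
#'   expressed genes are candidates.
#' @param annotation optional annotation map ([read_gmt()] layout); if
#'   `NULL`, the enrichment filter only applies the size rule.
#' @param tf optional TF label table ([read_tf_labels()] layout).
#' @param extra_genes curated genes force-added to the candidate set.
#' @param fpkm_min expressed-gene threshold (default 2).
#' @param stage_level_filter test stage means in the expression filter
#'   (default `TRUE`).
#' @param fdr_max,lfc_min DEG screen cutoffs (defaults 0.05 and 1).
#' @param r_min absolute-correlation cutoff for edges (default 0.8).
#' @param hrr_max HRR cutoff (default 30).
#' @param inflation MCL inflation (default 3).
#' @param mcl_weights edge weighting for the clustering step: `"uniform"`
#'   (default; one constant weight per network, the constant-per-cutoff
#'   convention) or `"hrr"` (cluster on the 1/HRR edge weights).
#' @param merge_r eigenprofile-correlation threshold for module merging
#'   (default 0.9).
#' @param top_n hub list size per module (default 10).
#' @param enrich_fdr,min_term_genes enrichment significance rule (defaults
#'   0.05 and 2).
#' @param drop_rule cluster-removal rule, see [drop_meaningless()].
#' @param connectivity connectivity mode, see [intramodular_connectivity()].
#' @param stage_level_cor correlate stage means instead of samples
#'   (default `FALSE`).
#' @return object of class `"hrr_gcn"` with components `expression`
#'   (filtered), `candidates`, `corr`, `hrr`, `graph`, `topology`,
#'   `clusters_raw`, `enrichment`, `clusters`, `modules`, `hubs`,
#'   `key_genes`, `tf_network`, `counts` (the stage-by-stage funnel) and
#'   `params`.
#' @seealso [generate_gcn_dataset()] for synthetic benchmark input;
#'   [run_gcn_pipeline()] for the config-file driven variant that writes all
#'   artifacts.
#' @export
hrr_gcn <- function(es, deg = NULL, annotation = NULL, tf = NULL,
                    extra_genes = character(), fpkm_min = 2,
                    stage_level_filter = TRUE, fdr_max = 0.05, lfc_min = 1,
                    r_min = 0.8, hrr_max = 30, inflation = 3,
                    mcl_weights = c("uniform", "hrr"), merge_r = 0.9,
                    top_n = 10, enrich_fdr = 0.05, min_term_genes = 2,
                    drop_rule = c("or", "and"),
                    connectivity = c("weighted", "degree"),
                    stage_level_cor = FALSE) {
  stopifnot(inherits(es, "expr_set"))
  drop_rule <- match.arg(drop_rule)
  connectivity <- match.arg(connectivity)
  mcl_weights <- match.arg(mcl_weights)
  cl <- match.call()
  params <- list(fpkm_min = fpkm_min, stage_level_filter = stage_level_filter,
                 fdr_max = fdr_max, lfc_min = lfc_min, r_min = r_min,
                 hrr_max = hrr_max, inflation = inflation,
                 mcl_weights = mcl_weights, merge_r = merge_r,
                 top_n = top_n, enrich_fdr = enrich_fdr,
                 min_term_genes = min_term_genes, drop_rule = drop_rule,
                 connectivity = connectivity, stage_level_cor = stage_level_cor)

  expressed <- filter_expressed(es, threshold = fpkm_min,
                                stage_level = stage_level_filter)
  candidates <- if (is.null(deg)) rownames(expressed$values)
                else intersect(select_candidates(deg, fdr_max, lfc_min, extra_genes),
                               rownames(expressed$values))
  tf_genes <- if (!is.null(tf)) unique(tf$gene) else character(0)
  if (length(candidates) < 3) {
    warnf("fewer than 3 candidate genes; network is empty")
    corr <- NULL; hrr <- NULL
    graph <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    corr <- pearson_matrix(expressed, genes = candidates,
                           stage_level = stage_level_cor)
    hrr <- hrr_transform(corr)
    graph <- build_network(corr, hrr, r_min = r_min, hrr_max = hrr_max,
                           tf_genes = tf_genes)
  }
  if (igraph::vcount(graph) == 0) {
    topo <- NULL; clusters_raw <- NULL
  } else {
    topo <- topology_report(graph)
    clusters_raw <- mcl(graph, inflation = inflation,
                        edge_weights = if (mcl_weights == "uniform") "uniform"
                                       else "attribute")
  }

  prof <- stage_means(expressed)
  enrichment <- NULL
  clusters <- clusters_raw
  if (!is.null(clusters_raw)) {
    if (!is.null(annotation)) {
      enrichment <- enrich_clusters(clusters_raw, annotation,
                                    universe = candidates,
                                    min_genes = min_term_genes,
                                    fdr_cut = enrich_fdr)
      verdicts <- enrichment$verdicts
    } else {
      verdicts <- setNames(rep(TRUE, length(clusters_raw$clusters)),
                           names(clusters_raw$clusters))
    }
    clusters <- drop_meaningless(clusters_raw, verdicts, rule = drop_rule)
  }

  modules <- NULL; hubs <- NULL; key_genes <- character(0); tfnet <- NULL
  if (!is.null(clusters) && length(clusters$clusters) > 0) {
    modules <- merge_clusters(clusters, prof$z, merge_r = merge_r)
    hubs <- module_hubs(graph, modules, es = expressed, top_n = top_n,
                        mode = connectivity)
    key_genes <- vapply(hubs, `[[`, character(1), "key_gene")
    if (length(tf_genes))
      tfnet <- tf_subnetwork(corr, key_genes, tf_genes, r_min = r_min)
  }

  counts <- list(
    genes_total = nrow(es$values),
    genes_expressed = nrow(expressed$values),
    candidates = length(candidates),
    network_nodes = igraph::vcount(graph),
    network_edges = igraph::ecount(graph),
    clusters_raw = if (!is.null(clusters_raw)) length(clusters_raw$clusters) else 0L,
    clusters_kept = if (!is.null(clusters)) length(clusters$clusters) else 0L,
    clustered_genes = if (!is.null(clusters)) length(clusters$assignment) else 0L,
    modules = if (!is.null(modules)) length(modules$modules) else 0L,
    key_genes = length(key_genes),
    tf_edges = if (!is.null(tfnet)) nrow(tfnet) else 0L,
    tfs_coexpressed = if (!is.null(tfnet)) attr(tfnet, "n_tfs") else 0L)

  structure(list(call = cl, params = params, expression = expressed,
                 stage_profiles = prof, candidates = candidates, corr = corr,
                 hrr = hrr, graph = graph, topology = topo,
                 clusters_raw = clusters_raw, enrichment = enrichment,
                 clusters = clusters, modules = modules, hubs = hubs,
                 key_genes = key_genes, tf_network = tfnet, counts = counts),
            class = "hrr_gcn")
}

#' @export
print.hrr_gcn <- function(x, ...) {
  cat("HRR gene co-expression network\n")
  cat(sprintf("  %d genes -> %d expressed -> %d candidates\n",
              x$counts$genes_total, x$counts$genes_expressed, x$counts$candidates))
  cat(sprintf("  network: %d nodes, %d edges (|r| >= %g, HRR <= %d)\n",
              x$counts$network_nodes, x$counts$network_edges,
              x$params$r_min, x$params$hrr_max))
  cat(sprintf("  clusters: %d (MCL, I = %g), %d kept after filtering\n",
              x$counts$clusters_raw, x$params$inflation, x$counts$clusters_kept))
  cat(sprintf("  modules: %d, key genes: %d, co-expressed TFs: %d\n",
              x$counts$modules, x$counts$key_genes, x$counts$tfs_coexpressed))
  invisible(x)
}

#' @export
summary.hrr_gcn <- function(object, ...) {
  structure(list(fit = object), class = "summary.hrr_gcn")
}

#' @export
print.summary.hrr_gcn <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$topology)) { cat("\nTopology:\n"); print(x$fit$topology) }
  if (!is.null(x$fit$modules)) {
    cat("\n")
    print(x$fit$modules)
    cat("\nKey genes:\n")
    for (id in names(x$fit$hubs))
      cat(sprintf("  module %s: %s\n", id, x$fit$hubs[[id]]$key_gene))
  }
  invisible(x)
}

#' @export
coef.hrr_gcn <- function(object, ...) {
  if (is.null(object$modules)) return(numeric(0))
  out <- lapply(names(object$hubs), function(id) {
    r <- object$hubs[[id]]$ranking
    setNames(r$score, r$gene)
  })
  names(out) <- names(object$hubs)
  out
}

#' Plot module stage profiles
#'
#' Draws each module's mean z-scored expression profile across stages.
#'
#' @param x an `"hrr_gcn"` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hrr_gcn <- function(x, ...) {
  if (is.null(x$modules) || length(x$modules$modules) == 0)
    stopf("no modules to plot")
  prof <- t(vapply(x$modules$modules, `[[`,
                   numeric(length(x$expression$stage_order)), "profile"))
  matplot(t(prof), type = "b", lty = 1, pch = 16, xaxt = "n",
          xlab = "stage", ylab = "mean z-scored expression", ...)
  axis(1, at = seq_along(x$expression$stage_order),
       labels = x$expression$stage_order)
  legend("topright", legend = paste("module", seq_len(nrow(prof))),
         col = seq_len(nrow(prof)), lty = 1, pch = 16, cex = 0.7)
  invisible(x)
}
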