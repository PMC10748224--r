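#' Merge clusters with similar stage profiles into modules
#'
#' Each cluster is summarised by its eigenprofile (the mean of its member
#' genes' z-scored stage profiles).  Clusters are agglomerated by
#' average-linkage hierarchical clustering on `1 - Pearson r` between
#' eigenprofiles and the tree is cut at height `1 - merge_r`, so merged
#' clusters have eigenprofile correlation at least `merge_r`.  Module ids are
#' ordered by peak-stage index, then by decreasing size.
#'
#' @param cs an `"mcl_clusters"` object (typically after
#'   [drop_meaningless()]).
#' @param zprofiles gene x stage matrix of z-scored stage profiles, as from
#'   `stage_means()$z`; every clustered gene must be present.
#' @param merge_r eigenprofile-correlation threshold for merging
#'   (default 0.9).
#' @return object of class `"module_set"`: list with `modules` (per module:
#'   `module_id`, `clusters`, `genes`, `profile` (mean member z-profile),
#'   `peak_stage`) and `assignment` (named integer vector gene -> module).
#' @export
merge_clusters <- function(cs, zprofiles, merge_r = 0.9) {
  stopifnot(inherits(cs, "mcl_clusters"), merge_r > 0, merge_r <= 1)
  genes <- unlist(cs$clusters, use.names = FALSE)
  missing <- setdiff(genes, rownames(zprofiles))
  if (length(missing))
    stopf("no stage profile for gene(s): %s", paste(head(missing, 5), collapse = ", "))
  if (length(cs$clusters) == 0)
    return(structure(list(modules = list(),
                          assignment = setNames(integer(0), character(0))),
                     class = "module_set"))
  eig <- t(vapply(cs$clusters,
                  function(g) colMeans(zprofiles[g, , drop = FALSE]),
                  numeric(ncol(zprofiles))))
  if (nrow(eig) == 1) {
    grp <- setNames(1L, names(cs$clusters))
  } else {
    rr <- suppressWarnings(cor(t(eig)))
    rr[!is.finite(rr)] <- 0; diag(rr) <- 1
    hc <- hclust(as.dist(1 - rr), method = "average")
    grp <- cutree(hc, h = 1 - merge_r)
  }
  mods <- lapply(split(names(cs$clusters), grp), function(cl_ids) {
    g <- sort(unlist(cs$clusters[cl_ids], use.names = FALSE))
    prof <- colMeans(zprofiles[g, , drop = FALSE])
    list(clusters = cl_ids, genes = g, profile = prof,
         peak_stage = colnames(zprofiles)[which.max(prof)],
         peak_index = which.max(prof))
  })
  ord <- order(vapply(mods, `[[`, integer(1), "peak_index"),
               -vapply(mods, function(m) length(m$genes), integer(1)))
  mods <- mods[ord]
  for (i in seq_along(mods)) mods[[i]]$module_id <- i
  mods <- lapply(mods, function(m) m[c("module_id", "clusters", "genes",
                                       "profile", "peak_stage")])
  assignment <- setNames(rep(seq_along(mods),
                             vapply(mods, function(m) length(m$genes), integer(1))),
                         unlist(lapply(mods, `[[`, "genes")))
  structure(list(modules = mods, assignment = assignment), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("Module set: %d modules over %d genes\n",
              length(x$modules), length(x$assignment)))
  for (m in x$modules)
    cat(sprintf("  module %d: %d genes (clusters %s), peak at %s\n",
                m$module_id, length(m$genes), paste(m$clusters, collapse = ","),
                m$peak_stage))
  invisible(x)
}

#' Intramodular connectivity
#'
#' Per-gene connectivity within a module: the sum of weights (default
#' `1/HRR`) of network edges whose both endpoints lie in the module
#' (`mode = "weighted"`), or the raw within-module degree
#' (`mode = "degree"`).  Genes with no within-module edge score 0.
#'
#' @param g igraph graph from [build_network()].
#' @param genes the module's gene ids (must be network nodes or absent from
#'   the graph entirely, in which case they score 0).
#' @param mode `"weighted"` (default) or `"degree"`.
#' @return named numeric vector of scores, one per gene in `genes`.
#' @export
intramodular_connectivity <- function(g, genes, mode = c("weighted", "degree")) {
  mode <- match.arg(mode)
  present <- intersect(genes, igraph::V(g)$name)
  scores <- setNames(numeric(length(genes)), genes)
  if (length(present) >= 2) {
    sub <- igraph::induced_subgraph(g, present)
    s <- if (mode == "weighted")
      igraph::strength(sub, weights = igraph::E(sub)$weight)
    else igraph::degree(sub)
    scores[names(s)] <- s
  }
  scores
}

#' Hub and key genes of a module
#'
#' Ranks genes by connectivity score (descending); ties are broken by higher
#' mean expression, then by gene-id order.  The hub list is the top
#' `min(top_n, module size)` genes; the key gene is the single top-ranked
#' gene.  Ties at rank 1 are recorded in `ties`.
#'
#' @param scores named numeric vector from [intramodular_connectivity()].
#' @param mean_expr optional named numeric vector of mean expression across
#'   all samples, used for tie-breaking.
#' @param top_n hub list size (default 10).
#' @return list with `ranking` (data.frame gene/score), `hub_genes`,
#'   `key_gene`, `ties` (genes tied with the key gene, if any).
#' @export
call_hubs <- function(scores, mean_expr = NULL, top_n = 10) {
  if (length(scores) == 0) stopf("empty module")
  me <- if (is.null(mean_expr)) setNames(numeric(length(scores)), names(scores))
        else mean_expr[names(scores)]
  me[is.na(me)] <- 0
  ord <- order(-scores, -me, names(scores))
  ranking <- data.frame(gene = names(scores)[ord], score = unname(scores[ord]),
                        stringsAsFactors = FALSE)
  top <- max(scores)
  tied <- names(scores)[scores == top]
  list(ranking = ranking,
       hub_genes = ranking$gene[seq_len(min(top_n, nrow(ranking)))],
       key_gene = ranking$gene[1],
       ties = if (length(tied) > 1) sort(tied) else character(0))
}

#' Hub report for every module
#'
#' @param g igraph graph from [build_network()].
#' @param ms a [merge_clusters()] result.
#' @param es the [expression_set()] (for mean-expression tie-breaking);
#'   optional.
#' @param top_n hub list size per module (default 10).
#' @param mode connectivity mode, see [intramodular_connectivity()].
#' @return named list (by module id) of [call_hubs()] results.
#' @export
module_hubs <- function(g, ms, es = NULL, top_n = 10,
                        mode = c("weighted", "degree")) {
  stopifnot(inherits(ms, "module_set"))
  mode <- match.arg(mode)
  me <- if (!is.null(es)) rowMeans(es$values) else NULL
  out <- lapply(ms$modules, function(m) {
    call_hubs(intramodular_connectivity(g, m$genes, mode = mode),
              mean_expr = me, top_n = top_n)
  })
  names(out) <- vapply(ms$modules, `[[`, integer(1), "module_id")
  out
}

#' Transcription-factor subnetwork around key genes
#'
#' Connects each key gene to every transcription factor whose absolute
#' Pearson correlation with it reaches `r_min` (inclusive); the correlation
#' matrix is used directly, independently of the HRR network.  TFs that are
#' themselves key genes are not used as partners, so every edge touches
#' exactly one key gene and one TF.
#'
#' @param cm a [pearson_matrix()] result covering the key genes and TFs.
#' @param key_genes character vector of key genes.
#' @param tf_genes character vector of TF-flagged genes.
#' @param r_min absolute correlation threshold (default 0.8).
#' @return object of class `"tf_subnetwork"`: data.frame with columns
#'   `key_gene`, `tf`, `r`, `sign`; attribute `n_tfs` counts distinct TFs.
#' @export
tf_subnetwork <- function(cm, key_genes, tf_genes, r_min = 0.8) {
  stopifnot(inherits(cm, "cor_mat"))
  r <- cm$r
  key_genes <- intersect(key_genes, rownames(r))
  partners <- setdiff(intersect(tf_genes, rownames(r)), key_genes)
  rows <- list()
  for (k in key_genes) for (t in partners) {
    if (abs(r[k, t]) >= r_min)
      rows[[length(rows) + 1L]] <- data.frame(
        key_gene = k, tf = t, r = r[k, t],
        sign = if (r[k, t] > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(key_gene = character(), tf = character(),
                         r = numeric(), sign = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("tf_subnetwork", "data.frame"),
            n_tfs = length(unique(out$tf)))
}

#' @export
print.tf_subnetwork <- function(x, ...) {
  cat(sprintf("TF subnetwork: %d edges, %d distinct TFs, %d key genes\n",
              nrow(x), attr(x, "n_tfs"), length(unique(x$key_gene))))
  if (nrow(x)) print.data.frame(head(x, 10))
  invisible(x)
}
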