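#' Expression set: gene x sample matrix with stage metadata
#'
#' Lightweight container for an FPKM-like nonnegative expression matrix whose
#' samples belong to ordered developmental stages.  Sample ids follow the
#' `<stage>_<replicate>` convention; stages can also be given explicitly.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must be
#'   nonnegative with unique, non-empty row and column names.
#' @param stages character vector mapping each column to a stage.  Defaults to
#'   the part of each column name before the last underscore.
#' @param stage_order optional character vector fixing the stage order;
#'   defaults to order of first appearance.
#' @return an object of class `"expr_set"`: a list with elements `values`
#'   (the matrix), `stages` (per-sample stage labels) and `stage_order`.
#' @examples
#' m <- matrix(rpois(12, 10), 2, 6,
#'             dimnames = list(c("g1", "g2"),
#'                             paste0(rep(c("VS", "FI"), each = 3), "_", 1:3)))
#' es <- expression_set(m)
#' es$stage_order
#' @export
expression_set <- function(values, stages = NULL, stage_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) || is.null(colnames(values)))
    stopf("`values` must have gene row names and sample column names")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids")
  if (any(!is.finite(values)) || any(values < 0))
    stopf("expression values must be finite and nonnegative")
  if (is.null(stages)) stages <- sub("_[^_]*$", "", colnames(values))
  if (length(stages) != ncol(values))
    stopf("`stages` must have one entry per sample")
  if (is.null(stage_order)) stage_order <- unique(stages)
  if (!all(stages %in% stage_order))
    stopf("samples map to stages outside `stage_order`: %s",
          paste(setdiff(stages, stage_order), collapse = ", "))
  structure(list(values = values, stages = as.character(stages),
                 stage_order = as.character(stage_order)),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("Expression set: %d genes x %d samples, %d stages (%s)\n",
              nrow(x$values), ncol(x$values), length(x$stage_order),
              paste(x$stage_order, collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

# subset genes, keeping metadata
subset_genes <- function(es, genes) {
  expression_set(es$values[genes, , drop = FALSE], es$stages, es$stage_order)
}

#' Read an expression matrix TSV
#'
#' Expects a header row whose first column holds gene ids and whose remaining
#' columns are `<stage>_<replicate>` sample ids.
#'
#' @param path file path.
#' @param stage_order optional explicit stage order.
#' @return an [expression_set()].
#' @export
read_expression <- function(path, stage_order = NULL) {
  df <- tryCatch(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stopf("%s: cannot parse (%s)", path, conditionMessage(e)))
  if (ncol(df) < 2) stopf("%s: expected gene id column plus sample columns", path)
  bad <- which(!vapply(df[-1], is.numeric, logical(1)))
  if (length(bad))
    stopf("%s: non-numeric expression column(s): %s", path,
          paste(names(df)[-1][bad], collapse = ", "))
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  expression_set(m, stage_order = stage_order)
}

#' Keep expressed genes
#'
#' Retains genes whose expression reaches `threshold` in at least one stage
#' (default, stage-level means: one pooled transcriptome per stage) or in at
#' least one individual sample (`stage_level = FALSE`).
#'
#' @param es an [expression_set()].
#' @param threshold minimum expression (FPKM units), default 2.
#' @param stage_level if `TRUE` (default) test stage means, else raw samples.
#' @return the filtered [expression_set()], gene order preserved.
#' @export
filter_expressed <- function(es, threshold = 2, stage_level = TRUE) {
  stopifnot(inherits(es, "expr_set"), threshold >= 0)
  if (stage_level) {
    sm <- stage_means(es)$mean
    keep <- apply(sm >= threshold, 1, any)
  } else {
    keep <- apply(es$values >= threshold, 1, any)
  }
  if (!any(keep)) warnf("no genes pass the expression filter (threshold %g)", threshold)
  subset_genes(es, rownames(es$values)[keep])
}

#' Per-stage mean and z-scored expression profiles
#'
#' @param es an [expression_set()].
#' @return list with `mean` (gene x stage matrix of replicate means) and `z`
#'   (stage profiles centred and scaled across stages using the population
#'   standard deviation; constant genes get an all-zero z-profile).
#' @export
stage_means <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  if (!all(es$stage_order %in% es$stages))
    stopf("stage(s) without samples: %s",
          paste(setdiff(es$stage_order, es$stages), collapse = ", "))
  m <- vapply(es$stage_order,
              function(s) rowMeans(es$values[, es$stages == s, drop = FALSE]),
              numeric(nrow(es$values)))
  m <- matrix(m, nrow = nrow(es$values), ncol = length(es$stage_order))
  dimnames(m) <- list(rownames(es$values), es$stage_order)
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))  # population sd across stages
  z <- (m - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  list(mean = m, z = z)
}

#' Read a differential-expression table
#'
#' Tab-separated with columns `gene`, `comparison`, `log2fc`, `fdr`.
#'
#' @param path file path.
#' @return data.frame with those four columns.
#' @export
read_deg_table <- function(path) {
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("%s: cannot parse (%s)", path, conditionMessage(e)))
  need <- c("gene", "comparison", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stopf("%s: missing column(s): %s", path, paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!is.finite(df$fdr) | df$fdr < 0 | df$fdr > 1)
  if (length(bad)) stopf("%s: line %d: fdr outside [0, 1]", path, bad[1] + 1L)
  df[need]
}

#' Select candidate genes from a DEG table
#'
#' A gene is selected if, in any comparison, its FDR is at or below `fdr_max`
#' and its absolute log2 fold change is at or above `lfc_min` (both cutoffs
#' inclusive).  Curated genes in `extra` are added regardless.
#'
#' @param deg data.frame as from [read_deg_table()].
#' @param fdr_max FDR cutoff, default 0.05.
#' @param lfc_min absolute log2 fold-change cutoff, default 1.
#' @param extra character vector of genes to force-include.
#' @return character vector of candidate gene ids (first-appearance order).
#' @export
select_candidates <- function(deg, fdr_max = 0.05, lfc_min = 1, extra = character()) {
  stopifnot(fdr_max > 0, lfc_min > 0)
  hit <- deg$fdr <= fdr_max & abs(deg$log2fc) >= lfc_min
  unique(c(deg$gene[hit], extra))
}

#' Read a GMT annotation file
#'
#' Tab-separated lines: term id, description, then member gene ids.
#'
#' @param path file path.
#' @return list with `terms` (named list of gene-id vectors) and
#'   `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("%s: line %d: expected term, description, >=1 gene", path, i)
    if (f[1] %in% names(terms)) stopf("%s: line %d: duplicate term '%s'", path, i, f[1])
    terms[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  list(terms = terms, descriptions = desc)
}

#' Read transcription-factor labels
#'
#' Tab-separated with columns `gene`, `family`.
#'
#' @param path file path.
#' @return data.frame with columns `gene` and `family`.
#' @export
read_tf_labels <- function(path) {
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("%s: cannot parse (%s)", path, conditionMessage(e)))
  if (!all(c("gene", "family") %in% names(df)))
    stopf("%s: expected columns gene, family", path)
  df[c("gene", "family")]
}
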