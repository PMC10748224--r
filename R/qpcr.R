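#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-sample fold changes for a target gene relative to a reference
#' gene, normalised to a calibrator sample: dCt = Ct_target - Ct_ref,
#' ddCt = dCt_sample - dCt_calibrator, fold change = 2^-ddCt.  The calibrator
#' itself always has fold change 1.
#'
#' @param ct data.frame with columns `sample`, `ct_target`, `ct_ref`.
#' @param calibrator sample id used as calibrator; must occur in `ct$sample`.
#' @return named numeric vector of fold changes, one per sample.
#' @examples
#' ct <- data.frame(sample = c("VS", "FI"), ct_target = c(24, 23),
#'                  ct_ref = c(20, 20))
#' ddct_fold_change(ct, calibrator = "VS")  # VS = 1, FI = 2
#' @export
ddct_fold_change <- function(ct, calibrator) {
  need <- c("sample", "ct_target", "ct_ref")
  if (!all(need %in% names(ct)))
    stopf("`ct` must have columns %s", paste(need, collapse = ", "))
  if (!all(is.finite(ct$ct_target)) || !all(is.finite(ct$ct_ref)))
    stopf("Ct values must be finite")
  if (!calibrator %in% ct$sample)
    stopf("calibrator sample '%s' not present", calibrator)
  dct <- ct$ct_target - ct$ct_ref
  ddct <- dct - dct[match(calibrator, ct$sample)]
  structure(2^(-ddct), names = as.character(ct$sample))
}

#' Correlate qPCR fold changes with expression profiles
#'
#' Per gene, the Pearson correlation between stage-mean expression and
#' stage-mean qPCR fold change, used to validate RNA-seq quantification
#' against an independent assay.
#'
#' @param fold_changes numeric matrix, genes x samples (or stages); column
#'   names must be sample ids of `es` or stage names.
#' @param es an [expression_set()].
#' @return named numeric vector of per-gene Pearson r; genes whose series has
#'   zero variance get `NA`.
#' @export
validate_against_qpcr <- function(fold_changes, es) {
  stopifnot(is.matrix(fold_changes), inherits(es, "expr_set"))
  fpkm <- stage_means(es)$mean
  if (all(colnames(fold_changes) %in% colnames(es$values))) {
    # per-sample fold changes: average replicates to stage level first
    st <- es$stages[match(colnames(fold_changes), colnames(es$values))]
    fc <- vapply(es$stage_order,
                 function(s) rowMeans(fold_changes[, st == s, drop = FALSE]),
                 numeric(nrow(fold_changes)))
  } else if (all(colnames(fold_changes) %in% es$stage_order)) {
    fc <- fold_changes[, es$stage_order, drop = FALSE]
  } else {
    stopf("fold-change columns match neither sample ids nor stage names")
  }
  genes <- intersect(rownames(fold_changes), rownames(fpkm))
  if (length(es$stage_order) < 3) stopf("need >=3 stages in common")
  out <- vapply(genes, function(g) {
    x <- fpkm[g, ]; y <- fc[g, ]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  out
}
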