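#' Stage design for a staged transcriptome experiment
#'
#' @param stages ordered stage labels; default the seven flower-development
#'   stages from vegetative growth (VS) through floral initiation (FI),
#'   morphogenesis (FM), three blooming stages (BS-1..BS-3) to senescence (FS).
#' @param replicates biological replicates per stage (default 3).
#' @return object of class `"stage_design"`.
#' @export
stage_design <- function(stages = c("VS", "FI", "FM", "BS-1", "BS-2", "BS-3", "FS"),
                         replicates = 3) {
  if (length(stages) < 2) stopf("need >=2 stages")
  if (anyDuplicated(stages)) stopf("duplicate stage labels")
  if (!is.numeric(replicates) || replicates < 2)
    stopf("need >=2 replicates per stage (correlation across samples is undefined otherwise)")
  structure(list(stages = as.character(stages), replicates = as.integer(replicates)),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat(sprintf("Stage design: %d stages x %d replicates (%s)\n",
              length(x$stages), x$replicates, paste(x$stages, collapse = ", ")))
  invisible(x)
}

# Unit shape templates on a 7-point stage grid: narrow Gaussian bumps (one
# per stage, slight shoulders for a gradual rise and fall), an early-phase
# plateau, a blooming plateau, and a sharply induced monotone rise.  Any two
# distinct templates have Pearson correlation <= 0.5 (checked in the test
# suite), so modules planted on different archetypes stay separable, and
# every template has an adjacent-stage step of at least 0.8 so planted genes
# clear the DEG fold-change screen at the default amplitude.  Interpolated
# for designs with a different stage count.
.shape_templates <- function() {
  bump <- function(centre, w = 0.45) exp(-((1:7 - centre) / w)^2)
  rbind(
    peak_VS    = bump(1),
    peak_FI    = bump(2),
    peak_FM    = bump(3),
    peak_BS1   = bump(4),
    peak_BS2   = bump(5),
    peak_BS3   = bump(6),
    spike_FS   = bump(7),
    high_early = c(1, 1, 1, 0, 0, 0, 0),
    high_bloom = c(0, 0, 0, 1, 1, 1, 0),
    rise_to_FS = c(0, 0.80, 0.86, 0.90, 0.94, 0.97, 1)
  )
}

#' Stage-peaked mean-profile archetypes
#'
#' Returns log-scale mean expression profiles for up to ten archetypes that
#' mimic characteristic stage-resolved patterns (single-stage peaks, an
#' early-phase plateau, a blooming plateau, a monotone rise to senescence).
#' Distinct archetypes are designed to have pairwise Pearson correlation at
#' most 0.5.
#'
#' @param design a [stage_design()].
#' @param archetype_count number of archetypes to return (<= 10).
#' @param base baseline natural-log expression added to every profile.
#' @param amplitude natural-log amplitude of the stage signal.  The default
#'   (1.2, about a 3.3-fold swing) makes the largest adjacent-stage change of
#'   every archetype comfortably exceed one log2 unit, so planted genes pass
#'   the usual DEG screen, while keeping the dynamic range moderate enough
#'   that FPKM-scale correlations are informative across all stages.
#' @return matrix, `archetype_count` rows x one column per stage.
#' @export
make_profiles <- function(design, archetype_count = 10, base = log(5), amplitude = 1.2) {
  stopifnot(inherits(design, "stage_design"))
  tpl <- .shape_templates()
  if (archetype_count > nrow(tpl))
    stopf("archetype_count (%d) exceeds the %d available templates",
          archetype_count, nrow(tpl))
  if (archetype_count < 1) stopf("archetype_count must be >= 1")
  ns <- length(design$stages)
  shapes <- t(apply(tpl[seq_len(archetype_count), , drop = FALSE], 1, function(v) {
    if (ns == ncol(tpl)) v
    else stats::approx(seq(0, 1, length.out = ncol(tpl)), v,
                       xout = seq(0, 1, length.out = ns))$y
  }))
  out <- base + amplitude * shapes
  dimnames(out) <- list(rownames(tpl)[seq_len(archetype_count)], design$stages)
  out
}

#' Generate a synthetic staged transcriptome with planted modules
#'
#' Simulates an FPKM-like expression matrix in which groups of genes share a
#' stage-peaked archetype profile (multiplicative log-normal noise), plus the
#' companion inputs a co-expression analysis consumes: a per-comparison DEG
#' table whose planted-module genes pass the FDR/log2FC screen, a GMT-style
#' annotation map whose terms are enriched inside planted modules, and
#' transcription-factor family labels for a subset of genes.  One member of
#' each module is planted as its hub by halving its noise, so it adheres most
#' tightly to the module profile and emerges with the highest connectivity.
#'
#' @param design a [stage_design()].
#' @param n_modules planted modules (default 10, one archetype each).
#' @param genes_per_module members per module (default 20, minimum 3).
#' @param n_background unstructured background genes (default 100).
#' @param noise_sd standard deviation of the log-scale Gaussian noise
#'   (default 0.2); the planted hub uses `hub_noise_factor * noise_sd`.
#' @param hub_noise_factor noise shrinkage for the hub gene (default 0.5).
#' @param offset_sd sd of the per-gene baseline offset (default 0.3).
#' @param tf_per_module members per module labelled as TFs (default 3).
#' @param terms_per_module annotation terms planted per module (default 2);
#'   each covers 90\% of members and about 2\% of non-members.
#' @param seed RNG seed; same seed reproduces the dataset exactly.
#' @param module_genes optional list of character vectors giving explicit
#'   (disjoint) module memberships; lengths must match `n_modules`.
#' @return object of class `"gcn_dataset"`: list with `expression` (an
#'   [expression_set()]), `deg`, `annotation`, `tf` and `truth` (planted
#'   modules, hubs, profiles, background genes, noise_sd, seed).
#' @export
generate_gcn_dataset <- function(design = stage_design(), n_modules = 10,
                                 genes_per_module = 20, n_background = 100,
                                 noise_sd = 0.2, hub_noise_factor = 0.5,
                                 offset_sd = 0.3, tf_per_module = 3,
                                 terms_per_module = 2, seed = 1,
                                 module_genes = NULL) {
  stopifnot(inherits(design, "stage_design"))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (n_modules < 0 || (n_modules > 0 && genes_per_module < 3))
    stopf("modules need >= 3 genes each")
  if (n_modules + n_background < 1) stopf("need at least one gene")

  profiles <- if (n_modules > 0) make_profiles(design, n_modules) else NULL
  if (is.null(module_genes)) {
    n_mod_genes <- n_modules * genes_per_module
    gene_ids <- sprintf("G%04d", seq_len(n_mod_genes + n_background))
    module_genes <- if (n_modules > 0)
      split(gene_ids[seq_len(n_mod_genes)],
            rep(seq_len(n_modules), each = genes_per_module))
    else list()
  } else {
    if (length(module_genes) != n_modules)
      stopf("module_genes must have one entry per module")
    if (anyDuplicated(unlist(module_genes)))
      stopf("planted module memberships overlap")
    gene_ids <- c(unlist(module_genes, use.names = FALSE),
                  sprintf("BG%04d", seq_len(n_background)))
  }
  n_genes <- length(gene_ids)
  background <- setdiff(gene_ids, unlist(module_genes))

  samples <- paste0(rep(design$stages, each = design$replicates), "_",
                    rep(seq_len(design$replicates), length(design$stages)))
  stage_of <- rep(design$stages, each = design$replicates)

  with_seed(seed, {
    logx <- matrix(0, n_genes, length(samples), dimnames = list(gene_ids, samples))
    truth_modules <- vector("list", n_modules)
    for (m in seq_len(n_modules)) {
      members <- module_genes[[m]]
      hub <- sample(members, 1)
      mu <- profiles[m, ]
      for (g in members) {
        off <- rnorm(1, 0, offset_sd)
        sdg <- noise_sd * if (g == hub) hub_noise_factor else 1
        logx[g, ] <- mu[stage_of] + off + rnorm(length(samples), 0, sdg)
      }
      tfs <- members[seq_len(min(tf_per_module, length(members)))]
      truth_modules[[m]] <- list(
        module_id = m, archetype = rownames(profiles)[m], genes = members,
        hub_gene = hub, tf_members = tfs,
        term_ids = sprintf("T%02d_%d", m, seq_len(terms_per_module)),
        mean_profile = unname(mu))
    }
    for (g in background) {
      mu <- log(5) + rnorm(length(design$stages), 0, 0.5)
      logx[g, ] <- mu[match(stage_of, design$stages)] +
        rnorm(1, 0, offset_sd) + rnorm(length(samples), 0, max(noise_sd, 1e-8))
    }
    es <- expression_set(exp(logx), stages = stage_of, stage_order = design$stages)

    # DEG table: true stage-mean log2 ratios; synthetic FDR column built so
    # planted-module genes pass the screen and background genes do not
    sm <- stage_means(es)$mean
    comparisons <- paste0(design$stages[-length(design$stages)], "/", design$stages[-1])
    in_module <- gene_ids %in% unlist(module_genes)
    deg <- do.call(rbind, lapply(seq_along(comparisons), function(i) {
      lfc <- log2(pmax(sm[, i + 1], 1e-6) / pmax(sm[, i], 1e-6))
      data.frame(gene = gene_ids, comparison = comparisons[i],
                 log2fc = unname(lfc),
                 fdr = ifelse(in_module, runif(n_genes, 0, 0.05),
                              runif(n_genes, 0.1, 1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(deg) <- NULL

    # annotation map: planted terms cover 90% of members, ~2% of non-members,
    # plus generic terms over random genes as enrichment negatives
    terms <- list(); desc <- character()
    for (m in seq_len(n_modules)) {
      members <- module_genes[[m]]
      others <- setdiff(gene_ids, members)
      for (tid in truth_modules[[m]]$term_ids) {
        inside <- sample(members, max(2, ceiling(0.9 * length(members))))
        outside <- sample(others, max(0, round(0.02 * length(others))))
        terms[[tid]] <- sort(unique(c(inside, outside)))
        desc[tid] <- sprintf("planted term for module %d", m)
      }
    }
    for (j in 1:3) {
      tid <- sprintf("T_bg_%d", j)
      terms[[tid]] <- sort(sample(gene_ids, max(2, round(0.1 * n_genes))))
      desc[tid] <- "generic background term"
    }

    tf_rows <- do.call(rbind, lapply(truth_modules, function(tm)
      if (length(tm$tf_members))
        data.frame(gene = tm$tf_members,
                   family = sample(c("AP2/ERF", "bHLH", "CO-like", "GRAS",
                                     "MIKC", "SBP", "WRKY"),
                                   length(tm$tf_members), replace = TRUE),
                   stringsAsFactors = FALSE)))
    if (length(background) >= 1) {
      bg_tf <- sample(background, max(1, round(0.05 * length(background))))
      tf_rows <- rbind(tf_rows, data.frame(gene = bg_tf,
        family = sample(c("GATA", "TCP", "NF-Y", "bZIP"), length(bg_tf), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    rownames(tf_rows) <- NULL

    structure(list(
      expression = es, deg = deg,
      annotation = list(terms = terms, descriptions = desc),
      tf = tf_rows,
      truth = list(planted_modules = truth_modules, background_genes = background,
                   noise_sd = noise_sd, seed = seed,
                   stages = design$stages, replicates = design$replicates)),
      class = "gcn_dataset")
  })
}

#' @export
print.gcn_dataset <- function(x, ...) {
  cat(sprintf("Synthetic GCN dataset: %d genes (%d planted in %d modules, %d background)\n",
              nrow(x$expression$values),
              nrow(x$expression$values) - length(x$truth$background_genes),
              length(x$truth$planted_modules), length(x$truth$background_genes)))
  print(x$expression)
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `expression.tsv`, `deg.tsv`, `annotation.gmt`, `tf.tsv` and the
#' ground-truth `truth.json` into `dir`.
#'
#' @param ds a [generate_gcn_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_gcn_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "gcn_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "deg.tsv", "annotation.gmt",
                            "tf.tsv", "truth.json"))
  expr <- data.frame(gene = rownames(ds$expression$values),
                     ds$expression$values, check.names = FALSE)
  write.table(expr, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$deg, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(vapply(names(ds$annotation$terms), function(t)
    paste(c(t, ds$annotation$descriptions[[t]], ds$annotation$terms[[t]]),
          collapse = "\t"), character(1)), paths[3])
  write.table(ds$tf, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth, paths[5], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Re-read a ground-truth file written by [write_gcn_dataset()]
#'
#' @param path path to `truth.json`.
#' @return the truth list (planted modules, background genes, noise_sd, seed).
#' @export
read_gcn_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  tr$planted_modules <- lapply(tr$planted_modules, function(m) {
    m$mean_profile <- as.numeric(m$mean_profile)
    m$genes <- as.character(m$genes)
    m$tf_members <- as.character(m$tf_members)
    m$term_ids <- as.character(m$term_ids)
    m
  })
  tr$background_genes <- as.character(tr$background_genes)
  tr
}

#' Planted module assignment as a named vector
#'
#' @param truth a truth list from a [generate_gcn_dataset()] result or
#'   [read_gcn_truth()].
#' @return named integer vector, gene id -> planted module id (background
#'   genes are absent).
#' @export
truth_assignment <- function(truth) {
  out <- integer(0)
  for (m in truth$planted_modules)
    out[m$genes] <- m$module_id
  out
}
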