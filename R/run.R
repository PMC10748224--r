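#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_gcn_pipeline()], with every
#' threshold at its conventional printed default.  Fields: input paths
#' (`expression`, `deg`, `gmt`, `tf`, `extra_genes` — all but `expression`
#' optional), thresholds (`fpkm_min` 2, `fdr_max` 0.05, `lfc_min` 1, `r_min`
#' 0.8, `hrr_max` 30, `inflation` 3, `merge_r` 0.9, `top_n` 10, `enrich_fdr`
#' 0.05, `min_term_genes` 2, `drop_rule` "or", `connectivity` "weighted"),
#' `seed`, and `out_dir`.
#'
#' @param ... named overrides of the defaults; unknown keys are rejected.
#' @return named list of configuration values.
#' @export
gcn_config <- function(...) {
  cfg <- list(expression = NULL, deg = NULL, gmt = NULL, tf = NULL,
              extra_genes = NULL, fpkm_min = 2, fdr_max = 0.05, lfc_min = 1,
              r_min = 0.8, hrr_max = 30, inflation = 3,
              mcl_weights = "uniform", merge_r = 0.9,
              top_n = 10, enrich_fdr = 0.05, min_term_genes = 2,
              drop_rule = "or", connectivity = "weighted", seed = 1,
              out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- c(fpkm_min = 0, fdr_max = 0, lfc_min = 0, r_min = 0, hrr_max = 1,
           inflation = 1, merge_r = 0, top_n = 1, enrich_fdr = 0, min_term_genes = 1)
  for (k in names(num))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < num[[k]])
      stopf("config key '%s' must be numeric >= %g", k, num[[k]])
  if (cfg$r_min > 1 || cfg$merge_r > 1) stopf("correlation thresholds must be <= 1")
  cfg
}

read_gcn_config <- function(path) {
  do.call(gcn_config, yaml::read_yaml(path))
}

#' Run the co-expression pipeline from a configuration
#'
#' Reads the input files named in the configuration, fits [hrr_gcn()], writes
#' every intermediate artifact into the output directory and returns a run
#' manifest (configuration echo, input file hashes, stage-by-stage record
#' counts, package version).  Identical configuration and inputs produce
#' byte-identical artifacts.
#'
#' @param config path to a YAML configuration file, or a list as from
#'   [gcn_config()].
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return the manifest list, invisibly; artifacts are written to `out_dir`.
#' @export
run_gcn_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_gcn_config(config)
         else do.call(gcn_config, config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stopf("no output directory configured")
  if (is.null(cfg$expression)) stopf("config must name an expression matrix")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  es <- read_expression(cfg$expression)
  deg <- if (!is.null(cfg$deg)) read_deg_table(cfg$deg)
  annot <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt)
  tf <- if (!is.null(cfg$tf)) read_tf_labels(cfg$tf)
  extra <- if (!is.null(cfg$extra_genes)) readLines(cfg$extra_genes) else character(0)

  fit <- hrr_gcn(es, deg = deg, annotation = annot, tf = tf,
                 extra_genes = extra, fpkm_min = cfg$fpkm_min,
                 fdr_max = cfg$fdr_max, lfc_min = cfg$lfc_min,
                 r_min = cfg$r_min, hrr_max = cfg$hrr_max,
                 inflation = cfg$inflation, mcl_weights = cfg$mcl_weights,
                 merge_r = cfg$merge_r,
                 top_n = cfg$top_n, enrich_fdr = cfg$enrich_fdr,
                 min_term_genes = cfg$min_term_genes,
                 drop_rule = cfg$drop_rule, connectivity = cfg$connectivity)

  write_gcn_artifacts(fit, out_dir)

  inputs <- Filter(Negate(is.null),
                   cfg[c("expression", "deg", "gmt", "tf", "extra_genes")])
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_hashes = lapply(inputs, function(p) unname(tools::md5sum(p))),
    counts = fit$counts,
    package_version = as.character(utils::packageVersion("hrrgcn")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write all artifacts of a fitted network
#'
#' Writes the network (SIF + GraphML), topology report (JSON), cluster and
#' module assignment TSVs, per-cluster enrichment TSV, per-module mean
#' z-profile matrix TSV (heatmap-ready), hub report JSON and TF subnetwork
#' SIF into `dir`.
#'
#' @param fit an [hrr_gcn()] fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_gcn_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "hrr_gcn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(fit$candidates, file.path(dir, "candidates.txt"))
  write_sif(fit$graph, file.path(dir, "network.sif"))
  write_graphml(fit$graph, file.path(dir, "network.graphml"))
  if (!is.null(fit$topology))
    jsonlite::write_json(unclass(fit$topology), file.path(dir, "topology.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(fit$clusters)) {
    write_clusters(fit$clusters, file.path(dir, "clusters.tsv"))
    if (!is.null(fit$enrichment)) {
      et <- enrichment_table(fit$enrichment)
      write.table(et, file.path(dir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(fit$modules)) {
    asg <- data.frame(gene = names(fit$modules$assignment),
                      cluster_id = unname(fit$clusters$assignment[names(fit$modules$assignment)]),
                      module_id = unname(fit$modules$assignment))
    asg <- asg[order(asg$module_id, asg$cluster_id, asg$gene), ]
    write.table(asg, file.path(dir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    prof <- t(vapply(fit$modules$modules, `[[`,
                     numeric(length(fit$expression$stage_order)), "profile"))
    rownames(prof) <- paste0("module_", seq_len(nrow(prof)))
    write.table(data.frame(module = rownames(prof), prof, check.names = FALSE),
                file.path(dir, "module_profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    hubs <- lapply(fit$hubs, function(h)
      list(key_gene = h$key_gene, hub_genes = h$hub_genes, ties = h$ties))
    jsonlite::write_json(hubs, file.path(dir, "hubs.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(fit$tf_network)) {
    writeLines(if (nrow(fit$tf_network))
      paste(fit$tf_network$key_gene, "co-expr", fit$tf_network$tf)
      else character(0), file.path(dir, "tf_network.sif"))
    write.table(as.data.frame(fit$tf_network), file.path(dir, "tf_network.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Simulate a benchmark dataset to disk
#'
#' Generates the default synthetic staged transcriptome (or any override of
#' its parameters) and writes the four pipeline inputs plus the ground-truth
#' file beside them.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param ... passed to [generate_gcn_dataset()].
#' @return invisibly, the dataset object.
#' @export
simulate_gcn_dataset <- function(dir, seed = 1, ...) {
  ds <- generate_gcn_dataset(seed = seed, ...)
  write_gcn_dataset(ds, dir)
  invisible(ds)
}
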