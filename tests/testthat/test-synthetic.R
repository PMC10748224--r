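test_that("profile archetypes have the documented shapes and stay separable", {
  d <- stage_design()
  p <- make_profiles(d)
  expect_equal(nrow(p), 10)
  expect_equal(colnames(p), d$stages)
  # peak-at-FI archetype is maximal at the FI stage
  expect_equal(which.max(p["peak_FI", ]), c(FI = 2L))
  # rise-to-FS is strictly nondecreasing
  expect_true(all(diff(p["rise_to_FS", ]) > 0))
  # any two distinct archetypes correlate at most 0.5
  r <- cor(t(p))
  diag(r) <- NA
  expect_true(max(r, na.rm = TRUE) <= 0.5)
  expect_error(make_profiles(d, archetype_count = 11), "exceeds")
})

test_that("design validation rejects degenerate layouts", {
  expect_error(stage_design(stages = "VS"), ">=2 stages")
  expect_error(stage_design(replicates = 1), ">=2 replicates")
  expect_error(stage_design(replicates = 0), ">=2 replicates")
  expect_error(
    generate_gcn_dataset(n_modules = 2, module_genes = list(c("a", "b", "c"),
                                                            c("c", "d", "e"))),
    "overlap")
})

test_that("noiseless generation reproduces the planted correlation structure", {
  ds <- generate_gcn_dataset(n_modules = 3, genes_per_module = 4,
                             n_background = 0, noise_sd = 0, seed = 7)
  lx <- log(ds$expression$values)
  m1 <- ds$truth$planted_modules[[1]]$genes
  # same module, zero noise: sample-wise correlation exactly 1
  expect_equal(unname(cor(lx[m1[1], ], lx[m1[2], ])), 1)
  expect_equal(unname(cor(ds$expression$values[m1[1], ],
                          ds$expression$values[m1[2], ])), 1)
  # across modules the log-scale correlation equals the profile correlation
  prof <- t(vapply(ds$truth$planted_modules, `[[`, numeric(7), "mean_profile"))
  stage_idx <- match(ds$expression$stages, ds$truth$stages)
  for (a in 1:2) for (b in (a + 1):3) {
    ga <- ds$truth$planted_modules[[a]]$genes[1]
    gb <- ds$truth$planted_modules[[b]]$genes[1]
    expect_equal(unname(cor(lx[ga, ], lx[gb, ])),
                 unname(cor(prof[a, stage_idx], prof[b, stage_idx])))
  }
})

test_that("the same seed reproduces the dataset byte for byte", {
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  write_gcn_dataset(generate_gcn_dataset(seed = 1), d1)
  write_gcn_dataset(generate_gcn_dataset(seed = 1), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the expression matrix
  d3 <- file.path(tempdir(), "ds_c")
  write_gcn_dataset(generate_gcn_dataset(seed = 2), d3)
  expect_false(unname(tools::md5sum(file.path(d1, "expression.tsv"))) ==
               unname(tools::md5sum(file.path(d3, "expression.tsv"))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_gcn_dataset(n_modules = 1, genes_per_module = 3,
                                               n_background = 2, seed = 5))
  expect_equal(runif(3), before)
})

test_that("planted modules are separable: intra-module |r| above 0.8, inter below", {
  for (seed in 1:5) {
    ds <- generate_gcn_dataset(n_modules = 5, genes_per_module = 10,
                               n_background = 0, noise_sd = 0.2, seed = seed)
    lab <- truth_assignment(ds$truth)
    r <- abs(cor(t(ds$expression$values[names(lab), ])))
    diag(r) <- NA
    same <- outer(lab, lab, "==")
    expect_gt(median(r[same], na.rm = TRUE), 0.8)
    expect_lt(median(r[!same]), 0.8)
    expect_gt(median(r[same], na.rm = TRUE), median(r[!same]))
  }
})

test_that("the DEG table lets planted genes through the screen and keeps background out", {
  ds <- generate_gcn_dataset(seed = 3)
  sel <- select_candidates(ds$deg)
  planted <- names(truth_assignment(ds$truth))
  expect_gt(mean(planted %in% sel), 0.97)
  expect_false(any(ds$truth$background_genes %in% sel))
})

test_that("annotation terms cover planted modules densely and outsiders sparsely", {
  ds <- generate_gcn_dataset(seed = 2)
  all_genes <- rownames(ds$expression$values)
  for (tm in ds$truth$planted_modules[1:3]) {
    for (tid in tm$term_ids) {
      tg <- ds$annotation$terms[[tid]]
      expect_gte(length(intersect(tg, tm$genes)) / length(tm$genes), 0.8)
      outside <- setdiff(all_genes, tm$genes)
      expect_lte(length(intersect(tg, outside)) / length(outside), 0.05)
    }
  }
})

test_that("ground truth round-trips through JSON", {
  dir <- file.path(tempdir(), "truth_rt")
  ds <- generate_gcn_dataset(n_modules = 2, genes_per_module = 5,
                             n_background = 10, seed = 11)
  write_gcn_dataset(ds, dir)
  tr <- read_gcn_truth(file.path(dir, "truth.json"))
  expect_equal(length(tr$planted_modules), 2)
  for (i in 1:2) {
    expect_equal(tr$planted_modules[[i]]$genes, ds$truth$planted_modules[[i]]$genes)
    expect_equal(tr$planted_modules[[i]]$hub_gene, ds$truth$planted_modules[[i]]$hub_gene)
    expect_equal(tr$planted_modules[[i]]$mean_profile,
                 ds$truth$planted_modules[[i]]$mean_profile)
  }
  expect_equal(tr$background_genes, ds$truth$background_genes)
  expect_equal(tr$noise_sd, ds$truth$noise_sd)
  expect_equal(tr$seed, ds$truth$seed)
  unlink(dir, recursive = TRUE)
})
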