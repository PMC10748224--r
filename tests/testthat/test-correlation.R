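test_that("pearson_matrix matches the closed-form coefficient and flags flat genes", {
  vals <- rbind(gA = c(1, 2, 3), gB = c(1, 2, 4), gC = c(4, 3, 2), gD = c(5, 5, 5))
  colnames(vals) <- c("S1_1", "S2_1", "S3_1")
  es <- expression_set(vals, stages = c("S1", "S2", "S3"))
  cm <- pearson_matrix(es)
  expect_equal(diag(cm$r), setNames(rep(1, 4), rownames(vals)))
  expect_equal(cm$r, t(cm$r))
  # hand Pearson for (1,2,3) vs (1,2,4): cov-sum 3, ss_x 2, ss_y 14/3
  expect_equal(cm$r["gA", "gB"], 3 / sqrt(2 * 14 / 3))
  expect_equal(cm$r["gA", "gB"], 0.9819805, tolerance = 1e-6)
  expect_equal(cm$r["gA", "gC"], -1)
  expect_true(cm$zero_var["gD"])
  expect_equal(unname(cm$r["gD", "gA"]), 0)
  expect_error(pearson_matrix(expression_set(vals[, 1:2, drop = FALSE],
                                             stages = c("S1", "S2"))),
               ">=3 samples")
  expect_error(pearson_matrix(es, genes = c("gA", "nope")), "not in matrix")
})

test_that("hrr_transform reproduces hand-ranked toy cases", {
  r <- matrix(c(1, .9, .85, .9, 1, .95, .85, .95, 1), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- hrr_transform(r)
  expect_equal(h["B", "C"], 1)  # mutual top partners
  expect_equal(h["A", "B"], 2)
  expect_equal(h["A", "C"], 2)
  expect_equal(h, t(h))
  expect_true(all(is.na(diag(h))))
})

test_that("hrr_transform agrees with the brute-force rank enumerator", {
  for (seed in 1:10) {
    n <- sample(10:30, 1)
    r <- random_cor(n, seed)
    expect_identical(hrr_transform(r), oracle_hrr(r))
  }
})

test_that("network edges obey inclusive |r| and HRR cutoffs", {
  # 4 genes, all pairwise |r| >= 0.9: complete graph K4 at any HRR <= 3
  vals <- rbind(a = c(1, 2, 3, 4.2), b = c(1, 2.1, 3, 4), c = c(1.2, 2, 3, 4),
                d = c(1, 2, 3.3, 4))
  colnames(vals) <- paste0("S", 1:4, "_1")
  es <- expression_set(vals, stages = paste0("S", 1:4))
  cm <- pearson_matrix(es)
  expect_true(all(abs(cm$r[upper.tri(cm$r)]) >= 0.9))
  g <- build_network(cm, hrr_max = 3)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 6)
  # edge attributes carry r, hrr, weight = 1/hrr and sign
  expect_equal(igraph::E(g)$weight, 1 / igraph::E(g)$hrr)
  expect_true(all(igraph::E(g)$sign == ifelse(igraph::E(g)$r > 0,
                                              "positive", "negative")))
})

test_that("raising hrr_max or lowering r_min never removes an edge", {
  r <- random_cor(15, 3)
  cm <- structure(list(r = r, zero_var = rep(FALSE, 15)), class = "cor_mat")
  h <- hrr_transform(r)
  edge_set <- function(g) {
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  suppressWarnings({
    e1 <- edge_set(build_network(cm, h, r_min = 0.5, hrr_max = 3))
    e2 <- edge_set(build_network(cm, h, r_min = 0.5, hrr_max = 6))
    e3 <- edge_set(build_network(cm, h, r_min = 0.3, hrr_max = 6))
  })
  expect_true(all(e1 %in% e2))
  expect_true(all(e2 %in% e3))
})

test_that("topology metrics match closed forms on canonical graphs", {
  as_named <- function(g) { igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g))); g }
  # triangle K3
  t3 <- topology_report(as_named(igraph::make_full_graph(3)))
  expect_equal(t3$density, 1)
  expect_equal(t3$clustering_coefficient, 1)
  expect_equal(t3$diameter, 1)
  expect_equal(t3$connected_components, 1)
  # star with 4 leaves: no triangles, diameter 2, centralization 1
  s4 <- topology_report(as_named(igraph::make_star(5, mode = "undirected")))
  expect_equal(s4$clustering_coefficient, 0)
  expect_equal(s4$diameter, 2)
  expect_equal(s4$avg_neighbors, 2 * 4 / 5)
  expect_equal(s4$centralization, (5 / 3) * (4 / 4 - 2 * 4 / (5 * 4)))
  # two disjoint edges
  d2 <- topology_report(as_named(igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)))
  expect_equal(d2$connected_components, 2)
  expect_equal(d2$avg_neighbors, 1)
  expect_equal(d2$density, 1 / 3)
  expect_equal(d2$diameter, 1)
  # path P4: CPL over connected pairs = (1+1+1+2+2+3)/6
  p4 <- topology_report(as_named(igraph::make_ring(4, circular = FALSE)))
  expect_equal(p4$characteristic_path_length, 10 / 6)
  expect_equal(p4$diameter, 3)
  expect_gte(p4$diameter, p4$characteristic_path_length)
  # K6 heterogeneity 0 (regular graph)
  k6 <- topology_report(as_named(igraph::make_full_graph(6)))
  expect_equal(k6$heterogeneity, 0)
  expect_equal(k6$density, 1)
  # single node: path metrics are 0
  one <- topology_report(as_named(igraph::make_empty_graph(1, directed = FALSE)))
  expect_equal(one$diameter, 0)
  expect_equal(one$characteristic_path_length, 0)
  expect_equal(one$connected_components, 1)
})

test_that("relabeling genes yields an isomorphic network and identical topology", {
  set.seed(5)
  n <- 12
  x <- matrix(rnorm(n * 9), n, 9,
              dimnames = list(sprintf("g%02d", 1:n),
                              paste0(rep(paste0("S", 1:3), each = 3), "_", 1:3)))
  es <- expression_set(abs(x) + 0.1)
  cm <- pearson_matrix(es)
  g1 <- suppressWarnings(build_network(cm, r_min = 0.3, hrr_max = 5))
  perm <- sample(n)
  vals2 <- es$values[perm, ]
  rownames(vals2) <- rownames(es$values)[perm]
  es2 <- expression_set(vals2)
  g2 <- suppressWarnings(build_network(pearson_matrix(es2), r_min = 0.3, hrr_max = 5))
  edge_set <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(edge_set(g1), edge_set(g2))
  expect_equal(unclass(topology_report(g1)), unclass(topology_report(g2)))
})

test_that("network writers emit SIF and GraphML", {
  fit <- default_fit_cache()$fit
  sif <- tempfile(fileext = ".sif"); gml <- tempfile(fileext = ".graphml")
  write_sif(fit$graph, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), igraph::ecount(fit$graph))
  expect_true(all(grepl(" co-expr ", lines)))
  write_graphml(fit$graph, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(fit$graph))
  expect_true("hrr" %in% igraph::edge_attr_names(g2))
  unlink(c(sif, gml))
})
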