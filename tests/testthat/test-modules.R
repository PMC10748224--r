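make_clusterset <- function(clusters) {
  cl <- lapply(clusters, sort)
  names(cl) <- as.character(seq_along(cl))
  ids <- rep(seq_along(cl), lengths(cl))
  structure(list(clusters = cl,
                 assignment = setNames(ids, unlist(cl, use.names = FALSE)),
                 unassigned = character(0), iterations = 1L, converged = TRUE),
            class = "mcl_clusters")
}

test_that("clusters with matching eigenprofiles merge; opposed ones never do", {
  z <- rbind(a1 = c(-1, 0, 1), a2 = c(-1, 0, 1),      # cluster 1
             b1 = c(-1, 0, 1), b2 = c(-1, 0, 1),      # cluster 2, identical profile
             c1 = c(1, 0, -1), c2 = c(1, 0, -1))      # cluster 3, anti-correlated
  colnames(z) <- c("S1", "S2", "S3")
  cs <- make_clusterset(list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")))
  ms <- merge_clusters(cs, z, merge_r = 0.9)
  expect_equal(length(ms$modules), 2)
  am <- ms$assignment
  expect_equal(unname(am["a1"]), unname(am["b1"]))   # identical profiles merged
  expect_false(unname(am["a1"]) == unname(am["c1"])) # r = -1 never merged
  # modules partition the clustered genes
  expect_setequal(names(am), rownames(z))
})

test_that("module ids are ordered by peak stage and raising merge_r refines modules", {
  set.seed(8)
  z <- rbind(x1 = c(2, 0, -1), x2 = c(1.8, 0.1, -1),
             y1 = c(-1, 0, 2), y2 = c(-1, 0.2, 1.9))
  colnames(z) <- c("S1", "S2", "S3")
  cs <- make_clusterset(list(c("y1", "y2"), c("x1", "x2")))
  ms <- merge_clusters(cs, z, merge_r = 0.9)
  expect_equal(ms$modules[[1]]$peak_stage, "S1")  # earliest peak gets id 1
  expect_equal(ms$modules[[2]]$peak_stage, "S3")
  # merge_r monotonicity on the default synthetic fit
  fit <- default_fit_cache()$fit
  n_mod <- vapply(c(0.5, 0.7, 0.9, 0.99), function(mr)
    length(merge_clusters(fit$clusters, fit$stage_profiles$z, mr)$modules),
    integer(1))
  expect_true(all(diff(n_mod) >= 0))
})

test_that("intramodular connectivity sums within-module edge weights", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "x"), to = c("b", "c", "a"),
               weight = c(0.5, 1.0, 10)), directed = FALSE)
  sc <- intramodular_connectivity(g, c("a", "b", "c"))
  # path a-b-c with weights (0.5, 1.0); the a-x edge lies outside the module
  expect_equal(sc, c(a = 0.5, b = 1.5, c = 1.0))
  # triangle with unit weights: each gene scores 2
  tri <- igraph::graph_from_data_frame(
    data.frame(from = c("p", "q", "r"), to = c("q", "r", "p"), weight = 1),
    directed = FALSE)
  expect_equal(intramodular_connectivity(tri, c("p", "q", "r")),
               c(p = 2, q = 2, r = 2))
  # gene with no within-module edges scores 0
  expect_equal(unname(intramodular_connectivity(g, c("c", "x"))["x"]), 0)
  # raw-degree mode
  expect_equal(intramodular_connectivity(g, c("a", "b", "c"), mode = "degree"),
               c(a = 1, b = 2, c = 1))
})

test_that("hub calls rank by score with expression tie-breaking", {
  sc <- c(g1 = 5, g2 = 3, g3 = 1)
  h <- call_hubs(sc)
  expect_equal(h$key_gene, "g1")
  expect_equal(h$hub_genes, c("g1", "g2", "g3"))  # all hubs when below top_n
  expect_length(h$ties, 0)
  # tie at rank 1 resolved by higher mean expression and recorded
  sc2 <- c(a = 2, b = 2, c = 1)
  h2 <- call_hubs(sc2, mean_expr = c(a = 1, b = 9, c = 5))
  expect_equal(h2$key_gene, "b")
  expect_setequal(h2$ties, c("a", "b"))
  # top_n truncation
  sc3 <- setNames(12:1, paste0("g", 1:12))
  expect_length(call_hubs(sc3)$hub_genes, 10)
  expect_error(call_hubs(numeric(0)), "empty")
})

test_that("connectivity is invariant to relabeling and outside edges", {
  b <- make_block_graph(3, 13)
  mod <- names(b$labels)[b$labels == 1]
  sc <- intramodular_connectivity(b$graph, mod)
  g2 <- igraph::add_edges(b$graph, c(mod[1], names(b$labels)[b$labels == 2][1]),
                          attr = list(weight = 5))
  expect_equal(intramodular_connectivity(g2, mod), sc)
})

test_that("TF subnetwork links key genes to TFs at the inclusive threshold", {
  genes <- c("k1", "k2", "t1", "t2", "t3")
  r <- diag(5); dimnames(r) <- list(genes, genes)
  r["k1", "t1"] <- r["t1", "k1"] <- 0.8      # boundary: included
  r["k1", "t2"] <- r["t2", "k1"] <- -0.85    # negative: included with sign
  r["k2", "t2"] <- r["t2", "k2"] <- 0.92
  r["k2", "t3"] <- r["t3", "k2"] <- 0.81
  r["k1", "t3"] <- r["t3", "k1"] <- 0.4
  r["k2", "t1"] <- r["t1", "k2"] <- -0.1
  cm <- structure(list(r = r, zero_var = setNames(rep(FALSE, 5), genes)),
                  class = "cor_mat")
  net <- tf_subnetwork(cm, key_genes = c("k1", "k2"), tf_genes = c("t1", "t2", "t3"))
  expect_equal(nrow(net), 4)
  expect_equal(attr(net, "n_tfs"), 3)
  expect_equal(net$sign[net$key_gene == "k1" & net$tf == "t2"], "negative")
  # every edge touches exactly one key gene and one TF (keys excluded as partners)
  net2 <- tf_subnetwork(cm, key_genes = c("k1", "k2"),
                        tf_genes = c("k2", "t1", "t2", "t3"))
  expect_false(any(net2$tf %in% c("k1", "k2")))
})
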