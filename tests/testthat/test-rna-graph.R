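uniform_W <- function(genes, value = 1) {
  W <- matrix(value, length(genes), length(genes),
              dimnames = list(genes, genes))
  structure(W, class = c("coexpression_matrix", "matrix", "array"))
}

test_that("graph edges respect the radius cutoff and KNN cap", {
  cfg <- comseg_config(D = 40)   # R_knn = 10
  cl <- rna_point_cloud(x = c(0, 9, 25), y = c(0, 0, 0),
                        gene = c("g", "g", "g"))
  g <- build_graph(cl, uniform_W("g"), cfg)
  # 9 um < R_knn: edge; 16 um and 25 um: no edge
  expect_identical(nrow(g$edges), 1L)
  expect_identical(c(g$edges$u, g$edges$v), c(1L, 2L))
  expect_equal(g$edges$len, 9)
  expect_true(all(g$edges$len <= cfg$R_knn))
})

test_that("graph construction equals brute-force KNN", {
  cfg <- comseg_config(D = 16)
  cl <- random_cloud(100, seed = 12)
  g <- build_graph(cl, uniform_W(cl$gene_names), cfg)
  oracle <- knn_edges_bruteforce(cbind(cl$x, cl$y, cl$z), cfg$R_knn,
                                 cfg$K_knn)
  expect_equal(g$edges[, c("u", "v")], oracle,
               ignore_attr = "row.names")
  # edge weights look up the co-expression of the incident genes
  W <- compute_coexpression(compute_pe_matrix(cl, cfg))
  g2 <- build_graph(cl, W, cfg)
  expect_equal(g2$edges$w,
               W[cbind(cl$gene[g2$edges$u], cl$gene[g2$edges$v])])
})

test_that("landmark merging contracts nuclear molecules into cell nodes", {
  cfg <- comseg_config(D = 8, nucleus_radius = 1.5)
  # 3 molecules inside a nucleus at origin, 2 free molecules
  cl <- rna_point_cloud(x = c(0, 0.5, -0.5, 4, 5), y = c(0, 0, 0, 0, 0),
                        gene = rep("g", 5))
  lm <- nucleus_landmarks(centroids = data.frame(nucleus_id = 1L, x = 0,
                                                 y = 0))
  g <- build_graph(cl, uniform_W("g"), cfg)
  gm <- merge_landmark_nodes(g, lm, cl, cfg)
  expect_identical(gm$n_nodes, g$n_nodes - 2L)   # 3 -> 1 cell node
  expect_identical(sum(gm$node_is_cell), 1L)
  expect_identical(gm$mol_nucleus, c(1L, 1L, 1L, 0L, 0L))
  expect_true(all(gm$mol2node[1:3] == gm$mol2node[1]))

  # a nucleus with no molecules still becomes an (isolated) cell node
  lm2 <- nucleus_landmarks(centroids = data.frame(
    nucleus_id = c(1L, 2L), x = c(0, 50), y = c(0, 0)))
  gm2 <- merge_landmark_nodes(g, lm2, cl, cfg)
  expect_identical(sum(gm2$node_is_cell), 2L)
  iso <- which(gm2$node_is_cell & gm2$node_nucleus == 2L)
  expect_false(iso %in% c(gm2$edges$u, gm2$edges$v))
})

test_that("contracted multi-edge weights are summed, lengths minimised", {
  cfg <- comseg_config(D = 20, nucleus_radius = 1.2)
  # nucleus absorbs molecules 1,2; both connect to free molecule 3
  cl <- rna_point_cloud(x = c(0, 1, 3, 4.2, 5.4, 20), y = rep(0, 6),
                        gene = c("a", "b", "a", "b", "a", "b"))
  W <- matrix(c(0.6, 0.2, 0.2, 0.4), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  g <- build_graph(cl, structure(W, class = c("coexpression_matrix",
                                              "matrix", "array")), cfg)
  lm <- nucleus_landmarks(centroids = data.frame(nucleus_id = 1L, x = 0.5,
                                                 y = 0))
  gm <- merge_landmark_nodes(g, lm, cl, cfg)
  cellnode <- which(gm$node_is_cell)
  m3 <- gm$mol2node[3]
  e <- gm$edges[(gm$edges$u == cellnode & gm$edges$v == m3) |
                  (gm$edges$v == cellnode & gm$edges$u == m3), ]
  # hand contraction: edges (1,3) w=0.6 and (2,3) w=0.2 sum to 0.8; the
  # contracted length is measured from the nucleus centroid at (0.5, 0)
  expect_equal(e$w, 0.6 + 0.2)
  expect_equal(e$len, 2.5)
})

test_that("modularity matches the ordered-pair double sum", {
  cfg <- comseg_config(D = 40)
  # two disconnected equal-weight triangles
  cl <- rna_point_cloud(x = c(0, 1, 0.5, 30, 31, 30.5),
                        y = c(0, 0, 0.9, 0, 0, 0.9), gene = rep("g", 6))
  g <- build_graph(cl, uniform_W("g"), cfg)
  memb <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(modularity_q(g, memb),
               modularity_direct(6, g$edges, memb))
  # every node in one community: Q = 0
  expect_equal(modularity_q(g, rep(1L, 6)), 0)
  # random partitions agree with the oracle
  set.seed(8)
  for (rep in 1:5) {
    memb <- sample.int(3, 6, replace = TRUE)
    expect_equal(modularity_q(g, memb),
                 modularity_direct(6, g$edges, memb))
  }
  # edgeless graph: m = 0 convention gives Q = 0
  cl0 <- rna_point_cloud(x = c(0, 100), y = c(0, 0), gene = c("g", "g"))
  g0 <- build_graph(cl0, uniform_W("g"), cfg)
  expect_equal(modularity_q(g0, c(1L, 2L)), 0)
  expect_error(modularity_q(g, memb[-1]), "cover")
})

test_that("component structure is recovered with one nucleus each", {
  cfg <- comseg_config(D = 40, nucleus_radius = 0.3)
  cl <- rna_point_cloud(x = c(0, 1, 0.5, 30, 31, 30.5),
                        y = c(0, 0, 0.9, 0, 0, 0.9), gene = rep("g", 6))
  lm <- nucleus_landmarks(centroids = data.frame(
    nucleus_id = c(1L, 2L), x = c(0, 30), y = c(0, 0)))
  g <- merge_landmark_nodes(build_graph(cl, uniform_W("g"), cfg), lm, cl,
                            cfg)
  p <- louvain_with_priors(g, cfg)
  expect_identical(p$n_communities, 2L)
  expect_identical(sort(p$comm_nucleus), c(1L, 2L))
  # all molecules of one component share their nucleus's community
  expect_length(unique(p$mol_membership[1:3]), 1L)
  expect_length(unique(p$mol_membership[4:6]), 1L)
})

test_that("negative-weight-only graphs stay fully singleton", {
  cfg <- comseg_config(D = 40)
  cl <- rna_point_cloud(x = c(0, 1, 2), y = rep(0, 3), gene = rep("g", 3))
  g <- build_graph(cl, uniform_W("g", value = -0.5), cfg)
  p <- louvain_with_priors(g, cfg)
  expect_identical(p$n_communities, 3L)
  expect_equal(p$Q, 0)
})

test_that("constrained Louvain is deterministic given the seed", {
  cl <- segregated_cloud(n_per = 80, seed = 10)
  cfg <- comseg_config(D = 8, seed = 5L)
  W <- compute_coexpression(compute_pe_matrix(cl, cfg))
  g <- build_graph(cl, W, cfg)
  p1 <- louvain_with_priors(g, cfg)
  p2 <- louvain_with_priors(g, cfg)
  expect_identical(p1$membership, p2$membership)
  # modularity is non-decreasing over aggregation passes
  expect_true(all(diff(p1$q_trace) >= -1e-12))
})

test_that("no community ever holds two cell nodes", {
  set.seed(31)
  for (rep in 1:4) {
    cl <- random_cloud(80, genes = c("a", "b"), extent = 12,
                       seed = 30 + rep)
    cfg <- comseg_config(D = 10, nucleus_radius = 2, seed = rep)
    W <- compute_coexpression(compute_pe_matrix(cl, cfg))
    lm <- nucleus_landmarks(centroids = data.frame(
      nucleus_id = 1:3, x = c(2, 6, 10), y = c(2, 10, 5)))
    g <- merge_landmark_nodes(build_graph(cl, W, cfg), lm, cl, cfg)
    p <- louvain_with_priors(g, cfg)
    cellcomms <- p$membership[g$node_is_cell]
    expect_false(anyDuplicated(cellcomms) > 0)
    # nuclear anchoring: nuclear molecules sit in their nucleus community
    for (nid in 1:3) {
      mols <- which(g$mol_nucleus == nid)
      if (!length(mols)) next
      expect_true(all(p$mol_membership[mols] ==
                        p$membership[g$node_is_cell &
                                       g$node_nucleus == nid]))
    }
  }
})
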