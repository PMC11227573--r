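# Small single-gene worlds with hand-placed nuclei exercise centroid
# labelling and geodesic assignment without the clustering stages.

one_gene_setup <- function(x, y, nuclei, cfg, labels = NULL) {
  cl <- rna_point_cloud(x = x, y = y, gene = rep("g", length(x)))
  W <- structure(matrix(1, 1, 1, dimnames = list("g", "g")),
                 class = c("coexpression_matrix", "matrix", "array"))
  lm <- nucleus_landmarks(centroids = nuclei)
  g <- merge_landmark_nodes(build_graph(cl, W, cfg), lm, cl, cfg)
  if (is.null(labels)) labels <- rep(1L, length(x))
  map <- structure(list(comm_id = 1L, comm_label = 1L, n_labels = 1L,
                        mol_label = labels),
                   class = "domain_map")
  list(cl = cl, lm = lm, g = g, map = map)
}

test_that("centroid labels come from nuclear RNAs or neighbour votes", {
  cfg <- comseg_config(D = 10, nucleus_radius = 1.5)
  # nucleus 1 holds 3 RNAs labelled 3; nucleus 2 is empty with labelled
  # neighbours; nucleus 3 has nothing within D/2
  cl <- rna_point_cloud(x = c(0, 0.5, 1, 20, 21, 22, 23), y = rep(0, 7),
                        gene = rep("g", 7))
  W <- structure(matrix(1, 1, 1, dimnames = list("g", "g")),
                 class = c("coexpression_matrix", "matrix", "array"))
  lm <- nucleus_landmarks(centroids = data.frame(
    nucleus_id = 1:3, x = c(0.5, 21, 60), y = c(0, 3, 0)))
  g <- merge_landmark_nodes(build_graph(cl, W, cfg), lm, cl, cfg)
  map <- structure(list(mol_label = c(3L, 3L, 3L, 1L, 1L, 1L, 2L)),
                   class = "domain_map")
  cen <- label_centroids(map, lm, cl, g, cfg)
  expect_identical(cen$label[1], 3L)
  expect_identical(cen$provenance[1], "nuclear-RNA")
  expect_identical(cen$label[2], 1L)   # 3 of 4 reachable vote label 1
  expect_identical(cen$provenance[2], "neighbor-vote")
  expect_true(is.na(cen$label[3]))
  expect_identical(cen$provenance[3], "none")
})

test_that("one connected label is fully claimed by its only centroid", {
  cfg <- comseg_config(D = 8, R_max = 20, nucleus_radius = 0.5)
  s <- one_gene_setup(x = seq(0, 8, by = 1), y = rep(0, 9),
                      nuclei = data.frame(nucleus_id = 1L, x = 0, y = 0),
                      cfg = cfg)
  cen <- label_centroids(s$map, s$lm, s$cl, s$g, cfg)
  asn <- geodesic_assign(s$g, cen, s$map, cfg)
  expect_true(all(asn$cell == 1L))
  expect_identical(asn$provenance[1], "nuclear")
  expect_true(all(asn$provenance[-1] == "graph-assigned"))
  # geodesic distance is at least the straight-line distance
  eu <- sqrt((s$cl$x - cen$x[1])^2 + (s$cl$y - cen$y[1])^2)
  ok <- asn$cell > 0 & asn$provenance == "graph-assigned"
  expect_true(all(asn$distance[ok] >= eu[ok] - 1e-9))
})

test_that("assignment follows the graph, not Euclidean shortcuts", {
  # U-shaped chain: molecule m sits 2 um from nucleus B's blob but is
  # connected only to nucleus A through the chain
  cfg <- comseg_config(D = 4, R_max = 30, nucleus_radius = 1)
  xs <- c(0, 0, 0, 0, 0, 1, 2, 2, 2, 2, 2,   4, 4, 5)
  ys <- c(0, 1, 2, 3, 4, 4, 4, 3, 2, 1, 0,   0, 1, 0)
  nuclei <- data.frame(nucleus_id = c(1L, 2L), x = c(0, 4.5), y = c(0, 0.5))
  s <- one_gene_setup(xs, ys, nuclei, cfg)
  cen <- label_centroids(s$map, s$lm, s$cl, s$g, cfg)
  asn <- geodesic_assign(s$g, cen, s$map, cfg)
  m <- 11                                   # the chain end at (2, 0)
  expect_identical(asn$cell[m], 1L)
  # oracle: igraph shortest paths over the merged edge list
  aN <- which(s$g$node_is_cell & s$g$node_nucleus == 1L)
  d <- geodesic_igraph(s$g$n_nodes, s$g$edges, aN)
  expect_equal(asn$distance[m], unname(d[s$g$mol2node[m]]),
               tolerance = 1e-9)
})

test_that("molecules beyond R_max stay unassigned", {
  cfg <- comseg_config(D = 8, R_max = 4.5, nucleus_radius = 0.5)
  s <- one_gene_setup(x = seq(0, 8, by = 1), y = rep(0, 9),
                      nuclei = data.frame(nucleus_id = 1L, x = 0, y = 0),
                      cfg = cfg)
  cen <- label_centroids(s$map, s$lm, s$cl, s$g, cfg)
  asn <- geodesic_assign(s$g, cen, s$map, cfg)
  expect_true(all(asn$cell[s$cl$x <= 4.5] == 1L))
  expect_true(all(asn$cell[s$cl$x > 4.5] == 0L))
  expect_true(all(asn$provenance[s$cl$x > 4.5] == "unassigned"))
})

test_that("labels gate which centroid can claim a molecule", {
  cfg <- comseg_config(D = 8, R_max = 20, nucleus_radius = 0.6)
  xs <- seq(0, 10, by = 1)
  labels <- c(rep(1L, 5), rep(2L, 6))
  s <- one_gene_setup(xs, rep(0, 11),
                      data.frame(nucleus_id = c(1L, 2L), x = c(0, 10),
                                 y = c(0, 0)), cfg, labels = labels)
  cen <- label_centroids(s$map, s$lm, s$cl, s$g, cfg)
  asn <- geodesic_assign(s$g, cen, s$map, cfg)
  expect_true(all(asn$cell[labels == 1L] == 1L))
  expect_true(all(asn$cell[labels == 2L] == 2L))
})

test_that("profiles count assigned molecules by cell and gene", {
  cl <- rna_point_cloud(x = 1:4, y = rep(0, 4),
                        gene = c("g1", "g1", "g2", "g2"))
  cells <- data.frame(cell_id = 1:2, x = 0, y = 0, z = 0, label = 1L,
                      provenance = "nuclear-RNA")
  asn <- structure(list(cell = c(1L, 1L, 1L, 2L),
                        provenance = rep("graph-assigned", 4),
                        distance = rep(1, 4), cells = cells),
                   class = "cell_assignment")
  prof <- profiles_from_assignment(asn, cl)
  expect_equal(as.matrix(prof),
               matrix(c(2, 0, 1, 1), 2, 2,
                      dimnames = list(c("1", "2"), c("g1", "g2"))))
  # unassigned molecules are excluded; empty cells stay as zero rows
  asn$cell <- c(0L, 0L, 0L, 0L)
  expect_equal(sum(profiles_from_assignment(asn, cl)), 0)
  # group-by oracle on a random fixture
  set.seed(61)
  cl2 <- random_cloud(200, seed = 61)
  cells2 <- data.frame(cell_id = 1:6, x = 0, y = 0, z = 0, label = 1L,
                       provenance = "nuclear-RNA")
  asn2 <- structure(list(cell = sample(0:6, 200, replace = TRUE),
                         provenance = "graph-assigned", distance = 1,
                         cells = cells2), class = "cell_assignment")
  prof2 <- profiles_from_assignment(asn2, cl2)
  for (c in 1:6) for (g in seq_along(cl2$gene_names))
    expect_equal(prof2[as.character(c), g],
                 sum(asn2$cell == c & cl2$gene == g))
})

test_that("convex well-separated cells agree with nearest-nucleus", {
  # blobs of one label on a coarse grid; geodesic assignment must match
  # the nearest-nucleus rule for virtually all molecules
  set.seed(77)
  centers <- expand.grid(x = c(10, 30, 50), y = c(10, 30))
  xs <- ys <- numeric(0); truth <- integer(0)
  for (i in seq_len(nrow(centers))) {
    th <- runif(60, 0, 2 * pi); r <- sqrt(runif(60)) * 5
    xs <- c(xs, centers$x[i] + r * cos(th))
    ys <- c(ys, centers$y[i] + r * sin(th))
    truth <- c(truth, rep(i, 60))
  }
  cfg <- comseg_config(D = 12, R_max = 12, nucleus_radius = 2)
  nuclei <- data.frame(nucleus_id = seq_len(nrow(centers)),
                       x = centers$x, y = centers$y)
  s <- one_gene_setup(xs, ys, nuclei, cfg)
  cen <- label_centroids(s$map, s$lm, s$cl, s$g, cfg)
  asn <- geodesic_assign(s$g, cen, s$map, cfg)
  d2 <- outer(xs, centers$x, "-")^2 + outer(ys, centers$y, "-")^2
  nearest <- apply(d2, 1L, which.min)
  expect_gte(mean(asn$cell == nearest), 0.99)
})
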