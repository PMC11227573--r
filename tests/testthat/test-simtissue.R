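test_that("grid geometry has exact cell and nucleus dimensions", {
  sim <- simulate_grid(2, 2)
  expect_identical(dim(sim$cell_mask), c(200L, 200L))
  for (id in 1:4) expect_identical(sum(sim$cell_mask == id), 10000L)
  # nucleus/cell area ratio approaches pi * 3.75^2 / 15^2
  ratio <- sum(sim$nucleus_mask == 1L) / sum(sim$cell_mask == 1L)
  expect_equal(ratio, pi * 3.75^2 / 15^2, tolerance = 0.01)
  sim1 <- simulate_grid(1, 1)
  expect_identical(sort(unique(as.vector(sim1$cell_mask))), 1L)
  # nucleus concentric with its cell
  lm <- simulation_landmarks(sim1)
  expect_equal(lm$centroids$x, 7.5, tolerance = 0.05)
  expect_equal(lm$centroids$y, 7.5, tolerance = 0.05)
})

test_that("L-shaped cells are four squares with a square-centre nucleus", {
  sim <- simulate_lshapes(1)
  expect_identical(sum(sim$cell_mask == 1L), 4L * 100L * 100L)
  sim10 <- simulate_lshapes(10, seed = 4)
  side <- 100
  for (id in 1:10) {
    vox <- which(sim10$nucleus_mask == id)
    expect_gt(length(vox), 0)
    co <- arrayInd(vox, dim(sim10$nucleus_mask))
    cen <- colMeans(co)
    # nucleus centre must coincide with the centre of one occupied square
    sq <- floor((cen - 0.5) / side)
    centre <- sq * side + side / 2 + 0.5
    expect_equal(unname(cen), unname(centre), tolerance = 1)
    expect_identical(sim10$cell_mask[round(centre[1]), round(centre[2])],
                     id)
  }
  # seeded nucleus placement is reproducible
  expect_identical(simulate_lshapes(10, seed = 4)$nucleus_mask,
                   sim10$nucleus_mask)
  expect_false(identical(simulate_lshapes(10, seed = 5)$nucleus_mask,
                         sim10$nucleus_mask))
})

test_that("cell growth fills space, respects masks and the midline", {
  # one nucleus, no competition: every allowed voxel is claimed
  nuc <- matrix(0L, 40, 40); nuc[20, 20] <- 1L
  cm <- grow_cells(nuc, seed = 2)
  expect_true(all(cm == 1L))
  # a lacuna is never entered
  allowed <- matrix(TRUE, 40, 40); allowed[5:10, 5:10] <- FALSE
  cm2 <- grow_cells(nuc, allowed, seed = 2)
  expect_true(all(cm2[5:10, 5:10] == 0L))
  expect_true(all(cm2[!allowed] == 0L))
  expect_true(all(cm2[allowed] == 1L))
  # two nuclei with equal deterministic speeds split at the midline
  nuc2 <- matrix(0L, 60, 31); nuc2[15, 16] <- 1L; nuc2[45, 16] <- 2L
  cm3 <- grow_cells(nuc2, speed_range = c(1, 1), seed = 3)
  voronoi <- outer(seq_len(60), rep(1, 31)) # nearest seed by x coordinate
  own <- ifelse(abs(voronoi - 15) < abs(voronoi - 45), 1L, 2L)
  mismatch <- mean(cm3[abs(voronoi - 15) != abs(voronoi - 45)] !=
                     own[abs(voronoi - 15) != abs(voronoi - 45)])
  expect_lte(mismatch, 0.05)
  boundary_rows <- unique(which(cm3 == 1L, arr.ind = TRUE)[, 1])
  expect_lte(max(boundary_rows), 31)        # within 1 voxel of midline 30
})

test_that("nucleus dropout removes exactly the requested fraction", {
  sim <- simulate_grid(10, 10)
  expect_identical(drop_nuclei(sim, 0)$cells$has_nucleus,
                   rep(TRUE, 100))
  d <- drop_nuclei(sim, 0.2, seed = 6)
  expect_identical(sum(!d$cells$has_nucleus), 20L)
  gone <- d$cells$cell_id[!d$cells$has_nucleus]
  expect_false(any(gone %in% d$nucleus_mask))
  expect_true(all(gone %in% d$cell_mask))   # cells retained
  expect_identical(drop_nuclei(sim, 0.2, seed = 6)$cells$has_nucleus,
                   d$cells$has_nucleus)
})

test_that("expression sampling scales counts by the capture factor", {
  sim <- simulate_grid(1, 1)
  model0 <- expression_model(matrix(c(2, 1, 0), 1, 3,
                                    dimnames = list(NULL,
                                                    c("a", "b", "c"))),
                             capture_factor = 0)
  s0 <- sample_expression(sim, model0, seed = 1, mode = "constant")
  expect_identical(sum(s0$profiles), 0L)
  model3 <- expression_model(matrix(c(2, 1, 0), 1, 3,
                                    dimnames = list(NULL,
                                                    c("a", "b", "c"))),
                             capture_factor = 3)
  s3 <- sample_expression(sim, model3, seed = 1, mode = "constant")
  expect_identical(unname(s3$profiles[1, ]), c(6L, 3L, 0L))
})

test_that("sampled counts concentrate around the model means", {
  # 1000 cells from a 2-type model: realised per-type means within 3 sigma
  cells <- data.frame(cell_id = 1:1000, type = NA_integer_,
                      has_nucleus = TRUE)
  sim <- comseg:::new_tissue_simulation(matrix(1L, 2, 2), matrix(0L, 2, 2),
                                        0.15, cells, list())
  model <- marker_panel_model(n_types = 2, n_markers = 3, marker_mean = 5,
                              dispersion = 8)
  s <- sample_expression(sim, model, seed = 12)
  for (t in 1:2) {
    rows <- which(s$cells$type == t)
    mu <- model$profiles[t, ] * model$capture_factor
    sd_nb <- sqrt(model$profiles[t, ] +
                    model$profiles[t, ]^2 / 8) * model$capture_factor
    got <- colMeans(s$profiles[rows, ])
    expect_true(all(abs(got - mu) <= 3 * sd_nb / sqrt(length(rows)) + 0.2))
  }
})

test_that("molecules are placed uniformly inside their own cell", {
  sim <- simulate_grid(2, 2, n_types = 2)
  model <- marker_panel_model()
  sim <- sample_expression(sim, model, seed = 3, types = sim$cells$type)
  sim <- place_rna(sim, seed = 4)
  # support: every molecule's voxel carries its cell label
  vs <- sim$voxel_size
  ix <- ceiling(sim$cloud$x / vs[1]); iy <- ceiling(sim$cloud$y / vs[2])
  expect_true(all(sim$cell_mask[cbind(ix, iy)] == sim$true_cell))
  # closure: placed counts equal the sampled profiles exactly
  for (i in 1:4) {
    cid <- sim$cells$cell_id[i]
    placed <- tabulate(sim$cloud$gene[sim$true_cell == cid],
                       nbins = length(sim$gene_names))
    expect_identical(placed, unname(sim$profiles[i, ]))
  }
  # determinism of the full generation chain
  sim2 <- place_rna(sample_expression(simulate_grid(2, 2, n_types = 2),
                                      model, seed = 3,
                                      types = sim$cells$type), seed = 4)
  expect_identical(sim2$cloud$x, sim$cloud$x)
  expect_identical(sim2$true_cell, sim$true_cell)
})

test_that("within-cell placement passes a quadrant uniformity test", {
  sim <- simulate_grid(1, 1)
  model <- expression_model(matrix(3400, 1, 1,
                                   dimnames = list(NULL, "g")))
  sim <- sample_expression(sim, model, seed = 5, mode = "constant")
  sim <- place_rna(sim, seed = 6)
  n <- length(sim$cloud)
  expect_gt(n, 5000)
  qx <- sim$cloud$x > 7.5; qy <- sim$cloud$y > 7.5
  counts <- table(qx, qy)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("degenerate single-voxel cells confine their molecules", {
  cells <- data.frame(cell_id = 1L, type = 1L, has_nucleus = TRUE)
  mask <- matrix(0L, 5, 5); mask[3, 4] <- 1L
  sim <- comseg:::new_tissue_simulation(mask, matrix(0L, 5, 5), 0.5,
                                        cells, list())
  sim$profiles <- matrix(20L, 1, 1, dimnames = list("1", "g"))
  sim$gene_names <- "g"
  sim <- place_rna(sim, seed = 8)
  expect_true(all(sim$cloud$x >= 1 & sim$cloud$x <= 1.5))
  expect_true(all(sim$cloud$y >= 1.5 & sim$cloud$y <= 2))
})
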