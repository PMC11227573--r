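#' @name simtissue
#' @title Synthetic tissue simulation
#' @description
#' Ground-truth generators for benchmarking RNA-to-cell assignment:
#' regular grids of square cells, interlocking L-shaped cells, and
#' nucleus-seeded grown tissue with lacunar exclusion masks.  Cell and
#' nucleus geometry live on an integer label raster with a physical voxel
#' size; RNA molecules are placed uniformly inside their cell's mask from
#' sampled expression profiles, so the per-cell ground truth counts equal
#' the sampled profiles exactly.
NULL

new_tissue_simulation <- function(cell_mask, nucleus_mask, voxel_size,
                                  cells, params) {
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 cells = cells, profiles = NULL, gene_names = NULL,
                 cloud = NULL, true_cell = NULL, params = params),
            class = "tissue_simulation")
}

#' @export
print.tissue_simulation <- function(x, ...) {
  cat(sprintf("tissue_simulation: %d cells (%d with nucleus), raster %s\n",
              nrow(x$cells), sum(x$cells$has_nucleus),
              paste(dim(x$cell_mask), collapse = "x")))
  if (!is.null(x$cloud))
    cat(sprintf("  %d RNA molecules over %d genes\n", length(x$cloud),
                length(x$gene_names)))
  invisible(x)
}

# disc/sphere stamp around a centre, in voxel units
stamp_disc <- function(mask, value, cx, cy, r_vox) {
  i0 <- max(1L, floor(cx - r_vox)); i1 <- min(dim(mask)[1L], ceiling(cx + r_vox))
  j0 <- max(1L, floor(cy - r_vox)); j1 <- min(dim(mask)[2L], ceiling(cy + r_vox))
  ii <- i0:i1; jj <- j0:j1
  sub <- outer((ii - 0.5 - cx)^2, (jj - 0.5 - cy)^2, "+") <= r_vox^2
  blk <- mask[ii, jj]
  blk[sub] <- value
  mask[ii, jj] <- blk
  mask
}

#' Simulate a regular grid of square cells
#'
#' Cells are 15 um x 15 um squares rasterised at 0.150 um/voxel; each
#' nucleus is a disc of radius 3.75 um at the cell centre.  Cell types are
#' assigned in a checkerboard pattern over `n_types`.
#'
#' @param nx,ny Number of cells per axis.
#' @param voxel_size Micrometres per voxel.
#' @param cell_size Side length of a cell (micrometres).
#' @param nucleus_radius Nucleus radius (micrometres).
#' @param n_types Number of planted cell types (checkerboard assignment).
#' @return A `tissue_simulation` (geometry only; see
#'   [sample_expression()] and [place_rna()]).
#' @export
simulate_grid <- function(nx, ny, voxel_size = 0.150, cell_size = 15,
                          nucleus_radius = 3.75, n_types = 1L) {
  stopifnot(nx >= 1L, ny >= 1L)
  side <- round(cell_size / voxel_size)
  cm <- matrix(0L, nx * side, ny * side)
  nm <- matrix(0L, nx * side, ny * side)
  cells <- NULL
  for (jy in seq_len(ny)) for (jx in seq_len(nx)) {
    id <- as.integer((jy - 1L) * nx + jx)
    ii <- ((jx - 1L) * side + 1L):(jx * side)
    jj <- ((jy - 1L) * side + 1L):(jy * side)
    cm[ii, jj] <- id
    cx <- (jx - 0.5) * side; cy <- (jy - 0.5) * side
    nm <- stamp_disc(nm, id, cx, cy, nucleus_radius / voxel_size)
    cells <- rbind(cells, data.frame(
      cell_id = id, type = ((jx + jy) %% n_types) + 1L,
      has_nucleus = TRUE))
  }
  new_tissue_simulation(cm, nm, voxel_size, cells,
                        list(scenario = "grid", nx = nx, ny = ny,
                             voxel_size = voxel_size, cell_size = cell_size,
                             nucleus_radius = nucleus_radius,
                             n_types = n_types))
}

#' Simulate interlocking L-shaped cells
#'
#' Each cell is an L-tetromino of four 15 um x 15 um squares; two mirrored
#' L's interlock into a 2 x 4 squares block, and blocks tile the plane.
#' The nucleus (disc of radius 3.75 um) sits at the centre of one of the
#' four squares, drawn uniformly with `seed`.  Cells are numbered so that
#' the two interlocked partners of a block are consecutive (odd, even).
#'
#' @param n_shapes Number of L-shaped cells (>= 1).
#' @param voxel_size Micrometres per voxel.
#' @param square_size Side of each constituent square (micrometres).
#' @param nucleus_radius Nucleus radius (micrometres).
#' @param seed Seed for nucleus placement.
#' @return A `tissue_simulation` (geometry only).
#' @export
simulate_lshapes <- function(n_shapes, voxel_size = 0.150, square_size = 15,
                             nucleus_radius = 3.75, seed = 1L) {
  stopifnot(n_shapes >= 1L)
  side <- round(square_size / voxel_size)
  n_blocks <- ceiling(n_shapes / 2)
  bx <- ceiling(sqrt(n_blocks))       # blocks per row
  by <- ceiling(n_blocks / bx)
  cm <- matrix(0L, bx * 4L * side, by * 2L * side)
  nm <- matrix(0L, nrow(cm), ncol(cm))
  # squares of the two interlocked L's, in block-local (col, row) units:
  # cell A: (0,0) (1,0) (2,0) (0,1);  cell B: (3,1) (2,1) (1,1) (3,0)
  sq_a <- cbind(c(0L, 1L, 2L, 0L), c(0L, 0L, 0L, 1L))
  sq_b <- cbind(c(3L, 2L, 1L, 3L), c(1L, 1L, 1L, 0L))
  cells <- NULL
  rng <- local({ set.seed(seed); function(n) sample.int(n, 1L) })
  for (b in seq_len(n_blocks)) {
    obx <- ((b - 1L) %% bx) * 4L * side
    oby <- ((b - 1L) %/% bx) * 2L * side
    for (half in 1:2) {
      id <- (b - 1L) * 2L + half
      if (id > n_shapes) next
      sq <- if (half == 1L) sq_a else sq_b
      for (s in 1:4) {
        ii <- (obx + sq[s, 1L] * side + 1L):(obx + (sq[s, 1L] + 1L) * side)
        jj <- (oby + sq[s, 2L] * side + 1L):(oby + (sq[s, 2L] + 1L) * side)
        cm[ii, jj] <- id
      }
      pick <- rng(4L)
      cx <- obx + (sq[pick, 1L] + 0.5) * side
      cy <- oby + (sq[pick, 2L] + 0.5) * side
      nm <- stamp_disc(nm, id, cx, cy, nucleus_radius / voxel_size)
      cells <- rbind(cells, data.frame(
        cell_id = id, type = ((id - 1L) %% 2L) + 1L, has_nucleus = TRUE))
    }
  }
  new_tissue_simulation(cm, nm, voxel_size, cells,
                        list(scenario = "lshape", n_shapes = n_shapes,
                             voxel_size = voxel_size,
                             square_size = square_size,
                             nucleus_radius = nucleus_radius, seed = seed))
}

#' Grow cells from nucleus seeds
#'
#' Iterative frontier expansion: each cell draws a per-round expansion
#' probability ("speed") once, uniformly from `speed_range`, and in every
#' round dilates its frontier by one voxel with that probability.  Rounds
#' visit cells in seeded-random order, so contested voxels go to the first
#' claimant of the round.  Growth never enters voxels outside
#' `allowed_mask`.  2D uses 8-connectivity, 3D 26-connectivity.
#'
#' @param nucleus_raster Integer label matrix/array of nucleus seeds.
#' @param allowed_mask Logical mask of voxels cells may occupy (`NULL` =
#'   everywhere); must cover all nuclei.
#' @param voxel_size Micrometres per voxel.
#' @param speed_range Range of the per-cell expansion probability.
#' @param seed Seed for speeds and round order.
#' @return Integer cell label raster of the same shape.
#' @export
grow_cells <- function(nucleus_raster, allowed_mask = NULL,
                       voxel_size = 0.150, speed_range = c(0.5, 1),
                       seed = 1L) {
  dm <- dim(nucleus_raster)
  nd <- length(dm)
  if (is.null(allowed_mask)) allowed_mask <- array(TRUE, dm)
  if (any(nucleus_raster > 0L & !allowed_mask))
    stop("'allowed_mask' must cover every nucleus voxel")
  ids <- sort(unique(nucleus_raster[nucleus_raster > 0L]))
  if (!length(ids)) stop("no nuclei to grow from")
  set.seed(seed)
  speed <- runif(length(ids), speed_range[1L], speed_range[2L])
  cm <- nucleus_raster
  cm[!allowed_mask] <- 0L
  # neighbour offsets as linear-index shifts, with border guard via coords
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  frontier <- lapply(ids, function(id) which(cm == id))
  repeat {
    any_claimable <- FALSE
    for (k in sample.int(length(ids))) {
      fr <- frontier[[k]]
      if (!length(fr)) next
      co <- arrayInd(fr, dm)
      claim <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- co + matrix(offs[o, ], nrow(co), nd, byrow = TRUE)
        ok <- rowSums(nb >= 1L) == nd &
          rowSums(nb <= matrix(dm, nrow(co), nd, byrow = TRUE)) == nd
        if (!any(ok)) next
        lin <- nb[ok, 1L]
        if (nd >= 2L) lin <- lin + dm[1L] * (nb[ok, 2L] - 1L)
        if (nd == 3L) lin <- lin + dm[1L] * dm[2L] * (nb[ok, 3L] - 1L)
        claim <- c(claim, lin[cm[lin] == 0L & allowed_mask[lin]])
      }
      claim <- unique(claim)
      if (!length(claim)) { frontier[[k]] <- integer(0); next }
      any_claimable <- TRUE
      # the frontier dilates fully or not at all this round
      if (runif(1L) <= speed[k]) {
        cm[claim] <- ids[k]
        frontier[[k]] <- claim
      }
    }
    if (!any_claimable) break
  }
  cm
}

#' Remove a fraction of nuclei from a simulation
#'
#' Emulates nuclei lost at the section boundary during sample
#' preparation: a seeded-random `floor(fraction * N)` subset of nuclei is
#' erased from the nucleus raster; the cells and their RNAs are retained
#' and flagged `has_nucleus = FALSE`.
#'
#' @param sim A `tissue_simulation`.
#' @param fraction Fraction in \[0, 1) of nuclei to remove.
#' @param seed Seed for the subset draw.
#' @return The modified `tissue_simulation`.
#' @export
drop_nuclei <- function(sim, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n_drop <- floor(fraction * nrow(sim$cells))
  if (n_drop == 0L) return(sim)
  set.seed(seed)
  drop <- sample(sim$cells$cell_id, n_drop)
  sim$nucleus_mask[sim$nucleus_mask %in% drop] <- 0L
  sim$cells$has_nucleus[sim$cells$cell_id %in% drop] <- FALSE
  sim$params$dropped_nuclei <- drop
  sim
}

#' Expression model for simulated cells
#'
#' @param profiles Cell-type x gene matrix of mean counts (non-negative),
#'   with genes as column names.
#' @param freq Per-type frequency (defaults to uniform; must sum to 1).
#' @param capture_factor Multiplier applied to sampled counts, reflecting
#'   the higher capture rate of smFISH relative to scRNA-seq (default 3).
#' @param dispersion Negative-binomial size parameter for count sampling
#'   (`NULL` = Poisson).
#' @return An object of class `expression_model`.
#' @export
expression_model <- function(profiles, freq = NULL, capture_factor = 3,
                             dispersion = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("gene", seq_len(ncol(profiles)))
  if (any(profiles < 0)) stop("mean profiles must be non-negative")
  if (is.null(freq)) freq <- rep(1 / nrow(profiles), nrow(profiles))
  if (abs(sum(freq) - 1) > 1e-8) stop("type frequencies must sum to 1")
  structure(list(profiles = profiles, freq = freq,
                 capture_factor = capture_factor, dispersion = dispersion,
                 gene_names = colnames(profiles)),
            class = "expression_model")
}

#' Marker-panel expression model
#'
#' Convenience builder: `n_types` cell types, each with `n_markers`
#' exclusive marker genes at mean `marker_mean` and a small off-target
#' leak `leak_mean` on the other types' markers.
#'
#' @param n_types,n_markers Panel design.
#' @param marker_mean,leak_mean On- and off-target mean counts per gene.
#' @param dispersion Negative-binomial size parameter.
#' @param capture_factor See [expression_model()].
#' @return An `expression_model`.
#' @export
marker_panel_model <- function(n_types = 2L, n_markers = 5L,
                               marker_mean = 4, leak_mean = 0.05,
                               dispersion = 8, capture_factor = 3) {
  G <- n_types * n_markers
  prof <- matrix(leak_mean, n_types, G)
  for (t in seq_len(n_types))
    prof[t, ((t - 1L) * n_markers + 1L):(t * n_markers)] <- marker_mean
  colnames(prof) <- sprintf("t%d_m%d", rep(seq_len(n_types),
                                           each = n_markers),
                            rep(seq_len(n_markers), n_types))
  expression_model(prof, capture_factor = capture_factor,
                   dispersion = dispersion)
}

# stochastic rounding: floor + Bernoulli on the fractional part, so the
# expectation of the scaled count is exact
stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (runif(length(x)) < (x - f)))
}

#' Sample per-cell expression profiles
#'
#' Each cell receives a type (drawn by the model frequencies unless
#' `types` is given) and an integer gene-count vector: a negative-binomial
#' (or Poisson) draw around the type mean, the constant rounded mean, or a
#' row sampled from a user-supplied reference matrix.  Counts are then
#' multiplied by the capture factor with stochastic rounding.
#'
#' @param sim A `tissue_simulation`.
#' @param model An [expression_model()].
#' @param seed Seed.
#' @param types Optional integer type per cell (overrides random draw).
#' @param mode `"sample"` (count law around the type mean), `"constant"`,
#'   or `"reference"` (rows of `reference` sampled per type).
#' @param reference Optional list of per-type count matrices for
#'   `mode = "reference"`.
#' @return The simulation with `profiles` (cells x genes counts), per-cell
#'   types and `gene_names` filled in.
#' @export
sample_expression <- function(sim, model, seed = 1L, types = NULL,
                              mode = c("sample", "constant", "reference"),
                              reference = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  nc <- nrow(sim$cells)
  G <- ncol(model$profiles)
  if (is.null(types))
    types <- sample.int(nrow(model$profiles), nc, replace = TRUE,
                        prob = model$freq)
  stopifnot(length(types) == nc)
  counts <- matrix(0L, nc, G, dimnames = list(sim$cells$cell_id,
                                              model$gene_names))
  for (i in seq_len(nc)) {
    mu <- model$profiles[types[i], ]
    base <- switch(mode,
      constant = round(mu),
      sample = if (is.null(model$dispersion)) stats::rpois(G, mu)
               else rnbinom(G, size = model$dispersion, mu = mu),
      reference = {
        rows <- reference[[types[i]]]
        rows[sample.int(nrow(rows), 1L), ]
      })
    counts[i, ] <- stochastic_round(base * model$capture_factor)
  }
  sim$cells$type <- as.integer(types)
  sim$profiles <- counts
  sim$gene_names <- model$gene_names
  sim$params$expression_seed <- seed
  sim
}

#' Place RNA molecules uniformly inside their cells
#'
#' For each cell and gene, the ground-truth count of molecules is placed
#' uniformly over the cell's mask voxels, with uniform sub-voxel jitter,
#' and converted to micrometres.  The per-cell placed counts equal the
#' sampled profiles exactly.
#'
#' @param sim A `tissue_simulation` with sampled `profiles`.
#' @param seed Seed.
#' @return The simulation with `cloud` ([rna_point_cloud()]) and
#'   `true_cell` (ground-truth cell id per molecule) filled in.
#' @export
place_rna <- function(sim, seed = 1L) {
  if (is.null(sim$profiles)) stop("sample expression profiles first")
  set.seed(seed)
  dm <- dim(sim$cell_mask)
  nd <- length(dm)
  vox <- split(seq_along(sim$cell_mask), sim$cell_mask)
  vox[["0"]] <- NULL
  per_cell <- rowSums(sim$profiles)
  total <- sum(per_cell)
  xs <- ys <- zs <- numeric(total)
  gene <- integer(total)
  true_cell <- integer(total)
  at <- 0L
  for (i in seq_len(nrow(sim$cells))) {
    cnt <- per_cell[i]
    if (cnt == 0L) next
    cid <- sim$cells$cell_id[i]
    vx <- vox[[as.character(cid)]]
    if (is.null(vx)) stop("cell ", cid, " has no mask voxels")
    pick <- vx[sample.int(length(vx), cnt, replace = TRUE)]
    co <- arrayInd(pick, dm)
    idx <- at + seq_len(cnt)
    xs[idx] <- (co[, 1L] - 1L + runif(cnt)) * sim$voxel_size[1L]
    ys[idx] <- (co[, 2L] - 1L + runif(cnt)) * sim$voxel_size[2L]
    zs[idx] <- if (nd == 3L)
      (co[, 3L] - 1L + runif(cnt)) * sim$voxel_size[3L] else 0
    gene[idx] <- rep(seq_len(ncol(sim$profiles)), sim$profiles[i, ])
    true_cell[idx] <- cid
    at <- at + cnt
  }
  perm <- sample.int(total)           # shuffle so ids carry no cell order
  sim$cloud <- rna_point_cloud(xs[perm], ys[perm], zs[perm], gene[perm],
                               gene_levels = sim$gene_names)
  sim$true_cell <- true_cell[perm]
  sim$params$placement_seed <- seed
  sim
}

#' Nucleus landmarks of a simulation
#'
#' @param sim A `tissue_simulation`.
#' @return A [nucleus_landmarks()] built from the simulation's nucleus
#'   raster (dropped nuclei absent).
#' @export
simulation_landmarks <- function(sim) {
  nucleus_landmarks(label_image = sim$nucleus_mask,
                    voxel_size = sim$voxel_size)
}

#' One-call benchmark fixtures
#'
#' Builds a complete, seeded study condition: geometry (`"grid"` with
#' checkerboard types or `"lshape"` with alternating interlocked types),
#' optional nucleus dropout, a marker-panel expression model, RNA
#' placement and a matched default configuration.
#'
#' @param scenario `"grid"` or `"lshape"`.
#' @param nx,ny Grid dimensions (grid scenario).
#' @param n_shapes Number of L-shaped cells (lshape scenario).
#' @param n_types,n_markers,marker_mean Marker panel design.
#' @param dropout Fraction of nuclei removed.
#' @param seed Master seed for all stochastic steps.
#' @return A list: `sim`, `cloud`, `landmarks`, `truth` (per-molecule
#'   cell id), `types` (per-cell), `model`, `config`.
#' @export
simulate_benchmark <- function(scenario = c("grid", "lshape"), nx = 10L,
                               ny = 10L, n_shapes = 32L, n_types = 2L,
                               n_markers = 5L, marker_mean = 4,
                               dropout = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  model <- marker_panel_model(n_types = n_types, n_markers = n_markers,
                              marker_mean = marker_mean)
  # D is set to the area-equivalent cell diameter of the scenario geometry;
  # R_max covers the farthest point of a cell from its nucleus.
  if (scenario == "grid") {
    sim <- simulate_grid(nx, ny, n_types = n_types)
    types <- sim$cells$type
    D <- 2 * sqrt(15^2 / pi)                  # ~16.9 um for a 15 um square
    cfg <- comseg_config(D = D, R_max = 15, seed = seed)
  } else {
    sim <- simulate_lshapes(n_shapes, seed = seed)
    types <- sim$cells$type
    D <- 2 * sqrt(4 * 15^2 / pi)              # ~33.9 um for 4 squares
    cfg <- comseg_config(D = D, R_max = 3.5 * 15, seed = seed)
  }
  if (dropout > 0) sim <- drop_nuclei(sim, dropout, seed = seed + 1L)
  sim <- sample_expression(sim, model, seed = seed + 2L, types = types)
  sim <- place_rna(sim, seed = seed + 3L)
  list(sim = sim, cloud = sim$cloud, landmarks = simulation_landmarks(sim),
       truth = sim$true_cell, types = types, model = model, config = cfg)
}
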