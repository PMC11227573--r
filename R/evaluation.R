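#' Ground truth of a simulation
#'
#' @param sim A `tissue_simulation` with placed RNAs.
#' @return An object of class `ground_truth`: `true_cell` per molecule and
#'   `cells_in_scope` (ids of cells retaining a nucleus; only these enter
#'   the evaluation metrics).
#' @export
ground_truth <- function(sim) {
  if (is.null(sim$true_cell)) stop("simulation has no placed RNAs")
  structure(list(true_cell = sim$true_cell,
                 cells_in_scope =
                   sim$cells$cell_id[sim$cells$has_nucleus]),
            class = "ground_truth")
}

#' Match ground-truth cells to predicted cells
#'
#' @param gt A [ground_truth()] object.
#' @param pred A `cell_assignment`.
#' @param mode `"by_nucleus"` matches each ground-truth cell to the
#'   predicted cell carrying the same nucleus id (the simulation case);
#'   `"by_overlap"` matches it to the predicted cell with the most shared
#'   molecules, ties toward the smaller predicted id.
#' @return Data frame `gt_cell`, `pred_cell` (`NA` when no predicted cell
#'   matches).
#' @export
match_cells <- function(gt, pred, mode = c("by_nucleus", "by_overlap")) {
  mode <- match.arg(mode)
  if (length(gt$true_cell) != length(pred$cell))
    stop("ground truth and prediction cover different molecule sets")
  gt_cells <- gt$cells_in_scope
  if (mode == "by_nucleus") {
    pc <- ifelse(gt_cells %in% pred$cells$cell_id, gt_cells, NA_integer_)
  } else {
    pc <- rep(NA_integer_, length(gt_cells))
    keep <- pred$cell > 0L
    if (any(keep)) {
      tab <- table(gt = gt$true_cell[keep], pred = pred$cell[keep])
      for (i in seq_along(gt_cells)) {
        r <- as.character(gt_cells[i])
        if (!r %in% rownames(tab)) next
        row <- tab[r, ]
        if (max(row) == 0L) next
        best <- as.integer(colnames(tab)[row == max(row)])
        pc[i] <- min(best)
      }
    }
  }
  data.frame(gt_cell = as.integer(gt_cells), pred_cell = as.integer(pc))
}

#' Per-cell Jaccard, wrongly-associated and missing RNA fractions
#'
#' For each in-scope ground-truth cell c with RNA set X_c, matched to the
#' predicted set Y_c: `J_c = |X ∩ Y| / |X ∪ Y|`, `WA_c = |Y \ X| / |Y|`
#' (false discovery) and `MS_c = |X \ Y| / |X|` (false negative).  Means
#' are unweighted over in-scope cells; cells with an empty predicted set
#' have undefined WA and are excluded from the WA mean (their MS is 1).
#'
#' @param gt A [ground_truth()].
#' @param pred A `cell_assignment`.
#' @param matching Optional [match_cells()] table (defaults to
#'   `by_nucleus`).
#' @return An object of class `evaluation_report` with `per_cell` (data
#'   frame of J, WA, MS per cell) and the means `jaccard`, `wa`, `ms`.
#' @export
jaccard_wa_ms <- function(gt, pred, matching = NULL) {
  if (is.null(matching)) matching <- match_cells(gt, pred, "by_nucleus")
  J <- WA <- MS <- numeric(nrow(matching))
  nx <- ny <- integer(nrow(matching))
  for (i in seq_len(nrow(matching))) {
    X <- which(gt$true_cell == matching$gt_cell[i])
    Y <- if (is.na(matching$pred_cell[i])) integer(0)
         else which(pred$cell == matching$pred_cell[i])
    nx[i] <- length(X); ny[i] <- length(Y)
    inter <- length(intersect(X, Y))
    J[i] <- if (length(X) + length(Y) > 0)
      inter / (length(X) + length(Y) - inter) else NA_real_
    WA[i] <- if (length(Y)) (length(Y) - inter) / length(Y) else NA_real_
    MS[i] <- if (length(X)) (length(X) - inter) / length(X) else NA_real_
  }
  per_cell <- data.frame(cell = matching$gt_cell,
                         pred_cell = matching$pred_cell,
                         J = J, WA = WA, MS = MS, n_true = nx, n_pred = ny)
  per_cell <- per_cell[per_cell$n_true > 0L, , drop = FALSE]
  structure(list(per_cell = per_cell,
                 jaccard = mean(per_cell$J),
                 wa = mean(per_cell$WA, na.rm = TRUE),
                 ms = mean(per_cell$MS)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report over %d cells: J = %.3f, WA = %.3f, MS = %.3f\n",
    nrow(x$per_cell), x$jaccard, x$wa, x$ms))
  invisible(x)
}

#' Nearest-nucleus (Watershed) baseline
#'
#' Assigns each molecule to the nucleus at minimal distance — the
#' distance to the nearest voxel of the nucleus region when a label image
#' is available, otherwise to the centroid — equivalent to a Voronoi
#' tessellation with the nuclei as markers.  Molecules beyond
#' `max_distance` of every nucleus stay unassigned.
#'
#' @param cloud An [rna_point_cloud()].
#' @param landmarks A [nucleus_landmarks()].
#' @param max_distance Maximum assignment distance (micrometres).
#' @return A `cell_assignment`.
#' @export
watershed_baseline <- function(cloud, landmarks, max_distance) {
  n <- length(cloud)
  cell <- integer(n)
  dist <- rep(NA_real_, n)
  q <- cbind(cloud$x, cloud$y, cloud$z)
  if (!is.null(landmarks$label_image)) {
    lm <- landmarks$label_image
    vs <- landmarks$voxel_size
    inside <- nucleus_membership(cloud, landmarks, comseg_config(D = 1))
    bnd <- region_boundary_voxels(lm)
    dat <- cbind((bnd$idx[, 1L] - 0.5) * vs[1L],
                 (bnd$idx[, 2L] - 0.5) * vs[2L],
                 if (ncol(bnd$idx) == 3L) (bnd$idx[, 3L] - 0.5) * vs[3L]
                 else 0)
    res <- radius_knn_cpp(dat, q, max_distance, 1L, FALSE)
    hit <- res$idx[, 1L] > 0L
    cell[hit] <- bnd$label[res$idx[hit, 1L]]
    dist[hit] <- res$dist[hit, 1L]
    cell[inside > 0L] <- inside[inside > 0L]
    dist[inside > 0L] <- 0
  } else {
    cen <- landmarks$centroids
    res <- radius_knn_cpp(cbind(cen$x, cen$y, cen$z), q, max_distance,
                          1L, FALSE)
    hit <- res$idx[, 1L] > 0L
    cell[hit] <- cen$nucleus_id[res$idx[hit, 1L]]
    dist[hit] <- res$dist[hit, 1L]
  }
  cen <- landmarks$centroids
  structure(list(cell = cell,
                 provenance = ifelse(cell > 0L, "graph-assigned",
                                     "unassigned"),
                 distance = dist,
                 cells = data.frame(cell_id = as.integer(cen$nucleus_id),
                                    x = cen$x, y = cen$y, z = cen$z,
                                    label = NA_integer_,
                                    provenance = "nearest-nucleus")),
            class = "cell_assignment")
}

# voxels of labelled regions that touch background (plus singleton
# regions), as index matrix + label vector
region_boundary_voxels <- function(lm) {
  dm <- dim(lm)
  nd <- length(dm)
  inner <- lm > 0L
  for (ax in seq_len(nd)) {
    sh <- shift_array(lm, ax, 1L) > 0L & shift_array(lm, ax, -1L) > 0L
    inner <- inner & sh
  }
  bound <- which(lm > 0L & !inner)
  list(idx = arrayInd(bound, dm), label = lm[bound])
}

shift_array <- function(a, axis, by) {
  dm <- dim(a)
  out <- array(0L, dm)
  src <- lapply(dm, seq_len)
  dst <- src
  if (by > 0) { dst[[axis]] <- (1L + by):dm[axis]; src[[axis]] <- 1L:(dm[axis] - by) }
  else { dst[[axis]] <- 1L:(dm[axis] + by); src[[axis]] <- (1L - by):dm[axis] }
  out_idx <- do.call(expand.grid, dst)
  src_idx <- do.call(expand.grid, src)
  out[as.matrix(out_idx)] <- a[as.matrix(src_idx)]
  out
}

#' Cosine cell-type calling against a reference
#'
#' Cells with more than `min_molecules` molecules are normalised and
#' classified to the reference type centroid at minimal cosine distance.
#'
#' @param profiles Cells x genes count matrix (rows named by cell id).
#' @param reference Type x gene centroid matrix; its columns must cover
#'   the profile genes.
#' @param normalization `"log_cpm"` (per-cell total scaling + `log1p`),
#'   `"pearson"` (approximate Pearson residuals) or `"none"`; applied to
#'   both sides.
#' @param min_molecules Cells with at most this many molecules are
#'   excluded (default 5).
#' @return Data frame `cell_id`, `type` (row index into `reference`),
#'   `cosine_distance`.
#' @export
cell_type_call <- function(profiles, reference,
                           normalization = c("log_cpm", "pearson", "none"),
                           min_molecules = 5L) {
  normalization <- match.arg(normalization)
  profiles <- as.matrix(profiles)
  reference <- as.matrix(reference)
  if (!all(colnames(profiles) %in% colnames(reference)))
    stop("reference does not cover all profile genes")
  reference <- reference[, colnames(profiles), drop = FALSE]
  keep <- which(rowSums(profiles) > min_molecules)
  if (!length(keep)) stop("no cell passes the molecule filter")
  P <- normalize_profiles(profiles[keep, , drop = FALSE], normalization)
  R <- normalize_profiles(reference, normalization)
  pn <- sqrt(rowSums(P^2)); rn <- sqrt(rowSums(R^2))
  zero <- pn == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero expression vector excluded")
    keep <- keep[!zero]; P <- P[!zero, , drop = FALSE]; pn <- pn[!zero]
  }
  cosd <- 1 - (P %*% t(R)) / outer(pn, pmax(rn, .Machine$double.eps))
  type <- apply(cosd, 1L, which.min)          # ties -> smallest type id
  data.frame(cell_id = as.integer(rownames(profiles))[keep],
             type = as.integer(type),
             cosine_distance = cosd[cbind(seq_along(type), type)])
}

normalize_profiles <- function(M, normalization) {
  switch(normalization,
    none = M,
    log_cpm = {
      tot <- pmax(rowSums(M), 1)
      log1p(M / tot * 1e4)
    },
    pearson = {
      tot <- pmax(rowSums(M), 1)
      gmean <- colSums(M) / sum(tot)
      mu <- outer(tot, gmean)
      theta <- 100
      (M - mu) / sqrt(mu + mu^2 / theta + .Machine$double.eps)
    })
}

#' Keep cells overlapping exactly one nucleus
#'
#' Ground-truth filter for membrane-derived segmentations: a nucleus is
#' attributed to a cell when their rasters overlap by at least
#' `min_overlap_px` pixels; only cells with exactly one attributed
#' nucleus are retained.
#'
#' @param cell_mask,nucleus_mask Congruent integer label rasters.
#' @param min_overlap_px Minimum overlap in pixels.
#' @return Integer vector of retained cell labels.
#' @export
gt_filter_one_nucleus <- function(cell_mask, nucleus_mask,
                                  min_overlap_px = 20L) {
  if (!identical(dim(cell_mask), dim(nucleus_mask)))
    stop("rasters must be congruent")
  both <- cell_mask > 0L & nucleus_mask > 0L
  if (!any(both)) return(integer(0))
  tab <- table(cell = cell_mask[both], nucleus = nucleus_mask[both])
  n_nuc <- apply(tab >= min_overlap_px, 1L, sum)
  sort(as.integer(names(n_nuc)[n_nuc == 1L]))
}
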