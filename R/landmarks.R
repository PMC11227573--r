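#' Nucleus landmarks
#'
#' Nuclei are the spatial prior of the pipeline.  They can be supplied as
#' an integer label image (2D matrix or 3D array; label 0 is background)
#' with a physical voxel size, as a centroid table in micrometres, or both.
#' When a raster is given, centroids are computed as label-region means of
#' voxel centres.
#'
#' @param label_image Integer 2D matrix or 3D array of nucleus labels, or
#'   `NULL`.
#' @param voxel_size Micrometres per voxel, one value per axis (recycled);
#'   required with `label_image`.
#' @param centroids Data frame with columns `nucleus_id`, `x`, `y` and
#'   optionally `z` (micrometres), or `NULL`.
#'
#' @return An object of class `nucleus_landmarks` with elements
#'   `label_image`, `voxel_size`, `centroids`, `nucleus_ids`.
#' @export
nucleus_landmarks <- function(label_image = NULL, voxel_size = NULL,
                              centroids = NULL) {
  if (is.null(label_image) && is.null(centroids))
    stop("provide a label image or a centroid table")
  if (!is.null(label_image)) {
    if (is.null(voxel_size)) stop("'voxel_size' is required with a raster")
    nd <- length(dim(label_image))
    if (!nd %in% c(2L, 3L)) stop("'label_image' must be 2D or 3D")
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    storage.mode(label_image) <- "integer"
    if (any(label_image < 0L)) stop("negative labels are not allowed")
    comp <- raster_centroids(label_image, voxel_size)
    if (is.null(centroids)) centroids <- comp
    else {
      centroids <- normalize_centroids(centroids)
      m <- match(comp$nucleus_id, centroids$nucleus_id)
      if (anyNA(m)) stop("raster labels missing from centroid table")
      d <- sqrt((comp$x - centroids$x[m])^2 + (comp$y - centroids$y[m])^2 +
                  (comp$z - centroids$z[m])^2)
      if (any(d > max(voxel_size)))
        stop("centroid table disagrees with raster centroids by > 1 voxel")
    }
  } else {
    centroids <- normalize_centroids(centroids)
  }
  centroids <- normalize_centroids(centroids)
  if (anyDuplicated(centroids$nucleus_id))
    stop("duplicate nucleus ids in centroid table")
  if (any(centroids$nucleus_id <= 0))
    stop("nucleus ids must be positive integers")
  structure(list(label_image = label_image, voxel_size = voxel_size,
                 centroids = centroids,
                 nucleus_ids = as.integer(centroids$nucleus_id)),
            class = "nucleus_landmarks")
}

normalize_centroids <- function(tab) {
  tab <- as.data.frame(tab)
  if (!all(c("nucleus_id", "x", "y") %in% names(tab)))
    stop("centroid table needs columns nucleus_id, x, y")
  if (!"z" %in% names(tab)) tab$z <- 0
  data.frame(nucleus_id = as.integer(tab$nucleus_id),
             x = as.numeric(tab$x), y = as.numeric(tab$y),
             z = as.numeric(tab$z))
}

raster_centroids <- function(label_image, voxel_size) {
  idx <- which(label_image > 0L)
  if (!length(idx))
    return(data.frame(nucleus_id = integer(), x = numeric(),
                      y = numeric(), z = numeric()))
  lab <- label_image[idx]
  dm <- dim(label_image)
  ai <- arrayInd(idx, dm)
  if (ncol(ai) == 2L) ai <- cbind(ai, 1L)
  # voxel centre of index i is (i - 0.5) * voxel_size
  xs <- (ai[, 1L] - 0.5) * voxel_size[1L]
  ys <- (ai[, 2L] - 0.5) * voxel_size[2L]
  zs <- if (length(dm) == 3L) (ai[, 3L] - 0.5) * voxel_size[3L] else rep(0, length(idx))
  data.frame(nucleus_id = as.integer(sort(unique(lab))),
             x = as.numeric(tapply(xs, lab, mean)),
             y = as.numeric(tapply(ys, lab, mean)),
             z = as.numeric(tapply(zs, lab, mean)))
}

#' @export
print.nucleus_landmarks <- function(x, ...) {
  cat(sprintf("nucleus_landmarks: %d nuclei (%s)\n", length(x$nucleus_ids),
              if (is.null(x$label_image)) "centroids only" else "label image"))
  invisible(x)
}

#' Read nucleus landmarks from a TIFF label image or a centroid table
#'
#' @param path Path to a TIFF (2D image or 3D stack of integer labels) or
#'   a CSV with columns `nucleus_id`, `x`, `y` and optionally `z`.
#' @param voxel_size Micrometres per voxel (per axis, recycled); required
#'   for TIFF input.
#' @return A [nucleus_landmarks()] object in physical micrometre
#'   coordinates.
#' @export
read_nucleus_landmarks <- function(path, voxel_size = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(voxel_size)) stop("'voxel_size' is required for TIFF input")
    nucleus_landmarks(label_image = read_label_tiff(path),
                      voxel_size = voxel_size)
  } else {
    nucleus_landmarks(centroids = read.csv(path))
  }
}

# Label rasters are stored with dim1 = x, dim2 = y; TIFF stores row =
# image y, so slices are transposed on the way in and out.  Labels are
# written as 16-bit grey.
read_label_tiff <- function(path) {
  sl <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  sl <- lapply(sl, function(m) t(round(m)))
  if (length(sl) == 1L) {
    m <- sl[[1L]]
    storage.mode(m) <- "integer"
    m
  } else {
    a <- array(0L, dim = c(dim(sl[[1L]]), length(sl)))
    for (k in seq_along(sl)) a[, , k] <- as.integer(sl[[k]])
    a
  }
}

write_label_tiff <- function(label_image, path) {
  if (max(label_image) > 65535L) stop("labels exceed 16-bit range")
  nd <- length(dim(label_image))
  sl <- if (nd == 2L) list(label_image)
        else lapply(seq_len(dim(label_image)[3L]),
                    function(k) label_image[, , k])
  sl <- lapply(sl, function(m) t(m) / 65535)
  tiff::writeTIFF(sl, path, bits.per.sample = 16L)
  invisible(path)
}

# Integer nucleus id per molecule (0 = none).  With a raster the molecule's
# voxel is looked up; with centroids only, molecules within
# cfg$nucleus_radius of a centroid belong to the nearest such centroid.
nucleus_membership <- function(cloud, landmarks, cfg) {
  n <- length(cloud)
  if (!is.null(landmarks$label_image)) {
    dm <- dim(landmarks$label_image)
    vs <- landmarks$voxel_size
    ix <- pmin(pmax(ceiling(cloud$x / vs[1L]), 1L), dm[1L])
    iy <- pmin(pmax(ceiling(cloud$y / vs[2L]), 1L), dm[2L])
    if (length(dm) == 3L) {
      iz <- pmin(pmax(ceiling(cloud$z / vs[3L]), 1L), dm[3L])
      lin <- ix + dm[1L] * (iy - 1L) + dm[1L] * dm[2L] * (iz - 1L)
    } else {
      lin <- ix + dm[1L] * (iy - 1L)
    }
    as.integer(landmarks$label_image[lin])
  } else {
    cen <- landmarks$centroids
    q <- scaled_coords(cloud, cfg)
    dat <- cbind(cen$x, cen$y, cen$z * cfg$z_anisotropy)
    res <- radius_knn_cpp(dat, q, cfg$nucleus_radius, 1L, FALSE)
    out <- integer(n)
    hit <- res$idx[, 1L] > 0L
    out[hit] <- as.integer(cen$nucleus_id[res$idx[hit, 1L]])
    out
  }
}
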