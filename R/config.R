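#' Pipeline configuration
#'
#' Bundles every tunable parameter of the segmentation pipeline.  Only two
#' parameters are normally adjusted per dataset: the mean cell diameter `D`
#' and the maximum cell radius `R_max`, both in micrometres.  Three radii
#' are derived from `D` and recomputed whenever `D` changes (see
#' [update_config()]): `R_pe = D/2` (neighbourhood for proximity-weighted
#' expression), `R_knn = D/4` (maximum edge length of the molecule graph)
#' and `R_centroid = D/2` (neighbourhood for centroid label votes).
#'
#' @param D Mean cell diameter in micrometres (> 0).
#' @param R_max Maximum cell radius in micrometres; molecules farther than
#'   this geodesic distance from every same-label centroid stay unassigned.
#'   Defaults to one diameter.
#' @param K_pe Neighbour cap for the proximity-weighted expression vector.
#' @param K_knn Neighbour count of the molecule KNN graph.
#' @param K_centroid Neighbours used when voting a profile label for a
#'   nucleus centroid without nuclear RNAs.
#' @param K_small Neighbours used when relabelling communities too small to
#'   cluster; defaults to `K_knn`.
#' @param leiden_resolution Resolution of the Leiden clustering of
#'   community expression vectors.
#' @param pca `"auto"` applies PCA to community expression vectors when the
#'   panel exceeds `pca_gene_threshold` genes; `"on"`/`"off"` force it.
#' @param pca_components Maximum number of principal components retained.
#' @param pca_gene_threshold Panel size above which `"auto"` enables PCA.
#' @param K_expr Neighbour count of the cosine KNN graph in expression
#'   space fed to Leiden.
#' @param min_community_size Communities with fewer RNA molecules than this
#'   are not clustered directly; they inherit the majority label of nearby
#'   labelled molecules.
#' @param z_anisotropy Multiplier applied to z coordinates before any
#'   distance computation (1 leaves z isotropic with xy).
#' @param nucleus_radius Radius (micrometres) of the sphere used to decide
#'   nucleus membership when landmarks are centroid-only; ignored when a
#'   label image is available.  Defaults to `D/4`.
#' @param label_constrained_paths If `TRUE` (default) geodesic assignment
#'   paths may only traverse molecules carrying the source centroid's
#'   profile label.
#' @param normalization Normalisation applied to community expression
#'   vectors before clustering: `"median_log1p"` (total-sum scaling to the
#'   median community total, then `log1p`) or `"none"`.
#' @param seed Integer seed propagated to every stochastic step (Louvain
#'   sweep order, Leiden).
#'
#' @return An object of class `comseg_config`.
#' @seealso [update_config()], [comseg_segment()]
#' @export
#' @examples
#' cfg <- comseg_config(D = 15, R_max = 15)
#' cfg$R_knn  # 3.75
comseg_config <- function(D, R_max = D, K_pe = 40L, K_knn = 10L,
                          K_centroid = 15L, K_small = K_knn,
                          leiden_resolution = 1, pca = c("auto", "on", "off"),
                          pca_components = 20L, pca_gene_threshold = 30L,
                          K_expr = 15L, min_community_size = 3L,
                          z_anisotropy = 1, nucleus_radius = D / 4,
                          label_constrained_paths = TRUE,
                          normalization = c("median_log1p", "none"),
                          seed = 1L) {
  pca <- match.arg(pca)
  normalization <- match.arg(normalization)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("'D' must be a single positive number (micrometres)")
  if (!is.numeric(R_max) || length(R_max) != 1L || R_max < D / 2)
    stop("'R_max' must be at least D/2")
  ks <- c(K_pe = K_pe, K_knn = K_knn, K_centroid = K_centroid,
          K_small = K_small, K_expr = K_expr)
  if (any(ks < 1)) stop("all K parameters must be >= 1")
  if (z_anisotropy <= 0) stop("'z_anisotropy' must be positive")
  if (min_community_size < 1) stop("'min_community_size' must be >= 1")
  cfg <- list(D = D, R_max = R_max,
              K_pe = as.integer(K_pe), K_knn = as.integer(K_knn),
              K_centroid = as.integer(K_centroid),
              K_small = as.integer(K_small),
              R_pe = D / 2, R_knn = D / 4, R_centroid = D / 2,
              leiden_resolution = leiden_resolution, pca = pca,
              pca_components = as.integer(pca_components),
              pca_gene_threshold = as.integer(pca_gene_threshold),
              K_expr = as.integer(K_expr),
              min_community_size = as.integer(min_community_size),
              z_anisotropy = z_anisotropy, nucleus_radius = nucleus_radius,
              label_constrained_paths = isTRUE(label_constrained_paths),
              normalization = normalization, seed = as.integer(seed))
  class(cfg) <- "comseg_config"
  cfg
}

#' Update a configuration, recomputing derived radii
#'
#' Fields passed by name replace the current values; if `D` changes, the
#' derived radii `R_pe`, `R_knn`, `R_centroid` (and the default
#' `nucleus_radius`) are recomputed from the new diameter.
#'
#' @param cfg A [comseg_config()] object.
#' @param ... Named fields to replace.
#' @return The updated `comseg_config`.
#' @export
update_config <- function(cfg, ...) {
  stopifnot(inherits(cfg, "comseg_config"))
  new <- list(...)
  bad <- setdiff(names(new), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (any(names(new) %in% c("R_pe", "R_knn", "R_centroid")))
    stop("derived radii cannot be set directly; set 'D'")
  keep_nr <- !is.null(new$nucleus_radius)
  args <- cfg[setdiff(names(cfg), c("R_pe", "R_knn", "R_centroid"))]
  args[names(new)] <- new
  if (!is.null(new$D) && !keep_nr) args$nucleus_radius <- new$D / 4
  do.call(comseg_config, args)
}

#' @export
print.comseg_config <- function(x, ...) {
  cat("comseg configuration\n")
  cat(sprintf("  D = %g um, R_max = %g um\n", x$D, x$R_max))
  cat(sprintf("  derived radii: R_pe = %g, R_knn = %g, R_centroid = %g um\n",
              x$R_pe, x$R_knn, x$R_centroid))
  cat(sprintf("  K: pe %d, knn %d, centroid %d, small %d, expr %d\n",
              x$K_pe, x$K_knn, x$K_centroid, x$K_small, x$K_expr))
  cat(sprintf("  leiden resolution %g, pca %s, seed %d\n",
              x$leiden_resolution, x$pca, x$seed))
  invisible(x)
}
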