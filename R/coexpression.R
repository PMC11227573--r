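#' Proximity-weighted expression vector of one molecule
#'
#' For an anchor molecule at position x, the local expression of gene g is
#' the sum over its neighbours y carrying gene g (at most `K_pe`
#' neighbours, all within `R_pe = D/2`) of the linearly decaying kernel
#' `(R_pe - ||x - y||) / R_pe`.  The anchor is excluded from its own
#' neighbourhood, and ties at the K-th neighbour distance are broken by
#' molecule index.
#'
#' @param cloud An [rna_point_cloud()].
#' @param anchor Index of the anchor molecule (row of `cloud`).
#' @param cfg A [comseg_config()].
#' @return Numeric gene-length vector, named by gene.
#' @export
compute_pe_vector <- function(cloud, anchor, cfg) {
  stopifnot(anchor >= 1L, anchor <= length(cloud))
  compute_pe_matrix(cloud, cfg, rows = anchor)[1L, ]
}

#' Proximity-weighted expression matrix
#'
#' Stacks the proximity-weighted expression vectors of all molecules into
#' an N_molecules x N_genes matrix; row i equals
#' `compute_pe_vector(cloud, i, cfg)`.
#'
#' @inheritParams compute_pe_vector
#' @param rows Optional subset of molecule indices to compute (used
#'   internally; the result then has `length(rows)` rows).
#' @return Dense numeric matrix with genes as named columns.
#' @export
compute_pe_matrix <- function(cloud, cfg, rows = NULL) {
  n <- length(cloud)
  if (n == 0L) stop("empty point cloud")
  g <- length(cloud$gene_names)
  co <- scaled_coords(cloud, cfg)
  if (is.null(rows)) {
    res <- radius_knn_cpp(co, co, cfg$R_pe, cfg$K_pe, TRUE)
    m <- n
  } else {
    res <- radius_knn_cpp(co, co[rows, , drop = FALSE], cfg$R_pe,
                          cfg$K_pe + 1L, FALSE)
    # self appears among the neighbours of its own query: drop it, then
    # keep the K_pe nearest of the remainder
    for (r in seq_along(rows)) {
      keepi <- which(res$idx[r, ] > 0L & res$idx[r, ] != rows[r])
      keepi <- keepi[seq_len(min(cfg$K_pe, length(keepi)))]
      idx <- rep(0L, cfg$K_pe + 1L)
      dst <- rep(NA_real_, cfg$K_pe + 1L)
      idx[seq_along(keepi)] <- res$idx[r, keepi]
      dst[seq_along(keepi)] <- res$dist[r, keepi]
      res$idx[r, ] <- idx
      res$dist[r, ] <- dst
    }
    m <- length(rows)
  }
  keep <- which(res$idx > 0L)
  pe <- matrix(0, m, g, dimnames = list(NULL, cloud$gene_names))
  if (length(keep)) {
    ri <- ((keep - 1L) %% m) + 1L
    gi <- cloud$gene[res$idx[keep]]
    w <- (cfg$R_pe - res$dist[keep]) / cfg$R_pe
    li <- ri + (gi - 1L) * m              # linear index into pe
    agg <- rowsum(w, li)
    pe[as.integer(rownames(agg))] <- agg
  }
  pe
}

#' Gene-gene co-expression matrix
#'
#' Pearson correlation of the columns of the proximity-weighted expression
#' matrix.  Genes whose column has zero variance (never locally expressed)
#' carry no co-expression evidence: their rows, columns and diagonal
#' entries are set to 0.
#'
#' @param pe Proximity-weighted expression matrix from
#'   [compute_pe_matrix()] (>= 2 rows).
#' @return Symmetric gene x gene matrix with entries in \[-1, 1\], of
#'   class `coexpression_matrix`.
#' @export
compute_coexpression <- function(pe) {
  if (nrow(pe) < 2L)
    stop("correlation is undefined for a single-row expression matrix")
  sds <- apply(pe, 2L, stats::sd)
  W <- suppressWarnings(stats::cor(pe))
  degen <- !is.finite(sds) | sds == 0
  W[degen, ] <- 0
  W[, degen] <- 0
  W[!is.finite(W)] <- 0
  structure(W, class = c("coexpression_matrix", "matrix", "array"))
}

#' Import an externally computed co-expression matrix
#'
#' Accepts a gene x gene table (for instance derived from scRNA-seq) and
#' aligns it to the run's gene vocabulary.
#'
#' @param tab Square numeric matrix or data frame with gene names on both
#'   dimensions.
#' @param gene_names Gene vocabulary of the run; every vocabulary gene
#'   must be present in `tab`.
#' @param tol Symmetry tolerance.
#' @return A `coexpression_matrix` aligned to `gene_names`.
#' @export
import_external_coexpression <- function(tab, gene_names, tol = 1e-8) {
  W <- as.matrix(tab)
  if (nrow(W) != ncol(W)) stop("co-expression table must be square")
  if (is.null(rownames(W)) || is.null(colnames(W)))
    stop("co-expression table needs gene names on rows and columns")
  miss <- setdiff(gene_names, rownames(W))
  if (length(miss))
    stop("co-expression table is missing gene(s): ",
         paste(miss, collapse = ", "))
  W <- W[gene_names, gene_names, drop = FALSE]
  if (max(abs(W - t(W))) > tol)
    stop("co-expression table is not symmetric within tolerance")
  W <- (W + t(W)) / 2
  structure(W, class = c("coexpression_matrix", "matrix", "array"))
}
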