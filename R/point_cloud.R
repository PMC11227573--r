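#' RNA point cloud
#'
#' The universal input of the pipeline: one row per detected RNA molecule
#' with physical coordinates in micrometres and a gene identity drawn from
#' a fixed, ordered gene vocabulary.  2D data are represented as 3D with
#' z identically zero.
#'
#' @param x,y,z Numeric coordinate vectors (micrometres).  `z` may be
#'   `NULL` for 2D data.
#' @param gene Gene identity per molecule: character, factor, or integer
#'   index into `gene_levels`.
#' @param gene_levels Optional character vector fixing the gene vocabulary
#'   and its order; defaults to first-appearance order of `gene`.
#' @param ids Optional unique integer molecule identifiers (default
#'   `seq_len(n)`).
#'
#' @return An object of class `rna_point_cloud` with elements `x`, `y`,
#'   `z`, `gene` (integer index), `gene_names`, `ids`.
#' @export
#' @examples
#' cl <- rna_point_cloud(x = c(0, 1), y = c(0, 0), gene = c("a", "b"))
#' cl$gene_names
rna_point_cloud <- function(x, y, z = NULL, gene, gene_levels = NULL,
                            ids = NULL) {
  n <- length(x)
  if (length(y) != n || length(gene) != n)
    stop("'x', 'y' and 'gene' must have equal length")
  if (is.null(z)) z <- rep(0, n)
  if (length(z) != n) stop("'z' must match the length of 'x'")
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("non-finite coordinate at row ", bad[1L])
  if (is.numeric(gene) && is.null(gene_levels))
    stop("integer 'gene' requires 'gene_levels'")
  if (is.numeric(gene)) {
    gi <- as.integer(gene)
    if (any(gi < 1L | gi > length(gene_levels)))
      stop("gene index out of range of 'gene_levels'")
  } else {
    gene <- as.character(gene)
    if (is.null(gene_levels)) gene_levels <- unique(gene)
    if (!all(gene %in% gene_levels))
      stop("gene(s) not in vocabulary: ",
           paste(setdiff(gene, gene_levels), collapse = ", "))
    gi <- match(gene, gene_levels)
  }
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  structure(list(x = x, y = y, z = z, gene = gi,
                 gene_names = as.character(gene_levels), ids = ids),
            class = "rna_point_cloud")
}

#' @export
print.rna_point_cloud <- function(x, ...) {
  cat(sprintf("rna_point_cloud: %d molecules, %d genes, %s\n",
              length(x$x), length(x$gene_names),
              if (all(x$z == 0)) "2D" else "3D"))
  invisible(x)
}

#' @export
length.rna_point_cloud <- function(x) length(x$x)

# n x 3 coordinate matrix with the z-anisotropy factor applied; all
# distance computations in the package go through this.
scaled_coords <- function(cloud, cfg = NULL) {
  zf <- if (is.null(cfg)) 1 else cfg$z_anisotropy
  cbind(cloud$x, cloud$y, cloud$z * zf)
}

#' Read an RNA point cloud from a delimited table
#'
#' @param path Path to a CSV (or TSV) file with one row per molecule.
#' @param columns Named character vector mapping the roles `x`, `y`, `z`,
#'   `gene` to column names in the file.  A missing or absent `z` column
#'   yields a 2D cloud with z = 0.
#' @param gene_levels Optional gene vocabulary (order-fixing); default is
#'   first-appearance order.
#' @param sep Field separator; guessed from the file extension by default.
#' @return An [rna_point_cloud()].
#' @export
read_point_cloud <- function(path,
                             columns = c(x = "x", y = "y", z = "z",
                                         gene = "gene"),
                             gene_levels = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c("x", "y", "gene")
  for (role in need) {
    cn <- columns[[role]]
    if (is.null(cn) || !cn %in% names(tab))
      stop("missing required column '", if (is.null(cn)) role else cn,
           "' in ", path)
  }
  zcol <- columns[["z"]]
  z <- if (!is.null(zcol) && !is.na(zcol) && zcol %in% names(tab))
    as.numeric(tab[[zcol]]) else NULL
  for (role in c("x", "y")) {
    v <- tab[[columns[[role]]]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !anyNA(v))
        stop("non-numeric values in column '", columns[[role]], "'")
      tab[[columns[[role]]]] <- v2
    }
  }
  rna_point_cloud(x = tab[[columns[["x"]]]], y = tab[[columns[["y"]]]],
                  z = z, gene = tab[[columns[["gene"]]]],
                  gene_levels = gene_levels,
                  ids = if ("id" %in% names(tab)) tab[["id"]] else NULL)
}
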