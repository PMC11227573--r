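#' Write segmentation results to disk
#'
#' Persists (a) the per-molecule assignment table
#' (`assignment.csv`: id, x, y, z, gene, cell_id), (b) the sparse cell x
#' gene count matrix in MatrixMarket format (`profiles.mtx` with
#' `cells.txt` and `genes.txt` index files) and (c) a JSON run manifest
#' recording the full configuration including the seed.
#'
#' @param assignment A `cell_assignment`.
#' @param profiles The matching [profiles_from_assignment()] matrix.
#' @param out_dir Output directory (created if missing).
#' @param cloud The [rna_point_cloud()].
#' @param cfg The [comseg_config()] used for the run.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(assignment, profiles, out_dir, cloud, cfg) {
  assigned <- unique(assignment$cell[assignment$cell > 0L])
  if (!all(assigned %in% as.integer(rownames(profiles))))
    stop("assignment and profiles refer to different cell ids")
  if (!all(as.integer(rownames(profiles)) %in% assignment$cells$cell_id))
    stop("assignment and profiles refer to different cell ids")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(id = cloud$ids, x = cloud$x, y = cloud$y,
                       z = cloud$z,
                       gene = cloud$gene_names[cloud$gene],
                       cell_id = assignment$cell),
            file.path(out_dir, "assignment.csv"), row.names = FALSE)
  Matrix::writeMM(as(profiles, "CsparseMatrix"),
                  file.path(out_dir, "profiles.mtx"))
  writeLines(rownames(profiles), file.path(out_dir, "cells.txt"))
  writeLines(colnames(profiles), file.path(out_dir, "genes.txt"))
  manifest <- unclass(cfg)
  manifest$package_version <- as.character(utils::packageVersion("comseg"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read back persisted segmentation results
#'
#' @param out_dir Directory written by [write_results()].
#' @return List with `assignment` (data frame), `profiles` (sparse
#'   matrix with cell/gene dimnames) and `manifest` (list).
#' @export
read_results <- function(out_dir) {
  tab <- read.csv(file.path(out_dir, "assignment.csv"))
  prof <- as(Matrix::readMM(file.path(out_dir, "profiles.mtx")),
             "CsparseMatrix")
  dimnames(prof) <- list(readLines(file.path(out_dir, "cells.txt")),
                         readLines(file.path(out_dir, "genes.txt")))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(assignment = tab, profiles = prof, manifest = manifest)
}
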