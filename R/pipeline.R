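#' Run the full segmentation pipeline
#'
#' Chains the five stages: proximity-weighted expression, co-expression
#' matrix, landmark-merged KNN graph, constrained Louvain partition,
#' Leiden clustering of community expression vectors, centroid labelling
#' and label-constrained geodesic assignment.
#'
#' @param cloud An [rna_point_cloud()].
#' @param landmarks A [nucleus_landmarks()] object.
#' @param cfg A [comseg_config()].
#' @param W Optional externally supplied `coexpression_matrix` (e.g. from
#'   [import_external_coexpression()]); computed from the cloud when
#'   `NULL`.
#' @return An object of class `comseg_result`: `assignment`
#'   ([geodesic_assign()] output), `profiles` (cells x genes counts),
#'   `domain_map`, `partition`, `W`, `pe`, `centroids`, `config`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_benchmark("grid", nx = 3, ny = 3, seed = 7)
#' res <- comseg_segment(sim$cloud, sim$landmarks, sim$config)
#' res$assignment
#' }
comseg_segment <- function(cloud, landmarks, cfg, W = NULL) {
  pe <- compute_pe_matrix(cloud, cfg)
  if (is.null(W)) W <- compute_coexpression(pe)
  else W <- import_external_coexpression(W, cloud$gene_names)
  graph <- build_graph(cloud, W, cfg)
  graph <- merge_landmark_nodes(graph, landmarks, cloud, cfg)
  partition <- louvain_with_priors(graph, cfg)
  ce <- community_expression(partition, pe, cloud, cfg)
  map <- cluster_communities(ce, cfg)
  map <- relabel_small_communities(map, partition, cloud, cfg)
  centroids <- label_centroids(map, landmarks, cloud, graph, cfg)
  assignment <- geodesic_assign(graph, centroids, map, cfg)
  profiles <- profiles_from_assignment(assignment, cloud)
  structure(list(assignment = assignment, profiles = profiles,
                 domain_map = map, partition = partition, W = W, pe = pe,
                 centroids = centroids, graph = graph, config = cfg),
            class = "comseg_result")
}

#' @export
print.comseg_result <- function(x, ...) {
  a <- x$assignment
  assigned <- sum(a$cell > 0L)
  cat("comseg_result\n")
  cat(sprintf("  cells: %d   molecules: %d assigned / %d unassigned\n",
              nrow(a$cells), assigned, sum(a$cell == 0L)))
  cat(sprintf("  communities: %d (Q = %.3f), profile labels: %d\n",
              x$partition$n_communities, x$partition$Q,
              x$domain_map$n_labels))
  cat(sprintf("  mean molecules per non-empty cell: %.1f\n",
              if (assigned) assigned / sum(Matrix::rowSums(x$profiles) > 0)
              else 0))
  invisible(x)
}
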