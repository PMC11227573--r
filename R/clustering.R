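#' Community expression vectors
#'
#' The expression vector of a community is the arithmetic mean of the
#' proximity-weighted expression vectors of its member molecules
#' (molecules absorbed into a cell node contribute their own rows).
#' Communities holding no molecule (bare cell nodes) have no expression
#' vector and are omitted.
#'
#' @param partition A [louvain_with_priors()] result.
#' @param pe Proximity-weighted expression matrix (one row per molecule).
#' @param cloud The [rna_point_cloud()] the partition was computed on.
#' @param cfg A [comseg_config()].
#' @return An object of class `community_expression`: `expr` (communities
#'   x genes), `size` (number of member RNAs), `centroid` (mean molecule
#'   position per community) and `comm_id`.
#' @export
community_expression <- function(partition, pe, cloud, cfg) {
  memb <- partition$mol_membership
  if (length(memb) != nrow(pe))
    stop("PE matrix and partition refer to different molecule sets")
  expr_sum <- rowsum(pe, memb)
  size <- as.integer(table(memb)[rownames(expr_sum)])
  cen <- rowsum(scaled_coords(cloud, cfg), memb) / size
  structure(list(expr = expr_sum / size, size = size,
                 centroid = cen,
                 comm_id = as.integer(rownames(expr_sum))),
            class = "community_expression")
}

#' Cluster community expression vectors into transcriptomic profiles
#'
#' Communities with at least `min_community_size` RNAs are normalised
#' (total-sum scaling to the median community total followed by `log1p`),
#' optionally reduced with PCA, embedded in a cosine KNN graph and
#' clustered with Leiden at `cfg$leiden_resolution` (seeded).  Each
#' cluster becomes a transcriptomic profile label; smaller communities are
#' left unlabelled here and handled by [relabel_small_communities()].
#'
#' @param ce A [community_expression()] result.
#' @param cfg A [comseg_config()].
#' @return An object of class `domain_map` with per-community labels
#'   (`NA` for communities below the size threshold) and cluster centroids
#'   in expression space.
#' @export
cluster_communities <- function(ce, cfg) {
  eligible <- which(ce$size >= cfg$min_community_size)
  if (!length(eligible))
    stop("no community reaches the clustering size threshold; ",
         "consider increasing the cell diameter D")
  X <- ce$expr[eligible, , drop = FALSE]
  if (cfg$normalization == "median_log1p") {
    tot <- rowSums(X)
    target <- stats::median(tot[tot > 0])
    sf <- ifelse(tot > 0, tot / target, 1)
    X <- log1p(X / sf)
  }
  G <- ncol(X)
  use_pca <- switch(cfg$pca, on = TRUE, off = FALSE,
                    auto = G > cfg$pca_gene_threshold)
  if (use_pca && nrow(X) > 2L) {
    ncomp <- min(cfg$pca_components, G - 1L, nrow(X) - 1L)
    X <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[,
            seq_len(ncomp), drop = FALSE]
  }
  labs <- leiden_expression_clusters(X, cfg)
  comm_label <- rep(NA_integer_, length(ce$comm_id))
  comm_label[eligible] <- labs
  cen <- rowsum(ce$expr[eligible, , drop = FALSE], labs) /
    as.integer(table(labs))
  structure(list(comm_id = ce$comm_id, comm_label = comm_label,
                 cluster_centroids = cen, n_labels = max(labs)),
            class = "domain_map")
}

# Leiden (modularity objective, seeded) over a cosine-similarity graph.
# Up to `dense_limit` vectors the graph is the full positively weighted
# similarity graph, which is robust against carving homogeneous groups
# into slivers; beyond that it is sparsified to the K_expr nearest
# neighbours per node (weights kept).
leiden_expression_clusters <- function(X, cfg, dense_limit = 2000L) {
  n <- nrow(X)
  if (n == 1L) return(1L)
  nrm <- sqrt(rowSums(X^2))
  U <- X / ifelse(nrm > 0, nrm, 1)
  S <- U %*% t(U)
  S[S < 0] <- 0
  diag(S) <- 0
  if (n > dense_limit) {
    k <- min(cfg$K_expr, n - 1L)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(S[i, ], decreasing = TRUE)[seq_len(k)]
      keep[i, nb] <- TRUE
    }
    S[!(keep | t(keep))] <- 0
  }
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  set.seed(cfg$seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = cfg$leiden_resolution,
                               n_iterations = 5L)
  memb <- igraph::membership(cl)
  as.integer(match(memb, sort(unique(memb))))
}

#' Relabel communities too small to cluster
#'
#' Each unlabelled community receives the majority profile label among the
#' `K_small` labelled molecules spatially nearest to its centroid; ties
#' are broken toward the label of the single nearest labelled molecule.
#'
#' @param map A [cluster_communities()] result.
#' @param partition The [louvain_with_priors()] partition.
#' @param cloud The [rna_point_cloud()].
#' @param cfg A [comseg_config()].
#' @return The completed `domain_map`, now carrying `mol_label`: a profile
#'   label for every molecule.
#' @export
relabel_small_communities <- function(map, partition, cloud, cfg) {
  memb <- partition$mol_membership
  mol_label <- map$comm_label[match(memb, map$comm_id)]
  labelled <- which(!is.na(mol_label))
  if (!length(labelled))
    stop("no labelled molecules available for relabelling")
  todo <- which(is.na(map$comm_label))
  if (length(todo)) {
    co <- scaled_coords(cloud, cfg)
    dat <- co[labelled, , drop = FALSE]
    for (t in todo) {
      members <- which(memb == map$comm_id[t])
      q <- matrix(colMeans(co[members, , drop = FALSE]), 1L)
      span <- sqrt(max(rowSums(sweep(dat, 2L, as.numeric(q))^2))) + 1e-9
      res <- radius_knn_cpp(dat, q, span, cfg$K_small, FALSE)
      hit <- res$idx[1L, res$idx[1L, ] > 0L]
      votes <- mol_label[labelled[hit]]
      tab <- table(votes)
      win <- as.integer(names(tab)[tab == max(tab)])
      lab <- if (length(win) > 1L) votes[1L] else win
      map$comm_label[t] <- lab
      mol_label[members] <- lab
    }
  }
  map$mol_label <- mol_label
  map
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("domain_map: %d communities, %d profile labels%s\n",
              length(x$comm_id), x$n_labels,
              if (is.null(x$mol_label)) " (small communities pending)"
              else ""))
  invisible(x)
}
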