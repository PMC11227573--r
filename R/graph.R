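#' Build the co-expression-weighted KNN graph over molecules
#'
#' Each molecule is connected to at most `K_knn` nearest neighbours within
#' `R_knn = D/4` micrometres; the undirected edge set is the union of the
#' directed KNN relations.  Every edge carries two weights: the
#' co-expression weight `W[g_u, g_v]` of the incident genes (used by
#' community detection) and its Euclidean length in micrometres (used by
#' geodesic assignment).
#'
#' @param cloud An [rna_point_cloud()].
#' @param W A `coexpression_matrix` aligned to the cloud's vocabulary.
#' @param cfg A [comseg_config()].
#' @return An object of class `rna_graph`.
#' @export
build_graph <- function(cloud, W, cfg) {
  n <- length(cloud)
  if (!identical(dim(W), c(length(cloud$gene_names),
                           length(cloud$gene_names))))
    stop("'W' is not aligned to the cloud's gene vocabulary")
  co <- scaled_coords(cloud, cfg)
  res <- radius_knn_cpp(co, co, cfg$R_knn, cfg$K_knn, TRUE)
  keep <- which(res$idx > 0L)
  if (length(keep)) {
    u <- ((keep - 1L) %% n) + 1L
    v <- as.integer(res$idx[keep])
    len <- res$dist[keep]
    lo <- pmin(u, v); hi <- pmax(u, v)
    dup <- duplicated(cbind(lo, hi))
    edges <- data.frame(u = lo[!dup], v = hi[!dup], len = len[!dup])
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
    edges$w <- W[cbind(cloud$gene[edges$u], cloud$gene[edges$v])]
  } else {
    edges <- data.frame(u = integer(), v = integer(), len = numeric(),
                        w = numeric())
  }
  structure(list(n_nodes = n,
                 edges = edges[, c("u", "v", "w", "len")],
                 node_gene = cloud$gene,
                 node_is_cell = rep(FALSE, n),
                 node_nucleus = rep(0L, n),
                 node_pos = co,
                 mol2node = seq_len(n),
                 mol_nucleus = rep(0L, n),
                 gene_names = cloud$gene_names,
                 merged = FALSE),
            class = "rna_graph")
}

#' @export
print.rna_graph <- function(x, ...) {
  cat(sprintf("rna_graph: %d nodes (%d cell nodes), %d edges%s\n",
              x$n_nodes, sum(x$node_is_cell), nrow(x$edges),
              if (x$merged) ", landmark-merged" else ""))
  invisible(x)
}

#' Merge nuclear molecules into cell nodes
#'
#' All molecules inside the same nucleus are contracted into one "cell
#' node" placed at the nucleus centroid.  Contracted multi-edges sum their
#' co-expression weights and keep the shortest Euclidean length;
#' self-loops are dropped.  Every nucleus produces a cell node, including
#' nuclei containing no molecule (these stay edge-free until assignment).
#'
#' @param graph An [build_graph()] result.
#' @param landmarks A [nucleus_landmarks()] object.
#' @param cloud The [rna_point_cloud()] the graph was built from.
#' @param cfg A [comseg_config()].
#' @return The contracted `rna_graph`; `mol2node` maps each molecule to
#'   its (possibly contracted) node and `mol_nucleus` records nuclear
#'   membership.
#' @export
merge_landmark_nodes <- function(graph, landmarks, cloud, cfg) {
  if (graph$merged) stop("graph is already landmark-merged")
  memb <- nucleus_membership(cloud, landmarks, cfg)
  nuc_ids <- landmarks$nucleus_ids
  free <- which(memb == 0L)
  n_new <- length(free) + length(nuc_ids)
  old2new <- integer(graph$n_nodes)
  old2new[free] <- seq_along(free)
  for (k in seq_along(nuc_ids))
    old2new[memb == nuc_ids[k]] <- length(free) + k
  cen <- landmarks$centroids
  cen <- cen[match(nuc_ids, cen$nucleus_id), , drop = FALSE]
  pos <- rbind(graph$node_pos[free, , drop = FALSE],
               cbind(cen$x, cen$y, cen$z * cfg$z_anisotropy))
  e <- graph$edges
  if (nrow(e)) {
    u <- old2new[e$u]; v <- old2new[e$v]
    lo <- pmin(u, v); hi <- pmax(u, v)
    keep <- lo != hi                       # drop intra-nucleus self-loops
    key <- paste(lo[keep], hi[keep])
    agg_w <- tapply(e$w[keep], key, sum)
    w <- as.numeric(agg_w)
    len <- as.numeric(tapply(e$len[keep], key, min))
    ij <- do.call(rbind, strsplit(names(agg_w), " "))
    edges <- data.frame(u = as.integer(ij[, 1L]), v = as.integer(ij[, 2L]),
                        w = w, len = len)
    # edges touching a cell node measure from the nucleus centroid, so
    # geodesic distances are never shorter than straight-line distances
    cellish <- edges$u > length(free) | edges$v > length(free)
    if (any(cellish)) {
      d <- sqrt(rowSums((pos[edges$u[cellish], , drop = FALSE] -
                           pos[edges$v[cellish], , drop = FALSE])^2))
      edges$len[cellish] <- d
    }
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- e
  }
  graph$n_nodes <- n_new
  graph$edges <- edges
  graph$node_gene <- c(graph$node_gene[free], rep(NA_integer_,
                                                  length(nuc_ids)))
  graph$node_is_cell <- c(rep(FALSE, length(free)),
                          rep(TRUE, length(nuc_ids)))
  graph$node_nucleus <- c(rep(0L, length(free)), as.integer(nuc_ids))
  graph$node_pos <- pos
  graph$mol2node <- old2new
  graph$mol_nucleus <- memb
  graph$merged <- TRUE
  graph
}

#' Modularity of a node partition
#'
#' Evaluates the modularity Q of a partition over the positively weighted
#' subgraph: negative and zero co-expression edges contribute nothing.
#' With no positive edges Q is defined as 0.
#'
#' @param graph An `rna_graph`.
#' @param membership Integer community id per node (all nodes covered).
#' @return Scalar modularity Q.
#' @export
modularity_q <- function(graph, membership) {
  if (length(membership) != graph$n_nodes || anyNA(membership))
    stop("partition must cover every node of the graph")
  e <- graph$edges[graph$edges$w > 0, , drop = FALSE]
  m <- sum(e$w)
  if (m == 0) return(0)
  deg <- numeric(graph$n_nodes)
  agg_u <- rowsum(e$w, e$u); deg[as.integer(rownames(agg_u))] <- agg_u
  agg_v <- rowsum(e$w, e$v)
  deg[as.integer(rownames(agg_v))] <-
    deg[as.integer(rownames(agg_v))] + agg_v
  within <- membership[e$u] == membership[e$v]
  inw <- rowsum(e$w[within], membership[e$u][within])
  tot <- rowsum(deg, membership)
  sum(inw) / m - sum((tot / (2 * m))^2)
}

#' Landmark-constrained Louvain community detection
#'
#' Partitions the molecule graph by greedy modularity optimisation over
#' the positively weighted edges, under the constraint that no community
#' ever contains two cell nodes.  Node sweeps run in an order reshuffled
#' from the seeded generator before every pass; communities found in one
#' pass become nodes of an aggregated graph (cell-node communities marked
#' unmergeable), and the procedure repeats until modularity stops
#' improving.
#'
#' @param graph A landmark-merged (or plain) `rna_graph`.
#' @param cfg A [comseg_config()]; `cfg$seed` controls sweep order.
#' @return An object of class `community_partition`: `membership` (per
#'   node, 1-based contiguous), `n_communities`, `Q`, `q_trace` (Q after
#'   each pass), `comm_nucleus` (nucleus id per community, 0 if none) and
#'   `mol_membership` (community per molecule).
#' @export
louvain_with_priors <- function(graph, cfg) {
  e <- graph$edges[graph$edges$w > 0, , drop = FALSE]
  if (nrow(e) == 0L) {
    membership <- seq_len(graph$n_nodes)
    res <- list(Q = 0, q_trace = numeric())
  } else {
    out <- louvain_constrained_cpp(graph$n_nodes,
                                   as.integer(e$u - 1L),
                                   as.integer(e$v - 1L),
                                   as.numeric(e$w),
                                   graph$node_is_cell,
                                   cfg$seed)
    membership <- out$membership + 1L
    membership <- match(membership, sort(unique(membership)))
    res <- out
  }
  comm_nucleus <- integer(max(membership))
  cell_comm <- membership[graph$node_is_cell]
  if (anyDuplicated(cell_comm))
    stop("internal error: two cell nodes share a community")
  comm_nucleus[cell_comm] <- graph$node_nucleus[graph$node_is_cell]
  structure(list(membership = membership,
                 n_communities = max(membership),
                 Q = res$Q, q_trace = res$q_trace,
                 comm_nucleus = comm_nucleus,
                 mol_membership = membership[graph$mol2node]),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  invisible(x)
}
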