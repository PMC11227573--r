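#' Label nucleus centroids with transcriptomic profiles
#'
#' Every nucleus becomes a centroid node.  Nuclei containing RNAs take the
#' majority profile label of their nuclear RNAs; empty nuclei take the
#' majority label among at most `K_centroid` labelled molecules within
#' `R_centroid = D/2` of the centroid (ties toward the nearest molecule's
#' label); nuclei with no molecule in reach stay label-less and produce
#' empty cells.
#'
#' @param map A completed [relabel_small_communities()] domain map.
#' @param landmarks [nucleus_landmarks()].
#' @param cloud [rna_point_cloud()].
#' @param graph The landmark-merged [build_graph()] graph (provides
#'   nuclear membership).
#' @param cfg [comseg_config()].
#' @return Data frame of centroid nodes: `cell_id`, `x`, `y`, `z`,
#'   `label`, `provenance` (`"nuclear-RNA"`, `"neighbor-vote"` or
#'   `"none"`).
#' @export
label_centroids <- function(map, landmarks, cloud, graph, cfg) {
  if (is.null(map$mol_label)) stop("domain map is incomplete")
  cen <- landmarks$centroids
  cen <- cen[match(landmarks$nucleus_ids, cen$nucleus_id), , drop = FALSE]
  lab <- rep(NA_integer_, nrow(cen))
  prov <- rep("none", nrow(cen))
  co <- scaled_coords(cloud, cfg)
  for (k in seq_len(nrow(cen))) {
    nid <- cen$nucleus_id[k]
    nuclear <- which(graph$mol_nucleus == nid)
    if (length(nuclear)) {
      tab <- table(map$mol_label[nuclear])
      win <- as.integer(names(tab)[tab == max(tab)])
      lab[k] <- min(win)
      prov[k] <- "nuclear-RNA"
    } else {
      q <- matrix(c(cen$x[k], cen$y[k], cen$z[k] * cfg$z_anisotropy), 1L)
      res <- radius_knn_cpp(co, q, cfg$R_centroid, cfg$K_centroid, FALSE)
      hit <- res$idx[1L, res$idx[1L, ] > 0L]
      if (length(hit)) {
        votes <- map$mol_label[hit]
        tab <- table(votes)
        win <- as.integer(names(tab)[tab == max(tab)])
        lab[k] <- if (length(win) > 1L) votes[1L] else win
        prov[k] <- "neighbor-vote"
      }
    }
  }
  data.frame(cell_id = as.integer(cen$nucleus_id), x = cen$x, y = cen$y,
             z = cen$z, label = lab, provenance = prov)
}

#' Assign molecules to cells by same-label geodesic proximity
#'
#' Runs a multi-source Dijkstra from all centroid nodes simultaneously,
#' with Euclidean edge lengths.  Sources are partitioned by profile
#' label: a molecule of label L is reachable only through molecules of
#' label L (unless `cfg$label_constrained_paths` is `FALSE`), and is
#' assigned to the label-matching centroid of smallest geodesic distance.
#' Molecules farther than `R_max` from every admissible centroid stay
#' unassigned; nuclear molecules always belong to their own nucleus.
#' Centroid nodes without any graph edge (empty nuclei) are first
#' connected to at most `K_centroid` same-label molecules within
#' `R_centroid`.
#'
#' @param graph The landmark-merged `rna_graph`.
#' @param centroids [label_centroids()] output.
#' @param map Completed domain map (per-molecule labels).
#' @param cfg [comseg_config()].
#' @return An object of class `cell_assignment`: `cell` (cell id per
#'   molecule, 0 = unassigned), `provenance` per molecule (`"nuclear"`,
#'   `"graph-assigned"` or `"unassigned"`), `distance` (geodesic, `NA`
#'   for unassigned) and `cells` (the centroid table).
#' @export
geodesic_assign <- function(graph, centroids, map, cfg) {
  stopifnot(graph$merged)
  n <- graph$n_nodes
  node_label <- rep(NA_integer_, n)
  # a free node corresponds to exactly one molecule
  node_of_mol <- graph$mol2node
  free_mol <- which(graph$mol_nucleus == 0L)
  node_label[node_of_mol[free_mol]] <- map$mol_label[free_mol]
  cell_nodes <- which(graph$node_is_cell)
  cn_ids <- graph$node_nucleus[cell_nodes]
  cn_label <- centroids$label[match(cn_ids, centroids$cell_id)]
  node_label[cell_nodes] <- cn_label
  edges <- graph$edges
  # connect edge-free centroid nodes (empty nuclei) to nearby same-label
  # molecules so they can claim RNAs
  touched <- unique(c(edges$u, edges$v))
  lonely <- setdiff(cell_nodes, touched)
  extra <- NULL
  for (u in lonely) {
    l <- node_label[u]
    if (is.na(l)) next
    cand <- node_of_mol[free_mol][which(map$mol_label[free_mol] == l)]
    if (!length(cand)) next
    d <- sqrt(rowSums(sweep(graph$node_pos[cand, , drop = FALSE], 2L,
                            graph$node_pos[u, ])^2))
    ok <- which(d <= cfg$R_centroid)
    if (!length(ok)) next
    ok <- ok[order(d[ok], cand[ok])][seq_len(min(length(ok),
                                                 cfg$K_centroid))]
    extra <- rbind(extra, data.frame(u = u, v = cand[ok], w = 0,
                                     len = d[ok]))
  }
  if (!is.null(extra)) edges <- rbind(edges, extra)
  dist_out <- rep(NA_real_, n)
  cell_out <- rep(NA_integer_, n)
  for (l in sort(unique(cn_label[!is.na(cn_label)]))) {
    src <- cell_nodes[which(cn_label == l)]
    allowed <- if (cfg$label_constrained_paths)
      !is.na(node_label) & node_label == l
    else rep(TRUE, n)
    allowed[src] <- TRUE
    res <- dijkstra_multisource_cpp(n, as.integer(edges$u - 1L),
                                    as.integer(edges$v - 1L),
                                    as.numeric(edges$len),
                                    as.integer(src - 1L),
                                    as.integer(graph$node_nucleus[src]),
                                    allowed, cfg$R_max)
    claim <- which(is.finite(res$dist) & res$dist <= cfg$R_max &
                     (!is.na(node_label) & node_label == l))
    upd <- claim[is.na(dist_out[claim]) | res$dist[claim] < dist_out[claim] |
                   (res$dist[claim] == dist_out[claim] &
                      res$cell[claim] < cell_out[claim])]
    dist_out[upd] <- res$dist[upd]
    cell_out[upd] <- res$cell[upd]
  }
  n_mol <- length(graph$mol_nucleus)
  cell <- integer(n_mol)
  prov <- rep("unassigned", n_mol)
  distance <- rep(NA_real_, n_mol)
  nuclear <- which(graph$mol_nucleus > 0L)
  cell[nuclear] <- graph$mol_nucleus[nuclear]
  prov[nuclear] <- "nuclear"
  distance[nuclear] <- 0
  nd <- node_of_mol[free_mol]
  got <- which(!is.na(cell_out[nd]))
  cell[free_mol[got]] <- cell_out[nd[got]]
  prov[free_mol[got]] <- "graph-assigned"
  distance[free_mol[got]] <- dist_out[nd[got]]
  structure(list(cell = cell, provenance = prov, distance = distance,
                 cells = centroids),
            class = "cell_assignment")
}

#' @export
print.cell_assignment <- function(x, ...) {
  cat(sprintf(
    "cell_assignment: %d molecules -> %d cells (%d nuclear, %d graph, %d unassigned)\n",
    length(x$cell), nrow(x$cells), sum(x$provenance == "nuclear"),
    sum(x$provenance == "graph-assigned"), sum(x$cell == 0L)))
  invisible(x)
}

#' Single-cell expression profiles from an assignment
#'
#' @param assignment A [geodesic_assign()] (or [watershed_baseline()])
#'   result.
#' @param cloud The [rna_point_cloud()].
#' @return Sparse cells x genes integer count matrix (`dgCMatrix`) with
#'   cell ids as row names; cells without molecules are zero rows.
#' @export
profiles_from_assignment <- function(assignment, cloud) {
  cells <- assignment$cells$cell_id
  keep <- which(assignment$cell > 0L)
  i <- match(assignment$cell[keep], cells)
  if (anyNA(i)) stop("assignment names cell ids absent from the cell table")
  Matrix::sparseMatrix(i = i, j = cloud$gene[keep], x = 1,
                       dims = c(length(cells), length(cloud$gene_names)),
                       dimnames = list(as.character(cells),
                                       cloud$gene_names))
}
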