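# Independent brute-force oracles used to freeze expected values.  These
# deliberately avoid the package's spatial index, graph code and C++
# kernels: double loops, dense matrices and igraph only.

# proximity-weighted expression by all-pairs double loop
pe_bruteforce <- function(cloud, cfg) {
  co <- cbind(cloud$x, cloud$y, cloud$z * cfg$z_anisotropy)
  n <- nrow(co)
  G <- length(cloud$gene_names)
  pe <- matrix(0, n, G, dimnames = list(NULL, cloud$gene_names))
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(co, 2L, co[i, ])^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    within <- ord[d[ord] <= cfg$R_pe]
    sel <- within[seq_len(min(cfg$K_pe, length(within)))]
    for (j in sel)
      pe[i, cloud$gene[j]] <- pe[i, cloud$gene[j]] +
        (cfg$R_pe - d[j]) / cfg$R_pe
  }
  pe
}

# textbook Pearson correlation of two vectors
pearson_manual <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# modularity as the double sum over ordered node pairs
modularity_direct <- function(n, edges, membership) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    u <- edges$u[r]; v <- edges$v[r]; w <- edges$w[r]
    if (w <= 0) next
    A[u, v] <- A[u, v] + w
    A[v, u] <- A[v, u] + w
  }
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m == 0) return(0)
  q <- 0
  for (u in seq_len(n)) for (v in seq_len(n))
    if (membership[u] == membership[v])
      q <- q + A[u, v] - k[u] * k[v] / (2 * m)
  q / (2 * m)
}

# all-pairs KNN edge list with radius cutoff (union of directed relations)
knn_edges_bruteforce <- function(co, r, k) {
  n <- nrow(co)
  pairs <- NULL
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(co, 2L, co[i, ])^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    within <- ord[d[ord] <= r]
    sel <- within[seq_len(min(k, length(within)))]
    for (j in sel) pairs <- rbind(pairs, c(min(i, j), max(i, j)))
  }
  if (is.null(pairs)) return(data.frame(u = integer(), v = integer()))
  pairs <- unique(as.data.frame(pairs))
  names(pairs) <- c("u", "v")
  pairs[order(pairs$u, pairs$v), ]
}

# all set partitions of n elements as membership vectors (restricted
# growth strings); n <= 8 only
all_partitions <- function(n) {
  res <- list()
  rec <- function(memb, mx) {
    i <- length(memb) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- memb
      return(invisible())
    }
    for (c in seq_len(mx + 1L)) rec(c(memb, c), max(mx, c))
  }
  rec(integer(0), 0L)
  res
}

# geodesic distances through an edge list via igraph (oracle for the
# package's Dijkstra)
geodesic_igraph <- function(n, edges, from) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v, weight = edges$len),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  d <- igraph::distances(g, v = as.character(from),
                         to = as.character(seq_len(n)))
  d[1, ]
}

# deterministic random clouds for property tests
random_cloud <- function(n, genes = c("a", "b", "c"), extent = 20,
                         seed = 1, three_d = FALSE) {
  set.seed(seed)
  rna_point_cloud(x = runif(n, 0, extent), y = runif(n, 0, extent),
                  z = if (three_d) runif(n, 0, extent / 4) else NULL,
                  gene = sample(genes, n, replace = TRUE),
                  gene_levels = genes)
}

# two spatially segregated expression domains with disjoint gene pairs
segregated_cloud <- function(n_per = 150, seed = 5) {
  set.seed(seed)
  x1 <- runif(n_per, 0, 10);  y1 <- runif(n_per, 0, 10)
  x2 <- runif(n_per, 30, 40); y2 <- runif(n_per, 0, 10)
  rna_point_cloud(
    x = c(x1, x2), y = c(y1, y2),
    gene = c(sample(c("a", "b"), n_per, TRUE),
             sample(c("c", "d"), n_per, TRUE)),
    gene_levels = c("a", "b", "c", "d"))
}
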