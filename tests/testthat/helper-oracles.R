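# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written from first principles (no igraph, no p.adjust,
# no phyper) so that tests compare two genuinely different routes.

# Step-up FDR adjustment evaluated directly from its definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * p[o[j]] / j)
    q[o[i]] <- min(1, cand)
  }
  q
}

# Upper-tail hypergeometric probability by exhaustive enumeration.
brute_hyper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random undirected simple graph as an adjacency matrix.
random_adjacency <- function(n, p_edge = 0.4) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p_edge)
  a + t(a)
}

adjacency_to_graph <- function(a) {
  dimnames(a) <- list(paste0("v", seq_len(nrow(a))), paste0("v", seq_len(nrow(a))))
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# All-pairs shortest-path lengths by Floyd-Warshall.
brute_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Per-component diameters from the brute-force distance matrix.
brute_component_diameters <- function(a) {
  d <- brute_distances(a)
  n <- nrow(a)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1L
      comp[is.finite(d[v, ])] <- cid
    }
  }
  diam <- vapply(seq_len(cid), function(i) {
    idx <- which(comp == i)
    max(d[idx, idx, drop = FALSE])
  }, numeric(1))
  list(membership = comp, diameter = diam)
}

# Normalized betweenness by exhaustive enumeration of all simple paths:
# for each ordered pair keep only the shortest paths and accredit interior
# vertices with the fraction passing through them.
brute_betweenness <- function(a) {
  n <- nrow(a)
  bt <- numeric(n)
  if (n < 3) return(bt)
  all_paths <- function(s, t) {
    paths <- list()
    grow <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (w in which(a[v, ] == 1)) {
        if (!w %in% path) grow(c(path, w))
      }
    }
    grow(s)
    paths
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    len <- vapply(paths, length, integer(1))
    shortest <- paths[len == min(len)]
    for (p in shortest) {
      interior <- p[-c(1, length(p))]
      bt[interior] <- bt[interior] + 1 / length(shortest)
    }
  }
  bt / ((n - 1) * (n - 2) / 2)
}

# Mean local clustering coefficient by direct triangle counting.
brute_avg_clustering <- function(a) {
  n <- nrow(a)
  if (n == 0) return(0)
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(cc)
}

# Small deterministic count matrix for DEG unit tests.
toy_counts <- function() {
  m <- matrix(c(4, 8, 6, 12,
                16, 32, 20, 40,
                100, 200, 150, 300,
                7, 14, 9, 18), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  m
}
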