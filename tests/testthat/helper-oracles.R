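# Independent brute-force oracles used to validate the graph features.
# These deliberately avoid igraph and the package's own code paths.

# Floyd-Warshall hop distances from a 0/1 adjacency matrix
fw_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# shortest-path counts via matrix powers: walks of minimal length are
# exactly the shortest paths
path_counts <- function(A) {
  n <- nrow(A)
  d <- fw_distances(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  P <- diag(n)
  for (l in seq_len(max(d[is.finite(d)], 1))) {
    P <- P %*% A
    sigma[d == l] <- P[d == l]
  }
  list(d = d, sigma = sigma)
}

# total load centrality: sum over v and unordered pairs {s,t} of the
# fraction of shortest s-t paths through v
oracle_tlc <- function(A) {
  pc <- path_counts(A)
  n <- nrow(A)
  total <- 0
  for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v || !is.finite(pc$d[s, t])) next
    if (pc$d[s, v] + pc$d[v, t] == pc$d[s, t])
      total <- total + pc$sigma[s, v] * pc$sigma[v, t] / pc$sigma[s, t]
  }
  total
}

oracle_thc <- function(A) {
  d <- fw_distances(A)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv)
}

# exhaustive maximal-clique count (n <= 20)
oracle_cliques <- function(A) {
  n <- nrow(A)
  subsets <- lapply(seq_len(2^n) - 1, function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) == 0) return(FALSE)
    if (length(s) == 1) return(TRUE)
    all(A[s, s][upper.tri(diag(length(s)))] > 0)
  }, logical(1))
  cl <- subsets[is_clique]
  n_max <- 0
  for (c1 in cl) {
    maximal <- !any(vapply(cl, function(c2)
      length(c2) > length(c1) && all(c1 %in% c2), logical(1)))
    if (maximal) n_max <- n_max + 1
  }
  n_max
}

# average clustering via the A^3 diagonal (triangle counts)
oracle_cc <- function(A) {
  n <- nrow(A)
  k <- rowSums(A > 0)
  tri <- diag((A > 0) %*% (A > 0) %*% (A > 0)) / 2
  cv <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  mean(cv)
}

# Fiedler value from an independently assembled weighted Laplacian
oracle_lambda2 <- function(W) {
  diag(W) <- 0
  L <- diag(rowSums(W)) - W
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (length(ev) < 2) 0 else ev[2]
}

# union-find connected components
oracle_components <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) if (A[i, j] > 0) {
    ri <- find(parent, i); rj <- find(parent, j)
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), function(i) find(parent, i), integer(1))))
}

# random Erdos-Renyi weighted graph as a symmetric weight matrix
random_weight_matrix <- function(n, p) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[stats::runif(length(up)) < p]
  W[on] <- stats::runif(length(on), 0.2, 5)
  W + t(W)
}

# wrap a weight matrix into the package's graph container
sg_from_matrix <- function(W, Q = NA_integer_) {
  n <- nrow(W)
  idx <- which(upper.tri(W, diag = TRUE) & W > 0, arr.ind = TRUE)
  new_signal_graph(node_labels = as.character(seq_len(n)),
                   node_values = seq_len(n) / n,
                   edges = data.frame(i = idx[, 1], j = idx[, 2],
                                      weight = W[idx],
                                      count = rep(1L, nrow(idx))),
                   Q = Q, construction = "ERG_GRAPH", n_source = n)
}

# named unweighted standard graphs
sg_complete <- function(n) sg_from_matrix(1 * (matrix(1, n, n) - diag(n)))
sg_path <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  sg_from_matrix(W)
}
sg_cycle <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  W[1, n] <- W[n, 1] <- 1
  sg_from_matrix(W)
}
sg_star <- function(k) {
  W <- matrix(0, k + 1, k + 1)
  W[1, 2:(k + 1)] <- W[2:(k + 1), 1] <- 1
  sg_from_matrix(W)
}

# brute-force O(N^2)-pairs natural visibility oracle
oracle_visibility <- function(x) {
  n <- length(x)
  edges <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    visible <- TRUE
    if (b > a + 1) {
      cc <- (a + 1):(b - 1)
      bound <- x[a] + (x[b] - x[a]) * (cc - a) / (b - a)
      visible <- all(x[cc] < bound)
    }
    if (visible) edges[a, b] <- 1
  }
  edges
}

edge_set <- function(g) {
  e <- g$edges
  sort(paste(g$node_labels[e$i], g$node_labels[e$j], e$weight, e$count))
}

# a small deterministic fixture collection used by the I/O tests
fixture_waveforms <- function() {
  list(
    waveform(c(-3.5, 0, 2.25, 7, 1, -0.5, 0.125, 4), subject_id = "A01",
             group = "ASD", sex = "M", eye = "RIGHT", flash_td = 446,
             recording_index = 1L),
    waveform(c(0.1, 0.7, 0.3, 0.9, 0.2, 0.8, 0.4, 0.6), subject_id = "C01",
             group = "CONTROL", sex = "F", eye = "LEFT", flash_td = 113,
             recording_index = 2L)
  )
}

expect_waveforms_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$samples, b[[i]]$samples)
    for (f in c("subject_id", "group", "sex", "eye", "flash_td",
                "recording_index"))
      expect_identical(a[[i]][[f]], b[[i]][[f]])
  }
}
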