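#' Signal graph container
#'
#' All six time-series-to-graph constructions return this container: an
#' undirected graph whose nodes are either amplitude levels (quantization
#' and epsilon-ball graphs), time samples (visibility, recurrence, k-NN) or
#' ordinal patterns, and whose edges carry a positive `weight` plus an
#' integer transition `count` (>= 1). Each unordered pair, self-pairs
#' included, is stored once with `i <= j`.
#'
#' `weight` is a function of the endpoints alone (inverse level distance
#' for the quantization graph, 1 for the unweighted constructions);
#' `count` accumulates how many temporal transitions realized the edge.
#'
#' @param node_labels Character labels, one per node.
#' @param node_values Numeric value per node (amplitude level or sample
#'   value), `NA` where not meaningful.
#' @param edges `data.frame(i, j, weight, count)` with node indices
#'   `i <= j`.
#' @param Q Quantization resolution that produced the graph (or `NA`).
#' @param construction One of `"ERG_GRAPH"`, `"VG"`, `"RN"`, `"KNN"`,
#'   `"EBALL"`, `"OPN"`.
#' @param n_source Number of samples in the source signal.
#' @param meta Optional list of provenance metadata (subject id etc.).
#' @return An object of class `signal_graph`.
#' @export
new_signal_graph <- function(node_labels, node_values, edges, Q,
                             construction, n_source, meta = list()) {
  construction <- match.arg(construction,
                            c("ERG_GRAPH", "VG", "RN", "KNN", "EBALL", "OPN"))
  edges <- as.data.frame(edges)
  stopifnot(all(c("i", "j", "weight", "count") %in% names(edges)),
            all(edges$i <= edges$j), all(edges$weight > 0),
            all(edges$count >= 1))
  structure(
    list(node_labels = as.character(node_labels),
         node_values = as.numeric(node_values),
         n_nodes = length(node_labels),
         edges = edges, Q = Q, construction = construction,
         n_source = n_source, meta = meta),
    class = "signal_graph"
  )
}

#' @exportS3Method base::print
print.signal_graph <- function(x, ...) {
  nself <- sum(x$edges$i == x$edges$j)
  cat(sprintf("<signal_graph:%s> %d nodes, %d edges (%d self-loops), Q = %s\n",
              x$construction, x$n_nodes, nrow(x$edges), nself,
              ifelse(is.na(x$Q), "-", x$Q)))
  invisible(x)
}

# collapse a sequence of node indices (temporal trajectory) into the
# unordered edge table with transition counts
edges_from_transitions <- function(idx_from, idx_to, weight_fun) {
  i <- pmin(idx_from, idx_to)
  j <- pmax(idx_from, idx_to)
  key <- paste(i, j)
  tab <- table(key)
  first <- !duplicated(key)
  ef <- data.frame(i = i[first], j = j[first])
  ef$count <- as.integer(tab[paste(ef$i, ef$j)])
  ef$weight <- weight_fun(ef$i, ef$j)
  ef[order(ef$i, ef$j), c("i", "j", "weight", "count")]
}

# unordered pair matrix (i < j) -> unweighted edge table
edges_from_pairs <- function(i, j) {
  if (length(i) == 0)
    return(data.frame(i = integer(), j = integer(),
                      weight = numeric(), count = integer()))
  data.frame(i = pmin(i, j), j = pmax(i, j), weight = 1, count = 1L)
}

#' Build the amplitude-quantization graph of a waveform
#'
#' The core transform: nodes are the quantization levels actually visited
#' by the signal and each consecutive sample pair `(q(t), q(t+1))`
#' contributes an edge between the two corresponding levels. Edge weight is
#' inverse level distance, `w(vi, vj) = 1 / (|li - lj| + epsilon)` with
#' `epsilon = 1/(Q-1)`, so transitions between nearby amplitude states are
#' strongly connected while large jumps yield weak long-range edges.
#' Repeated transitions increment `count` only (weight depends on the
#' levels alone). A sample staying at its level produces a self-loop with
#' weight `1/epsilon = Q - 1`.
#'
#' @param q An `erg_quantized` signal from [quantize()].
#' @return A `signal_graph` with `construction = "ERG_GRAPH"`. The sum of
#'   edge counts equals `N - 1` and the node count is at most `Q`.
#' @export
build_erg_graph <- function(q) {
  stopifnot(is_quantized(q))
  lv <- q$levels
  nodes <- sort(unique(lv))
  idx <- match(lv, nodes)
  n <- length(lv)
  edges <- if (n >= 2) {
    edges_from_transitions(idx[-n], idx[-1], function(i, j)
      1 / (abs(nodes[i] - nodes[j]) + q$epsilon))
  } else {
    data.frame(i = integer(), j = integer(), weight = numeric(),
               count = integer())
  }
  src <- q$source
  new_signal_graph(
    node_labels = format(nodes, digits = 15, trim = TRUE),
    node_values = nodes, edges = edges, Q = q$Q,
    construction = "ERG_GRAPH", n_source = n,
    meta = list(subject_id = src$subject_id, group = src$group,
                degenerate = isTRUE(src$degenerate)))
}

#' Build the natural visibility graph of a waveform
#'
#' Nodes are time samples; samples `(ta, xa)` and `(tb, xb)` are connected
#' when every intermediate sample `(tc, xc)` lies strictly below the
#' straight line joining them:
#' `xc < xa + (xb - xa) (tc - ta) / (tb - ta)`. Unweighted.
#'
#' @param w A normalized `erg_waveform` with at least 2 samples.
#' @return A `signal_graph` with `construction = "VG"`.
#' @export
build_visibility_graph <- function(w) {
  stopifnot(is_waveform(w))
  x <- w$samples
  n <- length(x)
  if (n < 2) stop("visibility graph needs at least 2 samples")
  from <- vector("list", n - 1)
  to <- vector("list", n - 1)
  for (a in seq_len(n - 1)) {
    s <- (x[(a + 1):n] - x[a]) / seq_len(n - a)
    # b is visible from a iff slope(a,b) strictly exceeds every earlier slope
    vis <- s > cummax(c(-Inf, s[-length(s)]))
    b <- ((a + 1):n)[vis]
    from[[a]] <- rep.int(a, length(b))
    to[[a]] <- b
  }
  i <- unlist(from); j <- unlist(to)
  new_signal_graph(node_labels = as.character(seq_len(n) - 1L),
                   node_values = x, edges = edges_from_pairs(i, j),
                   Q = NA_integer_, construction = "VG", n_source = n,
                   meta = list(subject_id = w$subject_id, group = w$group))
}

#' Build a recurrence network from a waveform
#'
#' Nodes are time samples; two distinct samples are connected when their
#' amplitudes recur, i.e. `|x(ti) - x(tj)| < eps_r`. Embedding dimension 1
#' with delay 1 on the normalized amplitude (both exposed as parameters).
#'
#' @param w A normalized `erg_waveform`.
#' @param eps_r Recurrence threshold (> 0); 0.1 on the normalized scale is
#'   the conventional default.
#' @param embedding_dim Delay-embedding dimension (default 1).
#' @param delay Embedding delay in samples (default 1).
#' @return A `signal_graph` with `construction = "RN"`.
#' @export
build_recurrence_network <- function(w, eps_r = 0.1, embedding_dim = 1,
                                     delay = 1) {
  stopifnot(is_waveform(w), eps_r > 0, embedding_dim >= 1, delay >= 1)
  x <- w$samples
  n_vec <- length(x) - (embedding_dim - 1) * delay
  if (n_vec < 2) stop("recurrence network needs at least 2 state vectors")
  emb <- sapply(seq_len(embedding_dim), function(d)
    x[seq_len(n_vec) + (d - 1) * delay])
  emb <- matrix(emb, nrow = n_vec)
  dm <- as.matrix(stats::dist(emb, method = "maximum"))
  sel <- which(upper.tri(dm) & dm < eps_r, arr.ind = TRUE)
  new_signal_graph(node_labels = as.character(seq_len(n_vec) - 1L),
                   node_values = x[seq_len(n_vec)],
                   edges = edges_from_pairs(sel[, 1], sel[, 2]),
                   Q = NA_integer_, construction = "RN", n_source = length(x),
                   meta = list(subject_id = w$subject_id, group = w$group))
}

#' Build a k-nearest-neighbour graph from a waveform
#'
#' Nodes are time samples; each sample is joined to its `k` nearest
#' neighbours by amplitude distance `|x(ti) - x(tj)|` and the directed
#' neighbour sets are symmetrized by union. Distance ties are broken by the
#' smaller time index so the output is deterministic.
#'
#' @param w A normalized `erg_waveform` with at least `k + 1` samples.
#' @param k Number of neighbours (default 3).
#' @return A `signal_graph` with `construction = "KNN"`.
#' @export
build_knn_graph <- function(w, k = 3) {
  stopifnot(is_waveform(w), k >= 1)
  x <- w$samples
  n <- length(x)
  if (n <= k) stop("k-NN graph needs at least k + 1 samples")
  i <- integer(0); j <- integer(0)
  for (a in seq_len(n)) {
    d <- abs(x - x[a])
    d[a] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    i <- c(i, rep.int(a, k)); j <- c(j, nb)
  }
  key <- paste(pmin(i, j), pmax(i, j))
  keep <- !duplicated(key)
  new_signal_graph(node_labels = as.character(seq_len(n) - 1L),
                   node_values = x,
                   edges = edges_from_pairs(i[keep], j[keep]),
                   Q = NA_integer_, construction = "KNN", n_source = n,
                   meta = list(subject_id = w$subject_id, group = w$group))
}

#' Build an epsilon-ball graph over quantization levels
#'
#' Nodes are the distinct quantization levels visited by the signal; two
#' distinct levels are connected when `|li - lj| < eps_b`, regardless of
#' temporal order. Unweighted.
#'
#' @param q An `erg_quantized` signal.
#' @param eps_b Ball radius (> 0). The default `2/(Q-1)` connects adjacent
#'   and next-adjacent levels.
#' @return A `signal_graph` with `construction = "EBALL"`.
#' @export
build_eball_graph <- function(q, eps_b = 2 / (q$Q - 1)) {
  stopifnot(is_quantized(q), eps_b > 0)
  nodes <- sort(unique(q$levels))
  dm <- abs(outer(nodes, nodes, "-"))
  sel <- which(upper.tri(dm) & dm < eps_b, arr.ind = TRUE)
  src <- q$source
  new_signal_graph(node_labels = format(nodes, digits = 15, trim = TRUE),
                   node_values = nodes,
                   edges = edges_from_pairs(sel[, 1], sel[, 2]),
                   Q = q$Q, construction = "EBALL",
                   n_source = length(q$levels),
                   meta = list(subject_id = src$subject_id, group = src$group))
}

#' Build an ordinal partition network from a waveform
#'
#' Nodes are ordinal patterns: the rank order of `m` consecutive samples
#' (delay 1), ties broken earlier-index-smaller. Consecutive windows are
#' joined by an edge whose `count` accumulates the number of transitions;
#' a window followed by the same pattern yields a self-loop.
#'
#' @param w A normalized `erg_waveform` with at least `m + 1` samples.
#' @param m Embedding (pattern) dimension, >= 2; 3 is the conventional
#'   default.
#' @return A `signal_graph` with `construction = "OPN"`. Node count is at
#'   most `min(N - m + 1, m!)`.
#' @export
build_opn <- function(w, m = 3) {
  stopifnot(is_waveform(w), m >= 2)
  x <- w$samples
  n <- length(x)
  if (n <= m) stop("ordinal partition network needs at least m + 1 samples")
  nw <- n - m + 1
  pat <- vapply(seq_len(nw), function(t)
    paste(order(x[t:(t + m - 1)], seq_len(m)), collapse = "-"),
    character(1))
  nodes <- unique(pat)
  idx <- match(pat, nodes)
  edges <- edges_from_transitions(idx[-nw], idx[-1], function(i, j) rep(1, length(i)))
  new_signal_graph(node_labels = nodes, node_values = rep(NA_real_, length(nodes)),
                   edges = edges, Q = NA_integer_, construction = "OPN",
                   n_source = n,
                   meta = list(subject_id = w$subject_id, group = w$group))
}

#' Convert a signal graph to an igraph object
#'
#' @param g A `signal_graph`.
#' @param include_self_loops Keep self-loops (default `FALSE`; the spectral
#'   and feature views work on the simple graph).
#' @param use_count_weight Multiply edge weights by transition counts
#'   (sensitivity analysis; default `FALSE` keeps the level-determined
#'   weights).
#' @return An igraph graph with vertex attributes `name`, `value` and edge
#'   attributes `weight`, `count`, `length` (inverse weight, used for
#'   weighted shortest paths).
#' @export
as_igraph <- function(g, include_self_loops = FALSE,
                      use_count_weight = FALSE) {
  stopifnot(inherits(g, "signal_graph"))
  e <- g$edges
  if (!include_self_loops) e <- e[e$i != e$j, , drop = FALSE]
  w <- if (use_count_weight) e$weight * e$count else e$weight
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$node_labels)
  ig <- igraph::set_vertex_attr(ig, "value", value = g$node_values)
  if (nrow(e) > 0) {
    ig <- igraph::add_edges(ig, rbind(e$i, e$j))
    ig <- igraph::set_edge_attr(ig, "weight", value = w)
    ig <- igraph::set_edge_attr(ig, "count", value = e$count)
    ig <- igraph::set_edge_attr(ig, "length", value = 1 / w)
  }
  ig
}

#' Spectral summary of a signal graph
#'
#' Builds the weighted adjacency matrix `A` over visited nodes (self-loops
#' excluded: the combinatorial Laplacian `L = D - A` is invariant to them
#' and the density denominator presumes a simple graph), the diagonal
#' degree matrix `D`, the Laplacian with its full dense eigendecomposition
#' (node counts stay <= Q, so an iterative solver is unnecessary), and the
#' graph density `rho = 2E / (V (V - 1))` with `E` the number of non-self-
#' loop edges (`rho = 0` for a single-node graph).
#'
#' @param g A `signal_graph`.
#' @param use_count_weight Multiply weights by transition counts.
#' @return A list with `adjacency`, `degree`, `laplacian`, `eigenvalues`
#'   (ascending), `fiedler_value`, `fiedler_vector`, `density`,
#'   `n_components`.
#' @export
spectral_summary <- function(g, use_count_weight = FALSE) {
  stopifnot(inherits(g, "signal_graph"), g$n_nodes >= 1)
  n <- g$n_nodes
  A <- matrix(0, n, n, dimnames = list(g$node_labels, g$node_labels))
  e <- g$edges[g$edges$i != g$edges$j, , drop = FALSE]
  w <- if (use_count_weight) e$weight * e$count else e$weight
  A[cbind(e$i, e$j)] <- w
  A[cbind(e$j, e$i)] <- w
  D <- diag(rowSums(A), n)
  L <- D - A
  ev <- eigen(L, symmetric = TRUE)
  lambda <- rev(ev$values)
  vecs <- ev$vectors[, rev(seq_len(n)), drop = FALSE]
  comps <- igraph::count_components(igraph::graph_from_adjacency_matrix(
    A > 0, mode = "undirected"))
  list(adjacency = A, degree = D, laplacian = L, eigenvalues = lambda,
       fiedler_value = if (n >= 2) lambda[2] else 0,
       fiedler_vector = if (n >= 2) vecs[, 2] else vecs[, 1],
       density = if (n >= 2) 2 * nrow(e) / (n * (n - 1)) else 0,
       n_components = comps)
}

#' Number of connected components of a signal graph
#'
#' @param g A `signal_graph`.
#' @return Integer count (isolated nodes count as components).
#' @export
n_components <- function(g) {
  igraph::count_components(as_igraph(g))
}
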