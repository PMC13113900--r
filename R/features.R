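#' All-pairs shortest-path distances of a signal graph
#'
#' Hop counts on the simple (self-loop-free) graph by default. In weighted
#' mode the edge length is the inverse of the edge weight (for the
#' quantization graph this is the amplitude gap `|li - lj| + epsilon`).
#' Disconnected pairs have distance `Inf`.
#'
#' @param g A `signal_graph`.
#' @param weighted Use inverse-weight edge lengths instead of hop counts.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
all_pairs_distances <- function(g, weighted = FALSE) {
  ig <- as_igraph(g)
  igraph::distances(ig, weights = if (weighted) igraph::E(ig)$length else NA)
}

# restrict a signal_graph to its largest connected component (simple view);
# ties broken by the component containing the smallest node index
giant_component <- function(g) {
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  if (comp$no <= 1) return(g)
  big <- which.max(comp$csize)
  keep <- which(comp$membership == big)
  remap <- match(seq_len(g$n_nodes), keep)
  e <- g$edges
  e <- e[e$i %in% keep & e$j %in% keep, , drop = FALSE]
  e$i <- remap[e$i]; e$j <- remap[e$j]
  new_signal_graph(g$node_labels[keep], g$node_values[keep], e, g$Q,
                   g$construction, g$n_source, g$meta)
}

check_connected <- function(g, connectivity, what) {
  nc <- n_components(g)
  if (nc == 1) return(g)
  if (connectivity == "strict")
    stop(what, ": graph is disconnected (", nc, " components)")
  warning(what, " computed on the largest of ", nc, " components")
  giant_component(g)
}

#' Total load centrality
#'
#' Sum over all nodes of the shortest-path betweenness
#' `sum_{s != v != t} sigma_st(v) / sigma_st` over unordered pairs
#' `{s, t}`, unnormalized, with hop-count shortest paths by default. High
#' values mean many amplitude states serve as obligatory transit points.
#'
#' @param g A `signal_graph`.
#' @param weighted Use inverse-weight edge lengths for shortest paths.
#' @return A nonnegative real.
#' @export
total_load_centrality <- function(g, weighted = FALSE) {
  ig <- as_igraph(g)
  sum(igraph::betweenness(ig, directed = FALSE,
                          weights = if (weighted) igraph::E(ig)$length else NA))
}

#' Total harmonic centrality
#'
#' `sum_v sum_{u != v} 1 / d(v, u)` with `1/Inf := 0`, so disconnected
#' graphs are handled gracefully.
#'
#' @inheritParams total_load_centrality
#' @return A nonnegative real.
#' @export
total_harmonic_centrality <- function(g, weighted = FALSE) {
  d <- all_pairs_distances(g, weighted)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv)
}

#' Number of maximal cliques
#'
#' Count of maximal fully interconnected node subsets of the simple view of
#' the graph (Bron-Kerbosch with pivoting, via igraph).
#'
#' @param g A `signal_graph`.
#' @return Integer >= 1 for non-empty graphs (isolated nodes are maximal
#'   cliques of size 1).
#' @export
number_of_maximal_cliques <- function(g) {
  as.integer(igraph::count_max_cliques(as_igraph(g)))
}

#' Graph diameter and radius
#'
#' Maximum and minimum node eccentricity (hop counts by default). On a
#' disconnected graph the default `"giant"` policy computes them on the
#' largest connected component with a warning; `"strict"` raises an error.
#'
#' @inheritParams total_load_centrality
#' @param connectivity `"giant"` (default) or `"strict"`.
#' @return A real (integer-valued in hop mode).
#' @export
graph_diameter <- function(g, weighted = FALSE,
                           connectivity = c("giant", "strict")) {
  connectivity <- match.arg(connectivity)
  g <- check_connected(g, connectivity, "diameter")
  if (g$n_nodes == 1) return(0)
  max(all_pairs_distances(g, weighted))
}

#' @rdname graph_diameter
#' @export
graph_radius <- function(g, weighted = FALSE,
                         connectivity = c("giant", "strict")) {
  connectivity <- match.arg(connectivity)
  g <- check_connected(g, connectivity, "radius")
  if (g$n_nodes == 1) return(0)
  min(apply(all_pairs_distances(g, weighted), 1, max))
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' `c_v = 2 |edges among neighbours of v| / (k_v (k_v - 1))` on the simple
#' unweighted view, with `c_v := 0` for degree < 2 (the ratio is 0/0
#' there).
#'
#' @param g A `signal_graph`.
#' @return A real in `[0, 1]`.
#' @export
average_clustering <- function(g) {
  ig <- as_igraph(g)
  if (igraph::vcount(ig) == 0) return(0)
  igraph::transitivity(ig, type = "localaverage", isolates = "zero")
}

#' Average path length
#'
#' `(1 / (V (V - 1))) * sum_{i != j} d(vi, vj)` over ordered pairs, hop
#' counts by default; connectivity handled as in [graph_diameter()].
#'
#' @inheritParams graph_diameter
#' @return A nonnegative real.
#' @export
average_path_length <- function(g, weighted = FALSE,
                                connectivity = c("giant", "strict")) {
  connectivity <- match.arg(connectivity)
  g <- check_connected(g, connectivity, "average path length")
  if (g$n_nodes == 1) return(0)
  d <- all_pairs_distances(g, weighted)
  sum(d[row(d) != col(d)]) / (g$n_nodes * (g$n_nodes - 1))
}

#' Algebraic connectivity (Fiedler value)
#'
#' Second-smallest eigenvalue of the weighted combinatorial Laplacian
#' `L = D - A` (self-loops excluded). Zero for disconnected graphs; 0 by
#' convention for a single node. Higher values indicate a tightly connected
#' amplitude trajectory with few structural bottlenecks.
#'
#' @param g A `signal_graph`.
#' @param use_count_weight Multiply weights by transition counts.
#' @return A nonnegative real.
#' @export
algebraic_connectivity <- function(g, use_count_weight = FALSE) {
  spectral_summary(g, use_count_weight)$fiedler_value
}

#' Graph density
#'
#' Fraction of possible edges that are present, `2E / (V (V - 1))`,
#' excluding self-loops; defined as 0 for a single-node graph.
#'
#' @param g A `signal_graph`.
#' @return A real in `[0, 1]`.
#' @export
graph_density <- function(g) {
  n <- g$n_nodes
  if (n < 2) return(0)
  e <- sum(g$edges$i != g$edges$j)
  2 * e / (n * (n - 1))
}

#' Extract the nine graph features of a waveform graph
#'
#' Computes total load centrality (`tlc`), total harmonic centrality
#' (`thc`), number of maximal cliques (`gnc`), `diameter`, `radius`,
#' average clustering (`cc`), average path length (`apl`), algebraic
#' connectivity (`lambda2`) and `density` from one shared distance matrix
#' and spectral summary. On disconnected graphs the connectivity-dependent
#' features (diameter, radius, apl, lambda2) follow the giant-component
#' policy unless `connectivity = "strict"`.
#'
#' @param g A `signal_graph`.
#' @param weighted_paths Use inverse-weight edge lengths for the
#'   path-based features (default hop counts).
#' @param connectivity `"giant"` (default) or `"strict"`.
#' @return A one-row tibble with the nine features plus provenance columns
#'   (`subject_id`, `group`, `construction`, `Q`, `n_nodes`,
#'   `n_components`).
#' @export
extract_features <- function(g, weighted_paths = FALSE,
                             connectivity = c("giant", "strict")) {
  connectivity <- match.arg(connectivity)
  stopifnot(inherits(g, "signal_graph"), g$n_nodes >= 1)
  ig <- as_igraph(g)
  nc <- igraph::count_components(ig)
  gc <- if (nc > 1) {
    if (connectivity == "strict")
      stop("extract_features: graph is disconnected (", nc, " components)")
    giant_component(g)
  } else g
  wts <- if (weighted_paths) igraph::E(ig)$length else NA
  d_gc <- all_pairs_distances(gc, weighted_paths)
  off <- row(d_gc) != col(d_gc)
  d_all <- if (nc > 1) all_pairs_distances(g, weighted_paths) else d_gc
  inv <- 1 / d_all
  diag(inv) <- 0
  inv[is.infinite(d_all)] <- 0
  spec <- spectral_summary(gc)
  tibble::tibble(
    tlc = sum(igraph::betweenness(ig, directed = FALSE, weights = wts)),
    thc = sum(inv),
    gnc = as.integer(igraph::count_max_cliques(ig)),
    diameter = if (gc$n_nodes > 1) max(d_gc) else 0,
    radius = if (gc$n_nodes > 1) min(apply(d_gc, 1, max)) else 0,
    cc = average_clustering(g),
    apl = if (gc$n_nodes > 1) sum(d_gc[off]) / (gc$n_nodes * (gc$n_nodes - 1)) else 0,
    lambda2 = spec$fiedler_value,
    density = graph_density(g),
    subject_id = g$meta$subject_id %||% NA_character_,
    group = g$meta$group %||% NA_character_,
    construction = g$construction,
    Q = g$Q,
    n_nodes = g$n_nodes,
    n_components = nc
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

feature_names <- function() {
  c("tlc", "thc", "gnc", "diameter", "radius", "cc", "apl", "lambda2",
    "density")
}

#' Build a graph and extract features for a whole waveform collection
#'
#' Runs normalize -> quantize -> construct -> extract for every waveform
#' and stacks the results into a study table: one row per (waveform,
#' construction, Q) with subject/group/sex/eye/flash metadata, the nine
#' graph features, and optionally time-domain morphology features
#' (prefixed `td_`).
#'
#' @param waves List of [waveform()] objects (raw; normalization is applied
#'   internally).
#' @param Q Quantization resolution (default 50).
#' @param method One of `"erg"`, `"vg"`, `"rn"`, `"knn"`, `"eball"`,
#'   `"opn"`.
#' @param params List of construction parameters: `eps_r`, `k`, `eps_b`,
#'   `m` (defaults 0.1, 3, `2/(Q-1)`, 3).
#' @param include_td Also compute the built-in time-domain feature set
#'   (see [td_features()]).
#' @param weighted_paths,connectivity Passed to [extract_features()].
#' @return A tibble with a `family` attribute naming each feature column's
#'   family (`GRAPH` or `TD`).
#' @export
extract_feature_table <- function(waves, Q = 50,
                                  method = c("erg", "vg", "rn", "knn",
                                             "eball", "opn"),
                                  params = list(), include_td = FALSE,
                                  weighted_paths = FALSE,
                                  connectivity = "giant") {
  method <- match.arg(method)
  p <- utils::modifyList(list(eps_r = 0.1, k = 3, eps_b = 2 / (Q - 1),
                              m = 3), params)
  rows <- lapply(waves, function(w) {
    wn <- normalize(w)
    g <- switch(method,
      erg = build_erg_graph(quantize(wn, Q)),
      vg = build_visibility_graph(wn),
      rn = build_recurrence_network(wn, eps_r = p$eps_r),
      knn = build_knn_graph(wn, k = p$k),
      eball = build_eball_graph(quantize(wn, Q), eps_b = p$eps_b),
      opn = build_opn(wn, m = p$m))
    ft <- suppressWarnings(
      extract_features(g, weighted_paths = weighted_paths,
                       connectivity = connectivity))
    meta <- tibble::tibble(subject_id = w$subject_id, group = w$group,
                           sex = w$sex, eye = w$eye, flash_td = w$flash_td,
                           recording_index = w$recording_index)
    ft <- ft[, c(feature_names(), "Q", "construction", "n_nodes",
                 "n_components")]
    out <- dplyr::bind_cols(meta, ft)
    if (include_td) out <- dplyr::bind_cols(out, td_features(w))
    out
  })
  tbl <- dplyr::bind_rows(rows)
  fam <- stats::setNames(rep("GRAPH", length(feature_names())),
                         feature_names())
  if (include_td) {
    td_cols <- grep("^td_", names(tbl), value = TRUE)
    fam <- c(fam, stats::setNames(rep("TD", length(td_cols)), td_cols))
  }
  attr(tbl, "family") <- fam
  tbl
}

#' Time-domain morphology features of a raw waveform
#'
#' A minimal conventional descriptor set for fusion configurations: a-wave
#' amplitude (depth of the early trough, searched in the first 40% of the
#' epoch) and latency, b-wave amplitude and latency, b/a ratio,
#' peak-to-peak range, total signal energy, and the root-mean-square of the
#' 75-235 Hz band (the oscillatory-potential band).
#'
#' @param w A raw `erg_waveform` (microvolts).
#' @return A one-row tibble of `td_` columns.
#' @export
td_features <- function(w) {
  stopifnot(is_waveform(w))
  x <- w$samples
  n <- length(x)
  t_ms <- (seq_len(n) - 1) / w$sampling_rate * 1000
  early <- seq_len(max(2, floor(0.4 * n)))
  ia <- early[which.min(x[early])]
  ib <- which.max(x)
  # OP band via FFT mask
  sp <- stats::fft(x - mean(x))
  fr <- (seq_len(n) - 1) / n * w$sampling_rate
  fr <- pmin(fr, w$sampling_rate - fr)
  keep <- fr >= 75 & fr <= 235
  op <- Re(stats::fft(sp * keep, inverse = TRUE)) / n
  tibble::tibble(
    td_a_amp = -x[ia], td_a_time = t_ms[ia],
    td_b_amp = x[ib], td_b_time = t_ms[ib],
    td_ba_ratio = x[ib] / ifelse(x[ia] == 0, NA_real_, abs(x[ia])),
    td_p2p = max(x) - min(x),
    td_energy = sum(x^2),
    td_op_rms = sqrt(mean(op^2))
  )
}
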