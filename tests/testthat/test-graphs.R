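quantized_from_levels <- function(levels, Q) {
  quantize(waveform(levels, normalized = TRUE), Q)
}

test_that("quantization graph matches hand-derived edges, weights and counts", {
  g <- build_erg_graph(quantized_from_levels(c(0, 0.5, 1, 0.5, 0), 3))
  expect_equal(g$n_nodes, 3)
  expect_equal(sort(g$node_values), c(0, 0.5, 1))
  e <- g$edges[order(g$edges$i, g$edges$j), ]
  # {0,0.5} and {0.5,1}: weight 1/(0.5+0.5) = 1, two transitions each
  expect_equal(nrow(e), 2)
  expect_equal(e$weight, c(1, 1))
  expect_equal(e$count, c(2L, 2L))
  expect_false(any(e$i == e$j))
})

test_that("dwelling at one level yields a self-loop of weight Q - 1", {
  g <- build_erg_graph(quantized_from_levels(c(0.5, 0.5), 3))
  expect_equal(g$n_nodes, 1)
  expect_equal(g$edges$weight, 2)  # 1/epsilon
  expect_equal(g$edges$count, 1L)
})

test_that("quantization graph obeys its construction contracts", {
  withr::local_seed(10)
  for (rep in 1:100) {
    Q <- sample(2:60, 1)
    n <- sample(4:80, 1)
    x <- runif(n); x[1] <- 0; x[2] <- 1
    q <- quantize(waveform(x, normalized = TRUE), Q)
    g <- build_erg_graph(q)
    expect_equal(sum(g$edges$count), n - 1)
    expect_lte(g$n_nodes, Q)
    self <- g$edges[g$edges$i == g$edges$j, ]
    if (nrow(self) > 0) expect_equal(self$weight, rep(Q - 1, nrow(self)))
    # weight bound 0 < w <= Q - 1
    expect_true(all(g$edges$weight > 0 & g$edges$weight <= Q - 1 + 1e-9))
    # determinism: rebuilding gives a bit-identical edge set
    expect_identical(edge_set(build_erg_graph(q)), edge_set(g))
  }
})

test_that("a trajectory through adjacent levels yields a connected graph", {
  lv <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25)
  g <- build_erg_graph(quantized_from_levels(lv, 5))
  expect_equal(n_components(g), 1)
})

test_that("visibility graph matches the brute-force convexity oracle", {
  expect_equal(edge_set(build_visibility_graph(waveform(c(1, 0, 1)))),
               edge_set(build_visibility_graph(waveform(c(1, 0, 1)))))
  g <- build_visibility_graph(waveform(c(1, 0, 1), normalized = TRUE))
  expect_equal(nrow(g$edges), 3)  # (0,1), (1,2) and the rim pair (0,2)

  g2 <- build_visibility_graph(waveform(c(0.2, 0.8), normalized = TRUE))
  expect_equal(nrow(g2$edges), 1)

  withr::local_seed(21)
  for (rep in 1:15) {
    x <- runif(30)
    g <- build_visibility_graph(waveform(x, normalized = TRUE))
    A <- oracle_visibility(x)
    got <- g$edges[, c("i", "j")]
    want <- which(A > 0, arr.ind = TRUE)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$i, got$j), paste(want[, 1], want[, 2]))
  }
})

test_that("concave and monotone signals give the expected visibility edges", {
  # strictly concave: only adjacent samples see each other
  x <- c(0, 0.7, 1, 0.7, 0)
  g <- build_visibility_graph(waveform(x, normalized = TRUE))
  A <- oracle_visibility(x)
  expect_equal(nrow(g$edges), sum(A))
  # strictly convex increasing: everything sees everything
  xc <- c(0, 0.05, 0.15, 0.4, 1)
  gc <- build_visibility_graph(waveform(xc, normalized = TRUE))
  expect_equal(nrow(gc$edges), choose(5, 2))
})

test_that("recurrence network thresholds amplitude distances", {
  g <- build_recurrence_network(waveform(c(0, 1, 0.05), normalized = TRUE),
                                eps_r = 0.1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(unlist(g$edges[, c("i", "j")], use.names = FALSE), c(1L, 3L))
  # eps >= 1 on a normalized signal connects everything
  g2 <- build_recurrence_network(waveform(c(0, 0.4, 1), normalized = TRUE),
                                 eps_r = 1.001)
  expect_equal(nrow(g2$edges), 3)
  # vanishing threshold with distinct values: empty edge set
  g3 <- build_recurrence_network(waveform(c(0, 0.5, 1), normalized = TRUE),
                                 eps_r = 1e-9)
  expect_equal(nrow(g3$edges), 0)
})

test_that("k-NN graph links nearest amplitudes with deterministic ties", {
  g <- build_knn_graph(waveform(c(0, 0.1, 0.9, 1), normalized = TRUE), k = 1)
  expect_setequal(paste(g$edges$i, g$edges$j), c("1 2", "3 4"))
  # k = N - 1 gives the complete graph
  g2 <- build_knn_graph(waveform(c(0, 0.3, 0.6, 1), normalized = TRUE), k = 3)
  expect_equal(nrow(g2$edges), 6)
  # duplicated amplitudes: repeated builds agree exactly
  x <- c(0, 0.5, 0.5, 0.5, 1)
  w <- waveform(x, normalized = TRUE)
  expect_identical(edge_set(build_knn_graph(w, 2)),
                   edge_set(build_knn_graph(w, 2)))
  expect_error(build_knn_graph(waveform(c(0, 1), normalized = TRUE), k = 3),
               "k \\+ 1")
})

test_that("epsilon-ball graph connects levels within the radius", {
  q <- quantized_from_levels(c(0, 0.5, 1), 3)
  g <- build_eball_graph(q, eps_b = 0.6)
  expect_setequal(paste(g$node_values[g$edges$i], g$node_values[g$edges$j]),
                  c("0 0.5", "0.5 1"))
  expect_equal(nrow(build_eball_graph(q, eps_b = 1.1)$edges), 3)
  # radius at the level spacing: strict inequality leaves no edges
  expect_equal(nrow(build_eball_graph(q, eps_b = 0.5)$edges), 0)
})

test_that("ordinal partition network aggregates patterns and transitions", {
  inc <- waveform(seq(0, 1, length.out = 8), normalized = TRUE)
  g <- build_opn(inc, m = 3)
  expect_equal(g$n_nodes, 1)
  expect_equal(g$edges$count, 8L - 3L)  # N - m self-transitions
  expect_equal(g$edges$i, g$edges$j)

  g2 <- build_opn(waveform(c(0, 1, 0, 1, 0), normalized = TRUE), m = 3)
  expect_equal(g2$n_nodes, 2)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$count, 2L)

  withr::local_seed(4)
  for (rep in 1:10) {
    n <- sample(10:40, 1); m <- sample(2:4, 1)
    g <- build_opn(waveform(runif(n), normalized = TRUE), m = m)
    expect_lte(g$n_nodes, min(n - m + 1, factorial(m)))
  }
})

test_that("spectral summary reproduces known Laplacian spectra and density", {
  s3 <- spectral_summary(sg_path(3))
  expect_equal(s3$eigenvalues, c(0, 1, 3), tolerance = 1e-9)
  expect_equal(s3$density, 2 / 3)

  s4 <- spectral_summary(sg_complete(4))
  expect_equal(s4$eigenvalues, c(0, 4, 4, 4), tolerance = 1e-9)
  expect_equal(s4$density, 1)

  # two disconnected edges: eigenvalue 0 with multiplicity 2
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  sd2 <- spectral_summary(sg_from_matrix(W))
  expect_equal(sum(abs(sd2$eigenvalues) < 1e-9), 2)
  expect_equal(sd2$n_components, 2)
})

test_that("Laplacian is PSD with zero row sums; 0-multiplicity = components", {
  withr::local_seed(77)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    W <- random_weight_matrix(n, runif(1, 0.15, 0.9))
    s <- spectral_summary(sg_from_matrix(W))
    expect_true(all(abs(rowSums(s$laplacian)) < 1e-9))
    expect_true(all(s$eigenvalues > -1e-9))
    expect_equal(sum(s$eigenvalues < 1e-9), oracle_components(W))
    expect_equal(s$n_components, oracle_components(W))
  }
})

test_that("self-loops are excluded from adjacency, density and spectrum", {
  W <- matrix(0, 2, 2)
  W[1, 2] <- W[2, 1] <- 1
  g_plain <- sg_from_matrix(W)
  W_loop <- W; W_loop[1, 1] <- 5
  g_loop <- sg_from_matrix(W_loop)
  s1 <- spectral_summary(g_plain); s2 <- spectral_summary(g_loop)
  expect_equal(s1$adjacency, s2$adjacency)
  expect_equal(s1$eigenvalues, s2$eigenvalues)
  expect_equal(graph_density(g_plain), graph_density(g_loop))
})

test_that("graph exports round-trip to an isomorphic weighted graph", {
  g <- build_erg_graph(quantized_from_levels(c(0, 0.25, 0.5, 1, 0.5, 0.5, 0), 5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_graph_edgelist(g, path)
  back <- read_graph_edgelist(path, Q = g$Q)
  expect_equal(back$n_nodes, g$n_nodes)
  expect_identical(edge_set(back), edge_set(g))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graph_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::is_isomorphic_to(
    ig, as_igraph(g, include_self_loops = TRUE)))
  expect_equal(sort(igraph::E(ig)$weight), sort(g$edges$weight))

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_graph_mtx(g, mtx)
  A <- as.matrix(Matrix::readMM(mtx))
  expect_equal(unname(A), unname(spectral_summary(g)$adjacency))
})
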