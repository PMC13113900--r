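test_that("complete-graph features match closed forms for n = 2..10", {
  for (n in 2:10) {
    g <- sg_complete(n)
    f <- extract_features(g)
    expect_equal(f$tlc, 0)
    expect_equal(f$thc, n * (n - 1))
    expect_equal(f$gnc, 1)
    expect_equal(f$diameter, 1)
    expect_equal(f$radius, 1)
    expect_equal(f$cc, if (n >= 3) 1 else 0)
    expect_equal(f$apl, 1)
    expect_equal(f$lambda2, n, tolerance = 1e-9)
    expect_equal(f$density, 1)
  }
})

test_that("path-graph features match closed forms for n = 2..10", {
  for (n in 2:10) {
    f <- extract_features(sg_path(n))
    expect_equal(f$gnc, n - 1)
    expect_equal(f$diameter, n - 1)
    expect_equal(f$radius, floor(n / 2))
    expect_equal(f$cc, 0)
    expect_equal(f$lambda2, 2 * (1 - cos(pi / n)), tolerance = 1e-9)
  }
  # hand-derived small cases
  p3 <- extract_features(sg_path(3))
  expect_equal(p3$tlc, 1)
  expect_equal(p3$thc, 5)
  expect_equal(p3$apl, 4 / 3)
  expect_equal(p3$density, 2 / 3)
  expect_equal(extract_features(sg_path(4))$tlc, 4)
})

test_that("cycle-graph features match closed forms for n = 3..10", {
  for (n in 3:10) {
    f <- extract_features(sg_cycle(n))
    expect_equal(f$diameter, floor(n / 2))
    expect_equal(f$radius, floor(n / 2))
    expect_equal(f$lambda2, 2 * (1 - cos(2 * pi / n)), tolerance = 1e-9)
    expect_equal(f$gnc, if (n == 3) 1 else n)
  }
})

test_that("star-graph features match closed forms for k = 2..9 leaves", {
  for (k in 2:9) {
    f <- extract_features(sg_star(k))
    expect_equal(f$tlc, choose(k, 2))
    expect_equal(f$diameter, 2)
    expect_equal(f$radius, 1)
    expect_equal(f$apl, (2 * k + k * (k - 1) * 2) / ((k + 1) * k))
    expect_equal(f$lambda2, 1, tolerance = 1e-9)
  }
})

test_that("K4 feature vector equals the complete-graph reference values", {
  f <- extract_features(sg_complete(4))
  expect_equal(
    unlist(f[, c("tlc", "thc", "gnc", "diameter", "radius", "cc", "apl",
                 "lambda2", "density")]),
    c(tlc = 0, thc = 12, gnc = 1, diameter = 1, radius = 1, cc = 1,
      apl = 1, lambda2 = 4, density = 1), tolerance = 1e-9)
})

test_that("every feature matches its brute-force oracle on random graphs", {
  withr::local_seed(123)
  n_checked <- 0
  while (n_checked < 60) {
    n <- sample(3:12, 1)
    W <- random_weight_matrix(n, runif(1, 0.25, 0.9))
    A <- 1 * (W > 0)
    g <- sg_from_matrix(W)
    d <- fw_distances(A)
    expect_equal(unname(all_pairs_distances(g)), d)
    expect_equal(total_load_centrality(g), oracle_tlc(A), tolerance = 1e-9)
    expect_equal(total_harmonic_centrality(g), oracle_thc(A),
                 tolerance = 1e-9)
    expect_equal(number_of_maximal_cliques(g), oracle_cliques(A))
    expect_equal(average_clustering(g), oracle_cc(A), tolerance = 1e-9)
    expect_equal(algebraic_connectivity(g), oracle_lambda2(W),
                 tolerance = 1e-9)
    if (oracle_components(A) == 1) {
      expect_equal(graph_diameter(g), max(d))
      expect_equal(graph_radius(g), min(apply(d, 1, max)))
      expect_equal(average_path_length(g),
                   sum(d[row(d) != col(d)]) / (n * (n - 1)), tolerance = 1e-9)
    }
    n_checked <- n_checked + 1
  }
})

test_that("metric sanity: radius <= diameter <= 2 radius and apl <= diameter", {
  withr::local_seed(9)
  checked <- 0
  while (checked < 40) {
    n <- sample(3:12, 1)
    W <- random_weight_matrix(n, runif(1, 0.3, 0.9))
    g <- sg_from_matrix(W)
    if (n_components(g) != 1) next
    dia <- graph_diameter(g); rad <- graph_radius(g)
    expect_lte(rad, dia)
    expect_lte(dia, 2 * rad)
    expect_lte(average_path_length(g), dia)
    checked <- checked + 1
  }
})

test_that("disconnected graphs follow the giant-component policy", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1  # P3 plus an edge P2
  W[4, 5] <- W[5, 4] <- 1
  g <- sg_from_matrix(W)
  expect_warning(d <- graph_diameter(g), "largest")
  expect_equal(d, 2)
  expect_error(graph_diameter(g, connectivity = "strict"), "disconnected")
  expect_error(extract_features(g, connectivity = "strict"), "disconnected")
  f <- suppressWarnings(extract_features(g))
  expect_equal(f$diameter, 2)   # giant component is the P3
  expect_equal(f$n_components, 2)
  # harmonic centrality stays global: pairs across components contribute 0
  expect_equal(f$thc, oracle_thc(1 * (W > 0)), tolerance = 1e-9)
})

test_that("features are invariant to affine rescaling of the raw waveform", {
  withr::local_seed(33)
  x <- as.numeric(arima.sim(list(ar = 0.8), 120))
  f1 <- extract_feature_table(list(waveform(x)), Q = 30)
  f2 <- extract_feature_table(list(waveform(3.7 * x + 11)), Q = 30)
  for (col in c("tlc", "thc", "gnc", "diameter", "radius", "cc", "apl",
                "lambda2", "density"))
    expect_identical(f1[[col]], f2[[col]])
})

test_that("feature extraction is deterministic", {
  withr::local_seed(2)
  w <- generate_waveform(preset("CONTROL_LIKE"))
  g <- build_erg_graph(quantize(normalize(w), 50))
  expect_identical(extract_features(g), extract_features(g))
})

test_that("weighted path mode uses amplitude-gap edge lengths", {
  # two levels 0 and 1 at Q = 3: gap + epsilon = 1.5, hop distance 1
  q <- quantize(waveform(c(0, 1), normalized = TRUE), 3)
  g <- build_erg_graph(q)
  expect_equal(unname(all_pairs_distances(g)[1, 2]), 1)
  expect_equal(unname(all_pairs_distances(g, weighted = TRUE)[1, 2]), 1.5)
})
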