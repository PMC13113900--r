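test_that("min-max normalization maps extremes to 0 and 1 and is idempotent", {
  w <- normalize(waveform(c(-2, 0, 2)))
  expect_equal(w$samples, c(0, 0.5, 1))
  expect_true(w$normalized)
  expect_false(w$degenerate)
  # a signal already spanning [0, 1] is unchanged
  w2 <- normalize(waveform(c(0, 0.3, 1, 0.7)))
  expect_equal(normalize(w2)$samples, w2$samples)
})

test_that("flat signals normalize to constant 0.5 with a degenerate flag", {
  w <- normalize(waveform(c(5, 5, 5, 5)))
  expect_equal(w$samples, rep(0.5, 4))
  expect_true(w$degenerate)
  # and quantization + graph construction stay total: single node, self-loops
  g <- build_erg_graph(quantize(w, 3))
  expect_equal(g$n_nodes, 1)
  expect_true(all(g$edges$i == g$edges$j))
})

test_that("quantization maps to exact levels k/(Q-1) with epsilon = 1/(Q-1)", {
  w <- normalize(waveform(c(0, 0.5, 1)))
  q <- quantize(w, 3)
  expect_equal(q$levels, c(0, 0.5, 1))
  expect_equal(q$epsilon, 0.5)

  w2 <- waveform(c(0.24, 0.26, 0, 1), normalized = TRUE)
  q5 <- quantize(w2, 5)
  expect_equal(q5$levels[1:2], c(0.25, 0.25))

  expect_equal(quantize(normalize(waveform(0:9)), 50)$epsilon, 1 / 49)
  expect_error(quantize(w, 1), "Q must be")
})

test_that("rounding ties go half-away-from-zero", {
  # x * (Q-1) = 0.5 and 1.5 exactly: both must round up
  w <- waveform(c(0.25, 0.75, 0, 1), normalized = TRUE)
  expect_equal(quantize(w, 3)$levels, c(0.5, 1, 0, 1))
})

test_that("quantization is idempotent and within half a level of the input", {
  withr::local_seed(7)
  for (rep in 1:20) {
    x <- runif(50)
    x[1] <- 0; x[2] <- 1
    w <- waveform(x, normalized = TRUE)
    for (Q in c(2, 3, 7, 50)) {
      q <- quantize(w, Q)
      expect_true(all(abs(x - q$levels) <= 1 / (2 * (Q - 1)) + 1e-12))
      expect_identical(quantize(waveform(q$levels, normalized = TRUE), Q)$levels,
                       q$levels)
      expect_true(all(vapply(q$levels, function(l)
        isTRUE(all.equal(l * (Q - 1), round(l * (Q - 1)))), logical(1))))
    }
  }
})

test_that("quantization refines from coarse to fine", {
  # exact per-step monotonicity of the distinct-level count does not hold
  # (two values straddling a coarse bin boundary can merge at a finer Q,
  # e.g. {0.4, 0.6} distinct at Q = 2 but both 0.5 at Q = 3), so the
  # property is a strong monotone trend plus exact bounds
  withr::local_seed(42)
  for (rep in 1:50) {
    x <- runif(40)
    x[1] <- 0; x[2] <- 1
    w <- waveform(x, normalized = TRUE)
    qs <- 2:80
    counts <- vapply(qs, function(Q)
      length(unique(quantize(w, Q)$levels)), numeric(1))
    expect_true(all(counts <= pmin(40, qs)))
    expect_gte(counts[length(counts)], counts[1])
    expect_gt(stats::cor(counts, qs, method = "spearman"), 0.9)
    # at a resolution finer than half the smallest gap, nothing merges
    gap <- min(diff(sort(unique(x))))
    Q_fine <- ceiling(1 / gap) + 2
    expect_equal(length(unique(quantize(w, Q_fine)$levels)),
                 length(unique(x)))
  }
})

test_that("long CSV round-trip is bit-for-bit on samples and metadata", {
  waves <- fixture_waveforms()
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveforms(waves, path)
  back <- read_waveforms(path)
  expect_waveforms_equal(waves, back)
  expect_equal(back[[1]]$n_samples, 8)
})

test_that("wide CSV round-trips, including 500-sample waveforms", {
  withr::local_seed(3)
  waves <- list(generate_waveform(preset("CONTROL_LIKE"), subject_id = "W1"),
                generate_waveform(preset("EXPANSIVE"), subject_id = "W2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveforms(waves, path, dialect = "wide")
  back <- read_waveforms(path, dialect = "wide")
  expect_equal(back[[1]]$n_samples, 500)
  expect_waveforms_equal(waves, back)
})

test_that("UNKNOWN enums are written as empty fields and survive the round trip", {
  waves <- list(waveform(c(1, 2, 3, 4), subject_id = "U1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveforms(waves, path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  expect_true(all(is.na(raw$group) | raw$group == ""))
  expect_waveforms_equal(waves, read_waveforms(path))
})

test_that("malformed input is rejected with informative errors", {
  waves <- fixture_waveforms()
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveforms(waves, path)
  df <- read.csv(path, stringsAsFactors = FALSE)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "amplitude_uv")], p2, row.names = FALSE)
  expect_error(read_waveforms(p2), "amplitude_uv")

  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(rbind(df, df[1, ]), p3, row.names = FALSE)
  expect_error(read_waveforms(p3), "duplicated")

  p4 <- withr::local_tempfile(fileext = ".csv")
  df4 <- df
  df4$sample_index[df4$sample_index == 3] <- 9L
  write.csv(df4, p4, row.names = FALSE)
  expect_error(read_waveforms(p4), "contiguous")

  expect_error(write_waveforms(list(), withr::local_tempfile()), "empty")
})

test_that("recordings with missing amplitudes are dropped with a warning", {
  waves <- fixture_waveforms()
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveforms(waves, path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character"))
  df$amplitude_uv[3] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_warning(back <- read_waveforms(path), "dropped")
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$subject_id, "C01")
})

test_that("feature table CSV round-trips exactly", {
  withr::local_seed(5)
  waves <- two_group_cohort(c("ASD", "CONTROL"), n_per_group = 3, seed = 2)
  ft <- extract_feature_table(waves, Q = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  for (f in c("tlc", "thc", "diameter", "cc", "apl", "lambda2", "density"))
    expect_identical(back[[f]], ft[[f]])
  expect_identical(back$subject_id, ft$subject_id)
})
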