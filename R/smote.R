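#' Synthetic minority oversampling (SMOTE)
#'
#' Brings every minority class up to the majority class count by
#' interpolating between a random minority example and one of its
#' `k_neighbors` nearest same-class neighbours (Euclidean distance,
#' interpolation factor uniform on [0, 1]). Only ever applied to training
#' partitions; synthetic rows are appended after the originals so callers
#' can verify no synthetic row leaks into validation data.
#'
#' If a minority class has fewer than `k_neighbors + 1` members the
#' neighbourhood shrinks to `size - 1` with a warning; a singleton class is
#' left as-is with a warning (no neighbours to interpolate with).
#'
#' @param x Numeric feature matrix.
#' @param y Factor (or character) class labels.
#' @param k_neighbors Neighbourhood size (default 5).
#' @return A list with oversampled `x`, `y` and `n_synthetic`.
#' @export
smote_balance <- function(x, y, k_neighbors = 5) {
  x <- as.matrix(x)
  y <- factor(y)
  counts <- table(y)
  n_max <- max(counts)
  add_x <- list(); add_y <- list()
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0) next
    idx <- which(y == cl)
    if (length(idx) == 1) {
      warning("class ", cl, " has a single member; oversampling skipped")
      next
    }
    k <- min(k_neighbors, length(idx) - 1)
    if (k < k_neighbors)
      warning("class ", cl, ": k_neighbors reduced to ", k)
    xm <- x[idx, , drop = FALSE]
    dm <- as.matrix(stats::dist(xm))
    diag(dm) <- Inf
    nb <- apply(dm, 1, function(d) order(d)[seq_len(k)])
    nb <- matrix(nb, nrow = k)
    base <- sample(length(idx), need, replace = TRUE)
    pick <- vapply(base, function(b) nb[sample.int(k, 1), b], numeric(1))
    u <- stats::runif(need)
    syn <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    add_x[[cl]] <- syn
    add_y[[cl]] <- rep(cl, need)
  }
  if (length(add_x) > 0) {
    x <- rbind(x, do.call(rbind, add_x))
    y <- factor(c(as.character(y), unlist(add_y)), levels = levels(y))
  }
  list(x = x, y = y, n_synthetic = length(unlist(add_y)))
}
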