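#' Cliff's delta effect size
#'
#' `delta = (#{xi > yj} - #{xi < yj}) / (nx * ny)`, the difference in
#' probability of superiority between two samples; invariant to jointly
#' monotone transforms and antisymmetric in its arguments. The magnitude is
#' binned as negligible (|d| < 0.15), small ([0.15, 0.28)), medium
#' ([0.28, 0.43)) or large (>= 0.43); bounds are lower-closed/upper-open
#' except the closed large bound.
#'
#' @param x,y Non-empty numeric samples.
#' @return A list with `delta` and `label`.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("cliffs_delta requires non-empty samples")
  d <- mean(sign(outer(x, y, "-")))
  list(delta = d, label = effect_label(d))
}

effect_label <- function(delta) {
  a <- abs(delta)
  if (a < 0.15) "negligible"
  else if (a < 0.28) "small"
  else if (a < 0.43) "medium"
  else "large"
}

#' Kruskal-Wallis H test across groups
#'
#' Rank-based one-way test with the average-rank tie correction; p-value
#' from the chi-square distribution with k - 1 degrees of freedom
#' (delegated to [stats::kruskal.test()]).
#'
#' @param groups A list of >= 2 non-empty numeric samples.
#' @return A list with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 1))
    stop("kruskal_wallis requires >= 2 non-empty groups")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn's post hoc test on pooled ranks
#'
#' For every group pair, the z statistic
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` on pooled
#' average ranks, with tie correction `T = sum(t^3 - t) / (12 (N - 1))`.
#' Two-sided p-values are Bonferroni-adjusted (multiplied by the number of
#' pairs, capped at 1), which never reports an adjusted p below the raw p.
#'
#' @param groups Named (or unnamed) list of numeric samples.
#' @param correction Only `"bonferroni"` is offered; pass `"none"` for raw
#'   p-values.
#' @param alpha Post hoc significance level; the conventional default
#'   0.017 corresponds to 0.05 / 3 pairwise comparisons.
#' @return A tibble with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adjusted`, `significant`, and an `alpha` attribute.
#' @export
dunn_posthoc <- function(groups, correction = c("bonferroni", "none"),
                         alpha = 0.017) {
  correction <- match.arg(correction)
  if (length(groups) < 2) stop("dunn_posthoc requires >= 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  gl <- rep(names(groups), lengths(groups))
  N <- length(pooled)
  r <- rank(pooled)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, gl, mean)
  n <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(sigma2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (correction == "bonferroni")
    pmin(1, p_raw * ncol(pairs)) else p_raw
  out <- tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ],
                        z = z, p_raw = p_raw, p_adjusted = p_adj,
                        significant = p_adj < alpha)
  attr(out, "alpha") <- alpha
  out
}

#' Group-difference statistics for a feature table
#'
#' For every feature column: Kruskal-Wallis H and p across groups, a
#' Shapiro-Wilk normality p-value recorded as metadata (the rationale for
#' using nonparametric tests), and per-pair Dunn's Bonferroni-adjusted
#' p-values with Cliff's delta and its effect-size label.
#'
#' @param tbl A feature table (e.g. from [extract_feature_table()]).
#' @param group_col Grouping column name (default `"group"`).
#' @param feature_cols Feature columns to test (default the nine graph
#'   features present in `tbl`).
#' @param alpha Post hoc alpha passed to [dunn_posthoc()].
#' @param per_subject_mean Average recordings per subject before testing
#'   (default `FALSE`: recordings are the sampling unit).
#' @return A list with `features` (one row per feature: `feature`, `kw_H`,
#'   `kw_p`, `shapiro_p`) and `pairwise` (one row per feature and group
#'   pair, with `dunn_p_adjusted`, `cliffs_delta`, `effect_label`).
#' @export
feature_stats_table <- function(tbl, group_col = "group",
                                feature_cols = NULL, alpha = 0.017,
                                per_subject_mean = FALSE) {
  tbl <- as.data.frame(tbl)
  if (!group_col %in% names(tbl)) stop("missing grouping column ", group_col)
  if (is.null(feature_cols))
    feature_cols <- intersect(feature_names(), names(tbl))
  missing_cols <- setdiff(feature_cols, names(tbl))
  if (length(missing_cols) > 0)
    stop("data error: missing feature column(s) ",
         paste(missing_cols, collapse = ", "))
  if (per_subject_mean) {
    if (!"subject_id" %in% names(tbl))
      stop("per_subject_mean requires a subject_id column")
    tbl <- stats::aggregate(tbl[feature_cols],
                            by = list(subject_id = tbl$subject_id,
                                      group = tbl[[group_col]]), mean)
    group_col <- "group"
  }
  groups_all <- unique(tbl[[group_col]])
  if (length(groups_all) < 2)
    stop("feature_stats_table requires >= 2 groups, got ",
         length(groups_all))
  feat_rows <- list(); pair_rows <- list()
  for (f in feature_cols) {
    by_grp <- split(tbl[[f]], tbl[[group_col]])
    kw <- kruskal_wallis(by_grp)
    sw_x <- tbl[[f]]
    if (length(sw_x) > 5000) sw_x <- sw_x[seq_len(5000)]
    sw <- if (length(unique(sw_x)) > 2 && length(sw_x) >= 3)
      tryCatch(stats::shapiro.test(sw_x)$p.value, error = function(e) NA_real_)
      else NA_real_
    feat_rows[[f]] <- tibble::tibble(feature = f, kw_H = kw$H, kw_p = kw$p,
                                     shapiro_p = sw)
    dn <- dunn_posthoc(by_grp, alpha = alpha)
    dn$cliffs_delta <- mapply(function(a, b)
      cliffs_delta(by_grp[[a]], by_grp[[b]])$delta, dn$group_a, dn$group_b)
    dn$effect_label <- vapply(dn$cliffs_delta, effect_label, character(1))
    dn$feature <- f
    pair_rows[[f]] <- dplyr::rename(dn, dunn_p_adjusted = "p_adjusted")
  }
  list(features = dplyr::bind_rows(feat_rows),
       pairwise = dplyr::bind_rows(pair_rows),
       alpha_posthoc = alpha)
}
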