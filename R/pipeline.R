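meta_cols <- function() {
  c("subject_id", "group", "sex", "eye", "flash_td", "recording_index",
    "Q", "construction", "n_nodes", "n_components", "label")
}

# numeric feature columns of a study table (anything numeric that is not
# bookkeeping metadata)
feature_cols_of <- function(tbl) {
  cand <- setdiff(names(tbl), meta_cols())
  cand[vapply(tbl[cand], is.numeric, logical(1))]
}

#' Build a classification scenario from a study table
#'
#' Maps diagnostic groups to classification labels, filters by sex and
#' flash strength, and handles eye laterality:
#' * `asd_vs_ctrl`: positive class is ASD together with the co-occurring
#'   ASD+ADHD group, versus CONTROL; pure ADHD rows are dropped.
#' * `adhd_vs_ctrl`: positive class is ADHD plus ASD+ADHD, versus CONTROL.
#' * `three_group`: ASD vs ADHD vs CONTROL, ASD+ADHD excluded.
#' * `four_group`: all four groups.
#'
#' `eye_mode = "R_PLUS_L"` pairs right- and left-eye recordings of the same
#' subject, flash and recording index and concatenates their feature
#' columns (suffixes `_R` / `_L`); unpaired recordings are dropped with a
#' message stating the count.
#'
#' @param tbl A feature table (one row per recording).
#' @param scenario One of `"asd_vs_ctrl"`, `"adhd_vs_ctrl"`,
#'   `"three_group"`, `"four_group"`.
#' @param sex `"ALL"` (default), `"M"` or `"F"`.
#' @param flash Keep only this flash strength (Td.s); `NULL` keeps all.
#' @param eye_mode `NULL` (keep all rows), `"RIGHT"`, `"LEFT"` or
#'   `"R_PLUS_L"`.
#' @return A tibble with a factor `label` column; errors if any scenario
#'   class ends up empty.
#' @export
build_scenario <- function(tbl, scenario = c("asd_vs_ctrl", "adhd_vs_ctrl",
                                             "three_group", "four_group"),
                           sex = "ALL", flash = NULL, eye_mode = NULL) {
  scenario <- match.arg(scenario)
  tbl <- tibble::as_tibble(tbl)
  if (sex != "ALL") tbl <- tbl[tbl$sex == sex, , drop = FALSE]
  if (!is.null(flash)) tbl <- tbl[!is.na(tbl$flash_td) &
                                    tbl$flash_td == flash, , drop = FALSE]
  map <- switch(scenario,
    asd_vs_ctrl = c(ASD = "ASD", ASD_ADHD = "ASD", CONTROL = "CONTROL"),
    adhd_vs_ctrl = c(ADHD = "ADHD", ASD_ADHD = "ADHD", CONTROL = "CONTROL"),
    three_group = c(ASD = "ASD", ADHD = "ADHD", CONTROL = "CONTROL"),
    four_group = c(ASD = "ASD", ADHD = "ADHD", ASD_ADHD = "ASD_ADHD",
                   CONTROL = "CONTROL"))
  tbl <- tbl[tbl$group %in% names(map), , drop = FALSE]
  tbl$label <- unname(map[tbl$group])
  if (!is.null(eye_mode)) {
    if (eye_mode %in% c("RIGHT", "LEFT")) {
      tbl <- tbl[tbl$eye == eye_mode, , drop = FALSE]
    } else if (eye_mode == "R_PLUS_L") {
      tbl <- pair_eyes(tbl)
    } else stop("unknown eye_mode: ", eye_mode)
  }
  expected <- unique(unname(map))
  empty <- setdiff(expected, unique(tbl$label))
  if (length(empty) > 0)
    stop("scenario class empty after filtering: ",
         paste(empty, collapse = ", "))
  tbl$label <- factor(tbl$label, levels = expected)
  tbl
}

# concatenate right- and left-eye feature vectors per
# (subject, flash, recording_index); unpaired recordings are dropped
pair_eyes <- function(tbl) {
  fc <- feature_cols_of(tbl)
  key <- c("subject_id", "flash_td", "recording_index")
  right <- tbl[tbl$eye == "RIGHT", , drop = FALSE]
  left <- tbl[tbl$eye == "LEFT", c(key, fc), drop = FALSE]
  merged <- dplyr::inner_join(right, left, by = key,
                              suffix = c("_R", "_L"))
  n_drop <- (nrow(right) + nrow(tbl[tbl$eye == "LEFT", ])) - 2 * nrow(merged)
  if (n_drop > 0)
    message(n_drop, " unpaired recording(s) dropped by R_PLUS_L pairing")
  merged$eye <- "R_PLUS_L"
  merged
}

#' Assign subjects to cross-validation folds
#'
#' Folds partition subjects, never rows: all recordings of a subject share
#' a fold, so repeated recordings can never span train and test. Within
#' each class, shuffled subjects are dealt round-robin so folds are
#' class-stratified at the subject level where sizes allow.
#'
#' @param tbl A table with `subject_id` and a `label` (or `group`) column;
#'   each subject must appear in exactly one class.
#' @param n_folds Number of folds (default 10).
#' @param seed RNG seed; identical seeds give identical assignments.
#' @param label_col Class column used for stratification.
#' @return A tibble `(subject_id, fold)`.
#' @export
subject_wise_folds <- function(tbl, n_folds = 10, seed = 1L,
                               label_col = if ("label" %in% names(tbl))
                                 "label" else "group") {
  subj <- unique(tbl[, c("subject_id", label_col)])
  if (anyDuplicated(subj$subject_id))
    stop("a subject appears in more than one class")
  if (nrow(subj) < n_folds)
    stop("fewer subjects (", nrow(subj), ") than folds (", n_folds, ")")
  withr::with_seed(seed, {
    out <- list()
    offset <- 0L
    for (cl in unique(as.character(subj[[label_col]]))) {
      ids <- subj$subject_id[subj[[label_col]] == cl]
      ids <- sample(ids)
      fold <- ((seq_along(ids) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(ids)) %% n_folds
      out[[cl]] <- tibble::tibble(subject_id = ids, fold = fold)
    }
    dplyr::bind_rows(out)
  })
}

#' Rank features by random-forest importance and keep the top k
#'
#' Stage 1 of the training pipeline: a 500-tree random forest is fit on the
#' training rows and features are ranked by mean impurity decrease.
#' `k = "auto"` picks k over the grid {3, 5, 7, 9, all} by 3-fold
#' subject-wise inner cross-validation balanced accuracy of a 200-tree
#' forest.
#'
#' @param tbl Training table with `subject_id` and label column.
#' @param feature_cols Candidate feature columns.
#' @param k Integer top-k or `"auto"`. Values above the number of
#'   candidates are clamped with a warning.
#' @param seed RNG seed.
#' @param label_col Label column name.
#' @return Character vector of selected column names (importance order).
#' @export
stage1_select_features <- function(tbl, feature_cols = feature_cols_of(tbl),
                                   k = "auto", seed = 1L,
                                   label_col = "label") {
  y <- factor(tbl[[label_col]])
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 classes to rank features")
  x <- as.matrix(tbl[, feature_cols, drop = FALSE])
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x, droplevels(y), ntree = 500))
  imp <- rf$importance[, "MeanDecreaseGini"]
  ranked <- names(sort(imp, decreasing = TRUE))
  if (identical(k, "auto")) {
    grid <- unique(pmin(c(3, 5, 7, 9, length(ranked)), length(ranked)))
    folds <- subject_wise_folds(tbl, n_folds = min(
      3, length(unique(tbl$subject_id))), seed = seed,
      label_col = label_col)
    fmap <- stats::setNames(folds$fold, folds$subject_id)
    ba <- vapply(grid, function(kk) {
      sel <- ranked[seq_len(kk)]
      mean(vapply(sort(unique(folds$fold)), function(f) {
        tr <- fmap[tbl$subject_id] != f
        if (nlevels(droplevels(y[tr])) < 2 || all(tr) || !any(tr))
          return(NA_real_)
        m <- withr::with_seed(seed + f, randomForest::randomForest(
          x[tr, sel, drop = FALSE], droplevels(y[tr]), ntree = 200))
        balanced_accuracy(y[!tr], predict(m, x[!tr, sel, drop = FALSE]))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    k <- grid[which.max(ba)]
  } else {
    k <- as.integer(k)
    if (k > length(ranked)) {
      warning("k clamped to the number of features (", length(ranked), ")")
      k <- length(ranked)
    }
  }
  ranked[seq_len(k)]
}

#' Pick a classifier by inner subject-wise cross-validation
#'
#' Stage 2 of the training pipeline: each candidate classifier is evaluated
#' on 3 subject-wise inner folds of the training data; minority
#' oversampling (SMOTE) is fit on the inner-training portion only, never on
#' validation rows. The candidate with the highest mean inner balanced
#' accuracy wins; ties go to the first candidate in registry order.
#'
#' @param tbl Training table.
#' @param feature_cols Feature columns to use.
#' @param classifiers Character vector of registry names.
#' @param seed RNG seed.
#' @param label_col Label column.
#' @param inner_folds Number of inner folds (default 3).
#' @return A list with `classifier` (winning name) and `inner_ba` (named
#'   mean inner balanced accuracies).
#' @export
stage2_inner_cv <- function(tbl, feature_cols,
                            classifiers = names(classifier_registry()),
                            seed = 1L, label_col = "label",
                            inner_folds = 3) {
  reg <- classifier_registry(classifiers)
  y <- droplevels(factor(tbl[[label_col]]))
  x <- as.matrix(tbl[, feature_cols, drop = FALSE])
  n_subj <- length(unique(tbl$subject_id))
  folds <- subject_wise_folds(tbl, n_folds = min(inner_folds, n_subj),
                              seed = seed, label_col = label_col)
  fmap <- stats::setNames(folds$fold, folds$subject_id)
  row_fold <- fmap[tbl$subject_id]
  scores <- vapply(names(reg), function(nm) {
    spec <- reg[[nm]]
    mean(vapply(sort(unique(folds$fold)), function(f) {
      tr <- row_fold != f
      if (!any(tr) || !any(!tr) || nlevels(droplevels(y[tr])) < 2)
        return(NA_real_)
      bal <- withr::with_seed(seed + 31 * f, suppressWarnings(
        smote_balance(x[tr, , drop = FALSE], droplevels(y[tr]))))
      model <- spec$fit(bal$x, bal$y, seed + 31 * f)
      balanced_accuracy(y[!tr], spec$predict(model, x[!tr, , drop = FALSE]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(classifier = names(reg)[which.max(scores)], inner_ba = scores)
}

#' Run the three-stage nested cross-validation pipeline
#'
#' For each of `n_folds` outer subject-wise folds: (1) features are ranked
#' and selected on the outer-training rows; (2) when more than one
#' candidate classifier is given, the best is picked by 3-fold subject-wise
#' inner cross-validation with SMOTE oversampling of the inner-training
#' portion; (3) the winner is refit on the oversampled outer-training set
#' and evaluated on the untouched outer-test rows. Balanced accuracy and
#' macro-F1 are reported per fold with their mean and SD.
#'
#' All randomness derives from `seed`, so identical calls give identical
#' results.
#'
#' @param tbl A labeled study table from [build_scenario()] (needs
#'   `subject_id` and `label`).
#' @param feature_cols Feature columns (default: all numeric non-metadata
#'   columns).
#' @param classifiers Registry names to consider (default all seven).
#' @param n_folds Outer folds (default 10).
#' @param top_k Stage-1 selection size or `"auto"`.
#' @param seed Master RNG seed.
#' @param folds Optional precomputed `(subject_id, fold)` assignment, e.g.
#'   to share folds across construction methods.
#' @return An object of class `cv_result`: list with `per_fold` tibble,
#'   `mean_ba`, `sd_ba`, `mean_f1`, `sd_f1`, `folds`, `seed`, `config`.
#' @export
run_nested_cv <- function(tbl, feature_cols = feature_cols_of(tbl),
                          classifiers = names(classifier_registry()),
                          n_folds = 10, top_k = "auto", seed = 1L,
                          folds = NULL) {
  stopifnot("subject_id" %in% names(tbl), "label" %in% names(tbl))
  tbl <- tibble::as_tibble(tbl)
  tbl$label <- droplevels(factor(tbl$label))
  reg <- classifier_registry(classifiers)
  if (is.null(folds))
    folds <- subject_wise_folds(tbl, n_folds = n_folds, seed = seed)
  fmap <- stats::setNames(folds$fold, folds$subject_id)
  row_fold <- fmap[tbl$subject_id]
  per_fold <- list()
  for (f in sort(unique(folds$fold))) {
    seed_f <- seed + 97L * f
    train <- tbl[row_fold != f, , drop = FALSE]
    test <- tbl[row_fold == f, , drop = FALSE]
    if (nrow(test) == 0 || nrow(train) == 0) next
    sel <- stage1_select_features(train, feature_cols, k = top_k,
                                  seed = seed_f)
    chosen <- if (length(reg) > 1)
      stage2_inner_cv(train, sel, classifiers = names(reg),
                      seed = seed_f)$classifier
    else names(reg)[1]
    spec <- reg[[chosen]]
    xtr <- as.matrix(train[, sel, drop = FALSE])
    ytr <- droplevels(train$label)
    bal <- withr::with_seed(seed_f,
                            suppressWarnings(smote_balance(xtr, ytr)))
    model <- spec$fit(bal$x, bal$y, seed_f)
    pred <- spec$predict(model, as.matrix(test[, sel, drop = FALSE]))
    if (!all(levels(tbl$label) %in% as.character(test$label)))
      warning("fold ", f, ": not all classes present in the test fold; ",
              "balanced accuracy computed over present classes")
    per_fold[[length(per_fold) + 1]] <- tibble::tibble(
      fold = f, ba = balanced_accuracy(test$label, pred),
      f1 = macro_f1(test$label, pred), classifier = chosen,
      n_selected = length(sel), selected = paste(sel, collapse = ","))
  }
  per_fold <- dplyr::bind_rows(per_fold)
  structure(list(
    per_fold = per_fold,
    mean_ba = mean(per_fold$ba), sd_ba = stats::sd(per_fold$ba),
    mean_f1 = mean(per_fold$f1), sd_f1 = stats::sd(per_fold$f1),
    folds = folds, seed = seed,
    config = list(classifiers = names(reg), n_folds = n_folds,
                  top_k = top_k, feature_cols = feature_cols)),
    class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d outer folds, classifiers: %s\n",
              nrow(x$per_fold), paste(unique(x$per_fold$classifier),
                                      collapse = ", ")))
  cat(sprintf("  balanced accuracy %.3f +/- %.3f, macro-F1 %.3f +/- %.3f\n",
              x$mean_ba, x$sd_ba, x$mean_f1, x$sd_f1))
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#'
#' @param x A `cv_result`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
cv_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cv_result"))
  obj <- list(per_fold = x$per_fold, mean_ba = x$mean_ba, sd_ba = x$sd_ba,
              mean_f1 = x$mean_f1, sd_f1 = x$sd_f1, seed = x$seed,
              config = x$config)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# scenario = NULL labels rows by group directly (every present group is a
# class); otherwise delegates to build_scenario()
label_table <- function(ft, scenario, sex = "ALL", flash = NULL,
                        eye_mode = NULL) {
  if (is.null(scenario)) {
    ft$label <- factor(ft$group)
    return(ft)
  }
  build_scenario(ft, scenario = scenario, sex = sex, flash = flash,
                 eye_mode = eye_mode)
}

#' Sweep the quantization resolution Q
#'
#' For each Q in the grid: extract features from every waveform, build the
#' scenario, run the nested cross-validation, and record the mean balanced
#' accuracy together with the mean graph density and mean connected
#' component count of the quantization graphs.
#'
#' @param waves List of raw waveforms.
#' @param q_grid Integer vector of Q values (within 2..200).
#' @param scenario,sex,flash,eye_mode Passed to [build_scenario()];
#'   `scenario = NULL` labels rows by their diagnostic group directly.
#' @param classifiers,n_folds,top_k,seed Passed to [run_nested_cv()].
#' @return A tibble `(Q, mean_ba, mean_density, mean_components)`.
#' @export
q_sweep <- function(waves, q_grid = seq(10, 80, 10),
                    scenario = "asd_vs_ctrl", sex = "ALL", flash = NULL,
                    eye_mode = NULL, classifiers = "xgb", n_folds = 10,
                    top_k = 9, seed = 1L) {
  stopifnot(all(q_grid >= 2 & q_grid <= 200))
  rows <- lapply(q_grid, function(Q) {
    ft <- extract_feature_table(waves, Q = Q, method = "erg")
    lab <- label_table(ft, scenario, sex, flash, eye_mode)
    cv <- run_nested_cv(lab, classifiers = classifiers, n_folds = n_folds,
                        top_k = top_k, seed = seed)
    tibble::tibble(Q = Q, mean_ba = cv$mean_ba,
                   mean_density = mean(ft$density),
                   mean_components = mean(ft$n_components))
  })
  dplyr::bind_rows(rows)
}

#' Compare the six graph construction methods
#'
#' Runs the identical preprocessing, feature extraction and nested
#' cross-validation for each requested construction with a single fixed
#' classifier, sharing one fold assignment across methods so the
#' comparison is controlled.
#'
#' @param waves List of raw waveforms.
#' @param methods Construction names (subset of erg, vg, rn, knn, eball,
#'   opn); at least 2.
#' @param Q,params Passed to [extract_feature_table()].
#' @param scenario,sex,flash,eye_mode Passed to [build_scenario()].
#' @param classifier Single registry name (default `"xgb"`).
#' @param n_folds,top_k,seed Passed to [run_nested_cv()].
#' @return A tibble `(method, mean_ba, sd_ba, mean_f1)`; the shared fold
#'   assignment is attached as attribute `folds`.
#' @export
compare_constructions <- function(waves,
                                  methods = c("erg", "vg", "rn", "knn",
                                              "eball", "opn"),
                                  Q = 50, params = list(),
                                  scenario = "asd_vs_ctrl", sex = "ALL",
                                  flash = NULL, eye_mode = NULL,
                                  classifier = "xgb", n_folds = 10,
                                  top_k = 9, seed = 1L) {
  stopifnot(length(methods) >= 2, length(classifier) == 1)
  folds <- NULL
  rows <- lapply(methods, function(m) {
    ft <- extract_feature_table(waves, Q = Q, method = m, params = params)
    lab <- label_table(ft, scenario, sex, flash, eye_mode)
    if (is.null(folds))
      folds <<- subject_wise_folds(lab, n_folds = n_folds, seed = seed)
    cv <- run_nested_cv(lab, classifiers = classifier, n_folds = n_folds,
                        top_k = top_k, seed = seed, folds = folds)
    tibble::tibble(method = m, mean_ba = cv$mean_ba, sd_ba = cv$sd_ba,
                   mean_f1 = cv$mean_f1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "folds") <- folds
  out
}
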