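# standardization helper shared by the distance/gradient based learners;
# zero-variance columns get sd 1 so constants pass through unchanged
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(center = ctr, sd = sdv)
}
apply_scaler <- function(sc, x) sweep(sweep(x, 2, sc$center), 2, sc$sd, "/")

# --- AdaBoost (SAMME) on depth-1 rpart stumps -------------------------------
# multiclass-capable boosting by exponential reweighting; stops early when a
# stump is no better than chance on the weighted sample
fit_adaboost <- function(x, y, n_estimators = 200) {
  df <- data.frame(x)
  K <- nlevels(y)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (b in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y), weights = w,
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2,
                          xval = 0, maxcompete = 0, maxsurrogate = 0))
    pred <- predict(fit, df, type = "class")
    miss <- as.numeric(pred != y)
    err <- sum(w * miss) / sum(w)
    if (err >= 1 - 1 / K || err <= 0) {
      if (err <= 0) { stumps[[b]] <- fit; alphas[b] <- 10 }
      break
    }
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[b]] <- fit
    alphas[b] <- alpha
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(model, x) {
  df <- data.frame(x)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (b in seq_along(model$stumps)) {
    p <- match(as.character(predict(model$stumps[[b]], df, type = "class")),
               model$levels)
    idx <- cbind(seq_len(nrow(df)), p)
    votes[idx] <- votes[idx] + model$alphas[b]
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

fit_xgb <- function(x, y, nrounds, max_depth, eta, seed) {
  K <- nlevels(y)
  params <- c(list(max_depth = max_depth, eta = eta, nthread = 1,
                   seed = seed),
              if (K == 2) list(objective = "binary:logistic")
              else list(objective = "multi:softmax", num_class = K))
  dm <- xgboost::xgb.DMatrix(as.matrix(x), label = as.integer(y) - 1L)
  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = nrounds, verbose = 0)
  list(booster = booster, levels = levels(y))
}

predict_xgb <- function(model, x) {
  p <- predict(model$booster, xgboost::xgb.DMatrix(as.matrix(x)))
  idx <- if (length(model$levels) == 2) as.integer(p > 0.5) + 1L
         else as.integer(p) + 1L
  factor(model$levels[idx], levels = model$levels)
}

#' The classifier registry
#'
#' Seven classifier specifications evaluated by the nested cross-validation
#' pipeline, with conventional defaults pinned here: random forest (`rf`,
#' 500 trees), AdaBoost (`adaboost`, 200 stump estimators, SAMME), gradient
#' boosting (`gradboost`, 200 estimators, depth 3, learning rate 0.1),
#' XGBoost (`xgb`, max depth 6), RBF-kernel SVM (`svm`), k-nearest
#' neighbours (`knn`, k = 5) and a multilayer perceptron (`mlp`, single
#' 128-unit hidden layer as provided by nnet, weight decay 1e-3).
#'
#' Each entry is a list with a `label` and `fit(x, y, seed)` /
#' `predict(model, x)` closures taking a numeric feature matrix and a
#' factor label vector. Model selection ties are broken by registry order.
#'
#' @param names Optional subset of registry names to return.
#' @return A named list of classifier specs.
#' @export
classifier_registry <- function(names = NULL) {
  reg <- list(
    rf = list(
      label = "Random Forest (500 trees)",
      fit = function(x, y, seed) withr::with_seed(seed,
        randomForest::randomForest(x, y, ntree = 500)),
      predict = function(model, x) predict(model, x)),
    adaboost = list(
      label = "AdaBoost (200 stumps, SAMME)",
      fit = function(x, y, seed) withr::with_seed(seed,
        fit_adaboost(x, y, n_estimators = 200)),
      predict = predict_adaboost),
    gradboost = list(
      label = "Gradient Boosting (200 estimators, depth 3, eta 0.1)",
      fit = function(x, y, seed) withr::with_seed(seed,
        fit_xgb(x, y, nrounds = 200, max_depth = 3, eta = 0.1, seed = seed)),
      predict = predict_xgb),
    xgb = list(
      label = "XGBoost (max_depth 6)",
      fit = function(x, y, seed) withr::with_seed(seed,
        fit_xgb(x, y, nrounds = 100, max_depth = 6, eta = 0.3, seed = seed)),
      predict = predict_xgb),
    svm = list(
      label = "SVM (RBF kernel)",
      fit = function(x, y, seed) withr::with_seed(seed, {
        sc <- fit_scaler(x)
        list(svm = e1071::svm(apply_scaler(sc, x), y, kernel = "radial"),
             scaler = sc)
      }),
      predict = function(model, x)
        predict(model$svm, apply_scaler(model$scaler, x))),
    knn = list(
      label = "KNN (k = 5)",
      fit = function(x, y, seed) {
        sc <- fit_scaler(x)
        list(x = apply_scaler(sc, x), y = y, scaler = sc, seed = seed)
      },
      predict = function(model, x) withr::with_seed(model$seed,
        class::knn(model$x, apply_scaler(model$scaler, x), model$y,
                   k = min(5, nrow(model$x))))),
    mlp = list(
      label = "MLP (128 hidden units)",
      fit = function(x, y, seed) withr::with_seed(seed, {
        sc <- fit_scaler(x)
        ymat <- nnet::class.ind(y)
        net <- nnet::nnet(apply_scaler(sc, x), ymat, size = 128,
                          softmax = TRUE, decay = 1e-3, maxit = 200,
                          MaxNWts = 50000, trace = FALSE)
        list(net = net, scaler = sc, levels = levels(y))
      }),
      predict = function(model, x) {
        p <- predict(model$net, apply_scaler(model$scaler, x))
        factor(model$levels[max.col(p, ties.method = "first")],
               levels = model$levels)
      })
  )
  if (is.null(names)) return(reg)
  unknown <- setdiff(names, base::names(reg))
  if (length(unknown) > 0)
    stop("unknown classifier(s): ", paste(unknown, collapse = ", "))
  reg[names]
}
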