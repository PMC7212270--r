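#' Supported classifier families
#'
#' Seven families share one train/predict-probability contract: random
#' forest, extremely randomized trees, gradient boosting, extreme gradient
#' boosting (XGBoost), a linear support vector classifier, a feed-forward
#' deep neural network, and a stacking ensemble (random forest, extra trees,
#' gradient boosting and SVC feeding a DNN meta-learner that also retains
#' the original feature space).
#'
#' @return Character vector of classifier identifiers.
#' @export
classifier_ids <- function() {
  c("random_forest", "extra_trees", "gradient_boosting", "xgboost",
    "svc", "dnn", "stacking")
}

#' Default hyperparameters per classifier family
#'
#' The shipped defaults are the grid-search optima published for this
#' framework (e.g. random forest: 100 trees, depth 15; XGBoost: learning
#' rate 0.01, 300 trees, depth 5; SVC: linear kernel, C = 0.01; DNN: two
#' 32-unit ReLU hidden layers, dropout 0.3, L2 0.01, Adagrad, 50 epochs,
#' batch 128, 2-unit softmax output).  Grid search itself is not
#' re-implemented.
#'
#' @param classifier_id One of [classifier_ids()].
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(classifier_id) {
  switch(
    classifier_id,
    random_forest = list(n_estimators = 100, max_depth = 15,
                         min_samples_leaf = 2, min_samples_split = 4,
                         max_features = "sqrt"),
    extra_trees = list(n_estimators = 100, max_depth = 15,
                       min_samples_leaf = 2, min_samples_split = 5,
                       max_features = "sqrt"),
    gradient_boosting = list(n_estimators = 500, max_depth = 20,
                             min_samples_leaf = 4, learning_rate = 0.1,
                             max_features = "sqrt"),
    xgboost = list(learning_rate = 0.01, n_estimators = 300, max_depth = 5,
                   min_child_weight = 3, gamma = 0, subsample = 0.8,
                   colsample_bytree = 0.8),
    svc = list(kernel = "linear", C = 0.01, gamma = "auto",
               probability = TRUE),
    dnn = list(hidden = c(32, 32), dropout = 0.3, l2 = 0.01,
               epochs = 50, batch_size = 128, learning_rate = 0.01),
    stacking = list(base_ids = c("random_forest", "extra_trees",
                                 "gradient_boosting", "svc"),
                    k_inner = 5),
    stop("unknown classifier id: ", classifier_id, call. = FALSE)
  )
}

#' Build a classifier specification
#'
#' @param classifier_id One of [classifier_ids()].
#' @param hyperparameters Named list of overrides merged over
#'   [default_hyperparameters()]; unknown names are rejected.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(classifier_id, hyperparameters = list()) {
  classifier_id <- match.arg(classifier_id, classifier_ids())
  defaults <- default_hyperparameters(classifier_id)
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown hyperparameter(s) for ", classifier_id, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(classifier_id = classifier_id, hyperparameters = hp),
            class = "classifier_spec")
}

as_classifier_spec <- function(x) {
  if (inherits(x, "classifier_spec")) x else classifier_spec(x)
}

check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(y) != nrow(X)) {
    stop("feature/label length mismatch: ", nrow(X), " rows vs ",
         length(y), " labels", call. = FALSE)
  }
  if (anyNA(X) || anyNA(y)) stop("missing values in training data",
                                 call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  list(X = X, y = y)
}

#' Fit a classifier under the uniform contract
#'
#' @param spec A [classifier_spec()] or a classifier id string.
#' @param X Numeric matrix (genes x features) with column names; no missing
#'   values.
#' @param y Binary labels (0 = unlabeled-as-negative, 1 = positive).
#' @param seed Integer seed; tree, margin and network families are
#'   deterministic under a fixed seed.
#' @return Object of class `pu_model`.
#' @export
fit_classifier <- function(spec, X, y, seed = 1L) {
  spec <- as_classifier_spec(spec)
  d <- check_xy(X, y)
  X <- d$X; y <- d$y
  hp <- spec$hyperparameters
  fit <- with_rng_stream(seed, paste0("fit:", spec$classifier_id), {
    switch(
      spec$classifier_id,
      random_forest = fit_ranger(X, y, hp, extratrees = FALSE, seed),
      extra_trees = fit_ranger(X, y, hp, extratrees = TRUE, seed),
      gradient_boosting = fit_xgb(X, y, list(
        # min_samples_leaf counts rows; xgboost min_child_weight counts
        # hessian mass (~0.25/row for logistic), hence the conversion
        eta = hp$learning_rate, nrounds = hp$n_estimators,
        max_depth = hp$max_depth,
        min_child_weight = 0.25 * hp$min_samples_leaf,
        gamma = 0, subsample = 1,
        colsample_bynode = sqrt(ncol(X)) / ncol(X), colsample_bytree = 1
      ), seed),
      xgboost = fit_xgb(X, y, list(
        eta = hp$learning_rate, nrounds = hp$n_estimators,
        max_depth = hp$max_depth, min_child_weight = hp$min_child_weight,
        gamma = hp$gamma, subsample = hp$subsample,
        colsample_bynode = 1, colsample_bytree = hp$colsample_bytree
      ), seed),
      svc = e1071::svm(X, factor(y, levels = 0:1), kernel = hp$kernel,
                       cost = hp$C, probability = TRUE, scale = FALSE),
      dnn = mlp_fit(X, y, hidden = hp$hidden, dropout = hp$dropout,
                    l2 = hp$l2, epochs = hp$epochs,
                    batch_size = hp$batch_size, lr = hp$learning_rate),
      stacking = fit_stacking_internal(hp$base_ids, X, y, hp$k_inner, seed)
    )
  })
  structure(list(spec = spec, fit = fit, feature_names = colnames(X)),
            class = "pu_model")
}

fit_ranger <- function(X, y, hp, extratrees, seed) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = 0:1)
  args <- list(
    formula = .y ~ ., data = df,
    num.trees = hp$n_estimators,
    mtry = max(1L, floor(sqrt(ncol(X)))),
    max.depth = hp$max_depth,
    min.node.size = hp$min_samples_leaf,
    probability = TRUE, num.threads = 1L,
    seed = derive_rng_stream(seed, "ranger")
  )
  if (extratrees) {
    args$splitrule <- "extratrees"
    args$num.random.splits <- 1L
  }
  do.call(ranger::ranger, args)
}

fit_xgb <- function(X, y, p, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(
    objective = "binary:logistic", eta = p$eta, max_depth = p$max_depth,
    min_child_weight = p$min_child_weight, gamma = p$gamma,
    subsample = p$subsample, colsample_bytree = p$colsample_bytree,
    colsample_bynode = p$colsample_bynode, tree_method = "hist",
    nthread = 1, seed = derive_rng_stream(seed, "xgb")
  )
  xgboost::xgb.train(params = params, data = dtrain, nrounds = p$nrounds,
                     verbose = 0)
}

fit_stacking_internal <- function(base_ids, X, y, k_inner, seed) {
  if (length(base_ids) < 2) {
    stop("stacking requires at least 2 base classifiers", call. = FALSE)
  }
  if (k_inner < 2) stop("k_inner must be >= 2", call. = FALSE)
  folds <- with_rng_stream(seed, "stack:folds",
                           stratified_folds(y, k_inner))
  oof <- matrix(NA_real_, nrow(X), length(base_ids),
                dimnames = list(NULL, paste0("base_", base_ids)))
  for (b in seq_along(base_ids)) {
    for (f in seq_len(k_inner)) {
      test <- folds == f
      m <- fit_classifier(base_ids[b], X[!test, , drop = FALSE], y[!test],
                          seed = derive_rng_stream(seed,
                            paste0("stack:", base_ids[b], ":fold:", f)))
      oof[test, b] <- predict_proba(m, X[test, , drop = FALSE])
    }
  }
  base_models <- lapply(seq_along(base_ids), function(b) {
    fit_classifier(base_ids[b], X, y,
                   seed = derive_rng_stream(seed,
                     paste0("stack:full:", base_ids[b])))
  })
  meta_X <- cbind(X, oof)
  hp <- default_hyperparameters("dnn")
  meta <- with_rng_stream(seed, "stack:meta",
    mlp_fit(meta_X, y, hidden = hp$hidden, dropout = hp$dropout, l2 = hp$l2,
            epochs = hp$epochs, batch_size = hp$batch_size,
            lr = hp$learning_rate))
  list(base_ids = base_ids, base_models = base_models, meta = meta,
       meta_names = colnames(meta_X))
}

#' Predict positive-class probabilities
#'
#' @param model A `pu_model` from [fit_classifier()].
#' @param X Matrix whose columns match the training feature set (names and
#'   order are checked).
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "pu_model") || inherits(model, "mlp") ||
              is.list(model))
  if (!is.matrix(X)) X <- as.matrix(X)
  if (inherits(model, "pu_model")) {
    if (!identical(colnames(X), model$feature_names)) {
      stop("feature mismatch; model was trained on [",
           paste(model$feature_names, collapse = ", "), "] but got [",
           paste(colnames(X), collapse = ", "), "]", call. = FALSE)
    }
    fit <- model$fit
  } else {
    fit <- model
  }
  p <- if (inherits(fit, "ranger")) {
    unname(stats::predict(fit, data = as.data.frame(X),
                          num.threads = 1L)$predictions[, "1"])
  } else if (inherits(fit, "xgb.Booster")) {
    unname(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
  } else if (inherits(fit, "svm")) {
    pr <- attr(stats::predict(fit, X, probability = TRUE), "probabilities")
    unname(pr[, "1"])
  } else if (inherits(fit, "mlp")) {
    mlp_predict(fit, X)
  } else if (is.list(fit) && !is.null(fit$meta)) {
    base_p <- vapply(fit$base_models, function(m) predict_proba(m, X),
                     numeric(nrow(X)))
    if (nrow(X) == 1) base_p <- matrix(base_p, nrow = 1)
    meta_X <- cbind(X, base_p)
    colnames(meta_X) <- fit$meta_names
    mlp_predict(fit$meta, meta_X)
  } else {
    stop("unrecognized fitted model", call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

# Stratified fold assignment: within each class, shuffle then deal members
# round-robin so fold class counts never differ by more than one.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Fit the stacking ensemble
#'
#' Base out-of-fold predictions are computed by internal stratified
#' cross-validation, concatenated with the original features, and fed to a
#' DNN meta-learner (the pass-through configuration, which outperforms
#' prediction-only stacking).
#'
#' @param base_ids Character vector of >= 2 base classifier ids.
#' @param X,y Training data as in [fit_classifier()].
#' @param k_inner Internal fold count (default 5).
#' @param seed Integer seed.
#' @return A `pu_model` with `classifier_id = "stacking"`.
#' @export
fit_stacking <- function(base_ids, X, y, k_inner = 5L, seed = 1L) {
  spec <- classifier_spec("stacking", list(base_ids = base_ids,
                                           k_inner = k_inner))
  fit_classifier(spec, X, y, seed = seed)
}

#' @export
print.pu_model <- function(x, ...) {
  cat("<pu_model>", x$spec$classifier_id, "on",
      length(x$feature_names), "features\n")
  invisible(x)
}
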