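#' Specify a learner
#'
#' Five learner kinds are supported, mirroring the usual tabular-genomics
#' roster: `random_forest` (ranger), `gradient_boosting` and
#' `boosted_trees_xgb_style` (two gradient-boosted-tree presets: a shallow
#' slow-learning-rate configuration and a deeper fast one), and
#' `regularized_linear` (ridge-penalized logistic regression with an
#' internally cross-validated penalty). `stacked_ensemble` is a super
#' learner: base learners produce out-of-fold predictions on the training
#' data and a meta-learner is fit on those predictions.
#'
#' @param kind One of "random_forest", "gradient_boosting",
#'   "regularized_linear", "boosted_trees_xgb_style", "stacked_ensemble".
#' @param hyperparameters Named list overriding the kind's defaults.
#' @param seed Integer seed for the learner's internal randomness.
#' @param base_specs For stacked ensembles: list of >= 2 base learner specs.
#' @param meta_kind Meta-learner kind for stacked ensembles (default
#'   "regularized_linear").
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(kind = c("random_forest", "gradient_boosting",
                                  "regularized_linear", "boosted_trees_xgb_style",
                                  "stacked_ensemble"),
                         hyperparameters = list(), seed = 1L,
                         base_specs = NULL, meta_kind = "regularized_linear") {
  kind <- match.arg(kind)
  if (kind == "stacked_ensemble") {
    if (is.null(base_specs) || length(base_specs) < 2) {
      abort("stacked_ensemble needs >= 2 base_specs", class = "cslvr_config_error")
    }
    stopifnot(all(vapply(base_specs, inherits, logical(1), "learner_spec")))
  }
  defaults <- switch(kind,
    random_forest = list(num.trees = 300L, min.node.size = 5L),
    gradient_boosting = list(eta = 0.1, max_depth = 3L, nrounds = 120L,
                             subsample = 0.8, colsample_bytree = 1.0),
    boosted_trees_xgb_style = list(eta = 0.3, max_depth = 5L, nrounds = 60L,
                                   subsample = 1.0, colsample_bytree = 0.8),
    regularized_linear = list(alpha = 0, nfolds = 5L),
    stacked_ensemble = list(inner_folds = 5L)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed),
                 base_specs = base_specs, meta_kind = meta_kind),
            class = "learner_spec")
}

#' The default learner roster
#'
#' The four base kinds plus a stacked ensemble over all of them.
#'
#' @param seed Seed propagated to every spec.
#' @return Named list of `learner_spec` objects.
#' @export
default_roster <- function(seed = 1L) {
  base <- list(
    random_forest = learner_spec("random_forest", seed = seed),
    gradient_boosting = learner_spec("gradient_boosting", seed = seed),
    regularized_linear = learner_spec("regularized_linear", seed = seed),
    boosted_trees_xgb_style = learner_spec("boosted_trees_xgb_style", seed = seed)
  )
  c(base, list(stacked_ensemble = learner_spec(
    "stacked_ensemble", seed = seed,
    base_specs = unname(base), meta_kind = "regularized_linear"
  )))
}

# --- internal fit / predict ------------------------------------------------

fit_learner <- function(spec, x, y) {
  hp <- spec$hyperparameters
  fitted <- switch(spec$kind,
    random_forest = {
      d <- as.data.frame(x)
      d$.y <- factor(y, levels = c(0, 1))
      local_seed_eval(spec$seed, ranger::ranger(
        dependent.variable.name = ".y", data = d, probability = TRUE,
        num.trees = hp$num.trees, min.node.size = hp$min.node.size,
        importance = "permutation", seed = spec$seed, num.threads = 1
      ))
    },
    gradient_boosting = ,
    boosted_trees_xgb_style = {
      dm <- xgboost::xgb.DMatrix(x, label = y)
      local_seed_eval(spec$seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      nthread = 1, seed = spec$seed),
        data = dm, nrounds = hp$nrounds, verbose = 0
      ))
    },
    regularized_linear = {
      foldid <- local_seed_eval(spec$seed,
                                sample(rep_len(seq_len(hp$nfolds), length(y))))
      local_seed_eval(spec$seed, glmnet::cv.glmnet(
        x, y, family = "binomial", alpha = hp$alpha, foldid = foldid,
        standardize = TRUE
      ))
    },
    stacked_ensemble = fit_stacked(spec, x, y)
  )
  structure(list(spec = spec, model = fitted, feature_names = colnames(x)),
            class = "cslvr_fitted_learner")
}

fit_stacked <- function(spec, x, y) {
  inner <- spec$hyperparameters$inner_folds
  folds <- stratified_folds(y, inner, seed = mix_seed(spec$seed, 101L))
  oof <- matrix(NA_real_, nrow = length(y), ncol = length(spec$base_specs))
  for (f in seq_len(inner)) {
    tr <- folds != f
    for (b in seq_along(spec$base_specs)) {
      bs <- spec$base_specs[[b]]
      bs$seed <- mix_seed(bs$seed, f * 10L + b)
      fit <- fit_learner(bs, x[tr, , drop = FALSE], y[tr])
      oof[!tr, b] <- predict_scores(fit, x[!tr, , drop = FALSE])
    }
  }
  colnames(oof) <- vapply(spec$base_specs, `[[`, character(1), "kind")
  base_fits <- purrr::map(spec$base_specs, fit_learner, x = x, y = y)
  meta_spec <- learner_spec(spec$meta_kind, seed = mix_seed(spec$seed, 777L))
  meta_fit <- fit_learner(meta_spec, oof, y)
  list(base_fits = base_fits, meta_fit = meta_fit, oof_colnames = colnames(oof))
}

predict_scores <- function(fitted, x) {
  spec <- fitted$spec
  switch(spec$kind,
    random_forest = {
      p <- predict(fitted$model, data = as.data.frame(x),
                   num.threads = 1)$predictions
      p[, "1"]
    },
    gradient_boosting = ,
    boosted_trees_xgb_style = predict(fitted$model, xgboost::xgb.DMatrix(x)),
    regularized_linear = as.numeric(
      predict(fitted$model, newx = x, s = "lambda.min", type = "response")),
    stacked_ensemble = {
      base_pred <- vapply(fitted$model$base_fits, predict_scores, numeric(nrow(x)),
                          x = x)
      base_pred <- matrix(base_pred, nrow = nrow(x),
                          dimnames = list(NULL, fitted$model$oof_colnames))
      predict_scores(fitted$model$meta_fit, base_pred)
    }
  )
}

# Stratified fold assignment: within each label class, persons are dealt to
# folds in shuffled order, so fold sizes and class balance differ by at most
# one person.
stratified_folds <- function(y, folds, seed) {
  assignment <- integer(length(y))
  local_seed_eval(seed, {
    for (lab in unique(y)) {
      idx <- sample(which(y == lab))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}
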