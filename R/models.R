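#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a randomly
#' chosen case outscores a randomly chosen control, counting ties as one
#' half. Midranks make this exact under ties without enumerating pairs.
#'
#' @param scores Numeric predictions (higher = more case-like).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)) # 0.75
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("AUC needs both classes present", class = "cslvr_model_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Median imputation of missing feature cells, with medians learned on the
# training rows only. Columns that are entirely missing in training fall
# back to 0 (the nominal diploid value).
impute_by_train <- function(x_train, x_other = NULL) {
  med <- apply(x_train, 2L, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- med[j]
    }
    m
  }
  if (is.null(x_other)) fill(x_train) else list(train = fill(x_train), other = fill(x_other))
}

cslv_feature_matrix <- function(cslv, person_ids) {
  pos <- match(person_ids, cslv$person_id)
  if (anyNA(pos)) {
    abort(sprintf("%d cohort persons missing from the CSLV table", sum(is.na(pos))),
          class = "cslvr_model_error")
  }
  as.matrix(cslv[pos, setdiff(names(cslv), "person_id"), drop = FALSE])
}

#' Fit a learner with cross-validation and a holdout
#'
#' The non-holdout cohort is partitioned into stratified folds; each fold is
#' scored by a model trained on the others, giving every non-holdout person
#' an out-of-fold score. `cv_auc` is the mean of the per-fold AUCs. A final
#' model refit on all non-holdout data scores the holdout and supplies the
#' feature importances. Deterministic given the learner seed and `seed`.
#'
#' @param cslv CSLV feature tibble ([compute_cslv()]).
#' @param assignment Cohort assignment ([match_controls()]).
#' @param learner A [learner_spec()]; default gradient-boosted trees.
#' @param folds Number of CV folds (default 5, >= 2).
#' @param seed Seed for the fold partition.
#' @return A `cslv_model` object: fields `replicate_id`, `learner`,
#'   `cv_auc`, `fold_aucs`, `holdout_auc`, `importances` (max-normalized,
#'   named), `scores` (tibble person_id, score, label, is_holdout; scores
#'   are out-of-fold for training persons and final-model predictions for
#'   holdout persons), `shuffled`.
#' @export
fit_evaluate <- function(cslv, assignment, learner = learner_spec("gradient_boosting"),
                         folds = 5L, seed = 1L) {
  if (folds < 2) abort("folds must be >= 2", class = "cslvr_config_error")
  x_all <- cslv_feature_matrix(cslv, assignment$person_id)
  y_all <- assignment$label
  hold <- assignment$is_holdout
  x_tr <- x_all[!hold, , drop = FALSE]
  y_tr <- y_all[!hold]
  fold_id <- stratified_folds(y_tr, folds, seed = mix_seed(seed, 31L))
  oof <- rep(NA_real_, length(y_tr))
  fold_aucs <- numeric(folds)
  for (f in seq_len(folds)) {
    in_tr <- fold_id != f
    if (length(unique(y_tr[!in_tr])) < 2 || length(unique(y_tr[in_tr])) < 2) {
      abort("A CV fold holds a single class; use a larger cohort or fewer folds",
            class = "cslvr_model_error")
    }
    xs <- impute_by_train(x_tr[in_tr, , drop = FALSE], x_tr[!in_tr, , drop = FALSE])
    sp <- learner
    sp$seed <- mix_seed(learner$seed, 1000L + f)
    fit <- fit_learner(sp, xs$train, y_tr[in_tr])
    oof[!in_tr] <- predict_scores(fit, xs$other)
    fold_aucs[f] <- auc(oof[!in_tr], y_tr[!in_tr])
  }
  # final refit on all non-holdout persons
  if (any(hold)) {
    xs <- impute_by_train(x_tr, x_all[hold, , drop = FALSE])
    final <- fit_learner(learner, xs$train, y_tr)
    hold_scores <- predict_scores(final, xs$other)
    holdout_auc <- if (length(unique(y_all[hold])) == 2) auc(hold_scores, y_all[hold]) else NA_real_
    x_fit <- xs$train
  } else {
    x_fit <- impute_by_train(x_tr)
    final <- fit_learner(learner, x_fit, y_tr)
    hold_scores <- numeric(0)
    holdout_auc <- NA_real_
  }
  scores <- tibble(
    person_id = c(assignment$person_id[!hold], assignment$person_id[hold]),
    score = c(oof, hold_scores),
    label = c(y_tr, y_all[hold]),
    is_holdout = c(rep(FALSE, sum(!hold)), rep(TRUE, sum(hold)))
  )
  structure(list(
    replicate_id = attr(assignment, "replicate_id"),
    learner = learner,
    cv_auc = mean(fold_aucs),
    fold_aucs = fold_aucs,
    holdout_auc = holdout_auc,
    importances = importance_from_fit(final, x_fit, y_tr),
    scores = scores,
    shuffled = isTRUE(attr(assignment, "shuffled"))
  ), class = "cslv_model")
}

#' Fit a stacked ensemble
#'
#' Convenience wrapper: builds a `stacked_ensemble` spec over the given base
#' specs and evaluates it exactly like any other learner. With a single base
#' spec the stack degenerates to (a recalibration of) that learner.
#'
#' @inheritParams fit_evaluate
#' @param base_specs List of base [learner_spec()]s (>= 2 for a true stack).
#' @param meta_kind Meta-learner kind (default "regularized_linear").
#' @return A `cslv_model`.
#' @export
stacked_ensemble_fit <- function(cslv, assignment, base_specs,
                                 meta_kind = "regularized_linear",
                                 folds = 5L, seed = 1L) {
  spec <- learner_spec("stacked_ensemble", base_specs = base_specs,
                       meta_kind = meta_kind, seed = seed)
  fit_evaluate(cslv, assignment, spec, folds = folds, seed = seed)
}

# --- importances -----------------------------------------------------------

# Max-normalize a non-negative importance vector; all-zero stays all-zero.
normalize_importance <- function(v) {
  v[is.na(v)] <- 0
  v <- pmax(v, 0)
  if (max(v) > 0) v <- v / max(v)
  v
}

importance_from_fit <- function(fitted, x, y, n_perm = 10L) {
  spec <- fitted$spec
  raw <- switch(spec$kind,
    gradient_boosting = ,
    boosted_trees_xgb_style = {
      # exact tree-path (SHAP) attribution; last column is the bias term
      contrib <- predict(fitted$model, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
      v <- colMeans(abs(contrib[, seq_len(ncol(x)), drop = FALSE]))
      setNames(as.numeric(v), colnames(x))
    },
    random_forest = {
      v <- ranger::importance(fitted$model)
      setNames(as.numeric(v), names(v))
    },
    regularized_linear = {
      cf <- as.numeric(stats::coef(fitted$model, s = "lambda.min"))[-1]
      sds <- apply(x, 2L, sd)
      setNames(abs(cf) * sds, colnames(x))
    },
    stacked_ensemble = permutation_importance(fitted, x, y, n_perm = n_perm)
  )
  normalize_importance(raw[colnames(x)])
}

# Mean AUC drop over n_perm seeded permutations of each feature column.
permutation_importance <- function(fitted, x, y, n_perm = 10L, seed = 99L) {
  base_auc <- auc(predict_scores(fitted, x), y)
  drops <- local_seed_eval(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(n_perm), function(i) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        base_auc - auc(predict_scores(fitted, xp), y)
      }, numeric(1)))
    }, numeric(1))
  })
  setNames(drops, colnames(x))
}

#' Extract normalized feature importances
#'
#' @param model_result A `cslv_model`.
#' @return Tibble `feature_name`, `importance` sorted descending.
#' @export
importance <- function(model_result) {
  stopifnot(inherits(model_result, "cslv_model"))
  tibble(feature_name = names(model_result$importances),
         importance = as.numeric(model_result$importances)) |>
    arrange(dplyr::desc(.data$importance))
}

#' @export
print.cslv_model <- function(x, ...) {
  cat(sprintf("<cslv_model> %s  cv_auc = %.3f  holdout_auc = %s%s\n",
              x$learner$kind, x$cv_auc,
              ifelse(is.na(x$holdout_auc), "NA", sprintf("%.3f", x$holdout_auc)),
              if (isTRUE(x$shuffled)) "  [label-shuffled]" else ""))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.cslv_model <- function(x, ...) importance(x)

#' Broom-style one-row model summary
#'
#' @param x A `cslv_model`.
#' @param ... Unused.
#' @return One-row tibble with learner kind, `cv_auc`, fold-AUC SD,
#'   `holdout_auc`, shuffled flag.
#' @name glance
#' @export
glance.cslv_model <- function(x, ...) {
  tibble(learner = x$learner$kind, replicate_id = x$replicate_id %||% NA_integer_,
         cv_auc = x$cv_auc, fold_sd = sd(x$fold_aucs),
         holdout_auc = x$holdout_auc, shuffled = x$shuffled)
}

#' Tidy a fitted object's feature importances
#'
#' @param x Fitted object.
#' @param ... Unused.
#' @name tidy
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a
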