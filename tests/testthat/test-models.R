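test_that("auc matches hand counts, handles ties, and rejects single classes", {
  expect_equal(auc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_error(auc(c(1, 2), c(1, 1)), class = "cslvr_model_error")
})

test_that("auc agrees with exhaustive pairwise counting and with pROC", {
  withr::with_seed(83, {
    for (i in 1:100) {
      n <- sample(4:8, 1)
      scores <- sample(seq(0.1, 0.9, by = 0.1), n, replace = TRUE)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      expect_equal(auc(scores, labels), brute_force_auc(scores, labels))
    }
  })
  # independent library cross-check on a handful of instances
  withr::with_seed(89, {
    for (i in 1:5) {
      scores <- rnorm(40)
      labels <- rep(c(0, 1), 20)
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc(scores, labels), ref)
    }
  })
})

test_that("negating tie-free scores mirrors the AUC around one half", {
  withr::with_seed(97, {
    for (i in 1:20) {
      scores <- rnorm(30)
      labels <- rep(c(0, 1), 15)
      expect_equal(auc(scores, labels) + auc(-scores, labels), 1)
    }
  })
})

test_that("cross-validated evaluation is deterministic and internally consistent", {
  a <- make_assignment(rep(c(1L, 0L), each = 40),
                       holdout = rep(c(TRUE, FALSE, FALSE, FALSE), 20))
  cs <- signal_cslv(a, effect = 1.5, seed = 101)
  m1 <- fit_evaluate(cs, a, learner_spec("regularized_linear", seed = 2), seed = 3)
  m2 <- fit_evaluate(cs, a, learner_spec("regularized_linear", seed = 2), seed = 3)
  expect_equal(m1$cv_auc, m2$cv_auc)
  expect_equal(m1$importances, m2$importances)
  expect_equal(m1$cv_auc, mean(m1$fold_aucs))
  expect_length(m1$fold_aucs, 5L)
  expect_true(all(m1$importances >= 0 & m1$importances <= 1))
  expect_equal(max(m1$importances), 1)
  # out-of-fold scores exist for every non-holdout person, predictions for holdout
  expect_setequal(m1$scores$person_id, a$person_id)
  expect_false(anyNA(m1$scores$score))
})

test_that("cv_auc is invariant to person ordering in the feature table", {
  a <- make_assignment(rep(c(1L, 0L), each = 30))
  cs <- signal_cslv(a, effect = 1, seed = 103)
  m_orig <- fit_evaluate(cs, a, learner_spec("regularized_linear", seed = 5), seed = 7)
  cs_perm <- cs[withr::with_seed(1, sample(nrow(cs))), ]
  m_perm <- fit_evaluate(cs_perm, a, learner_spec("regularized_linear", seed = 5), seed = 7)
  expect_equal(m_orig$cv_auc, m_perm$cv_auc)
})

test_that("label leakage is detected by tree learners", {
  a <- make_assignment(rep(c(1L, 0L), each = 50))
  cs <- signal_cslv(a, effect = 0, seed = 107)
  cs$leak <- as.numeric(a$label)
  m <- fit_evaluate(cs, a, learner_spec("boosted_trees_xgb_style", seed = 1), seed = 1)
  expect_gte(m$cv_auc, 0.99)
  expect_equal(names(which.max(m$importances)), "leak")
})

test_that("null features give chance-level AUC across seeds", {
  aucs <- vapply(1:10, function(s) {
    a <- make_assignment(rep(c(1L, 0L), each = 50))
    cs <- signal_cslv(a, n_noise = 9, effect = 0, seed = 200 + s)
    fit_evaluate(cs, a, learner_spec("regularized_linear", seed = s), seed = s)$cv_auc
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("a single informative feature earns importance one in every learner kind", {
  a <- make_assignment(rep(c(1L, 0L), each = 60))
  cs <- signal_cslv(a, n_noise = 5, effect = 3, seed = 109)
  for (kind in c("random_forest", "gradient_boosting", "regularized_linear")) {
    m <- fit_evaluate(cs, a, learner_spec(kind, seed = 11), seed = 11)
    expect_equal(names(which.max(m$importances)), "signal", info = kind)
    expect_equal(max(m$importances), 1, info = kind)
  }
})

test_that("permutation importance of an unused feature is approximately zero", {
  a <- make_assignment(rep(c(1L, 0L), each = 60))
  cs <- signal_cslv(a, n_noise = 3, effect = 3, seed = 113)
  x <- as.matrix(cs[, -1])
  # stump-depth boosting: only the signal feature can be split on
  spec <- learner_spec("gradient_boosting",
                       hyperparameters = list(max_depth = 1L, nrounds = 20L),
                       seed = 13)
  fit <- cslvr:::fit_learner(spec, x, a$label)
  drops <- cslvr:::permutation_importance(fit, x, a$label, n_perm = 5)
  expect_gt(drops[["signal"]], 0.2)
  expect_lt(max(abs(drops[setdiff(names(drops), "signal")])), 0.02)
})

test_that("the stacked ensemble tracks its base learners on a planted signal", {
  base <- list(learner_spec("regularized_linear", seed = 17),
               learner_spec("boosted_trees_xgb_style",
                            hyperparameters = list(nrounds = 30L), seed = 17))
  deltas <- vapply(1:3, function(s) {
    a <- make_assignment(rep(c(1L, 0L), each = 50))
    cs <- signal_cslv(a, n_noise = 5, effect = 1, seed = 300 + s)
    base_aucs <- vapply(base, function(sp) {
      fit_evaluate(cs, a, sp, seed = s)$cv_auc
    }, numeric(1))
    ens <- stacked_ensemble_fit(cs, a, base, seed = s)
    ens$cv_auc - min(base_aucs)
  }, numeric(1))
  expect_true(all(deltas >= -0.02))
})

test_that("tidy and glance expose importances and AUCs", {
  a <- make_assignment(rep(c(1L, 0L), each = 30))
  cs <- signal_cslv(a, effect = 1, seed = 127)
  m <- fit_evaluate(cs, a, learner_spec("regularized_linear", seed = 19), seed = 19)
  td <- tidy(m)
  expect_named(td, c("feature_name", "importance"))
  expect_equal(nrow(td), ncol(cs) - 1L)
  gl <- glance(m)
  expect_equal(gl$cv_auc, m$cv_auc)
  expect_false(gl$shuffled)
})
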