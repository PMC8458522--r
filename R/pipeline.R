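#' Configure an end-to-end experiment
#'
#' Bundles every knob of the replicated analysis: which split resolutions to
#' run, how many matched-cohort replicates, the learner roster, holdout
#' fraction, sex matching, an optional X-only arm at finer resolution, and
#' an optional label-shuffled arm for the permutation null.
#'
#' Inputs may be in-memory objects (probe-map tibble, persons x probes
#' matrix, phenotype tibble) or paths: a probe-map TSV, a directory of
#' `chr{c}.l2r.txt` files with persons sidecars, a phenotype TSV.
#'
#' @param probe_map Probe map tibble or TSV path.
#' @param l2r Persons x probes matrix or directory of per-chromosome l2r
#'   files.
#' @param phenotypes Phenotype tibble or TSV path.
#' @param splits Integer vector of split resolutions (default c(1, 4, 8)).
#' @param x_only Restrict to chromosome X and use `k_x` splits?
#' @param k_x Split count for the X-only arm (default 64).
#' @param n_replicates Matched-cohort replicates per split value.
#' @param roster Named list of [learner_spec()]s; default [default_roster()].
#' @param holdout_fraction Per-replicate stratified holdout (default 0.30).
#' @param match_sex Sex-match the controls?
#' @param n_shuffled_replicates Label-shuffled replicates for the
#'   permutation-null arm (0 disables it).
#' @param folds CV folds (default 5).
#' @param master_seed Master seed; every stage derives from it.
#' @param output_dir Optional directory for TSV outputs and the manifest.
#' @param split_mode "probes" (default) or "bp" (see [make_split_scheme()]).
#' @return A `run_config` list.
#' @export
run_config <- function(probe_map, l2r, phenotypes,
                       splits = c(1L, 4L, 8L), x_only = FALSE, k_x = 64L,
                       n_replicates = 100L, roster = NULL,
                       holdout_fraction = 0.30, match_sex = FALSE,
                       n_shuffled_replicates = 0L, folds = 5L,
                       master_seed = 1L, output_dir = NULL,
                       split_mode = "probes") {
  if (any(splits < 1)) abort("splits must be >= 1", class = "cslvr_config_error")
  structure(list(
    probe_map = probe_map, l2r = l2r, phenotypes = phenotypes,
    splits = as.integer(splits), x_only = x_only, k_x = as.integer(k_x),
    n_replicates = as.integer(n_replicates),
    roster = roster %||% default_roster(seed = master_seed),
    holdout_fraction = holdout_fraction, match_sex = match_sex,
    n_shuffled_replicates = as.integer(n_shuffled_replicates),
    folds = as.integer(folds), master_seed = as.integer(master_seed),
    output_dir = output_dir, split_mode = split_mode
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat keys mirroring the [run_config()] arguments; unknown keys are
#' rejected. The learner roster cannot be expressed in YAML and falls back
#' to the default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The yaml package is needed to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "roster")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "cslvr_config_error")
  }
  do.call(run_config, raw)
}

resolve_inputs <- function(config) {
  pm <- config$probe_map
  if (is.character(pm)) pm <- read_probe_map(pm)
  ph <- config$phenotypes
  if (is.character(ph)) ph <- read_phenotypes(ph)
  l2r <- config$l2r
  if (is.character(l2r)) {
    parts <- purrr::map(unique(pm$chromosome), function(chrom) {
      read_l2r(file.path(l2r, sprintf("chr%s.l2r.txt", chrom)), pm,
               chromosome = chrom)
    })
    l2r <- do.call(cbind, parts)
  }
  list(probe_map = pm, l2r = l2r, phenotypes = ph)
}

#' Run the replicated CSLV experiment
#'
#' For every split resolution and every matched-cohort replicate, fits the
#' whole learner roster with cross-validation and a holdout, then
#' aggregates: per-learner AUC summaries, Welch comparisons of each finer
#' split scheme against the coarsest, a quintile odds-ratio table on the
#' pooled out-of-fold scores of the best-mean learner at the finest
#' resolution (each person's score is their mean over the replicates that
#' contain them), the models x features importance matrix, and — when a
#' shuffled arm is configured — label-shuffled replicates with a Welch
#' comparison of the real-label and shuffled-label AUC distributions.
#'
#' @param config A [run_config()].
#' @return A `cslv_run` list; see the fields in the return section of the
#'   package vignette. Key elements: `results` (one row per replicate x
#'   split x learner), `summaries`, `split_tests`, `quintile_table`,
#'   `importances`, `shuffled_results`, `welch_shuffled`, `manifest`.
#' @export
run_experiment <- function(config) {
  inputs <- resolve_inputs(config)
  pm <- inputs$probe_map
  l2r <- inputs$l2r
  ph <- inputs$phenotypes
  splits <- config$splits
  if (config$x_only) {
    keep <- pm$chromosome == "X"
    l2r <- l2r[, keep, drop = FALSE]
    pm <- as_probe_map(pm[keep, c("probe_id", "chromosome", "position_bp")])
    splits <- config$k_x
  }
  replicates <- make_replicates(ph, config$n_replicates,
                                seed = config$master_seed,
                                match_sex = config$match_sex,
                                holdout_fraction = config$holdout_fraction)
  schemes <- setNames(
    purrr::map(splits, ~make_split_scheme(pm, .x, mode = config$split_mode)),
    as.character(splits))
  results <- list()
  imp_rows <- list()
  score_rows <- list()
  for (k in splits) {
    scheme <- schemes[[as.character(k)]]
    cslv <- compute_cslv(l2r, pm, scheme)
    for (r in seq_along(replicates)) {
      for (ln in names(config$roster)) {
        sp <- config$roster[[ln]]
        sp$seed <- mix_seed(config$master_seed, k * 100000L + r * 100L + match(ln, names(config$roster)))
        fit <- fit_evaluate(cslv, replicates[[r]], sp, folds = config$folds,
                            seed = sp$seed)
        results[[length(results) + 1L]] <- glance(fit) |> mutate(k = k, replicate_id = r)
        imp_rows[[length(imp_rows) + 1L]] <- importance(fit) |>
          mutate(k = k, replicate_id = r, learner = ln)
        score_rows[[length(score_rows) + 1L]] <- fit$scores |>
          mutate(k = k, replicate_id = r, learner = ln)
      }
    }
  }
  results <- bind_rows(results)
  importances <- bind_rows(imp_rows)
  scores <- bind_rows(score_rows)
  summaries <- results |>
    group_by(.data$k, .data$learner) |>
    summarise(summarize_aucs(.data$cv_auc,
                             label = sprintf("k=%d/%s", .data$k[1], .data$learner[1])),
              .groups = "drop")
  # best model per replicate = max cv_auc over the roster; finer-vs-coarsest
  # Welch tests on those per-replicate bests
  best_per_rep <- results |>
    group_by(.data$k, .data$replicate_id) |>
    summarise(cv_auc = max(.data$cv_auc), .groups = "drop")
  k0 <- splits[1]
  split_tests <- NULL
  if (length(splits) > 1) {
    base_aucs <- best_per_rep$cv_auc[best_per_rep$k == k0]
    split_tests <- bind_rows(purrr::map(splits[-1], function(k) {
      welch_from_samples(best_per_rep$cv_auc[best_per_rep$k == k], base_aucs) |>
        mutate(comparison = sprintf("k=%d vs k=%d", k, k0), .before = 1)
    }))
  }
  k_max <- max(splits)
  best_learner <- summaries |>
    filter(.data$k == k_max) |>
    arrange(dplyr::desc(.data$mean_auc)) |>
    pull(.data$learner) |>
    head(1)
  pooled <- scores |>
    filter(.data$k == k_max, .data$learner == best_learner) |>
    group_by(.data$person_id) |>
    summarise(score = mean(.data$score), label = .data$label[1], .groups = "drop")
  # small pooled cohorts can empty a quintile cell; fall back to the
  # continuity-corrected table rather than aborting the whole run
  qt <- tryCatch(quintile_table(pooled),
                 cslvr_stats_error = function(e) quintile_table(pooled, correct = TRUE))
  shuffled_results <- NULL
  welch_shuffled <- NULL
  if (config$n_shuffled_replicates > 0) {
    sp <- config$roster[[best_learner]]
    cslv_max <- compute_cslv(l2r, pm, schemes[[as.character(k_max)]])
    shuf_rows <- purrr::map(seq_len(config$n_shuffled_replicates), function(r) {
      a <- replicates[[((r - 1L) %% length(replicates)) + 1L]]
      a <- shuffle_labels(a, seed = mix_seed(config$master_seed, 5000L + r))
      spr <- sp
      spr$seed <- mix_seed(config$master_seed, 7000L + r)
      glance(fit_evaluate(cslv_max, a, spr, folds = config$folds, seed = spr$seed)) |>
        mutate(k = k_max, replicate_id = r)
    })
    shuffled_results <- bind_rows(shuf_rows)
    normal_aucs <- results$cv_auc[results$k == k_max & results$learner == best_learner]
    welch_shuffled <- welch_from_samples(normal_aucs, shuffled_results$cv_auc) |>
      mutate(comparison = "normal vs shuffled", .before = 1)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cslvr")),
    master_seed = config$master_seed,
    splits = splits, n_replicates = config$n_replicates,
    match_sex = config$match_sex, x_only = config$x_only,
    holdout_fraction = config$holdout_fraction,
    roster = names(config$roster),
    replicate_seeds = vapply(seq_along(replicates), mix_seed,
                             integer(1), seed = config$master_seed),
    digests = list(results = rlang::hash(results),
                   importances = rlang::hash(importances))
  )
  run <- structure(list(
    results = results, summaries = summaries, split_tests = split_tests,
    best_learner = best_learner, quintile_table = qt, pooled_scores = pooled,
    importances = importances, schemes = schemes, probe_map = pm,
    shuffled_results = shuffled_results, welch_shuffled = welch_shuffled,
    manifest = manifest, config = config
  ), class = "cslv_run")
  if (!is.null(config$output_dir)) write_run_outputs(run, config$output_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$results, file.path(out_dir, "model_results.tsv"), progress = FALSE)
  readr::write_tsv(run$summaries, file.path(out_dir, "auc_summaries.tsv"), progress = FALSE)
  if (!is.null(run$split_tests)) {
    readr::write_tsv(run$split_tests, file.path(out_dir, "split_tests.tsv"), progress = FALSE)
  }
  readr::write_tsv(run$quintile_table, file.path(out_dir, "quintile_table.tsv"), progress = FALSE)
  readr::write_tsv(run$importances, file.path(out_dir, "importances.tsv"), progress = FALSE)
  if (!is.null(run$shuffled_results)) {
    readr::write_tsv(run$shuffled_results, file.path(out_dir, "shuffled_results.tsv"),
                     progress = FALSE)
    readr::write_tsv(run$welch_shuffled, file.path(out_dir, "welch_shuffled.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Localize the most predictive chromosome regions
#'
#' Ranks features by mean normalized importance across all models at one
#' split resolution and maps the top entries back to genomic coordinates
#' (interval = first to last probe of the split). Optionally exports BED.
#'
#' @param run A `cslv_run`.
#' @param top_n How many regions to report; values beyond the feature count
#'   return the full ranking.
#' @param k Split resolution to localize (default: the finest in the run).
#' @param bed_path Optional BED output path (0-based half-open).
#' @return Tibble: `rank`, `feature_name`, `mean_importance`, `chromosome`,
#'   `start_bp`, `end_bp`, `label` (rendered `chr{c}:{start}–{end}`).
#' @export
localize <- function(run, top_n = 7L, k = NULL, bed_path = NULL) {
  stopifnot(inherits(run, "cslv_run"))
  if (is.null(run$importances) || nrow(run$importances) == 0) {
    abort("Run holds no importances", class = "cslvr_config_error")
  }
  k <- k %||% max(run$importances$k)
  scheme <- run$schemes[[as.character(k)]]
  ranked <- run$importances |>
    filter(.data$k == !!k) |>
    group_by(.data$feature_name) |>
    summarise(mean_importance = mean(.data$importance), .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_importance)) |>
    mutate(rank = row_number(), .before = 1) |>
    head(min(top_n, nrow(scheme)))
  coords <- split_coordinates(scheme, run$probe_map)
  out <- ranked |> left_join(coords, by = "feature_name")
  if (!is.null(bed_path)) write_bed(out, bed_path)
  out
}

#' @export
print.cslv_run <- function(x, ...) {
  cat(sprintf("<cslv_run> %d replicates x k in {%s} x %d learners\n",
              x$config$n_replicates, paste(x$config$splits, collapse = ","),
              length(x$config$roster)))
  print(x$summaries)
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.cslv_run <- function(x, ...) x$results

#' @rdname glance
#' @export
glance.cslv_run <- function(x, ...) x$summaries
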