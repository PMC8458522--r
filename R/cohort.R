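#' Draw an exactly matched case-control cohort
#'
#' Takes every case in the phenotype table and draws an equal number of
#' controls from the non-case pool so that the control age multiset is
#' identical to the case age multiset (exact per integer year; with
#' `match_sex = TRUE` the joint age-by-sex multisets are identical).
#' Controls are drawn uniformly without replacement within each stratum. A
#' 30% holdout (configurable), stratified by label, is reserved before any
#' cross-validation.
#'
#' @param phenotypes Phenotype tibble ([read_phenotypes()] format).
#' @param replicate_id Integer replicate index; combined with `seed` to give
#'   each replicate its own reproducible draw.
#' @param seed Master seed.
#' @param match_sex Also match sex within age strata?
#' @param holdout_fraction Fraction of each label class held out (default
#'   0.30); 0 disables the holdout.
#' @return A `cohort_assignment` tibble: one row per selected person with
#'   `person_id`, `age_years`, `sex`, `label` (1 = case), `is_holdout`.
#'   Attributes: `replicate_id`, `seed`, `match_sex`, `shuffled`.
#' @export
match_controls <- function(phenotypes, replicate_id = 1L, seed = 1L,
                           match_sex = FALSE, holdout_fraction = 0.30) {
  phenotypes <- validate_phenotypes(phenotypes)
  cases <- phenotypes |> filter(.data$is_case)
  pool <- phenotypes |> filter(!.data$is_case)
  if (nrow(cases) == 0) abort("No cases in phenotype table", class = "cslvr_cohort_error")
  strat_key <- function(d) {
    if (match_sex) paste(d$age_years, d$sex, sep = "/") else as.character(d$age_years)
  }
  case_strata <- table(strat_key(cases))
  pool_key <- strat_key(pool)
  rep_seed <- mix_seed(seed, replicate_id)
  controls <- local_seed_eval(rep_seed, {
    picked <- character(0)
    for (stratum in names(case_strata)) {
      need <- case_strata[[stratum]]
      avail <- pool$person_id[pool_key == stratum]
      if (length(avail) < need) {
        abort(sprintf("Stratum %s: need %d controls, pool has %d (deficit %d)",
                      stratum, need, length(avail), need - length(avail)),
              class = "cslvr_cohort_error")
      }
      picked <- c(picked, sample(avail, need))
    }
    picked
  })
  out <- bind_rows(
    cases |> mutate(label = 1L),
    pool |> filter(.data$person_id %in% controls) |> mutate(label = 0L)
  ) |>
    select("person_id", "age_years", "sex", "label")
  out$is_holdout <- FALSE
  if (holdout_fraction > 0) {
    out$is_holdout <- local_seed_eval(mix_seed(rep_seed, 7L), {
      flag <- logical(nrow(out))
      for (lab in c(0L, 1L)) {
        idx <- which(out$label == lab)
        n_hold <- round(length(idx) * holdout_fraction)
        flag[sample(idx, n_hold)] <- TRUE
      }
      flag
    })
  }
  structure(out, replicate_id = as.integer(replicate_id), seed = as.integer(seed),
            match_sex = match_sex, shuffled = FALSE,
            class = c("cohort_assignment", class(out)))
}

#' Build many replicate cohorts with distinct control sets
#'
#' Replicate r draws with a seed derived deterministically from
#' `(seed, r)`, so any replicate is reproducible in isolation. Control sets
#' are verified pairwise non-identical as sets (overlap is allowed); on a
#' collision the replicate is re-drawn with a perturbed seed, up to a
#' bounded number of retries.
#'
#' @inheritParams match_controls
#' @param n_replicates Number of cohorts to draw.
#' @param max_retries Redraw budget per replicate on control-set collision.
#' @return List of `cohort_assignment` tibbles.
#' @export
make_replicates <- function(phenotypes, n_replicates, seed = 1L,
                            match_sex = FALSE, holdout_fraction = 0.30,
                            max_retries = 25L) {
  if (n_replicates < 1) abort("n_replicates must be >= 1", class = "cslvr_config_error")
  seen <- character(0)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ok <- FALSE
    for (attempt in 0:max_retries) {
      a <- match_controls(phenotypes, replicate_id = r * 1000L + attempt,
                          seed = seed, match_sex = match_sex,
                          holdout_fraction = holdout_fraction)
      key <- paste(sort(a$person_id[a$label == 0L]), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        attr(a, "replicate_id") <- r
        out[[r]] <- a
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf("Could not draw a distinct control set for replicate %d; pool too small", r),
            class = "cslvr_cohort_error")
    }
  }
  out
}

#' Shuffle cohort labels for a permutation null
#'
#' Returns a copy of the assignment with labels permuted uniformly at
#' random. The ID sets, ages and holdout membership are untouched; only the
#' case/control assignment moves, so the label multiset is conserved.
#'
#' @param assignment A `cohort_assignment`.
#' @param seed Integer seed for the permutation.
#' @return The shuffled assignment, with attribute `shuffled = TRUE`.
#' @export
shuffle_labels <- function(assignment, seed = 1L) {
  out <- assignment
  out$label <- local_seed_eval(mix_seed(seed, 13L), sample(assignment$label))
  attr(out, "shuffled") <- TRUE
  out
}
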