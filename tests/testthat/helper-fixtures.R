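# Shared fixture builders and independent oracles. Everything is generated
# in code; no files ship with the tests.

# Hand-built probe map on three chromosomes with deliberately irregular
# probe spacing.
tiny_probe_map <- function() {
  as_probe_map(tibble::tibble(
    probe_id = c("a1", "a2", "a3", "a4", "b1", "b2", "x1", "x2", "x3"),
    chromosome = c("1", "1", "1", "1", "2", "2", "X", "X", "X"),
    position_bp = c(100L, 250L, 900L, 5000L, 10L, 20L, 500L, 600L, 70000L)
  ))
}

# Deterministic 23-chromosome map with n probes per chromosome at fixed
# positions; cheap enough to rebuild per test.
full_probe_map <- function(n = 10L) {
  rows <- lapply(cslv_chromosomes(), function(chrom) {
    tibble::tibble(
      probe_id = sprintf("%s_%03d", chrom, seq_len(n)),
      chromosome = chrom,
      position_bp = seq(1000L, by = 1000L, length.out = n)
    )
  })
  as_probe_map(dplyr::bind_rows(rows))
}

# Independent brute-force oracle for CSLV: explicit double loop over
# persons and splits, averaging non-missing probe values one by one.
brute_force_cslv <- function(l2r, scheme) {
  out <- matrix(NA_real_, nrow = nrow(l2r), ncol = nrow(scheme))
  for (p in seq_len(nrow(l2r))) {
    for (s in seq_len(nrow(scheme))) {
      acc <- c()
      for (j in seq(scheme$probe_start[s], scheme$probe_end[s])) {
        v <- l2r[p, j]
        if (!is.na(v)) acc <- c(acc, v)
      }
      if (length(acc) > 0) out[p, s] <- sum(acc) / length(acc)
    }
  }
  out
}

# Independent brute-force AUC: enumerate every case-control pair.
brute_force_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (ca in cases) {
    for (co in controls) {
      tot <- tot + (ca > co) + 0.5 * (ca == co)
    }
  }
  tot / (length(cases) * length(controls))
}

# Minimal cohort assignment without going through matching, for direct
# model tests.
make_assignment <- function(labels, holdout = rep(FALSE, length(labels)),
                            ids = sprintf("P%03d", seq_along(labels))) {
  structure(
    tibble::tibble(person_id = ids, age_years = 50L, sex = "female",
                   label = as.integer(labels), is_holdout = holdout),
    replicate_id = 1L, seed = 1L, match_sex = FALSE, shuffled = FALSE,
    class = c("cohort_assignment", class(tibble::tibble()))
  )
}

# A phenotype pool with a fixed number of cases and ample controls.
pool_phenotypes <- function(n_cases = 30L, n_pool = 300L, seed = 1L,
                            ages = 40:69) {
  withr::with_seed(seed, tibble::tibble(
    person_id = sprintf("H%05d", seq_len(n_cases + n_pool)),
    age_years = sample(ages, n_cases + n_pool, replace = TRUE),
    sex = sample(c("female", "male"), n_cases + n_pool, replace = TRUE),
    is_case = c(rep(TRUE, n_cases), rep(FALSE, n_pool))
  ))
}

# Cohort features where one named column carries signal proportional to the
# label plus noise; the rest are pure noise.
signal_cslv <- function(assignment, n_noise = 9L, effect = 2, seed = 1L) {
  n <- nrow(assignment)
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * (n_noise + 1L)), nrow = n)
    m[, 1] <- m[, 1] + effect * assignment$label
    colnames(m) <- c("signal", sprintf("noise%02d", seq_len(n_noise)))
    dplyr::bind_cols(tibble::tibble(person_id = assignment$person_id),
                     tibble::as_tibble(m))
  })
}
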