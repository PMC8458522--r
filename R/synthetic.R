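#' Describe a planted copy-number segment
#'
#' A contiguous genomic interval whose carriers have their l2r shifted by the
#' copy-state effect: a heterozygous deletion shifts by log2(1/2) = -1, a
#' single-copy duplication by log2(3/2) ~ +0.585. Carrier status is drawn
#' per person with a phenotype-specific frequency, which is how the
#' simulator plants case-control signal.
#'
#' @param chromosome Chromosome label ("1".."22", "X").
#' @param start_bp,end_bp 1-based inclusive interval bounds.
#' @param copy_state "deletion" or "duplication".
#' @param carrier_freq_cases,carrier_freq_controls Carrier probabilities in
#'   \[0, 1\] for cases and non-cases.
#' @return A `planted_segment` list.
#' @export
planted_segment <- function(chromosome, start_bp, end_bp,
                            copy_state = c("duplication", "deletion"),
                            carrier_freq_cases, carrier_freq_controls) {
  copy_state <- match.arg(copy_state)
  check_chromosomes(chromosome)
  if (start_bp > end_bp) abort("start_bp must be <= end_bp", class = "cslvr_config_error")
  freqs <- c(carrier_freq_cases, carrier_freq_controls)
  if (any(freqs < 0 | freqs > 1)) {
    abort("carrier frequencies must lie in [0, 1]", class = "cslvr_config_error")
  }
  structure(list(
    chromosome = chromosome,
    start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
    copy_state = copy_state,
    l2r_shift = if (copy_state == "duplication") log2(3 / 2) else log2(1 / 2),
    carrier_freq_cases = carrier_freq_cases,
    carrier_freq_controls = carrier_freq_controls
  ), class = "planted_segment")
}

#' Configure the synthetic cohort simulator
#'
#' The simulator emulates the structure of SNP-array l2r releases: per-probe
#' Gaussian intensity noise around a per-person baseline, planted CNV
#' segments whose carrier frequency may differ between cases and controls, a
#' constant additive shift on all X-chromosome probes of males (real arrays
#' are sex-normalized to an unknown degree, so the shift is a free parameter
#' rather than the one-copy value of -1), and ages drawn uniformly over a
#' recruitment window independently of case status.
#'
#' @param n_cases Number of cases.
#' @param n_controls_pool Number of non-case persons available for matching.
#' @param probes_per_chromosome Named integer vector, chromosome -> probe
#'   count. Default: 50 probes on each of 1..22 and X.
#' @param chromosome_length_bp Named vector of chromosome lengths in bp;
#'   defaults to 100 Mb each.
#' @param noise_sd Per-probe l2r standard deviation (default 0.15).
#' @param person_offset_sd SD of the per-person baseline shift (default 0.02).
#' @param cnv_segments List of [planted_segment()] objects.
#' @param male_x_shift Additive l2r shift applied to X probes of males
#'   (default -0.10: detectable, not dominant).
#' @param age_range Integer recruitment window, default c(40, 69).
#' @param sex_ratio Probability a person is female, in (0, 1).
#' @param seed Integer master seed; all draws are deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 500,
                              n_controls_pool = 2000,
                              probes_per_chromosome = NULL,
                              chromosome_length_bp = NULL,
                              noise_sd = 0.15,
                              person_offset_sd = 0.02,
                              cnv_segments = list(),
                              male_x_shift = -0.10,
                              age_range = c(40L, 69L),
                              sex_ratio = 0.5,
                              seed = 1L) {
  if (is.null(probes_per_chromosome)) {
    probes_per_chromosome <- setNames(rep(50L, 23L), cslv_chromosomes())
  }
  check_chromosomes(names(probes_per_chromosome))
  if (is.null(chromosome_length_bp)) {
    chromosome_length_bp <- setNames(rep(1e8, length(probes_per_chromosome)),
                                     names(probes_per_chromosome))
  }
  if (noise_sd <= 0) abort("noise_sd must be > 0", class = "cslvr_config_error")
  if (person_offset_sd < 0) abort("person_offset_sd must be >= 0", class = "cslvr_config_error")
  if (any(probes_per_chromosome < 1)) {
    abort("probes_per_chromosome must be >= 1 for every declared chromosome",
          class = "cslvr_config_error")
  }
  if (sex_ratio <= 0 || sex_ratio >= 1) abort("sex_ratio must be in (0, 1)",
                                              class = "cslvr_config_error")
  for (chrom in names(probes_per_chromosome)) {
    if (probes_per_chromosome[[chrom]] > chromosome_length_bp[[chrom]]) {
      abort(sprintf("Chromosome %s: %d probes exceed length %g bp", chrom,
                    probes_per_chromosome[[chrom]], chromosome_length_bp[[chrom]]),
            class = "cslvr_config_error")
    }
  }
  stopifnot(all(vapply(cnv_segments, inherits, logical(1), "planted_segment")))
  structure(list(
    n_cases = as.integer(n_cases),
    n_controls_pool = as.integer(n_controls_pool),
    probes_per_chromosome = probes_per_chromosome,
    chromosome_length_bp = chromosome_length_bp,
    noise_sd = noise_sd,
    person_offset_sd = person_offset_sd,
    cnv_segments = cnv_segments,
    male_x_shift = male_x_shift,
    age_range = as.integer(age_range),
    sex_ratio = sex_ratio,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a probe map
#'
#' For each declared chromosome, draws the configured number of probe
#' positions uniformly without replacement from `[1, chromosome_length_bp]`
#' and sorts them. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return Canonical probe-map tibble.
#' @export
simulate_probe_map <- function(config) {
  local_seed_eval(mix_seed(config$seed, 1L), {
    maps <- purrr::map(names(config$probes_per_chromosome), function(chrom) {
      n <- config$probes_per_chromosome[[chrom]]
      len <- config$chromosome_length_bp[[chrom]]
      pos <- sort(sample.int(len, n, replace = FALSE))
      tibble(probe_id = sprintf("%s_p%06d", chrom, seq_len(n)),
             chromosome = chrom, position_bp = pos)
    })
    as_probe_map(bind_rows(maps))
  })
}

#' Simulate an l2r cohort
#'
#' Each person's value at a probe is
#' `person_offset + segment_shift + male_x_shift + N(0, noise_sd)`,
#' where `segment_shift` applies when the person carries a planted segment
#' covering the probe, and `male_x_shift` when the person is male and the
#' probe is on X. Case status is fixed by the config counts; carrier status
#' is Bernoulli with the phenotype-specific frequency; ages are uniform over
#' the recruitment window independently of case status.
#'
#' @param config A [simulation_config()].
#' @param probe_map Probe map, typically from [simulate_probe_map()].
#' @return List with `l2r` (persons x probes matrix) and `phenotypes`
#'   (tibble person_id, age_years, sex, is_case).
#' @export
simulate_cohort <- function(config, probe_map) {
  n <- config$n_cases + config$n_controls_pool
  p <- nrow(probe_map)
  local_seed_eval(mix_seed(config$seed, 2L), {
    phenotypes <- tibble(
      person_id = sprintf("P%06d", seq_len(n)),
      age_years = sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE),
      sex = ifelse(runif(n) < config$sex_ratio, "female", "male"),
      is_case = c(rep(TRUE, config$n_cases), rep(FALSE, config$n_controls_pool))
    )
    values <- matrix(rnorm(n * p, sd = config$noise_sd), nrow = n) +
      rnorm(n, sd = config$person_offset_sd)
    if (config$male_x_shift != 0) {
      x_cols <- which(probe_map$chromosome == "X")
      if (length(x_cols) > 0) {
        male <- phenotypes$sex == "male"
        values[male, x_cols] <- values[male, x_cols] + config$male_x_shift
      }
    }
    for (seg in config$cnv_segments) {
      cols <- which(probe_map$chromosome == seg$chromosome &
                      probe_map$position_bp >= seg$start_bp &
                      probe_map$position_bp <= seg$end_bp)
      if (length(cols) == 0) next
      freq <- ifelse(phenotypes$is_case, seg$carrier_freq_cases, seg$carrier_freq_controls)
      carrier <- runif(n) < freq
      values[carrier, cols] <- values[carrier, cols] + seg$l2r_shift
    }
    list(l2r = l2r_matrix(values, phenotypes$person_id, probe_map),
         phenotypes = phenotypes)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits a probe map, one l2r file per chromosome (plus persons sidecar), a
#' phenotype TSV, and a JSON manifest recording the configuration and seed,
#' in the exact dialects the readers accept. Re-running with the same config
#' produces byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param out_dir Writable directory (created if absent).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probe_map <- simulate_probe_map(config)
  cohort <- simulate_cohort(config, probe_map)
  pm_path <- file.path(out_dir, "probe_map.tsv")
  readr::write_tsv(probe_map[c("probe_id", "chromosome", "position_bp")],
                   pm_path, progress = FALSE)
  l2r_paths <- character(0)
  for (chrom in unique(probe_map$chromosome)) {
    cols <- probe_map$chromosome == chrom
    path <- file.path(out_dir, sprintf("chr%s.l2r.txt", chrom))
    write_l2r(cohort$l2r[, cols, drop = FALSE],
              probe_map[cols, , drop = FALSE], path)
    l2r_paths <- c(l2r_paths, path)
  }
  ph_path <- file.path(out_dir, "phenotypes.tsv")
  write_phenotypes(cohort$phenotypes, ph_path)
  manifest <- list(
    config = config[setdiff(names(config), "cnv_segments")],
    cnv_segments = purrr::map(config$cnv_segments, unclass),
    files = c(probe_map = pm_path, phenotypes = ph_path),
    l2r_files = l2r_paths
  )
  mf_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(probe_map = pm_path, l2r = l2r_paths,
                 phenotypes = ph_path, manifest = mf_path))
}
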