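test_that("simulated probe maps have the configured size and are seed-deterministic", {
  cfg <- simulation_config(n_cases = 5, n_controls_pool = 20, seed = 3)
  pm <- simulate_probe_map(cfg)
  expect_equal(nrow(pm), 23L * 50L)
  expect_equal(pm, simulate_probe_map(cfg))
  # saturated draw is exhaustive
  cfg2 <- simulation_config(n_cases = 2, n_controls_pool = 4,
                            probes_per_chromosome = c("1" = 10L),
                            chromosome_length_bp = c("1" = 10L), seed = 1)
  expect_equal(simulate_probe_map(cfg2)$position_bp, 1:10)
})

test_that("impossible simulator configs are rejected", {
  expect_error(simulation_config(probes_per_chromosome = c("1" = 20L),
                                 chromosome_length_bp = c("1" = 10L)),
               class = "cslvr_config_error")
  expect_error(simulation_config(noise_sd = 0), class = "cslvr_config_error")
  expect_error(planted_segment("1", 10, 5, "deletion", 0.1, 0.1),
               class = "cslvr_config_error")
  expect_error(planted_segment("1", 1, 5, "deletion", 1.2, 0.1),
               class = "cslvr_config_error")
})

test_that("pure-noise cohorts have calibrated per-probe mean and SD", {
  cfg <- simulation_config(n_cases = 1000, n_controls_pool = 1000,
                           probes_per_chromosome = c("1" = 20L),
                           chromosome_length_bp = c("1" = 1e6),
                           male_x_shift = 0, person_offset_sd = 0, seed = 9)
  pm <- simulate_probe_map(cfg)
  co <- simulate_cohort(cfg, pm)
  n <- nrow(co$l2r)
  se <- cfg$noise_sd / sqrt(n)
  expect_true(all(abs(colMeans(co$l2r)) < 4 * se))
  emp_sd <- apply(co$l2r, 2, sd)
  expect_true(all(abs(emp_sd - cfg$noise_sd) / cfg$noise_sd < 0.10))
})

test_that("planted duplication at carrier frequency 1 shifts in-segment means by log2(3/2)", {
  seg <- planted_segment("1", 1, 5e5, "duplication", 1, 1)
  cfg <- simulation_config(n_cases = 500, n_controls_pool = 500,
                           probes_per_chromosome = c("1" = 20L),
                           chromosome_length_bp = c("1" = 1e6),
                           cnv_segments = list(seg),
                           male_x_shift = 0, person_offset_sd = 0, seed = 11)
  pm <- simulate_probe_map(cfg)
  co <- simulate_cohort(cfg, pm)
  in_seg <- pm$position_bp <= 5e5
  stopifnot(sum(in_seg) > 0)
  seg_vals <- co$l2r[, in_seg, drop = FALSE]
  se <- cfg$noise_sd / sqrt(length(seg_vals))
  expect_lt(abs(mean(seg_vals) - log2(3 / 2)), 4 * se)
})

test_that("equal carrier frequencies plant no case-control difference", {
  seg <- planted_segment("1", 1, 5e5, "duplication", 0.2, 0.2)
  cfg <- simulation_config(n_cases = 1000, n_controls_pool = 1000,
                           probes_per_chromosome = c("1" = 20L),
                           chromosome_length_bp = c("1" = 1e6),
                           cnv_segments = list(seg),
                           male_x_shift = 0, person_offset_sd = 0, seed = 13)
  pm <- simulate_probe_map(cfg)
  co <- simulate_cohort(cfg, pm)
  in_seg <- which(pm$position_bp <= 5e5)
  cslv_mean <- rowMeans(co$l2r[, in_seg, drop = FALSE])
  case <- co$phenotypes$is_case
  # carrier mixture inflates the variance; bound the SE from the sample
  se <- sqrt(var(cslv_mean[case]) / sum(case) + var(cslv_mean[!case]) / sum(!case))
  expect_lt(abs(mean(cslv_mean[case]) - mean(cslv_mean[!case])), 4 * se)
})

test_that("male X probes are shifted by male_x_shift relative to females", {
  cfg <- simulation_config(n_cases = 500, n_controls_pool = 500,
                           probes_per_chromosome = c("22" = 5L, "X" = 20L),
                           chromosome_length_bp = c("22" = 1e6, "X" = 1e6),
                           person_offset_sd = 0, seed = 17)
  pm <- simulate_probe_map(cfg)
  co <- simulate_cohort(cfg, pm)
  x_cols <- pm$chromosome == "X"
  male <- co$phenotypes$sex == "male"
  diff_x <- mean(co$l2r[male, x_cols]) - mean(co$l2r[!male, x_cols])
  diff_auto <- mean(co$l2r[male, !x_cols]) - mean(co$l2r[!male, !x_cols])
  expect_lt(abs(diff_x - cfg$male_x_shift), 0.02)
  expect_lt(abs(diff_auto), 0.02)
})

test_that("written fixtures read back cleanly and are byte-deterministic", {
  cfg <- simulation_config(n_cases = 3, n_controls_pool = 7,
                           probes_per_chromosome = c("1" = 4L, "X" = 3L),
                           chromosome_length_bp = c("1" = 1e5, "X" = 1e5),
                           seed = 19)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths <- write_fixture(cfg, d1)
  write_fixture(cfg, d2)
  pm <- read_probe_map(paths$probe_map)
  expect_equal(nrow(pm), 7L)
  ph <- read_phenotypes(paths$phenotypes)
  expect_equal(nrow(ph), 10L)
  m1 <- read_l2r(file.path(d1, "chr1.l2r.txt"), pm, chromosome = "1")
  expect_equal(dim(m1), c(10L, 4L))
  expect_setequal(rownames(m1), ph$person_id)
  # determinism: identical bytes across directories
  for (f in c("probe_map.tsv", "chr1.l2r.txt", "chrX.l2r.txt", "phenotypes.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # micro fixture stays hand-checkable
  expect_lte(length(readLines(file.path(d1, "chr1.l2r.txt"))), 10L)
})
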