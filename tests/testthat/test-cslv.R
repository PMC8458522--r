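test_that("split schemes produce the canonical feature counts", {
  pm <- full_probe_map(10)
  expect_equal(nrow(make_split_scheme(pm, 1)), 23L)
  expect_equal(nrow(make_split_scheme(pm, 4)), 92L)
  expect_equal(nrow(make_split_scheme(pm, 8)), 184L)
  sch <- make_split_scheme(pm, 4)
  expect_equal(sch$feature_name[1:4], c("chr1_s1", "chr1_s2", "chr1_s3", "chr1_s4"))
  expect_equal(tail(sch$feature_name, 1), "chrX_s4")
})

test_that("remainder probes go to the earliest splits", {
  pm <- as_probe_map(tibble::tibble(
    probe_id = sprintf("p%02d", 1:10), chromosome = "1",
    position_bp = seq(10L, 100L, by = 10L)))
  sch <- make_split_scheme(pm, 4)
  expect_equal(sch$n_probes, c(3L, 3L, 2L, 2L))
  # partition covers every probe exactly once
  covered <- unlist(Map(seq, sch$probe_start, sch$probe_end))
  expect_equal(sort(covered), 1:10)
})

test_that("a chromosome with fewer probes than k is a named configuration error", {
  pm <- tiny_probe_map() # chromosome "2" has 2 probes
  err <- expect_error(make_split_scheme(pm, 3), class = "cslvr_config_error")
  expect_match(conditionMessage(err), "Chromosome 2")
})

test_that("CSLV equals the probe-level brute force on random instances", {
  pm <- as_probe_map(tibble::tibble(
    probe_id = sprintf("p%02d", 1:30), chromosome = "1",
    position_bp = seq(100L, by = 100L, length.out = 30L)))
  sch <- make_split_scheme(pm, 3)
  withr::with_seed(21, {
    for (i in 1:100) {
      vals <- matrix(rnorm(5 * 30), nrow = 5)
      if (i %% 2 == 0) vals[sample(length(vals), 8)] <- NA  # exercise masking
      m <- l2r_matrix(vals, sprintf("P%d", 1:5), pm)
      got <- as.matrix(compute_cslv(m, pm, sch)[, -1])
      expect_equal(unname(got), brute_force_cslv(m, sch))
    }
  })
})

test_that("constant matrices give constant features and zeros give zeros", {
  pm <- full_probe_map(4)
  sch <- make_split_scheme(pm, 2)
  zero <- l2r_matrix(matrix(0, 3, nrow(pm)), c("A", "B", "C"), pm)
  expect_true(all(as.matrix(compute_cslv(zero, pm, sch)[, -1]) == 0))
  const <- l2r_matrix(matrix(0.25, 3, nrow(pm)), c("A", "B", "C"), pm)
  expect_true(all(as.matrix(compute_cslv(const, pm, sch)[, -1]) == 0.25))
})

test_that("probe-count-weighted split means refine to the whole-chromosome mean", {
  pm <- as_probe_map(tibble::tibble(
    probe_id = sprintf("p%02d", 1:10), chromosome = "1",
    position_bp = seq(10L, 100L, by = 10L)))
  withr::with_seed(23, {
    m <- l2r_matrix(matrix(rnorm(4 * 10), nrow = 4), sprintf("P%d", 1:4), pm)
  })
  c1 <- compute_cslv(m, pm, make_split_scheme(pm, 1))
  sch4 <- make_split_scheme(pm, 4)
  c4 <- as.matrix(compute_cslv(m, pm, sch4)[, -1])
  weighted <- c4 %*% sch4$n_probes / sum(sch4$n_probes)
  expect_equal(as.numeric(weighted), c1$chr1_s1)
})

test_that("a split that is entirely missing for a person is flagged NA", {
  pm <- as_probe_map(tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"), chromosome = "1",
    position_bp = c(10L, 20L, 30L, 40L)))
  vals <- matrix(1, 2, 4)
  vals[1, 1:2] <- NA
  m <- l2r_matrix(vals, c("A", "B"), pm)
  cs <- compute_cslv(m, pm, make_split_scheme(pm, 2))
  expect_true(is.na(cs$chr1_s1[1]))
  expect_equal(cs$chr1_s1[2], 1)
})

test_that("split coordinates are the min/max probe positions of each range", {
  pm <- tiny_probe_map()
  sch <- make_split_scheme(pm, 2)
  coords <- split_coordinates(sch, pm)
  # independent brute force over the probe ranges
  for (i in seq_len(nrow(sch))) {
    pos <- pm$position_bp[seq(sch$probe_start[i], sch$probe_end[i])]
    expect_equal(coords$start_bp[i], min(pos))
    expect_equal(coords$end_bp[i], max(pos))
  }
  # single-probe split collapses to one coordinate
  one <- coords[coords$feature_name == "chr2_s2", ]
  expect_equal(one$start_bp, one$end_bp)
  # rendered labels use the chrX:start–end report style
  expect_match(coords$label[coords$chromosome == "X"][1], "^chrX:[0-9]+–[0-9]+$")
})

test_that("split boundaries depend only on the probe map, never on l2r values", {
  pm <- full_probe_map(8)
  s1 <- make_split_scheme(pm, 4)
  s2 <- make_split_scheme(pm, 4)
  expect_identical(s1, s2)
})

test_that("equal-base-pair mode slices the spanned interval, not the probe counts", {
  pm <- as_probe_map(tibble::tibble(
    probe_id = sprintf("p%02d", 1:8), chromosome = "1",
    position_bp = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 100L)))
  sch <- make_split_scheme(pm, 2, mode = "bp")
  # bp midpoint ~50: seven probes land left, one right
  expect_equal(sch$n_probes, c(7L, 1L))
  expect_error(make_split_scheme(pm, 4, mode = "bp"), class = "cslvr_config_error")
})
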