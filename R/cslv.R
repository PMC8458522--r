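#' Build a k-split scheme over a probe map
#'
#' Splits each chromosome's probes into `k` nominally equal contiguous
#' blocks. "Nominally equal" means equal probe counts: block sizes differ by
#' at most one and, when the count is not divisible by `k`, the earlier
#' blocks take the extra probe. An equal-base-pair mode is available for
#' comparison; it slices the chromosome's spanned interval into `k` equal bp
#' windows and assigns probes by position (windows may then hold unequal
#' probe counts, but never zero under the probe-count precondition failing
#' -- empty windows raise an error).
#'
#' Feature names are `chr{c}_s{j}` in canonical chromosome order, so a
#' 23-chromosome map yields 23 features at k = 1, 92 at k = 4 and 184 at
#' k = 8.
#'
#' @param probe_map Canonical probe map.
#' @param k Splits per chromosome (>= 1); every chromosome must have at
#'   least `k` probes.
#' @param mode "probes" (default) or "bp".
#' @return A `cslv_split_scheme` tibble with one row per feature:
#'   `feature_name`, `chromosome`, `split`, `probe_start`, `probe_end`
#'   (1-based positions in the global probe order), `n_probes`.
#' @export
make_split_scheme <- function(probe_map, k, mode = c("probes", "bp")) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 1) abort("k must be >= 1", class = "cslvr_config_error")
  chroms <- intersect(cslv_chromosomes(), unique(probe_map$chromosome))
  rows <- purrr::map(chroms, function(chrom) {
    idx <- which(probe_map$chromosome == chrom)
    n <- length(idx)
    if (n < k) {
      abort(sprintf("Chromosome %s has %d probes, fewer than k = %d", chrom, n, k),
            class = "cslvr_config_error")
    }
    if (mode == "probes") {
      sizes <- block_sizes(n, k)
      ends <- cumsum(sizes)
      starts <- ends - sizes + 1L
    } else {
      pos <- probe_map$position_bp[idx]
      breaks <- seq(min(pos), max(pos), length.out = k + 1)
      bin <- pmin(findInterval(pos, breaks, rightmost.closed = TRUE), k)
      cnt <- tabulate(bin, nbins = k)
      if (any(cnt == 0)) {
        abort(sprintf("Chromosome %s: equal-bp split %d holds no probes",
                      chrom, which(cnt == 0)[1]), class = "cslvr_config_error")
      }
      ends <- cumsum(cnt)
      starts <- ends - cnt + 1L
      sizes <- cnt
    }
    tibble(feature_name = sprintf("chr%s_s%d", chrom, seq_len(k)),
           chromosome = chrom, split = seq_len(k),
           probe_start = idx[starts], probe_end = idx[ends],
           n_probes = as.integer(sizes))
  })
  out <- bind_rows(rows)
  attr(out, "k") <- k
  attr(out, "mode") <- mode
  class(out) <- c("cslv_split_scheme", class(out))
  out
}

#' Compute the CSLV feature table
#'
#' For every person and every split, takes the arithmetic mean of the
#' person's non-missing l2r values over the split's probe range (masked
#' mean: the divisor is the count of observed probes). A cell whose split
#' holds only missing values for that person is `NA`. Split boundaries are a
#' pure function of the probe map and `k`; the l2r values never influence
#' them.
#'
#' @param l2r Persons x probes matrix consistent with `probe_map`.
#' @param probe_map Canonical probe map.
#' @param scheme Split scheme from [make_split_scheme()].
#' @return Tibble: `person_id` column, then one numeric column per feature
#'   in scheme order. Units: mean log2 copy ratio.
#' @export
compute_cslv <- function(l2r, probe_map, scheme) {
  if (ncol(l2r) != nrow(probe_map)) {
    abort("l2r matrix and probe map have inconsistent probe counts",
          class = "cslvr_format_error")
  }
  feats <- matrix(NA_real_, nrow = nrow(l2r), ncol = nrow(scheme),
                  dimnames = list(rownames(l2r), scheme$feature_name))
  for (i in seq_len(nrow(scheme))) {
    block <- l2r[, seq(scheme$probe_start[i], scheme$probe_end[i]), drop = FALSE]
    m <- rowMeans(block, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    feats[, i] <- m
  }
  out <- as_tibble(feats)
  out <- tibble(person_id = rownames(l2r)) |> dplyr::bind_cols(out)
  out
}

#' Map splits back to genomic coordinates
#'
#' Each split's interval is the position of its first probe through the
#' position of its last probe, 1-based inclusive. The `label` column renders
#' the interval in the report style `chr{c}:{start}–{end}`.
#'
#' @param scheme Split scheme.
#' @param probe_map The probe map the scheme was built on.
#' @return Tibble: `feature_name`, `chromosome`, `start_bp`, `end_bp`,
#'   `label`.
#' @export
split_coordinates <- function(scheme, probe_map) {
  tibble(
    feature_name = scheme$feature_name,
    chromosome = scheme$chromosome,
    start_bp = probe_map$position_bp[scheme$probe_start],
    end_bp = probe_map$position_bp[scheme$probe_end]
  ) |>
    mutate(label = sprintf("chr%s:%d–%d", .data$chromosome,
                           .data$start_bp, .data$end_bp))
}

#' Write a CSLV table as TSV
#'
#' First column `person_id`, then one column per feature.
#'
#' @param cslv CSLV tibble from [compute_cslv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cslv <- function(cslv, path) {
  readr::write_tsv(cslv, path, progress = FALSE)
  invisible(path)
}
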