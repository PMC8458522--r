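#' Read a probe map
#'
#' Reads a tab-separated probe map with columns `probe_id`, `chromosome`,
#' `position_bp` and returns it in canonical order: chromosomes 1..22 then X,
#' positions ascending within a chromosome. A 0-based `index` column records
#' each probe's rank in that global order; all split construction and
#' coordinate reporting is defined against it.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `probe_id`, `chromosome`, `position_bp`,
#'   `index`, sorted canonically.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\tchromosome\tposition_bp",
#'              "p2\t1\t200", "p1\t1\t100"), tf)
#' read_probe_map(tf)
read_probe_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chromosome = readr::col_character(),
    position_bp = readr::col_double()
  ), progress = FALSE)
  required <- c("probe_id", "chromosome", "position_bp")
  if (!all(required %in% names(raw))) {
    abort(sprintf("Probe map must have columns %s", paste(required, collapse = ", ")),
          class = "cslvr_format_error")
  }
  as_probe_map(raw[required])
}

#' Coerce a data frame to a canonical probe map
#'
#' Validates probe-map invariants (unique IDs, known chromosome labels,
#' positive strictly-increasing positions within chromosome) and sorts into
#' canonical order, assigning 0-based indices after the sort.
#'
#' @param x Data frame with `probe_id`, `chromosome`, `position_bp`.
#' @return Probe-map tibble with an `index` column.
#' @export
as_probe_map <- function(x) {
  x <- as_tibble(x)
  if (anyDuplicated(x$probe_id)) {
    abort("Duplicate probe_id values in probe map", class = "cslvr_format_error")
  }
  check_chromosomes(x$chromosome)
  if (any(x$position_bp <= 0) || any(x$position_bp != floor(x$position_bp))) {
    abort("position_bp must be positive integers", class = "cslvr_format_error")
  }
  x <- x |>
    mutate(chromosome = as.character(.data$chromosome),
           position_bp = as.integer(.data$position_bp)) |>
    arrange(match(.data$chromosome, cslv_chromosomes()), .data$position_bp)
  dup_pos <- x |>
    group_by(.data$chromosome) |>
    summarise(dup = anyDuplicated(.data$position_bp) > 0, .groups = "drop")
  if (any(dup_pos$dup)) {
    abort("position_bp must be strictly increasing within a chromosome",
          class = "cslvr_format_error")
  }
  x$index <- seq_len(nrow(x)) - 1L
  x
}

#' Construct an l2r matrix
#'
#' An l2r matrix holds per-person, per-probe log2 intensity ratios relative
#' to the nominal two-copy state (0 = diploid). It is stored persons x
#' probes with person IDs as row names and probe IDs as column names; `NA`
#' marks a missing measurement and is never imputed at the I/O layer.
#'
#' @param values Numeric matrix, persons x probes.
#' @param person_ids Character vector, one per row.
#' @param probe_map Probe map whose probes label the columns.
#' @return The validated matrix with dimnames set.
#' @export
l2r_matrix <- function(values, person_ids, probe_map) {
  values <- as.matrix(values)
  if (length(person_ids) != nrow(values)) {
    abort("person_ids length must equal the number of rows", class = "cslvr_format_error")
  }
  if (anyDuplicated(person_ids)) {
    abort("person_ids must be unique", class = "cslvr_format_error")
  }
  if (ncol(values) != nrow(probe_map)) {
    abort(sprintf("Matrix has %d columns but probe map has %d probes",
                  ncol(values), nrow(probe_map)), class = "cslvr_format_error")
  }
  dimnames(values) <- list(as.character(person_ids), probe_map$probe_id)
  values
}

l2r_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".persons.txt")
}

#' Read an l2r matrix
#'
#' Reads a whitespace-delimited l2r file in the array-release dialect: one
#' row per probe (in probe-map order for the declared chromosome, or the
#' whole genome), one column per person, no header, token `NA` for missing.
#' Person IDs come from `person_ids` or, when omitted, from the sidecar file
#' `<stem>.persons.txt` next to `path` (one ID per line). The matrix is
#' returned transposed to persons x probes.
#'
#' @param path l2r file path.
#' @param probe_map Probe map (full, or the rows will be subset by
#'   `chromosome`).
#' @param person_ids Optional character vector of column identities.
#' @param chromosome Optional single chromosome label when `path` holds one
#'   chromosome's probes only.
#' @return Persons x probes numeric matrix (see [l2r_matrix()]).
#' @export
read_l2r <- function(path, probe_map, person_ids = NULL, chromosome = NULL) {
  if (!is.null(chromosome)) {
    check_chromosomes(chromosome)
    probe_map <- probe_map[probe_map$chromosome == chromosome, , drop = FALSE]
  }
  if (is.null(person_ids)) {
    sidecar <- l2r_sidecar_path(path)
    if (!file.exists(sidecar)) {
      abort(sprintf("No person_ids given and sidecar %s not found", sidecar),
            class = "cslvr_format_error")
    }
    person_ids <- readLines(sidecar)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != nrow(probe_map)) {
    abort(sprintf("l2r file has %d probe rows but probe map declares %d",
                  length(lines), nrow(probe_map)), class = "cslvr_format_error")
  }
  tokens <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(tokens)
  if (length(unique(widths)) > 1) {
    abort("Ragged l2r file: rows have differing column counts",
          class = "cslvr_format_error")
  }
  if (widths[1] != length(person_ids)) {
    abort(sprintf("l2r file has %d person columns but %d person IDs given",
                  widths[1], length(person_ids)), class = "cslvr_format_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(tokens)))
  probes_x_persons <- matrix(vals, nrow = nrow(probe_map), byrow = TRUE)
  l2r_matrix(t(probes_x_persons), person_ids, probe_map)
}

#' Write an l2r matrix
#'
#' Emits the dialect [read_l2r()] accepts: probes as rows in probe-map
#' order, persons as columns, values formatted to 6 significant digits so
#' read-write round trips are stable, `NA` for missing. Person IDs go to the
#' sidecar `<stem>.persons.txt`.
#'
#' @param values Persons x probes matrix consistent with `probe_map`.
#' @param probe_map Probe map labelling the columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_l2r <- function(values, probe_map, path) {
  if (ncol(values) != nrow(probe_map)) {
    abort("Matrix columns do not match probe map", class = "cslvr_format_error")
  }
  probes_x_persons <- t(values)
  fmt <- matrix(sprintf("%.6g", probes_x_persons), nrow = nrow(probes_x_persons))
  fmt[is.na(probes_x_persons)] <- "NA"
  writeLines(apply(fmt, 1L, paste, collapse = " "), path)
  writeLines(rownames(values), l2r_sidecar_path(path))
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with header `person_id  age_years  sex  is_case`; `sex` is "female"
#' or "male", `is_case` a logical (TRUE/FALSE). Every person appearing in an
#' l2r matrix must be present here before cohort construction.
#'
#' @param path TSV path.
#' @return Tibble with typed columns.
#' @export
read_phenotypes <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    age_years = readr::col_integer(),
    sex = readr::col_character(),
    is_case = readr::col_logical()
  ), progress = FALSE)
  validate_phenotypes(x)
}

validate_phenotypes <- function(x) {
  x <- as_tibble(x)
  required <- c("person_id", "age_years", "sex", "is_case")
  if (!all(required %in% names(x))) {
    abort(sprintf("Phenotype table must have columns %s",
                  paste(required, collapse = ", ")), class = "cslvr_format_error")
  }
  if (anyDuplicated(x$person_id)) {
    abort("Duplicate person_id in phenotype table", class = "cslvr_format_error")
  }
  bad_sex <- setdiff(unique(x$sex), c("female", "male"))
  if (length(bad_sex) > 0) {
    abort(sprintf("sex must be female/male, found: %s", paste(bad_sex, collapse = ", ")),
          class = "cslvr_format_error")
  }
  x[required]
}

#' Write a phenotype table
#'
#' @param phenotypes Tibble as returned by [read_phenotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(validate_phenotypes(phenotypes), path, progress = FALSE)
  invisible(path)
}

#' Export genomic intervals as BED
#'
#' Converts 1-based inclusive internal coordinates to BED's 0-based
#' half-open convention (start - 1, end) and prefixes chromosome labels with
#' "chr".
#'
#' @param regions Tibble with `chromosome`, `start_bp`, `end_bp` and
#'   optionally a `name` (or `feature_name`) column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name
        else if ("feature_name" %in% names(regions)) regions$feature_name
        else rep(".", nrow(regions))
  bed <- tibble(
    chrom = paste0("chr", regions$chromosome),
    start = as.integer(regions$start_bp) - 1L,
    end = as.integer(regions$end_bp),
    name = nm
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
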