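#' Call tables, coverage tracks and run configuration
#'
#' Readers and writers for the tabular interchange formats used throughout
#' the audit: insertion call tables (TSV, one row per call in one sample),
#' sample tables, bedGraph coverage tracks and BED locus exports. All genomic
#' coordinates are 0-based half-open (BED/bedGraph convention) in files and
#' in memory; human-readable reports render 1-based.
#'
#' A call row exists only if the insertion was detected with at least one
#' read in that sample: allelic dropout is represented by absence of a row,
#' never by a zero count.
#'
#' @name data-model-io
NULL

# mandatory call-table columns, exact names
.call_columns <- c("sample_id", "individual_id", "material", "cell_type",
                   "contig", "start", "end", "read_count", "junctions",
                   "prior_study", "prior_rcseq_only", "candidate_class",
                   "score")

validate_calls <- function(calls) {
  .assert(is.data.frame(calls), "calls must be a data frame")
  missing <- setdiff(.call_columns, names(calls))
  .assert(length(missing) == 0,
          "call table is missing mandatory column(s): %s",
          paste(missing, collapse = ", "))
  calls <- as_tibble(calls)
  # canonical column types, so in-memory and re-parsed tables compare equal
  for (col in c("start", "end", "read_count", "score")) {
    calls[[col]] <- as.double(calls[[col]])
  }
  bad_rc <- which(!is.finite(calls$read_count) | calls$read_count < 1)
  .assert(length(bad_rc) == 0,
          "read_count < 1 (or missing) at row(s): %s",
          paste(head(bad_rc, 5), collapse = ", "))
  bad_iv <- which(!(calls$start < calls$end))
  .assert(length(bad_iv) == 0,
          "start must be < end (0-based half-open) at row(s): %s",
          paste(head(bad_iv, 5), collapse = ", "))
  .assert(all(calls$material %in% .materials), "unknown material value")
  .assert(all(calls$cell_type %in% .cell_types), "unknown cell_type value")
  .assert(all(calls$junctions %in% .junctions), "unknown junctions value")
  .assert(all(calls$candidate_class %in% .candidate_classes),
          "unknown candidate_class value")
  calls
}

#' Read an insertion call table
#'
#' Parses a TSV of per-sample insertion calls into a validated calls tibble
#' plus a deduplicated sample table. Every input row becomes exactly one
#' call record; rows are never silently dropped (validation failures raise
#' errors naming the offending column or row). Columns beyond the documented
#' schema are preserved untouched as opaque annotations.
#'
#' @param path path to a TSV with the mandatory columns `sample_id`,
#'   `individual_id`, `material`, `cell_type`, `contig`, `start`, `end`,
#'   `read_count`, `junctions`, `prior_study`, `prior_rcseq_only`,
#'   `candidate_class`, `score`.
#' @return a list with `calls` (one row per call) and `samples` (one row per
#'   sample; `total_reads` is `NA` unless a sample table is read separately).
#' @seealso [write_call_table()], [read_sample_table()]
#' @export
read_call_table <- function(path) {
  calls <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  calls <- validate_calls(calls)
  samples <- calls |>
    distinct(.data$sample_id, .data$individual_id, .data$material,
             .data$cell_type) |>
    mutate(total_reads = NA_real_) |>
    arrange(.data$sample_id)
  .assert(!anyDuplicated(samples$sample_id),
          "sample_id maps to conflicting sample metadata")
  list(calls = calls, samples = samples)
}

#' Write an insertion call table
#' @param calls validated calls tibble (see [read_call_table()] for schema).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  calls <- validate_calls(calls)
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample table
#'
#' Sample tables carry per-sample metadata including `total_reads` (uniquely
#' mapped reads), which the call table itself does not.
#'
#' @param samples tibble with columns `sample_id`, `individual_id`,
#'   `material`, `cell_type`, `total_reads`.
#' @param path TSV path.
#' @return the sample tibble (read) or `path` invisibly (write).
#' @export
read_sample_table <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "individual_id", "material", "cell_type",
            "total_reads")
  missing <- setdiff(need, names(s))
  .assert(length(missing) == 0, "sample table missing column(s): %s",
          paste(missing, collapse = ", "))
  .assert(!anyDuplicated(s$sample_id), "duplicate sample_id")
  .assert(all(is.na(s$total_reads) | s$total_reads >= 0),
          "total_reads must be >= 0")
  .assert(all(s$cell_type[s$material == "bulk"] == "other"),
          "bulk samples must have cell_type 'other'")
  as_tibble(s)
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

# ---- coverage tracks ---------------------------------------------------

#' Construct a coverage track
#'
#' A coverage track is a tibble of non-overlapping, sorted genomic bins with
#' a non-negative `depth` (read count or mean depth per bin).
#'
#' @param bins data frame with columns `contig`, `start`, `end`, `depth`.
#' @param bin_scheme `"fixed_width"` or `"equal_read"`.
#' @param provenance free-text description of where the track came from.
#' @return a `coverage_track` tibble with attributes `bin_scheme` and
#'   `provenance`.
#' @export
coverage_track <- function(bins, bin_scheme = "fixed_width",
                           provenance = "unknown") {
  .assert(all(c("contig", "start", "end", "depth") %in% names(bins)),
          "coverage bins need columns contig, start, end, depth")
  bins <- as_tibble(bins)[, c("contig", "start", "end", "depth")]
  .assert(all(bins$depth >= 0), "negative depth in coverage track")
  .assert(all(bins$start < bins$end), "empty or inverted bin")
  bins <- bins |> arrange(.data$contig, .data$start)
  by_ct <- split(bins, bins$contig)
  for (ct in by_ct) {
    if (nrow(ct) > 1) {
      .assert(all(ct$start[-1] >= ct$end[-nrow(ct)]),
              "overlapping bins on contig %s", ct$contig[[1]])
    }
  }
  .assert(bin_scheme %in% c("fixed_width", "equal_read"),
          "unknown bin_scheme")
  structure(bins, bin_scheme = bin_scheme, provenance = provenance,
            class = c("coverage_track", class(bins)))
}

#' Read a bedGraph coverage track
#'
#' @param path 4-column bedGraph (contig, start, end, depth), no header.
#'   An empty file yields an empty track.
#' @inheritParams coverage_track
#' @return a `coverage_track` tibble.
#' @export
read_coverage_track <- function(path, bin_scheme = "fixed_width",
                                provenance = path) {
  cols <- readr::cols(contig = readr::col_character(),
                      start = readr::col_double(),
                      end = readr::col_double(),
                      depth = readr::col_double())
  bins <- readr::read_tsv(path, col_names = c("contig", "start", "end",
                                              "depth"),
                          col_types = cols, progress = FALSE)
  coverage_track(bins, bin_scheme = bin_scheme, provenance = provenance)
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_track <- function(track, path) {
  readr::write_tsv(as_tibble(track)[, c("contig", "start", "end", "depth")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Export loci as 6-column BED
#'
#' @param loci tibble with `contig`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  .assert(all(c("contig", "start", "end") %in% names(loci)),
          "loci need contig, start, end")
  bed <- tibble(
    contig = loci$contig, start = loci$start, end = loci$end,
    name = if ("name" %in% names(loci)) loci$name else ".",
    score = if ("score" %in% names(loci)) loci$score else 0,
    strand = if ("strand" %in% names(loci)) loci$strand else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- run configuration -------------------------------------------------

#' Default run configuration
#'
#' Central defaults for thresholds, bin sizes and seeds used by the analysis
#' drivers. A YAML file read with [read_run_config()] overrides any subset of
#' these; function arguments override both.
#'
#' @return a nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    thresholds = list(
      min_bulk_reads = 40L,      # bulk evidence floor for RC-seq gold sets
      max_min_reads = 6L,        # threshold table scan range
      knee_ratio = 0.5,          # pp fp reduction per pp sensitivity loss
      tsd_max_bp = 50L           # TSD flag limit for chimera rules
    ),
    coverage = list(
      bin_bp = 500000L,          # low-resolution QC bin size
      psd_segment_bins = 2^14L,  # Welch segment length
      pseudocount = 1            # read-equivalents added before log2
    )
  )
}

#' Read a run configuration file
#'
#' @param path YAML file with any subset of the keys of
#'   [default_run_config()]; missing keys fall back to the defaults.
#' @return a nested named list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_cfg(base[[k]], over[[k]])
      } else {
        over[[k]]
      }
    }
    base
  }
  merge_cfg(default_run_config(), user)
}
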