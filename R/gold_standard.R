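#' Gold-standard germline KNR insertion sets
#'
#' Per-individual sets of trusted germline known non-reference (KNR) L1
#' insertions, selected under method-specific rules. A gold-standard set is
#' the reference against which per-cell detection sensitivity is measured,
#' so the rules demand strong bulk evidence and corroboration by prior,
#' independent L1 profiling studies.
#'
#' All printed inequalities are inclusive (>=, <=) exactly as stated.
#' Every selector returns a `gold_standard_set`: a list with `method`,
#' `loci` (the selected loci per individual) and `selection_log` (one row
#' per considered locus with each criterion's pass/fail and the final
#' decision — every excluded locus has at least one named failed criterion).
#'
#' @name gold-standard
NULL

new_gold_standard_set <- function(method, loci, selection_log) {
  structure(list(method = method, loci = as_tibble(loci),
                 selection_log = as_tibble(selection_log)),
            class = "gold_standard_set")
}

#' @export
print.gold_standard_set <- function(x, ...) {
  cat(sprintf("<gold_standard_set method=%s: %d loci in %d individual(s)>\n",
              x$method, nrow(x$loci),
              dplyr::n_distinct(x$loci$individual_id)))
  invisible(x)
}

# bulk sample ids per individual, from an explicit sample table when given
.bulk_samples_by_individual <- function(bulk_calls, samples = NULL) {
  if (!is.null(samples)) {
    s <- samples[samples$material == "bulk", c("individual_id", "sample_id")]
  } else {
    s <- unique(bulk_calls[, c("individual_id", "sample_id")])
  }
  split(s$sample_id, s$individual_id)
}

#' Select the capture-based (RC-seq) gold-standard KNR set
#'
#' A locus enters the gold set of its individual iff it was detected with at
#' least `min_bulk_reads` reads in BOTH bulk samples of that individual AND
#' it was identified in a prior independent (non capture-based) L1 profiling
#' study. Loci known only from prior capture-based studies are excluded
#' unless `include_prior_rcseq_only = TRUE`, keeping the gold standard
#' independent of the method under audit.
#'
#' @param bulk_calls call tibble restricted to bulk material (schema of
#'   [read_call_table()]).
#' @param min_bulk_reads inclusive bulk read-count floor (default 40).
#' @param include_prior_rcseq_only also admit loci known only from prior
#'   capture-based studies.
#' @param samples optional sample table, used to count each individual's
#'   bulk samples even when a bulk produced no calls.
#' @return a `gold_standard_set`.
#' @export
select_rcseq_gold <- function(bulk_calls, min_bulk_reads = 40,
                              include_prior_rcseq_only = FALSE,
                              samples = NULL) {
  .assert(all(bulk_calls$material == "bulk"),
          "bulk_calls must contain only bulk samples")
  bulks <- .bulk_samples_by_individual(bulk_calls, samples)
  n_bulks <- vapply(bulks, length, integer(1))
  bad <- names(n_bulks)[n_bulks != 2]
  .assert(length(bad) == 0,
          "individual(s) without exactly two bulk samples: %s",
          paste(bad, collapse = ", "))

  log <- bulk_calls |>
    mutate(locus = .locus_key(.data$contig, .data$start, .data$end)) |>
    group_by(.data$individual_id, .data$locus, .data$contig, .data$start,
             .data$end) |>
    summarise(
      n_bulks_min_reads = sum(.data$read_count >= min_bulk_reads),
      prior_study = any(.data$prior_study),
      prior_rcseq_only = any(.data$prior_rcseq_only),
      .groups = "drop"
    ) |>
    mutate(
      pass_both_bulks = .data$n_bulks_min_reads == 2,
      pass_prior = .data$prior_study |
        (include_prior_rcseq_only & .data$prior_rcseq_only),
      included = .data$pass_both_bulks & .data$pass_prior,
      failed_criteria = paste0(
        ifelse(.data$pass_both_bulks, "",
               sprintf("min_%d_reads_in_both_bulks;", min_bulk_reads)),
        ifelse(.data$pass_prior, "", "prior_independent_study")
      )
    )
  new_gold_standard_set(
    "rcseq",
    log |> dplyr::filter(.data$included) |>
      select("individual_id", "contig", "start", "end"),
    log
  )
}

#' Select the whole-genome-sequencing gold-standard KNR set
#'
#' An insertion enters the gold set iff, in BOTH bulk samples of the
#' individual, all of: (a) >= 2 read-anchored mate (RAM) reads on each side
#' of the breakpoint; (b) >= 4 clipped reads supporting the call; (c) an
#' estimated target-site duplication or deletion <= 50 bp without a poly-A
#' tail, or <= 250 bp when a poly-A tail was detected; (d) at least half of
#' the clipped reads aligned within +/- 2 bp of the breakpoint; and (e) the
#' insertion was detected in prior independent L1 profiling studies.
#'
#' @param bulk_evidence tibble with one row per (individual, locus, bulk
#'   sample) and columns `individual_id`, `sample_id`, `contig`, `start`,
#'   `end`, `ram_reads_left`, `ram_reads_right`, `clipped_reads`,
#'   `clipped_reads_at_breakpoint`, `tsd_or_deletion_bp`, `polyA_detected`,
#'   `prior_study`.
#' @return a `gold_standard_set`.
#' @export
select_wgs_gold <- function(bulk_evidence) {
  need <- c("individual_id", "sample_id", "contig", "start", "end",
            "ram_reads_left", "ram_reads_right", "clipped_reads",
            "clipped_reads_at_breakpoint", "tsd_or_deletion_bp",
            "polyA_detected", "prior_study")
  missing <- setdiff(need, names(bulk_evidence))
  .assert(length(missing) == 0, "evidence table missing column(s): %s",
          paste(missing, collapse = ", "))
  ev <- as_tibble(bulk_evidence)
  .assert(all(complete.cases(ev[, need])),
          "evidence fields contain missing values")
  .assert(all(ev$ram_reads_left >= 0 & ev$ram_reads_right >= 0 &
                ev$clipped_reads >= 0 &
                ev$clipped_reads_at_breakpoint >= 0),
          "evidence read counts must be >= 0")

  per_bulk <- ev |>
    mutate(
      pass_ram = .data$ram_reads_left >= 2 & .data$ram_reads_right >= 2,
      pass_clipped = .data$clipped_reads >= 4,
      pass_tsd = .data$tsd_or_deletion_bp <=
        ifelse(.data$polyA_detected, 250, 50),
      pass_breakpoint = 2 * .data$clipped_reads_at_breakpoint >=
        .data$clipped_reads,
      pass_prior = .data$prior_study
    )
  log <- per_bulk |>
    mutate(locus = .locus_key(.data$contig, .data$start, .data$end)) |>
    group_by(.data$individual_id, .data$locus, .data$contig, .data$start,
             .data$end) |>
    summarise(
      n_bulks = dplyr::n(),
      pass_ram = all(.data$pass_ram),
      pass_clipped = all(.data$pass_clipped),
      pass_tsd = all(.data$pass_tsd),
      pass_breakpoint = all(.data$pass_breakpoint),
      pass_prior = all(.data$pass_prior),
      .groups = "drop"
    ) |>
    mutate(
      pass_in_both_bulks = .data$n_bulks == 2,
      included = .data$pass_in_both_bulks & .data$pass_ram &
        .data$pass_clipped & .data$pass_tsd & .data$pass_breakpoint &
        .data$pass_prior,
      failed_criteria = paste0(
        ifelse(.data$pass_in_both_bulks, "", "evidence_in_both_bulks;"),
        ifelse(.data$pass_ram, "", "ram_reads;"),
        ifelse(.data$pass_clipped, "", "clipped_reads;"),
        ifelse(.data$pass_tsd, "", "tsd_size;"),
        ifelse(.data$pass_breakpoint, "", "clipped_at_breakpoint;"),
        ifelse(.data$pass_prior, "", "prior_independent_study")
      )
    )
  new_gold_standard_set(
    "wgs",
    log |> dplyr::filter(.data$included) |>
      select("individual_id", "contig", "start", "end"),
    log
  )
}

#' Select the PCR-based (L1-IP) gold-standard KNR set
#'
#' An insertion enters the gold set iff it was detected with a confidence
#' score >= 0.5 in at least half of the individual's bulk samples (ceiling
#' for odd bulk counts) AND it was identified in prior independent L1
#' profiling studies.
#'
#' @param bulk_calls call tibble restricted to bulk material, with `score`
#'   populated.
#' @param samples optional sample table (counts bulks with no call rows).
#' @param min_score inclusive score floor (default 0.5).
#' @return a `gold_standard_set`.
#' @export
select_l1ip_gold <- function(bulk_calls, samples = NULL, min_score = 0.5) {
  .assert(all(bulk_calls$material == "bulk"),
          "bulk_calls must contain only bulk samples")
  bulks <- .bulk_samples_by_individual(bulk_calls, samples)
  n_bulks <- vapply(bulks, length, integer(1))
  .assert(all(n_bulks >= 1), "individual with no bulk samples")
  nb <- tibble(individual_id = names(n_bulks), n_bulks = as.integer(n_bulks))

  log <- bulk_calls |>
    mutate(locus = .locus_key(.data$contig, .data$start, .data$end)) |>
    group_by(.data$individual_id, .data$locus, .data$contig, .data$start,
             .data$end) |>
    summarise(
      n_pass_score = sum(!is.na(.data$score) & .data$score >= min_score),
      prior_study = any(.data$prior_study),
      .groups = "drop"
    ) |>
    dplyr::left_join(nb, by = "individual_id") |>
    mutate(
      pass_half_bulks = .data$n_pass_score >= ceiling(.data$n_bulks / 2),
      pass_prior = .data$prior_study,
      included = .data$pass_half_bulks & .data$pass_prior,
      failed_criteria = paste0(
        ifelse(.data$pass_half_bulks, "", "score_in_half_of_bulks;"),
        ifelse(.data$pass_prior, "", "prior_independent_study")
      )
    )
  new_gold_standard_set(
    "l1ip",
    log |> dplyr::filter(.data$included) |>
      select("individual_id", "contig", "start", "end"),
    log
  )
}
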