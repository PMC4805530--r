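#' Chimera rule engine
#'
#' Classifies annotated candidate insertion contigs as amplification/library
#' chimera artifacts versus plausible true L1 insertions, encoding as
#' explicit rules the sequence-level criteria that distinguish molecules a
#' retrotransposition event could not have produced.
#'
#' Definite rules (any one fired => verdict `chimera`):
#' * `R1` — the junction traces to a retrotransposition-incompetent source
#'   subfamily (e.g. an older primate-specific L1PA element);
#' * `R2` — a 3' junction with no poly-A tail (L1 integration proceeds
#'   through a poly-adenylated intermediate);
#' * `R3` — the 5' and 3' junctions trace to two distinct source elements
#'   (two independent chimeras misread as the two ends of one insertion).
#'
#' Soft outcomes:
#' * `R4` — a junction arising from inside an L1 body or within a poly-A
#'   tract cannot be distinguished from a true insertion breakpoint by
#'   sequence analysis alone => `indeterminate`, never `chimera`;
#' * flag `F1` — an implied target-site duplication larger than `tsd_max`
#'   (default 50 bp) is recorded as a reason but a flag alone never
#'   produces a `chimera` verdict; it blocks the
#'   `consistent_with_true_insertion` verdict.
#'
#' `consistent_with_true_insertion` requires all hallmarks: poly-A tail
#' present, TSD <= `tsd_max`, an annotated active source subfamily, a single
#' source element, and no soft reasons.
#'
#' @name chimera-rules
NULL

#' Classify annotated candidate contigs
#'
#' @param contigs tibble of per-contig annotations as produced by
#'   [simulate_candidate_contigs()] (columns `contig_id`, `junction_side`,
#'   `polyA_length`, `tsd_bp`, `source_subfamily`, `source_active`,
#'   `source_5p_id`, `source_3p_id`, `junction_in_l1_body`,
#'   `junction_in_polyA_tract`; `source_active` may be `NA` when the
#'   subfamily annotation is missing).
#' @param tsd_max largest TSD considered compatible with a true insertion
#'   (bp; default 50).
#' @return tibble of verdicts: `contig_id`, `verdict` (`chimera` /
#'   `indeterminate` / `consistent_with_true_insertion`), `reasons`
#'   (semicolon-joined rule ids; empty only for consistent contigs).
#' @export
classify_candidates <- function(contigs, tsd_max = 50) {
  need <- c("contig_id", "junction_side", "polyA_length", "tsd_bp",
            "source_active", "source_5p_id", "source_3p_id",
            "junction_in_l1_body", "junction_in_polyA_tract")
  missing <- setdiff(need, names(contigs))
  .assert(length(missing) == 0, "contig table missing column(s): %s",
          paste(missing, collapse = ", "))
  .assert(all(contigs$polyA_length >= 0, na.rm = TRUE),
          "polyA_length must be >= 0")

  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    ct <- contigs[i, ]
    reasons <- character(0)
    r1 <- isFALSE(ct$source_active)
    r2 <- ct$junction_side %in% c("three_prime", "both") &&
      ct$polyA_length == 0
    r3 <- ct$junction_side == "both" &&
      !is.na(ct$source_5p_id) && !is.na(ct$source_3p_id) &&
      ct$source_5p_id != ct$source_3p_id
    r4 <- isTRUE(ct$junction_in_l1_body) ||
      isTRUE(ct$junction_in_polyA_tract)
    f1 <- !is.na(ct$tsd_bp) && ct$tsd_bp > tsd_max
    unannot <- is.na(ct$source_active)

    if (r1) reasons <- c(reasons, "R1")
    if (r2) reasons <- c(reasons, "R2")
    if (r3) reasons <- c(reasons, "R3")
    if (r4) reasons <- c(reasons, "R4")
    if (f1) reasons <- c(reasons, "F1")
    if (unannot) reasons <- c(reasons, "unannotated")

    definite <- r1 || r2 || r3
    verdict <- if (definite) {
      "chimera"
    } else {
      consistent <- !r4 && !f1 && !unannot &&
        isTRUE(ct$source_active) &&
        !is.na(ct$polyA_length) && ct$polyA_length > 0 &&
        !is.na(ct$tsd_bp) && ct$tsd_bp <= tsd_max &&
        (is.na(ct$source_5p_id) || is.na(ct$source_3p_id) ||
           ct$source_5p_id == ct$source_3p_id)
      if (consistent) "consistent_with_true_insertion" else "indeterminate"
    }
    if (verdict == "indeterminate" && length(reasons) == 0) {
      reasons <- "incomplete_evidence"
    }
    tibble(contig_id = ct$contig_id, verdict = verdict,
           reasons = paste(reasons, collapse = ";"))
  })
  bind_rows(rows)
}

#' @rdname classify_candidates
#' @param contig a single-row contig annotation.
#' @export
classify_candidate <- function(contig, tsd_max = 50) {
  .assert(nrow(contig) == 1, "classify_candidate takes a single contig row")
  classify_candidates(contig, tsd_max = tsd_max)
}

#' Target-site duplication size implied by two flank alignments
#'
#' The apparent TSD of a candidate insertion is the overlap of the reference
#' intervals that its 5' and 3' flanks align to: a true insertion duplicates
#' a short target motif, so its flanks overlap by a few bp, while two
#' independent junction artifacts landing near the same locus can imply
#' arbitrarily large "TSDs".
#'
#' @param flank_left,flank_right lists or single-row data frames with
#'   `contig`, `start`, `end` (0-based half-open reference intervals).
#' @return the overlap length in bp (0 when disjoint or abutting).
#' @export
tsd_size <- function(flank_left, flank_right) {
  fl <- as.list(flank_left)
  fr <- as.list(flank_right)
  .assert(identical(fl$contig, fr$contig),
          "flank alignments on different reference contigs")
  .assert(fl$start < fl$end && fr$start < fr$end,
          "flank intervals must be non-empty half-open intervals")
  max(0, min(fl$end, fr$end) - max(fl$start, fr$start))
}

#' Evaluate the rule engine against simulation truth
#'
#' @param contigs annotated contigs (see [classify_candidates()]).
#' @param truth tibble `contig_id`, `class` from
#'   [simulate_candidate_contigs()].
#' @param tsd_max passed to the classifier.
#' @return list with `verdicts`, `confusion` (verdict x truth-class count
#'   table), `binary` (TP/FP/FN/TN counts treating `chimera` verdicts as
#'   positives and non-`true_insertion` classes as artifact truth), and
#'   `rule_precision` (per-rule fraction of firings on artifact-truth
#'   contigs).
#' @export
evaluate_classifier <- function(contigs, truth, tsd_max = 50) {
  .assert(setequal(contigs$contig_id, truth$contig_id),
          "contig ids do not match truth labels")
  v <- classify_candidates(contigs, tsd_max = tsd_max)
  df <- dplyr::inner_join(v, truth, by = "contig_id")
  confusion <- table(verdict = df$verdict, class = df$class)
  is_artifact <- df$class != "true_insertion"
  called <- df$verdict == "chimera"
  binary <- c(TP = sum(called & is_artifact),
              FP = sum(called & !is_artifact),
              FN = sum(!called & is_artifact),
              TN = sum(!called & !is_artifact))
  rules <- c("R1", "R2", "R3", "R4", "F1")
  rule_precision <- vapply(rules, function(r) {
    fired <- grepl(paste0("\\b", r, "\\b"), df$reasons)
    if (!any(fired)) return(NA_real_)
    mean(is_artifact[fired])
  }, numeric(1))
  list(verdicts = v, confusion = confusion, binary = binary,
       rule_precision = rule_precision)
}

#' L1 subfamily activity lookup
#'
#' Ships a small annotation table mapping L1 subfamilies to
#' retrotransposition competence (human-specific L1Hs active; older L1PA2 to
#' L1PA17 inactive), used to populate `source_active` from a subfamily name.
#'
#' @return tibble with `subfamily`, `active`.
#' @export
l1_subfamily_activity <- function() {
  path <- system.file("extdata", "l1_subfamily_activity.tsv",
                      package = "scL1audit")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
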