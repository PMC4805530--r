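#' Per-cell sensitivity for gold-standard KNR insertions
#'
#' The fraction of the individual's gold-standard germline KNR insertions
#' detected in the given single cell at or above the read-count threshold.
#' This is the allelic-dropout/sensitivity correction factor for that cell.
#'
#' @param cell_calls call tibble restricted to one single cell.
#' @param individual_gold tibble of the individual's gold loci (columns
#'   `contig`, `start`, `end`), or a `gold_standard_set` (its loci for the
#'   cell's individual are used).
#' @param min_reads inclusive read-count threshold.
#' @return a fraction in \[0, 1\].
#' @export
per_cell_sensitivity <- function(cell_calls, individual_gold, min_reads) {
  if (inherits(individual_gold, "gold_standard_set")) {
    .assert(nrow(cell_calls) > 0, "cell_calls is empty; cannot infer individual")
    ind <- unique(cell_calls$individual_id)
    .assert(length(ind) == 1, "cell_calls must come from a single cell")
    individual_gold <-
      individual_gold$loci[individual_gold$loci$individual_id == ind, ,
                           drop = FALSE]
  }
  .assert(nrow(individual_gold) > 0,
          "empty gold-standard set: cannot compute sensitivity for this cell")
  gold_keys <- .locus_key(individual_gold$contig, individual_gold$start,
                          individual_gold$end)
  hit <- cell_calls[cell_calls$read_count >= min_reads, , drop = FALSE]
  hit_keys <- unique(.locus_key(hit$contig, hit$start, hit$end))
  sum(gold_keys %in% hit_keys) / length(gold_keys)
}

#' Chimera adjustment of a somatic insertion rate
#'
#' Scales an unadjusted (pre-validation) somatic insertion rate by the
#' fraction of candidates that survived sequence-level chimera screening:
#' `pre_rate * (1 - n_chimeras / n_candidates)`.
#'
#' @param pre_rate unadjusted rate (insertions per cell).
#' @param n_candidates number of candidates examined (>= 1).
#' @param n_chimeras number classified as definite chimeras (0 <=
#'   `n_chimeras` <= `n_candidates`).
#' @return the adjusted rate (full precision; summaries print it rounded
#'   half-up to 2 decimals).
#' @export
chimera_adjust <- function(pre_rate, n_candidates, n_chimeras) {
  .assert(n_candidates >= 1, "n_candidates must be >= 1 (fraction undefined)")
  .assert(n_chimeras >= 0 && n_chimeras <= n_candidates,
          "need 0 <= n_chimeras <= n_candidates")
  .assert(pre_rate >= 0, "pre_rate must be non-negative")
  pre_rate * (1 - n_chimeras / n_candidates)
}

#' Sensitivity-corrected somatic insertion rate for one cell
#'
#' Counts the cell's somatic candidates at or above the read-count
#' threshold, removes those classified as chimeras, and divides the
#' remainder by the cell's sensitivity for gold-standard KNR insertions.
#' A cell with zero surviving candidates has rate 0 (no division is
#' performed, so such cells still enter group means).
#'
#' @param cell_calls call tibble restricted to one single cell
#'   (`somatic_candidate` rows are used).
#' @param chimera_verdicts optional tibble mapping candidate loci to
#'   verdicts: columns `contig`, `start`, `end`, `verdict` (a candidate is
#'   excluded when its verdict is `"chimera"`). `NULL` means no candidates
#'   were screened out.
#' @param min_reads inclusive read-count threshold.
#' @param sensitivity the cell's KNR sensitivity, in (0, 1].
#' @return a `cell_rate_estimate` tibble row: `sample_id`,
#'   `n_candidates_above_threshold`, `n_chimeras_excluded`, `sensitivity`,
#'   `corrected_rate`.
#' @export
per_cell_corrected_rate <- function(cell_calls, chimera_verdicts = NULL,
                                    min_reads, sensitivity) {
  .assert(is.numeric(sensitivity) && sensitivity > 0 && sensitivity <= 1,
          "sensitivity must lie in (0, 1]; cell is uncorrectable otherwise")
  sample_id <- unique(cell_calls$sample_id)
  .assert(length(sample_id) <= 1, "cell_calls must come from a single cell")
  cand <- cell_calls[cell_calls$candidate_class == "somatic_candidate" &
                       cell_calls$read_count >= min_reads, , drop = FALSE]
  n_cand <- nrow(cand)
  n_chim <- 0L
  if (n_cand > 0 && !is.null(chimera_verdicts)) {
    chim <- chimera_verdicts[chimera_verdicts$verdict == "chimera", ,
                             drop = FALSE]
    chim_keys <- .locus_key(chim$contig, chim$start, chim$end)
    n_chim <- sum(.locus_key(cand$contig, cand$start, cand$end) %in%
                    chim_keys)
  }
  rate <- if (n_cand == 0) 0 else (n_cand - n_chim) / sensitivity
  tibble(sample_id = if (length(sample_id)) sample_id else NA_character_,
         n_candidates_above_threshold = n_cand,
         n_chimeras_excluded = n_chim,
         sensitivity = sensitivity,
         corrected_rate = rate)
}

#' Corrected somatic insertion rates for a whole cohort
#'
#' Convenience driver: for every single cell, measures its gold-standard
#' KNR sensitivity and its chimera-screened candidate count at the chosen
#' threshold, and returns one [per_cell_corrected_rate()] row per cell.
#' Cells whose individual has an empty gold set are skipped with a warning.
#'
#' @param calls full call tibble.
#' @param gold a `gold_standard_set`.
#' @param min_reads inclusive read-count threshold.
#' @param chimera_verdicts as in [per_cell_corrected_rate()].
#' @return tibble of per-cell rate estimates with `individual_id` and
#'   `cell_type` attached.
#' @export
cohort_corrected_rates <- function(calls, gold, min_reads,
                                   chimera_verdicts = NULL) {
  sc <- calls[calls$material == "single_cell", , drop = FALSE]
  cells <- unique(sc[, c("sample_id", "individual_id", "cell_type")])
  gold_by_ind <- split(gold$loci, gold$loci$individual_id)
  skipped <- 0L
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ind <- cells$individual_id[[i]]
    g <- gold_by_ind[[ind]]
    if (is.null(g) || nrow(g) == 0) return(NULL)
    cc <- sc[sc$sample_id == cells$sample_id[[i]], , drop = FALSE]
    sens <- per_cell_sensitivity(cc[cc$candidate_class == "knr_call", ,
                                    drop = FALSE], g, min_reads)
    if (sens == 0) return(NULL)  # uncorrectable cell
    per_cell_corrected_rate(cc, chimera_verdicts, min_reads, sens) |>
      mutate(sample_id = cells$sample_id[[i]], individual_id = ind,
             cell_type = cells$cell_type[[i]])
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d cell(s) skipped (empty gold set or zero sensitivity)",
                    dropped))
  }
  bind_rows(rows)
}

#' Group summaries and ANOVA across cell types
#'
#' Per-group mean and SD of corrected rates, group size, percentage of cells
#' with rate zero, and a classic one-way ANOVA p-value across groups
#' (`NULL` with a single group). A Kruskal-Wallis p-value is reported
#' alongside as a nonparametric alternative.
#'
#' @param cell_estimates tibble with `corrected_rate` per cell.
#' @param groups vector of group labels (e.g. cell types), parallel to
#'   `cell_estimates` rows.
#' @return list with `summary` (tibble: `group`, `mean_rate`, `sd_rate`,
#'   `n_cells`, `pct_cells_zero`), `anova_p`, `kruskal_p`.
#' @export
aggregate_rates <- function(cell_estimates, groups) {
  .assert(length(groups) == nrow(cell_estimates),
          "groups must be parallel to cell_estimates")
  df <- tibble(rate = cell_estimates$corrected_rate,
               group = as.character(groups))
  summary <- df |>
    group_by(.data$group) |>
    summarise(mean_rate = mean(.data$rate),
              sd_rate = if (dplyr::n() > 1) sd(.data$rate) else 0,
              n_cells = dplyr::n(),
              pct_cells_zero = 100 * mean(.data$rate == 0),
              .groups = "drop")
  anova_p <- NULL
  kruskal_p <- NULL
  sizes <- table(df$group)
  if (length(sizes) >= 2 && all(sizes >= 2)) {
    if (var(df$rate) == 0) {
      anova_p <- 1  # F = 0: identical rate vectors across groups
      kruskal_p <- 1
    } else {
      fit <- aov(rate ~ group, data = df)
      anova_p <- summary(fit)[[1]][["Pr(>F)"]][[1]]
      kruskal_p <- stats::kruskal.test(rate ~ group, data = df)$p.value
    }
  }
  list(summary = summary, anova_p = anova_p, kruskal_p = kruskal_p)
}

#' Junction detection rates
#'
#' Fractions of calls (or candidates) detected at only the 5', only the 3',
#' or both L1 junctions.
#'
#' Modes:
#' * `per_call`: every (sample, locus) call counts separately — a candidate
#'   seen in 3 cells contributes 3;
#' * `per_candidate_single_cell_only`: one entry per candidate locus,
#'   restricted to candidates detected in exactly one cell (multi-cell
#'   candidates excluded entirely);
#' * `per_candidate_all`: one entry per candidate locus, merging junction
#'   evidence across samples — both junctions count as detected even when
#'   each was seen in a different single cell.
#'
#' @param calls call tibble (pre-filter to the material of interest).
#' @param mode one of the three modes above.
#' @return a `junction_rate_report`: list with `mode`, `fractions` (named
#'   `five_prime_only`, `three_prime_only`, `both`; sums to 1) and
#'   `denominator`.
#' @export
junction_detection_rates <- function(calls,
                                     mode = c("per_call",
                                              "per_candidate_single_cell_only",
                                              "per_candidate_all")) {
  mode <- match.arg(mode)
  .assert(all(calls$junctions %in% .junctions), "junctions field not populated")
  .assert(nrow(calls) > 0, "no calls in scope")
  key <- .locus_key(calls$contig, calls$start, calls$end)
  junc <- switch(
    mode,
    per_call = calls$junctions,
    per_candidate_single_cell_only = {
      df <- tibble(key = key, sample_id = calls$sample_id,
                   junctions = calls$junctions) |>
        group_by(.data$key) |>
        summarise(n_cells = dplyr::n_distinct(.data$sample_id),
                  junctions = .data$junctions[[1]], .groups = "drop")
      df$junctions[df$n_cells == 1]
    },
    per_candidate_all = {
      df <- tibble(key = key, junctions = calls$junctions) |>
        group_by(.data$key) |>
        summarise(
          has5 = any(.data$junctions %in% c("five_prime_only", "both")),
          has3 = any(.data$junctions %in% c("three_prime_only", "both")),
          .groups = "drop")
      ifelse(df$has5 & df$has3, "both",
             ifelse(df$has5, "five_prime_only", "three_prime_only"))
    }
  )
  .assert(length(junc) > 0, "no candidates left under mode %s", mode)
  fr <- vapply(.junctions, function(j) mean(junc == j), numeric(1))
  structure(list(mode = mode, fractions = fr, denominator = length(junc)),
            class = "junction_rate_report")
}

#' @export
print.junction_rate_report <- function(x, ...) {
  cat(sprintf(
    "<junction rates [%s], n=%d: 5'-only %.1f%%, 3'-only %.1f%%, both %.1f%%>\n",
    x$mode, x$denominator, 100 * x$fractions[["five_prime_only"]],
    100 * x$fractions[["three_prime_only"]], 100 * x$fractions[["both"]]))
  invisible(x)
}
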