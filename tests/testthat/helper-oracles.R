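# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive (loops, enumerations) and never
# call the implementation they check.

# ---- metric oracles ----------------------------------------------------

oracle_mapd <- function(contig, values) {
  diffs <- c()
  for (ct in unique(contig)) {
    x <- values[contig == ct]
    if (length(x) < 2) next
    for (i in seq_len(length(x) - 1)) diffs <- c(diffs, abs(x[i + 1] - x[i]))
  }
  median(diffs)
}

oracle_mdad <- function(values) {
  m <- median(values)
  devs <- numeric(length(values))
  for (i in seq_along(values)) devs[i] <- abs(values[i] - m)
  median(devs)
}

oracle_gini <- function(width, depth) {
  reads <- depth * width
  o <- order(depth)
  width <- width[o]; reads <- reads[o]
  cg <- c(0, cumsum(width) / sum(width))
  cr <- c(0, cumsum(reads) / sum(reads))
  auc <- 0
  for (i in seq_len(length(cg) - 1)) {
    auc <- auc + (cg[i + 1] - cg[i]) * (cr[i] + cr[i + 1]) / 2
  }
  1 - 2 * auc
}

# count overlapping bases one by one (intervals are small in tests)
oracle_tsd <- function(l_start, l_end, r_start, r_end) {
  n <- 0
  for (b in seq(min(l_start, r_start), max(l_end, r_end))) {
    if (b >= l_start && b < l_end && b >= r_start && b < r_end) n <- n + 1
  }
  n
}

# ---- gold-standard predicate oracles (clause-by-clause re-checks) ------

oracle_rcseq_gold <- function(bulk_calls, min_bulk_reads = 40,
                              include_prior_rcseq_only = FALSE) {
  keys <- unique(paste(bulk_calls$individual_id, bulk_calls$contig,
                       bulk_calls$start, bulk_calls$end))
  keep <- character(0)
  for (k in keys) {
    rows <- bulk_calls[paste(bulk_calls$individual_id, bulk_calls$contig,
                             bulk_calls$start, bulk_calls$end) == k, ]
    n_bulk_pass <- sum(rows$read_count >= min_bulk_reads)
    prior_ok <- any(rows$prior_study) ||
      (include_prior_rcseq_only && any(rows$prior_rcseq_only))
    if (n_bulk_pass == 2 && prior_ok) keep <- c(keep, k)
  }
  sort(keep)
}

oracle_wgs_gold <- function(ev) {
  keys <- unique(paste(ev$individual_id, ev$contig, ev$start, ev$end))
  keep <- character(0)
  for (k in keys) {
    rows <- ev[paste(ev$individual_id, ev$contig, ev$start, ev$end) == k, ]
    if (nrow(rows) != 2) next
    ok <- TRUE
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      a <- r$ram_reads_left >= 2 && r$ram_reads_right >= 2
      b <- r$clipped_reads >= 4
      cc <- if (r$polyA_detected) r$tsd_or_deletion_bp <= 250 else
        r$tsd_or_deletion_bp <= 50
      d <- r$clipped_reads_at_breakpoint >= r$clipped_reads / 2
      e <- r$prior_study
      if (!(a && b && cc && d && e)) ok <- FALSE
    }
    if (ok) keep <- c(keep, k)
  }
  sort(keep)
}

oracle_l1ip_gold <- function(bulk_calls, n_bulks_by_ind, min_score = 0.5) {
  keys <- unique(paste(bulk_calls$individual_id, bulk_calls$contig,
                       bulk_calls$start, bulk_calls$end))
  keep <- character(0)
  for (k in keys) {
    rows <- bulk_calls[paste(bulk_calls$individual_id, bulk_calls$contig,
                             bulk_calls$start, bulk_calls$end) == k, ]
    nb <- n_bulks_by_ind[[rows$individual_id[1]]]
    n_pass <- sum(!is.na(rows$score) & rows$score >= min_score)
    if (n_pass >= ceiling(nb / 2) && any(rows$prior_study)) {
      keep <- c(keep, k)
    }
  }
  sort(keep)
}

gold_key <- function(set) {
  sort(paste(set$loci$individual_id, set$loci$contig, set$loci$start,
             set$loci$end))
}

# ---- fixture builders --------------------------------------------------

make_call_row <- function(sample_id = "c1", individual_id = "ind01",
                          material = "single_cell",
                          cell_type = "hippocampal_neuron",
                          contig = "chr1", start = 100, end = 400,
                          read_count = 5, junctions = "both",
                          prior_study = TRUE, prior_rcseq_only = FALSE,
                          candidate_class = "knr_call", score = NA_real_) {
  tibble::tibble(sample_id = sample_id, individual_id = individual_id,
                 material = material, cell_type = cell_type, contig = contig,
                 start = start, end = end, read_count = read_count,
                 junctions = junctions, prior_study = prior_study,
                 prior_rcseq_only = prior_rcseq_only,
                 candidate_class = candidate_class, score = score)
}

# a pair of bulk calls for one locus of one individual
make_bulk_pair <- function(individual_id, contig, start, rc1, rc2,
                           prior_study = TRUE, prior_rcseq_only = FALSE,
                           score = NA_real_) {
  dplyr::bind_rows(
    make_call_row(sample_id = paste0(individual_id, "_bulk1"),
                  individual_id = individual_id, material = "bulk",
                  cell_type = "other", contig = contig, start = start,
                  end = start + 300, read_count = rc1,
                  prior_study = prior_study,
                  prior_rcseq_only = prior_rcseq_only, score = score),
    make_call_row(sample_id = paste0(individual_id, "_bulk2"),
                  individual_id = individual_id, material = "bulk",
                  cell_type = "other", contig = contig, start = start,
                  end = start + 300, read_count = rc2,
                  prior_study = prior_study,
                  prior_rcseq_only = prior_rcseq_only, score = score))
}

random_log2_track <- function(n, n_contigs = 2) {
  tibble::tibble(
    contig = sort(rep_len(paste0("chr", seq_len(n_contigs)), n)),
    start = rep(0, n), end = rep(1, n),
    log2_ratio = rnorm(n))
}

random_coverage_track <- function(n, bin_bp = 1000, max_depth = 50) {
  coverage_track(tibble::tibble(
    contig = "chr1", start = (seq_len(n) - 1) * bin_bp,
    end = seq_len(n) * bin_bp,
    depth = sample.int(max_depth, n, replace = TRUE)))
}
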