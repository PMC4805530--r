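#' Simulation configuration for synthetic call tables
#'
#' Defines the cohort and signal-model parameters of the synthetic
#' single-cell L1 insertion study that the audit runs against. Defaults
#' emulate the statistical structure of a MALBAC-amplified single-cell
#' retrotransposon capture study:
#'
#' * a per-individual panel of germline known non-reference (KNR) insertions
#'   whose single-cell read counts are bimodal — a low mode near 1 read
#'   (amplification non-uniformity at the insertion length scale) and an
#'   overdispersed high mode — with two-thirds of calls in the low mode;
#' * heavy per-cell allelic dropout of KNR insertions (detection probability
#'   `1 - knr_dropout_prob` per locus per cell);
#' * rare true somatic insertions (Poisson per cell) that behave like
#'   single-copy germline insertions: same dropout, same read-count mixture;
#' * abundant chimeric false positives whose read counts concentrate at 1–2
#'   reads (~97% single-read, ~99.6% at <= 2 reads);
#' * two bulk samples per individual carrying every germline KNR insertion
#'   at high read counts.
#'
#' @param n_individuals number of individuals.
#' @param cells_per_individual single cells per individual.
#' @param knr_per_individual germline KNR insertions per individual.
#' @param knr_dropout_prob per-cell, per-locus probability that a KNR
#'   insertion yields no call at all (absence of a row).
#' @param knr_mixture list with `weight_low`, `low_count_mean` (zero-truncated
#'   geometric mean of the low mode), `high_count_mean` and
#'   `high_count_dispersion` (NB mu and size of the high mode).
#' @param somatic_rate_per_cell true Poisson mean of somatic insertions per
#'   cell.
#' @param chimera_mean_per_cell Poisson mean of chimeric false-positive calls
#'   per cell.
#' @param chimera_count_prob success probability of the zero-truncated
#'   geometric read-count distribution of chimeras (0.935 puts 93.5% of
#'   chimeras at 1 read and 99.6% at <= 2 reads).
#' @param both_junction_prob_true probability that a true (KNR or somatic)
#'   single-cell call is detected at both the 5' and 3' junction.
#' @param both_junction_prob_chimera same for chimeric calls (low: a chimera
#'   is a single spurious junction).
#' @param knr_provenance_probs probabilities that a KNR locus was catalogued
#'   by a prior independent (non capture-based) study, only by prior
#'   capture-based studies, or is novel; must sum to 1.
#' @param bulk_count_mean,bulk_count_dispersion NB mu and size of bulk
#'   read counts at KNR loci.
#' @param cell_type_probs mixing proportions of single-cell types.
#' @param seed integer seed; required, every draw is reproducible from it.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_individuals = 3,
                              cells_per_individual = 57,
                              knr_per_individual = 140,
                              knr_dropout_prob = 0.55,
                              knr_mixture = list(weight_low = 2 / 3,
                                                 low_count_mean = 2.2,
                                                 high_count_mean = 20,
                                                 high_count_dispersion = 2),
                              somatic_rate_per_cell = 0.2,
                              chimera_mean_per_cell = 28,
                              chimera_count_prob = 0.935,
                              both_junction_prob_true = 0.6,
                              both_junction_prob_chimera = 0.02,
                              knr_provenance_probs = c(independent_prior = 0.8,
                                                       rcseq_prior_only = 0.1,
                                                       novel = 0.1),
                              bulk_count_mean = 150,
                              bulk_count_dispersion = 5,
                              cell_type_probs = c(hippocampal_neuron = 0.5,
                                                  hippocampal_glia = 0.15,
                                                  cortical_neuron = 0.2,
                                                  AGS_neuron = 0.15),
                              seed = NULL) {
  .assert(!is.null(seed), "a seed is required: simulations must be reproducible")
  probs <- c(knr_dropout_prob, knr_mixture$weight_low, chimera_count_prob,
             both_junction_prob_true, both_junction_prob_chimera)
  .assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  .assert(abs(sum(knr_provenance_probs) - 1) < 1e-9,
          "knr_provenance_probs must sum to 1")
  .assert(abs(sum(cell_type_probs) - 1) < 1e-9,
          "cell_type_probs must sum to 1")
  .assert(knr_mixture$low_count_mean >= 1,
          "a zero-truncated geometric mean must be >= 1")
  .assert(somatic_rate_per_cell >= 0 && chimera_mean_per_cell >= 0,
          "rates must be non-negative")
  .assert(n_individuals >= 1 && cells_per_individual >= 1 &&
            knr_per_individual >= 1, "cohort sizes must be positive")
  cfg <- list(n_individuals = n_individuals,
              cells_per_individual = cells_per_individual,
              knr_per_individual = knr_per_individual,
              knr_dropout_prob = knr_dropout_prob,
              knr_mixture = knr_mixture,
              somatic_rate_per_cell = somatic_rate_per_cell,
              chimera_mean_per_cell = chimera_mean_per_cell,
              chimera_count_prob = chimera_count_prob,
              both_junction_prob_true = both_junction_prob_true,
              both_junction_prob_chimera = both_junction_prob_chimera,
              knr_provenance_probs = knr_provenance_probs,
              bulk_count_mean = bulk_count_mean,
              bulk_count_dispersion = bulk_count_dispersion,
              cell_type_probs = cell_type_probs,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# draw read counts from the two-component KNR mixture
draw_knr_counts <- function(n, mix) {
  if (n == 0) return(integer(0))
  low <- runif(n) < mix$weight_low
  out <- integer(n)
  out[low] <- rztgeom(sum(low), prob = 1 / mix$low_count_mean)
  out[!low] <- rztnbinom(sum(!low), mu = mix$high_count_mean,
                         size = mix$high_count_dispersion)
  out
}

draw_junctions <- function(n, both_prob) {
  if (n == 0) return(character(0))
  u <- runif(n)
  ifelse(u < both_prob, "both",
         ifelse(u < both_prob + (1 - both_prob) * 0.55,
                "five_prime_only", "three_prime_only"))
}

# random non-overlapping-ish loci; L1 insertions are point-like (~6 kb max),
# represented as short target intervals
draw_loci <- function(n, prefix) {
  contig <- paste0("chr", sample(1:22, n, replace = TRUE))
  start <- sample.int(2e8, n, replace = TRUE)
  tibble(contig = contig, start = start, end = start + 300L,
         locus_id = paste0(prefix, "_", seq_len(n)))
}

#' Simulate a single-cell L1 insertion call study
#'
#' Generates per-sample insertion call tables, sample metadata and complete
#' ground-truth labels under a [simulation_config()]. Deterministic given the
#' config seed; each draw class (loci, bulk counts, cell calls, somatic
#' insertions, chimeras) uses its own named substream so adding one never
#' perturbs the others.
#'
#' @param config a [simulation_config()].
#' @return a list:
#' * `calls`: call table (schema of [read_call_table()]);
#' * `samples`: sample table with `total_reads`;
#' * `truth`: list with `call_labels` (`knr_true` / `somatic_true` /
#'   `chimera`, parallel to `calls` rows), `knr_loci` (per-individual panel
#'   with provenance and per-bulk read counts), `per_cell` (true somatic
#'   count, chimera count, realised KNR presence per cell), and
#'   `knr_presence` (cell x locus detection table).
#' @export
simulate_call_tables <- function(config) {
  .assert(inherits(config, "simulation_config"),
          "config must come from simulation_config()")
  cfg <- config
  individuals <- sprintf("ind%02d", seq_len(cfg$n_individuals))

  # -- germline KNR panels and bulk samples ------------------------------
  knr <- with_stream(cfg$seed, "knr_loci", {
    purrr_map <- lapply(individuals, function(ind) {
      loci <- draw_loci(cfg$knr_per_individual, paste0(ind, "_knr"))
      loci$individual_id <- ind
      loci$provenance <- sample(names(cfg$knr_provenance_probs),
                                nrow(loci), replace = TRUE,
                                prob = cfg$knr_provenance_probs)
      loci$bulk1_reads <- rnbinom(nrow(loci), mu = cfg$bulk_count_mean,
                                  size = cfg$bulk_count_dispersion)
      loci$bulk2_reads <- rnbinom(nrow(loci), mu = cfg$bulk_count_mean,
                                  size = cfg$bulk_count_dispersion)
      # a bulk call row exists only when >= 1 read
      loci
    })
    bind_rows(purrr_map)
  })
  knr$prior_study <- knr$provenance == "independent_prior"
  knr$prior_rcseq_only <- knr$provenance == "rcseq_prior_only"

  bulk_samples <- tibble(
    sample_id = paste0(rep(individuals, each = 2), "_bulk", 1:2),
    individual_id = rep(individuals, each = 2),
    material = "bulk", cell_type = "other"
  )

  bulk_calls <- bind_rows(
    knr |> mutate(sample_id = paste0(.data$individual_id, "_bulk1"),
                  read_count = .data$bulk1_reads),
    knr |> mutate(sample_id = paste0(.data$individual_id, "_bulk2"),
                  read_count = .data$bulk2_reads)
  ) |>
    dplyr::filter(.data$read_count >= 1) |>
    mutate(material = "bulk", cell_type = "other",
           junctions = "both", candidate_class = "knr_call",
           score = NA_real_) |>
    select("sample_id", "individual_id", "material", "cell_type", "contig",
           "start", "end", "read_count", "junctions", "prior_study",
           "prior_rcseq_only", "candidate_class", "score", "locus_id")

  # -- single cells -------------------------------------------------------
  cells <- with_stream(cfg$seed, "cells", {
    tibble(
      sample_id = paste0(rep(individuals, each = cfg$cells_per_individual),
                         "_cell",
                         sprintf("%03d", seq_len(cfg$cells_per_individual))),
      individual_id = rep(individuals, each = cfg$cells_per_individual),
      material = "single_cell",
      cell_type = sample(names(cfg$cell_type_probs),
                         cfg$n_individuals * cfg$cells_per_individual,
                         replace = TRUE, prob = cfg$cell_type_probs)
    )
  })

  # KNR calls in single cells: per cell x locus Bernoulli detection, then
  # read counts from the bimodal mixture
  knr_cell <- with_stream(cfg$seed, "knr_cells", {
    grid <- dplyr::inner_join(cells |> select("sample_id", "individual_id",
                                              "material", "cell_type"),
                              knr |> select("individual_id", "contig",
                                            "start", "end", "locus_id",
                                            "prior_study",
                                            "prior_rcseq_only"),
                              by = "individual_id",
                              relationship = "many-to-many")
    grid$detected <- runif(nrow(grid)) >= cfg$knr_dropout_prob
    det <- grid[grid$detected, , drop = FALSE]
    det$read_count <- draw_knr_counts(nrow(det), cfg$knr_mixture)
    det$junctions <- draw_junctions(nrow(det), cfg$both_junction_prob_true)
    list(calls = det, presence = grid[, c("sample_id", "locus_id",
                                          "detected")])
  })
  knr_cell_calls <- knr_cell$calls |>
    mutate(candidate_class = "knr_call", score = NA_real_) |>
    select("sample_id", "individual_id", "material", "cell_type", "contig",
           "start", "end", "read_count", "junctions", "prior_study",
           "prior_rcseq_only", "candidate_class", "score", "locus_id")

  # true somatic insertions: Poisson per cell, same dropout and read-count
  # behaviour as single-copy germline insertions
  somatic_calls <- with_stream(cfg$seed, "somatic", {
    n_true <- rpois(nrow(cells), cfg$somatic_rate_per_cell)
    idx <- rep(seq_len(nrow(cells)), n_true)
    out <- NULL
    if (length(idx) > 0) {
      loci <- draw_loci(length(idx), "som")
      out <- cells[idx, ] |>
        mutate(contig = loci$contig, start = loci$start, end = loci$end,
               locus_id = paste0(loci$locus_id, "_",
                                 .data$sample_id),
               detected = runif(length(idx)) >= cfg$knr_dropout_prob)
      out <- out[out$detected, , drop = FALSE]
      out$read_count <- draw_knr_counts(nrow(out), cfg$knr_mixture)
      out$junctions <- draw_junctions(nrow(out), cfg$both_junction_prob_true)
    }
    list(calls = out, n_true = tibble(sample_id = cells$sample_id,
                                      n_somatic_true = n_true))
  })
  som_cell_calls <- NULL
  if (!is.null(somatic_calls$calls) && nrow(somatic_calls$calls) > 0) {
    som_cell_calls <- somatic_calls$calls |>
      mutate(prior_study = FALSE, prior_rcseq_only = FALSE,
             candidate_class = "somatic_candidate", score = NA_real_) |>
      select("sample_id", "individual_id", "material", "cell_type", "contig",
             "start", "end", "read_count", "junctions", "prior_study",
             "prior_rcseq_only", "candidate_class", "score", "locus_id")
  }

  # chimeric artifacts: abundant, 1-2 reads, single junction
  chimera_calls <- with_stream(cfg$seed, "chimera", {
    n_chim <- rpois(nrow(cells), cfg$chimera_mean_per_cell)
    idx <- rep(seq_len(nrow(cells)), n_chim)
    out <- NULL
    if (length(idx) > 0) {
      loci <- draw_loci(length(idx), "chim")
      out <- cells[idx, ] |>
        mutate(contig = loci$contig, start = loci$start, end = loci$end,
               locus_id = paste0(loci$locus_id, "_", .data$sample_id),
               read_count = rztgeom(length(idx),
                                    prob = cfg$chimera_count_prob),
               junctions = {
                 u <- runif(length(idx))
                 ifelse(u < cfg$both_junction_prob_chimera, "both",
                        ifelse(u < cfg$both_junction_prob_chimera +
                                 (1 - cfg$both_junction_prob_chimera) * 0.7,
                               "five_prime_only", "three_prime_only"))
               })
    }
    out
  })
  chim_cell_calls <- NULL
  n_chim_per_cell <- tibble(sample_id = cells$sample_id, n_chimera = 0L)
  if (!is.null(chimera_calls) && nrow(chimera_calls) > 0) {
    chim_cell_calls <- chimera_calls |>
      mutate(prior_study = FALSE, prior_rcseq_only = FALSE,
             candidate_class = "somatic_candidate", score = NA_real_) |>
      select("sample_id", "individual_id", "material", "cell_type", "contig",
             "start", "end", "read_count", "junctions", "prior_study",
             "prior_rcseq_only", "candidate_class", "score", "locus_id")
    n_chim_per_cell <- chim_cell_calls |>
      count(.data$sample_id, name = "n_chimera") |>
      tidyr::complete(sample_id = cells$sample_id,
                      fill = list(n_chimera = 0L))
  }

  calls <- bind_rows(
    bulk_calls |> mutate(.truth = "knr_true"),
    knr_cell_calls |> mutate(.truth = "knr_true"),
    if (!is.null(som_cell_calls)) som_cell_calls |>
      mutate(.truth = "somatic_true"),
    if (!is.null(chim_cell_calls)) chim_cell_calls |>
      mutate(.truth = "chimera")
  )
  call_labels <- calls$.truth
  locus_ids <- calls$locus_id
  calls <- calls |> select(-".truth", -"locus_id")
  calls <- validate_calls(calls)

  samples <- with_stream(cfg$seed, "sample_depths", {
    bind_rows(bulk_samples, cells) |>
      mutate(total_reads = ifelse(.data$material == "bulk",
                                  round(rnorm(dplyr::n(), 3e7, 2e6)),
                                  round(rnorm(dplyr::n(), 1e7, 1e6)))) |>
      arrange(.data$sample_id)
  })

  truth <- list(
    call_labels = call_labels,
    call_locus_ids = locus_ids,
    knr_loci = knr |> select("individual_id", "contig", "start", "end",
                             "locus_id", "provenance", "prior_study",
                             "prior_rcseq_only", "bulk1_reads",
                             "bulk2_reads"),
    per_cell = cells |>
      select("sample_id", "individual_id", "cell_type") |>
      dplyr::left_join(somatic_calls$n_true, by = "sample_id") |>
      dplyr::left_join(n_chim_per_cell, by = "sample_id") |>
      mutate(n_somatic_true = dplyr::coalesce(.data$n_somatic_true, 0L),
             n_chimera = dplyr::coalesce(as.integer(.data$n_chimera), 0L)),
    knr_presence = knr_cell$presence
  )
  list(calls = calls, samples = samples, truth = truth)
}
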