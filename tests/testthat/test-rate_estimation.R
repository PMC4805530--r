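test_that("per-cell sensitivity is the detected fraction of gold loci", {
  gold <- tibble::tibble(contig = "chr1", start = (1:10) * 1000,
                         end = (1:10) * 1000 + 300)
  calls <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_call_row(contig = "chr1", start = i * 1000, end = i * 1000 + 300,
                  read_count = 3)
  }))
  expect_equal(per_cell_sensitivity(calls, gold, min_reads = 3), 0.6)
  expect_equal(per_cell_sensitivity(calls, gold, min_reads = 4), 0)
  all_called <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_call_row(contig = "chr1", start = i * 1000, end = i * 1000 + 300,
                  read_count = 1)
  }))
  expect_equal(per_cell_sensitivity(all_called, gold, min_reads = 1), 1)
  expect_error(per_cell_sensitivity(calls, gold[0, ], 1), "empty gold")
})

test_that("simulated per-cell sensitivity tracks one minus the dropout", {
  d <- 0.3
  sim <- simulate_call_tables(simulation_config(
    n_individuals = 1, cells_per_individual = 30, knr_per_individual = 100,
    knr_dropout_prob = d, knr_provenance_probs = c(independent_prior = 1,
                                                   rcseq_prior_only = 0,
                                                   novel = 0),
    somatic_rate_per_cell = 0, chimera_mean_per_cell = 0, seed = 19))
  gold <- select_rcseq_gold(sim$calls[sim$calls$material == "bulk", ],
                            samples = sim$samples)
  sc <- sim$calls[sim$calls$material == "single_cell", ]
  sens <- vapply(unique(sc$sample_id), function(s) {
    per_cell_sensitivity(sc[sc$sample_id == s, ], gold, min_reads = 1)
  }, numeric(1))
  n_pairs <- 30 * nrow(gold$loci)
  se <- sqrt(d * (1 - d) / n_pairs)
  expect_lt(abs(mean(sens) - (1 - d)), 4 * se + 0.01)
})

test_that("chimera adjustment reproduces its arithmetic and properties", {
  # worked ratios: 8 chimeras of 13 candidates, 7 of 12
  expect_equal(round_half_up(chimera_adjust(0.38, 13, 8), 2), 0.15)
  expect_equal(round_half_up(chimera_adjust(0.44, 12, 7), 2), 0.18)
  # identity with no chimeras
  expect_equal(chimera_adjust(0.73, 9, 0), 0.73)
  # linear in the unadjusted rate; monotone decreasing in chimera count
  expect_equal(chimera_adjust(2 * 0.3, 10, 4), 2 * chimera_adjust(0.3, 10, 4))
  adj <- vapply(0:10, function(k) chimera_adjust(1, 10, k), numeric(1))
  expect_true(all(diff(adj) < 0))
  expect_error(chimera_adjust(0.5, 0, 0), "n_candidates")
  expect_error(chimera_adjust(0.5, 3, 4), "n_chimeras")
})

test_that("corrected rates divide surviving candidates by sensitivity", {
  cand <- make_call_row(candidate_class = "somatic_candidate",
                        prior_study = FALSE, read_count = 5)
  est <- per_cell_corrected_rate(cand, NULL, min_reads = 3,
                                 sensitivity = 0.25)
  expect_equal(est$corrected_rate, 4)
  # zero candidates -> rate 0, no division
  none <- cand[0, ]
  expect_equal(per_cell_corrected_rate(none, NULL, 3, 0.01)$corrected_rate, 0)
  # chimera verdicts remove matching candidates
  verdicts <- tibble::tibble(contig = "chr1", start = 100, end = 400,
                             verdict = "chimera")
  est2 <- per_cell_corrected_rate(cand, verdicts, 3, 0.25)
  expect_equal(est2$n_chimeras_excluded, 1L)
  expect_equal(est2$corrected_rate, 0)
  expect_error(per_cell_corrected_rate(cand, NULL, 3, 0), "sensitivity")
  # correction inflates, never deflates
  expect_gte(est$corrected_rate, nrow(cand))
})

test_that("cohort-corrected rates recover the true somatic rate", {
  lambda <- 0.3
  means <- vapply(1:4, function(s) {
    sim <- simulate_call_tables(simulation_config(
      n_individuals = 1, cells_per_individual = 120,
      knr_per_individual = 140, somatic_rate_per_cell = lambda, seed = s))
    gold <- select_rcseq_gold(sim$calls[sim$calls$material == "bulk", ],
                              samples = sim$samples)
    lab <- sim$truth$call_labels
    chim <- sim$calls[lab == "chimera", c("contig", "start", "end")]
    chim$verdict <- "chimera"
    est <- cohort_corrected_rates(sim$calls, gold, min_reads = 3,
                                  chimera_verdicts = chim)
    mean(est$corrected_rate)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - lambda), 4 * se + 0.03)
})

test_that("group aggregation reports means, zero fractions and ANOVA", {
  est <- tibble::tibble(corrected_rate = c(1, 2, 3, 1, 2, 3))
  groups <- rep(c("a", "b"), each = 3)
  ag <- aggregate_rates(est, groups)
  expect_equal(ag$anova_p, 1)  # identical vectors: F = 0
  expect_equal(ag$summary$mean_rate, c(2, 2))

  zeros <- tibble::tibble(corrected_rate = rep(0, 8))
  agz <- aggregate_rates(zeros, rep(c("a", "b"), each = 4))
  expect_equal(agz$summary$mean_rate, c(0, 0))
  expect_equal(agz$summary$sd_rate, c(0, 0))
  expect_equal(agz$summary$pct_cells_zero, c(100, 100))

  single <- aggregate_rates(est, rep("a", 6))
  expect_null(single$anova_p)
})

test_that("null-group ANOVA p-values are uniform", {
  set.seed(11)
  pvals <- vapply(1:400, function(i) {
    est <- tibble::tibble(corrected_rate = rpois(40, 2) / runif(40, 0.2, 1))
    aggregate_rates(est, rep(c("a", "b"), each = 20))$anova_p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("junction rates honour their counting mode", {
  # every call at both junctions
  allboth <- dplyr::bind_rows(
    make_call_row(sample_id = "a", junctions = "both"),
    make_call_row(sample_id = "b", junctions = "both"))
  expect_equal(junction_detection_rates(allboth, "per_call")$fractions[["both"]], 1)

  # one candidate 5'-only in cell A and 3'-only in cell B
  split_cand <- dplyr::bind_rows(
    make_call_row(sample_id = "a", junctions = "five_prime_only"),
    make_call_row(sample_id = "b", junctions = "three_prime_only"))
  merged <- junction_detection_rates(split_cand, "per_candidate_all")
  expect_equal(merged$fractions[["both"]], 1)
  expect_equal(merged$denominator, 1)
  # ... and it is excluded entirely from the single-cell-only mode
  extra <- make_call_row(sample_id = "c", contig = "chr9",
                         junctions = "five_prime_only")
  solo <- junction_detection_rates(dplyr::bind_rows(split_cand, extra),
                                   "per_candidate_single_cell_only")
  expect_equal(solo$denominator, 1)
  expect_equal(solo$fractions[["five_prime_only"]], 1)
})

test_that("per-call junction fractions match the configured probability", {
  q <- 0.6
  sim <- simulate_call_tables(simulation_config(
    n_individuals = 1, cells_per_individual = 40, knr_per_individual = 120,
    both_junction_prob_true = q, somatic_rate_per_cell = 0,
    chimera_mean_per_cell = 0, seed = 23))
  sc <- sim$calls[sim$calls$material == "single_cell", ]
  rep <- junction_detection_rates(sc, "per_call")
  expect_equal(sum(rep$fractions), 1, tolerance = 1e-12)
  se <- sqrt(q * (1 - q) / nrow(sc))
  expect_lt(abs(rep$fractions[["both"]] - q), 4 * se)
})

test_that("junction fractions sum to one in every mode", {
  sim <- simulate_call_tables(simulation_config(
    n_individuals = 1, cells_per_individual = 20, knr_per_individual = 50,
    seed = 29))
  sc <- sim$calls[sim$calls$material == "single_cell", ]
  for (mode in c("per_call", "per_candidate_single_cell_only",
                 "per_candidate_all")) {
    expect_equal(sum(junction_detection_rates(sc, mode)$fractions), 1,
                 tolerance = 1e-12)
  }
})
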