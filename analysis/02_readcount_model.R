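#!/usr/bin/env Rscript
# Read-count signal modelling on the simulated cohort: per-sample
# histograms of gold-standard KNR calls versus somatic candidates, the
# two-component EM mixture fit, the fraction of somatic candidates
# compatible with the true-insertion high mode, and the
# sensitivity/specificity threshold table with the knee-chosen read-count
# filter. Run analysis/01_simulate_cohort.R first.

suppressPackageStartupMessages(library(scL1audit))

cfg <- default_run_config()
calls <- read_call_table("results/cohort_calls.tsv")$calls
samples <- read_sample_table("results/cohort_samples.tsv")
gold <- select_rcseq_gold(calls[calls$material == "bulk", ],
                          samples = samples)

h_knr_sc <- per_sample_histogram(calls, "knr_single_cell", gold)
h_knr_bulk <- per_sample_histogram(calls, "knr_bulk", gold)
h_som <- per_sample_histogram(calls, "somatic_single_cell")
for (h in list(h_knr_sc, h_knr_bulk, h_som)) print(h)
readr::write_tsv(dplyr::bind_rows(
  dplyr::mutate(h_knr_sc$counts, population = h_knr_sc$population),
  dplyr::mutate(h_knr_bulk$counts, population = h_knr_bulk$population),
  dplyr::mutate(h_som$counts, population = h_som$population)),
  "results/readcount_histograms.tsv")

fit <- fit_two_component_mixture(h_knr_sc)
print(fit)
cat(sprintf("KNR mixture: %.0f%% low mode / %.0f%% high mode\n",
            100 * fit$weight_low, 100 * fit$weight_high))

tf <- estimate_true_fraction(h_som, fit, n_boot = 200,
                             seed = cfg$seed)
cat(sprintf(
  "estimated true-somatic fraction among candidates: %.3f%% (95%% CI %.3f-%.3f%%)\n",
  100 * tf$fraction, 100 * tf$ci[1], 100 * tf$ci[2]))

tab <- threshold_table(calls, gold,
                       max_min_reads = cfg$thresholds$max_min_reads)
print(as.data.frame(tab), digits = 3)
readr::write_tsv(tab, "results/threshold_table.tsv")

chosen <- choose_threshold(tab, knee_ratio = cfg$thresholds$knee_ratio)
cat(sprintf(
  "knee-chosen threshold: min_reads = %d (i.e. '> %d reads'), retaining %.1f%% of gold KNR calls and %.2f%% of candidate (false-positive) calls\n",
  chosen, chosen - 1, 100 * tab$call_sensitivity[tab$min_reads == chosen],
  100 * tab$fp_retained[tab$min_reads == chosen]))
writeLines(as.character(chosen), "results/chosen_min_reads.txt")
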