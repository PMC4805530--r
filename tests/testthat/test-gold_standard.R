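test_that("the bulk read floor is inclusive and applies to both bulks", {
  calls <- dplyr::bind_rows(
    make_bulk_pair("ind01", "chr1", 1000, 40, 41),   # boundary: in
    make_bulk_pair("ind01", "chr2", 2000, 39, 400),  # one bulk below: out
    make_bulk_pair("ind01", "chr3", 3000, 500, 500,
                   prior_study = FALSE)               # no prior study: out
  )
  set <- select_rcseq_gold(calls)
  expect_equal(nrow(set$loci), 1)
  expect_equal(set$loci$contig, "chr1")
  # the audit log names why the others fell out
  log <- set$selection_log
  expect_match(log$failed_criteria[log$contig == "chr2"], "both_bulks")
  expect_match(log$failed_criteria[log$contig == "chr3"], "prior")
})

test_that("capture-only prior loci are admitted only on request", {
  prior <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_bulk_pair("ind01", "chr1", i * 1000, 100, 100)
  }))
  rc_only <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_bulk_pair("ind01", "chr2", i * 1000, 100, 100,
                   prior_study = FALSE, prior_rcseq_only = TRUE)
  }))
  calls <- dplyr::bind_rows(prior, rc_only)
  expect_equal(nrow(select_rcseq_gold(calls)$loci), 10)
  expect_equal(nrow(select_rcseq_gold(
    calls, include_prior_rcseq_only = TRUE)$loci), 14)
})

test_that("individuals need exactly two bulk samples", {
  one_bulk <- make_call_row(sample_id = "b1", material = "bulk",
                            cell_type = "other", read_count = 100)
  expect_error(select_rcseq_gold(one_bulk), "ind01")
})

test_that("raising the bulk floor never adds loci", {
  set.seed(42)
  calls <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_bulk_pair("ind01", "chr1", i * 1000,
                   sample.int(120, 1), sample.int(120, 1),
                   prior_study = runif(1) < 0.8)
  }))
  sets <- lapply(c(10, 40, 80), function(th) {
    gold_key(select_rcseq_gold(calls, min_bulk_reads = th))
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("WGS clauses are inclusive at their printed boundaries", {
  base <- tibble::tibble(
    individual_id = "ind01", contig = "chr1", start = 100, end = 400,
    ram_reads_left = 2, ram_reads_right = 2, clipped_reads = 4,
    clipped_reads_at_breakpoint = 2, tsd_or_deletion_bp = 50,
    polyA_detected = FALSE, prior_study = TRUE)
  both <- dplyr::bind_rows(base |> dplyr::mutate(sample_id = "b1"),
                           base |> dplyr::mutate(sample_id = "b2"))
  expect_equal(nrow(select_wgs_gold(both)$loci), 1)

  # TSD 51 fails without a poly-A tail but passes with one (<= 250 rule)
  tsd51 <- both |> dplyr::mutate(tsd_or_deletion_bp = 51)
  expect_equal(nrow(select_wgs_gold(tsd51)$loci), 0)
  tsd51A <- tsd51 |> dplyr::mutate(polyA_detected = TRUE)
  expect_equal(nrow(select_wgs_gold(tsd51A)$loci), 1)

  # breakpoint-concordance clause: "at least half of clipped reads"
  bp1 <- both |> dplyr::mutate(clipped_reads_at_breakpoint = 1)
  expect_equal(nrow(select_wgs_gold(bp1)$loci), 0)

  missing <- both[, setdiff(names(both), "clipped_reads")]
  expect_error(select_wgs_gold(missing), "clipped_reads")
})

test_that("the L1-IP half-of-bulks rule uses the ceiling", {
  mk <- function(ind, scores, prior = TRUE, start = 100) {
    dplyr::bind_rows(lapply(seq_along(scores), function(i) {
      make_call_row(sample_id = paste0(ind, "_b", i), individual_id = ind,
                    material = "bulk", cell_type = "other", start = start,
                    end = start + 300, read_count = 10,
                    prior_study = prior, score = scores[i])
    }))
  }
  # 2 of 4 bulks at >= 0.5: exactly half, included
  expect_equal(nrow(select_l1ip_gold(mk("i1", c(0.5, 0.6, 0.1, 0.2)))$loci), 1)
  # 1 of 3: below ceil(3/2) = 2, excluded
  expect_equal(nrow(select_l1ip_gold(mk("i2", c(0.5, 0.4, 0.4)))$loci), 0)
  # 2 of 3: included
  expect_equal(nrow(select_l1ip_gold(mk("i3", c(0.5, 0.5, 0.4)))$loci), 1)
})

test_that("random gold-selection instances match brute-force predicate oracles", {
  set.seed(7)
  for (rep in 1:60) {
    # RC-seq
    calls <- dplyr::bind_rows(lapply(1:8, function(i) {
      make_bulk_pair(sample(c("i1", "i2"), 1), "chr1", i * 1000,
                     sample.int(80, 1), sample.int(80, 1),
                     prior_study = runif(1) < 0.6,
                     prior_rcseq_only = runif(1) < 0.3)
    }))
    flag <- runif(1) < 0.5
    expect_identical(
      gold_key(select_rcseq_gold(calls, min_bulk_reads = 40,
                                 include_prior_rcseq_only = flag)),
      oracle_rcseq_gold(calls, 40, flag))

    # WGS
    ev <- dplyr::bind_rows(lapply(1:6, function(i) {
      loc <- tibble::tibble(individual_id = "i1", contig = "chr1",
                            start = i * 1000, end = i * 1000 + 300)
      dplyr::bind_rows(loc |> dplyr::mutate(sample_id = "b1"),
                       loc |> dplyr::mutate(sample_id = "b2")) |>
        dplyr::mutate(
          ram_reads_left = sample(0:4, 2, replace = TRUE),
          ram_reads_right = sample(0:4, 2, replace = TRUE),
          clipped_reads = sample(0:8, 2, replace = TRUE),
          clipped_reads_at_breakpoint = pmin(sample(0:8, 2, replace = TRUE),
                                             clipped_reads),
          tsd_or_deletion_bp = sample(c(0, 20, 50, 51, 250, 251), 2,
                                      replace = TRUE),
          polyA_detected = runif(2) < 0.5,
          prior_study = runif(2) < 0.8)
    }))
    expect_identical(gold_key(select_wgs_gold(ev)), oracle_wgs_gold(ev))

    # L1-IP
    nb <- sample(2:5, 1)
    lcalls <- dplyr::bind_rows(lapply(1:6, function(i) {
      dplyr::bind_rows(lapply(seq_len(nb), function(b) {
        make_call_row(sample_id = paste0("i1_b", b), individual_id = "i1",
                      material = "bulk", cell_type = "other",
                      start = i * 1000, end = i * 1000 + 300,
                      read_count = 10, prior_study = runif(1) < 0.7,
                      score = round(runif(1), 2))
      }))
    }))
    samples <- tibble::tibble(sample_id = paste0("i1_b", seq_len(nb)),
                              individual_id = "i1", material = "bulk",
                              cell_type = "other", total_reads = 1e6)
    expect_identical(
      gold_key(select_l1ip_gold(lcalls, samples = samples)),
      oracle_l1ip_gold(lcalls, list(i1 = nb)))
  }
})

test_that("every excluded locus carries at least one named failed criterion", {
  calls <- dplyr::bind_rows(
    make_bulk_pair("ind01", "chr1", 1000, 39, 39),
    make_bulk_pair("ind01", "chr2", 2000, 100, 100, prior_study = FALSE),
    make_bulk_pair("ind01", "chr3", 3000, 100, 100)
  )
  log <- select_rcseq_gold(calls)$selection_log
  excluded <- log[!log$included, ]
  expect_true(all(nchar(excluded$failed_criteria) > 0))
  included <- log[log$included, ]
  expect_true(all(gsub(";", "", included$failed_criteria) == ""))
})
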