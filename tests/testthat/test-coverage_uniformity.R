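test_that("equal-read bins are equal-width on a uniform reference", {
  ref <- coverage_track(tibble::tibble(
    contig = "chr1", start = (0:99) * 10000, end = (1:100) * 10000,
    depth = 20))
  bins <- equal_read_bins(ref, target_bin_bp = 100000)
  expect_equal(nrow(bins), 10)
  expect_true(all(bins$end - bins$start == 100000))
})

test_that("equal-read bins halve their width where depth doubles", {
  # first half of the contig at depth 2d, second half at d
  ref <- coverage_track(tibble::tibble(
    contig = "chr1", start = (0:119) * 10000, end = (1:120) * 10000,
    depth = rep(c(40, 20), each = 60)))
  bins <- equal_read_bins(ref, target_bin_bp = 200000)
  w_hot <- bins$end[bins$end <= 600000] - bins$start[bins$end <= 600000]
  w_cold <- bins$start[bins$start >= 600000]
  w_cold <- bins$end[bins$start >= 600000] - bins$start[bins$start >= 600000]
  expect_equal(median(w_cold) / median(w_hot), 2, tolerance = 0.1)
  expect_error(equal_read_bins(coverage_track(tibble::tibble(
    contig = "chr1", start = 0, end = 1000, depth = 0))), "zero total reads")
})

test_that("equal-read boundaries match a greedy cumulative-sum oracle", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(50:150, 1)
    ref <- random_coverage_track(n, bin_bp = 1000)
    target <- sample(c(5000, 10000, 20000), 1)
    bins <- equal_read_bins(ref, target_bin_bp = target)
    # oracle: walk bins, cutting at the first edge reaching each quota
    reads <- ref$depth * 1000
    n_out <- max(1, round(n * 1000 / target))
    quota <- sum(reads) / n_out
    cuts <- c(); acc <- 0; j <- 1
    for (b in seq_len(n)) {
      acc <- acc + reads[b]
      while (j < n_out && acc >= j * quota - 1e-9) {
        cuts <- c(cuts, ref$end[b]); j <- j + 1
      }
    }
    bounds <- unique(c(min(ref$start), cuts, max(ref$end)))
    expect_equal(bins$start, bounds[-length(bounds)])
    expect_equal(bins$end, bounds[-1])
  }
})

test_that("log2 ratio tracks are centred and respect sex corrections", {
  mk <- function(depths, contigs) coverage_track(tibble::tibble(
    contig = contigs, start = 0:(length(depths) - 1) * 1000,
    end = 1:length(depths) * 1000, depth = depths))
  ct <- rep(c("chr1", "chr2"), each = 20)
  ref <- coverage_track(tibble::tibble(
    contig = ct, start = rep((0:19) * 1000, 2), end = rep((1:20) * 1000, 2),
    depth = 50))
  # identical sample: all zero
  lr <- normalized_log2(ref, ref)
  expect_true(all(abs(lr$log2_ratio) < 1e-12))
  # doubled sample: ~1 before centring (recorded), 0 after
  dbl <- coverage_track(dplyr::mutate(tibble::as_tibble(ref), depth = 100))
  lr2 <- normalized_log2(dbl, ref)
  expect_true(all(abs(lr2$log2_ratio) < 1e-6))
  expect_equal(attr(lr2, "autosomal_center"), 1, tolerance = 1e-3)
})

test_that("chrX re-centring zeroes the sample's chrX median", {
  set.seed(10)
  ct <- c(rep("chr1", 30), rep("chrX", 15), rep("chrY", 5))
  pos <- unlist(lapply(rle(ct)$lengths, seq_len)) - 1
  ref <- coverage_track(tibble::tibble(contig = ct, start = pos * 1000,
                                       end = (pos + 1) * 1000,
                                       depth = rpois(50, 100)))
  # female sample against male reference: chrX at double relative depth
  samp_depth <- rpois(50, ifelse(ct == "chrX", 200, 100))
  samp_depth[ct == "chrY"] <- 0
  samp <- coverage_track(tibble::tibble(contig = ct, start = pos * 1000,
                                        end = (pos + 1) * 1000,
                                        depth = samp_depth))
  lr <- normalized_log2(samp, ref,
                        sex_correction = list(chrX_to_own_median = TRUE,
                                              chrY_zero = TRUE))
  expect_equal(median(lr$log2_ratio[lr$contig == "chrX"]), 0)
  expect_true(all(lr$log2_ratio[lr$contig == "chrY"] == 0))
  # without correction the chrX bins sit well above zero
  lr0 <- normalized_log2(samp, ref)
  expect_gt(median(lr0$log2_ratio[lr0$contig == "chrX"]), 0.5)
})

test_that("MAPD and MDAD have their closed forms on simple tracks", {
  const <- tibble::tibble(contig = "chr1", start = 0:9, end = 1:10,
                          log2_ratio = rep(0.7, 10))
  expect_equal(mapd(const), 0)
  expect_equal(mdad(const), 0)
  a <- 0.3
  alt <- tibble::tibble(contig = "chr1", start = 0:9, end = 1:10,
                        log2_ratio = rep(c(a, -a), 5))
  expect_equal(mapd(alt), 2 * a)
  vals <- tibble::tibble(contig = "chr1", start = 0:3, end = 1:4,
                         log2_ratio = c(0, 0, 0, 1))
  expect_equal(mdad(vals), 0)
  expect_error(mapd(const[1, ]), "2 bins")
})

test_that("MAPD/MDAD match brute-force oracles and are shift-invariant", {
  set.seed(12)
  for (i in 1:60) {
    tr <- random_log2_track(sample(10:60, 1), n_contigs = sample(1:3, 1))
    expect_equal(mapd(tr), oracle_mapd(tr$contig, tr$log2_ratio),
                 tolerance = 1e-12)
    expect_equal(mdad(tr), oracle_mdad(tr$log2_ratio), tolerance = 1e-12)
    shifted <- dplyr::mutate(tr, log2_ratio = log2_ratio + 1.37)
    expect_equal(mapd(shifted), mapd(tr), tolerance = 1e-12)
    expect_equal(mdad(shifted), mdad(tr), tolerance = 1e-12)
  }
})

test_that("Lorenz/Gini hit their closed forms and the brute-force oracle", {
  even <- coverage_track(tibble::tibble(contig = "chr1", start = (0:9) * 10,
                                        end = (1:10) * 10, depth = 5))
  lg <- lorenz_gini(even)
  expect_equal(lg$gini, 0, tolerance = 1e-12)
  expect_equal(lg$lorenz$cum_read_fraction, lg$lorenz$cum_genome_fraction)

  B <- 8
  onehot <- coverage_track(tibble::tibble(contig = "chr1",
                                          start = (0:(B - 1)) * 10,
                                          end = (1:B) * 10,
                                          depth = c(rep(0, B - 1), 10)))
  expect_equal(lorenz_gini(onehot)$gini, (B - 1) / B, tolerance = 1e-12)
  expect_error(lorenz_gini(coverage_track(tibble::tibble(
    contig = "chr1", start = 0, end = 10, depth = 0))), "all-zero")

  set.seed(13)
  for (i in 1:40) {
    tr <- random_coverage_track(sample(10:80, 1))
    lg <- lorenz_gini(tr)
    expect_equal(lg$gini, oracle_gini(tr$end - tr$start, tr$depth),
                 tolerance = 1e-9)
    # curve invariants: endpoints, monotone, convex
    cr <- lg$lorenz$cum_read_fraction
    expect_equal(cr[1], 0); expect_equal(cr[length(cr)], 1)
    expect_true(all(diff(cr) >= -1e-12))
    expect_true(all(diff(diff(cr)) >= -1e-9))
    # Gini invariant under uniform depth rescaling
    scaled <- coverage_track(dplyr::mutate(tibble::as_tibble(tr),
                                           depth = depth * 3.5))
    expect_equal(lorenz_gini(scaled)$gini, lg$gini, tolerance = 1e-12)
  }
})

test_that("a pure sinusoid concentrates spectral power at its frequency", {
  bin_bp <- 100
  n <- 4096
  x <- 10 + 5 * sin(2 * pi * (0:(n - 1)) * bin_bp / 1000)
  tr <- coverage_track(tibble::tibble(contig = "chr1",
                                      start = (0:(n - 1)) * bin_bp,
                                      end = (1:n) * bin_bp, depth = x))
  ps <- power_spectral_density(tr, segment_bins = 1024)
  # the peak lands on the frequency-grid point nearest 1e-3 /bp
  expect_equal(ps$frequency[which.max(ps$power)], 1e-3, tolerance = 0.005)
  expect_true(all(diff(ps$frequency) > 0))
  expect_lte(max(ps$frequency), 1 / (2 * bin_bp))
  expect_error(power_spectral_density(tr, segment_bins = 8192),
               "shorter than one")
})

test_that("white-noise spectra conserve variance (Parseval)", {
  tr <- simulate_coverage_track("flat", 2^16 * 100, 100, seed = 15)
  ps <- power_spectral_density(tr, segment_bins = 2048)
  expect_lt(abs(sum(ps$power) / var(tr$depth) - 1), 0.01)
})

test_that("subsampling thins binomially and keeps QC metrics stable", {
  tr <- simulate_coverage_track("flat", 1e6, 100,
                                params = list(mean_depth = 30), seed = 16)
  expect_identical(subsample_track(tr, 1), tr)
  half <- subsample_track(tr, 0.5, seed = 17)
  se <- sqrt(15 / nrow(tr))
  expect_lt(abs(mean(half$depth) - 15), 3 * se)
  expect_error(subsample_track(tr, 1.5, seed = 1), "fraction")

  # low-resolution MAPD is insensitive to a 10x read-depth reduction
  deep <- simulate_coverage_track("mda_like", 200e6, 500000,
                                  params = list(mean_depth = 3000,
                                                wave_bp = 400000), seed = 18)
  ref <- coverage_track(tibble::tibble(contig = deep$contig,
                                       start = deep$start, end = deep$end,
                                       depth = 3000))
  shallow <- subsample_track(deep, 0.1, seed = 19)
  m_deep <- mapd(normalized_log2(deep, ref))
  m_shallow <- mapd(normalized_log2(shallow, ref))
  expect_lt(abs(m_shallow - m_deep) / m_deep, 0.1)
})

test_that("pooling cells removes stochastic power but keeps systematic peaks", {
  K <- 8
  tracks <- lapply(1:K, function(s) {
    simulate_coverage_track("malbac_like", 2^14 * 100, 100, seed = 100 + s)
  })
  pooled <- pool_tracks(tracks)
  ps1 <- power_spectral_density(tracks[[1]], segment_bins = 2048)
  psK <- power_spectral_density(pooled, segment_bins = 2048)
  peak_f <- 1e-3
  off_peak <- abs(ps1$frequency - peak_f) > 1e-4
  white1 <- sum(ps1$power[off_peak])
  whiteK <- sum(psK$power[off_peak])
  # stochastic (off-peak) power drops roughly as 1/K
  expect_lt(whiteK / white1, 2 / K)
  # the systematic periodic peak survives pooling
  peak1 <- max(ps1$power[!off_peak])
  peakK <- max(psK$power[!off_peak])
  expect_gt(peakK / peak1, 0.8)
})
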