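#' Detection theory for bulk versus single-cell sequencing
#'
#' Closed-form calculator for the simplified sampling model of somatic
#' mutation detection. A mutation carried by `k` of `n` pooled cells
#' (mosaicism `k/n`) at locus depth `D` is supported on average by
#' `(k/n) * D/2` reads (heterozygous, single copy). Errors accrue as a
#' constant fraction `e` of reads, so calling requires at least
#' `T = z * e * D` supporting reads, where `z` sets the confidence margin.
#' Combining the two gives the depth-independent detectability bound
#' `k/n >= 2 * z * e`. The closed forms intentionally carry no variance
#' terms; [detection_probability_mc()] supplies the variance empirically.
#'
#' @name detection-theory
NULL

#' Expected variant-supporting reads
#' @param k cells carrying the mutation (0 <= k <= n).
#' @param n cells pooled (>= 1).
#' @param D read depth at the locus (>= 0).
#' @return `(k/n) * D / 2`.
#' @export
expected_variant_reads <- function(k, n, D) {
  .assert(all(n >= 1), "n must be >= 1")
  .assert(all(k >= 0 & k <= n), "need 0 <= k <= n")
  .assert(all(D >= 0), "D must be >= 0")
  (k / n) * D / 2
}

#' Read-count detection threshold
#' @param z confidence factor (> 0).
#' @param e fraction of error reads, in \[0, 1).
#' @param D read depth at the locus (>= 0).
#' @return `z * e * D`.
#' @export
detection_threshold <- function(z, e, D) {
  .assert(all(z > 0), "z must be positive")
  .assert(all(e >= 0 & e < 1), "e must lie in [0, 1)")
  .assert(all(D >= 0), "D must be >= 0")
  z * e * D
}

#' Minimum detectable mosaicism in bulk sequencing
#'
#' The depth-independent bound below which a somatic mutation cannot clear
#' the error-driven read threshold: `k/n >= 2 * z * e`.
#'
#' @inheritParams detection_threshold
#' @return `2 * z * e`.
#' @export
min_detectable_mosaicism <- function(z, e) {
  .assert(all(z > 0), "z must be positive")
  .assert(all(e >= 0 & e < 1), "e must lie in [0, 1)")
  2 * z * e
}

#' Monte-Carlo detection probability
#'
#' Simulates the read-sampling model behind the closed forms: variant reads
#' are Binomial(`D`, `m/2`) for mosaicism `m`, and a locus is detected when
#' they reach the threshold `z * e * D`. At large `D` the detection
#' probability crosses 50% near `m = 2 * z * e`.
#'
#' @param mosaicism vector of `k/n` values in \[0, 1\].
#' @param D read depth.
#' @param e error-read fraction.
#' @param z confidence factor.
#' @param n_sims simulated loci per mosaicism value.
#' @param seed integer seed.
#' @return tibble with `mosaicism`, `detection_prob`.
#' @export
detection_probability_mc <- function(mosaicism, D, e, z, n_sims = 2000,
                                     seed = 1) {
  .assert(all(mosaicism >= 0 & mosaicism <= 1),
          "mosaicism must lie in [0, 1]")
  thr <- detection_threshold(z, e, D)
  with_stream(seed, "detection_mc", {
    probs <- vapply(mosaicism, function(m) {
      reads <- rbinom(n_sims, size = round(D), prob = m / 2)
      mean(reads >= thr)
    }, numeric(1))
    tibble(mosaicism = mosaicism, detection_prob = probs)
  })
}

#' Hardy-Weinberg heterozygosity among insertion carriers
#'
#' For a polymorphic insertion at allele frequency `p` under Hardy-Weinberg
#' equilibrium, the fraction of carrier individuals that are heterozygous is
#' `2pq / (p^2 + 2pq)` with `q = 1 - p` (equivalently `(2 - 2p)/(2 - p)`).
#' Most known non-reference L1 insertions segregate at low `p`, so carriers
#' are overwhelmingly heterozygous — single copy per cell, like a somatic
#' insertion.
#'
#' @param p allele frequency in (0, 1\].
#' @return heterozygous fraction among carriers (0 at `p = 1`; tends to 1
#'   as `p` tends to 0).
#' @export
hw_heterozygosity <- function(p) {
  .assert(all(p > 0 & p <= 1),
          "p must lie in (0, 1]: carrier heterozygosity is undefined at p = 0")
  q <- 1 - p
  2 * p * q / (p^2 + 2 * p * q)
}

#' Heterozygous-or-hemizygous fraction of a genotype summary
#'
#' Share of genotyped gold-standard insertions present in a single copy per
#' cell (heterozygous or hemizygous carriers).
#'
#' @param n_single_copy insertions genotyped as single-copy.
#' @param n_total insertions genotyped (>= 1).
#' @return list with `fraction` and `percent` (rounded half-up to integer).
#' @export
heterozygous_fraction <- function(n_single_copy, n_total) {
  .assert(n_total >= 1, "n_total must be >= 1")
  .assert(n_single_copy >= 0 && n_single_copy <= n_total,
          "need 0 <= n_single_copy <= n_total")
  frac <- n_single_copy / n_total
  list(fraction = frac, percent = round_half_up(100 * frac, 0))
}
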