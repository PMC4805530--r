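#' Simulate binned single-cell coverage tracks
#'
#' Generates fixed-width binned read-count tracks emulating the uniformity
#' profiles of the two single-cell whole-genome amplification chemistries
#' compared by the audit, plus an unamplified control:
#'
#' * `malbac_like`: a systematic quasi-periodic ~1 kb peak/trough pattern
#'   (amplicon-scale non-uniformity inherent to the chemistry — the pattern
#'   is a property of the genome/chemistry, so its phase is fixed across
#'   cells and survives pooling) plus per-cell stochastic multiplicative
#'   noise and Poisson read sampling;
#' * `mda_like`: smooth long-wavelength multiplicative waviness (length
#'   scale well above 30 kb) plus Poisson read sampling — uniform at fine
#'   scales, wavy at large scales;
#' * `flat`: constant expected depth plus Poisson sampling (bulk-like).
#'
#' @param kind `"mda_like"`, `"malbac_like"` or `"flat"`.
#' @param length_bp total track length in bp (single contig `chr1`).
#' @param bin_bp bin width in bp; must not exceed `length_bp`.
#' @param params optional overrides: `mean_depth` (expected reads per bin,
#'   default 30), `period_bp` (MALBAC peak spacing, default 1000),
#'   `malbac_amp` (relative peak amplitude, default 0.8), `malbac_noise_sd`
#'   (log-normal sd of per-cell noise, default 0.3), `wave_bp` (MDA waviness
#'   length scale, default 300000), `wave_sd` (log-scale sd of MDA waviness,
#'   default 0.5), `phase_bp` (MALBAC phase offset, default 0).
#' @param seed integer seed (required).
#' @return a `coverage_track` with integer read counts per bin.
#' @export
simulate_coverage_track <- function(kind = c("mda_like", "malbac_like",
                                             "flat"),
                                    length_bp, bin_bp, params = list(),
                                    seed = NULL) {
  kind <- match.arg(kind)
  .assert(!is.null(seed), "a seed is required: simulations must be reproducible")
  .assert(length_bp >= bin_bp && bin_bp > 0,
          "need length_bp >= bin_bp > 0")
  p <- modifyList(list(mean_depth = 30, period_bp = 1000, malbac_amp = 0.8,
                       malbac_noise_sd = 0.3, wave_bp = 300000,
                       wave_sd = 0.5, phase_bp = 0), params)
  n <- floor(length_bp / bin_bp)
  start <- (seq_len(n) - 1) * bin_bp
  mid <- start + bin_bp / 2

  lambda <- switch(
    kind,
    flat = rep(p$mean_depth, n),
    malbac_like = {
      # deterministic systematic component: same peak/trough locations in
      # every simulated cell
      systematic <- 1 + p$malbac_amp *
        cos(2 * pi * (mid - p$phase_bp) / p$period_bp)
      noise <- with_stream(seed, "malbac_noise", {
        exp(rnorm(n, mean = -p$malbac_noise_sd^2 / 2,
                  sd = p$malbac_noise_sd))
      })
      p$mean_depth * systematic * noise
    },
    mda_like = {
      w <- with_stream(seed, "mda_wave", {
        k <- max(3L, round(p$wave_bp / bin_bp))
        raw <- rnorm(n + 2 * k)
        sm <- stats::filter(raw, rep(1 / k, k), sides = 2)
        sm <- sm[(k + 1):(k + n)]
        sm[!is.finite(sm)] <- 0
        s <- sd(sm)
        if (s > 0) sm <- sm * (p$wave_sd / s)
        sm
      })
      p$mean_depth * exp(w - p$wave_sd^2 / 2)
    }
  )
  depth <- with_stream(seed, "poisson_reads", rpois(n, pmax(lambda, 0)))
  coverage_track(tibble(contig = "chr1", start = start,
                        end = start + bin_bp, depth = as.numeric(depth)),
                 bin_scheme = "fixed_width",
                 provenance = sprintf("simulated:%s(seed=%d)", kind, seed))
}
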