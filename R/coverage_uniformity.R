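#' Single-cell amplification-uniformity QC
#'
#' Equal-read binning against a reference sample, reference-normalised log2
#' copy-number tracks with sex-chromosome corrections, the MAPD and MDAD
#' dispersion scores, Lorenz curves with Gini coefficients, Welch power
#' spectral density of binned read depth, and binomial read subsampling.
#'
#' @name coverage-uniformity
NULL

.track_reads <- function(track) {
  track$depth * (track$end - track$start)
}

#' Equal-read bin boundaries from a reference track
#'
#' Splits each contig into bins holding (as nearly as possible) equal
#' numbers of reference reads, targeting an expected span of
#' `target_bin_bp` on the reference. Boundaries snap to the reference
#' track's source-bin edges. Regions the reference covers poorly get wider
#' bins, so per-bin counting noise is equalised across samples compared on
#' the same boundaries; the boundaries are computed once on the designated
#' reference and then frozen for every compared sample.
#'
#' @param reference_track a `coverage_track` with positive total reads.
#' @param target_bin_bp target expected bin span in bp (default 500 kb).
#' @return tibble of bin boundaries (`contig`, `start`, `end`).
#' @export
equal_read_bins <- function(reference_track, target_bin_bp = 500000) {
  .assert(target_bin_bp > 0, "target_bin_bp must be positive")
  reads_all <- .track_reads(reference_track)
  .assert(sum(reads_all) > 0, "reference track has zero total reads")
  out <- lapply(split(seq_len(nrow(reference_track)),
                      reference_track$contig), function(idx) {
    ct <- reference_track[idx, ]
    reads <- .track_reads(ct)
    total <- sum(reads)
    span <- max(ct$end) - min(ct$start)
    n_out <- max(1L, round(span / target_bin_bp))
    if (total == 0 || n_out == 1) {
      return(tibble(contig = ct$contig[[1]], start = min(ct$start),
                    end = max(ct$end)))
    }
    quota <- total / n_out
    cum <- cumsum(reads)
    targets <- quota * seq_len(n_out - 1)
    # first source bin whose cumulative reads reach each quota multiple
    cut_idx <- findInterval(targets, cum, left.open = TRUE) + 1
    cut_idx <- pmin(cut_idx, nrow(ct))
    bounds <- unique(c(min(ct$start), ct$end[cut_idx], max(ct$end)))
    tibble(contig = ct$contig[[1]], start = bounds[-length(bounds)],
           end = bounds[-1])
  })
  bind_rows(out) |> arrange(.data$contig, .data$start)
}

# cumulative-read interpolator: reads of `track` falling in arbitrary
# intervals of the same contig (depth piecewise constant; gaps carry zero)
.bin_reads <- function(track, bins) {
  res <- numeric(nrow(bins))
  track_by <- split(seq_len(nrow(track)), track$contig)
  for (ct in unique(bins$contig)) {
    bidx <- which(bins$contig == ct)
    tidx <- track_by[[ct]]
    if (is.null(tidx)) { res[bidx] <- 0; next }
    tt <- track[tidx, ]
    reads <- .track_reads(tt)
    # knots at every source edge; duplicate knots across gaps keep the
    # cumulative flat there
    x <- c(tt$start[1], tt$end)
    y <- c(0, cumsum(reads))
    gaps <- which(tt$start[-1] > tt$end[-nrow(tt)])
    if (length(gaps) > 0) {
      x <- c(x, tt$start[gaps + 1])
      y <- c(y, cumsum(reads)[gaps])
      o <- order(x)
      x <- x[o]; y <- y[o]
    }
    cum <- function(g) approx(x, y, xout = pmin(pmax(g, min(x)), max(x)),
                              ties = "ordered")$y
    res[bidx] <- cum(bins$end[bidx]) - cum(bins$start[bidx])
  }
  res
}

#' Reference-normalised log2 copy-number track
#'
#' Summarises sample and reference reads over shared bins and returns
#' per-bin `log2((sample + eps) / (reference + eps))`, centred so the
#' autosomal median is 0. Optional sex-chromosome corrections for samples
#' whose sex differs from the reference's: `chrX_to_own_median` re-centres
#' chrX bins to the sample's own chrX median (exactly 0 afterwards), and
#' `chrY_zero` sets chrY bins to 0 so absent-Y samples do not skew
#' genome-wide dispersion scores.
#'
#' @param sample,reference `coverage_track`s summarisable over `bins`.
#' @param bins bin boundaries (e.g. from [equal_read_bins()]); default: the
#'   reference track's own bins.
#' @param sex_correction list with logicals `chrX_to_own_median`,
#'   `chrY_zero`.
#' @param pseudocount read-equivalents added to both numerator and
#'   denominator (default 1).
#' @return a `log2_ratio_track` tibble (`contig`, `start`, `end`,
#'   `log2_ratio`) with attributes `autosomal_center` (the subtracted
#'   median) and `pseudocount`.
#' @export
normalized_log2 <- function(sample, reference, bins = NULL,
                            sex_correction = list(chrX_to_own_median = FALSE,
                                                  chrY_zero = FALSE),
                            pseudocount = 1) {
  if (is.null(bins)) {
    bins <- as_tibble(reference)[, c("contig", "start", "end")]
  }
  .assert(length(intersect(bins$contig, sample$contig)) > 0 &&
            length(intersect(bins$contig, reference$contig)) > 0,
          "bins share no contigs with the sample/reference tracks")
  s <- .bin_reads(sample, bins)
  r <- .bin_reads(reference, bins)
  raw <- log2((s + pseudocount) / (r + pseudocount))
  auto <- !(bins$contig %in% c("chrX", "chrY"))
  .assert(any(auto), "no autosomal bins to centre on")
  center <- median(raw[auto])
  val <- raw - center
  if (isTRUE(sex_correction$chrX_to_own_median)) {
    xb <- bins$contig == "chrX"
    if (any(xb)) val[xb] <- raw[xb] - median(raw[xb])
  }
  if (isTRUE(sex_correction$chrY_zero)) {
    val[bins$contig == "chrY"] <- 0
  }
  out <- tibble(contig = bins$contig, start = bins$start, end = bins$end,
                log2_ratio = val)
  structure(out, autosomal_center = center, pseudocount = pseudocount,
            class = c("log2_ratio_track", class(out)))
}

#' Median absolute pairwise deviation (MAPD)
#'
#' Median over genomically adjacent same-contig bin pairs of
#' `|x[i+1] - x[i]|` of the log2 ratios — a small-step noise score; lower
#' is more uniform. Pairs never span contig boundaries.
#'
#' @param track a `log2_ratio_track` (or tibble with `contig` and
#'   `log2_ratio` in genomic order).
#' @return a non-negative scalar.
#' @export
mapd <- function(track) {
  .assert(nrow(track) >= 2, "MAPD needs at least 2 bins")
  diffs <- unlist(lapply(split(track$log2_ratio, track$contig), function(x) {
    if (length(x) < 2) return(numeric(0))
    abs(diff(x))
  }), use.names = FALSE)
  .assert(length(diffs) >= 1, "MAPD needs at least one adjacent same-contig pair")
  median(diffs)
}

#' Median absolute deviation from the median (MDAD)
#'
#' Median of `|x - median(x)|` over all bins of the log2 ratios — a global
#' dispersion score; lower is more uniform.
#'
#' @inheritParams mapd
#' @return a non-negative scalar.
#' @export
mdad <- function(track) {
  .assert(nrow(track) >= 1, "MDAD needs at least 1 bin")
  x <- track$log2_ratio
  median(abs(x - median(x)))
}

#' Lorenz curve and Gini coefficient of coverage
#'
#' Bins sorted by depth ascending; the curve traces the cumulative fraction
#' of reads against the cumulative fraction of the genome. Perfectly even
#' coverage lies on the diagonal (Gini 0); concentration of reads in few
#' bins bows the curve down. `gini = 1 - 2 * AUC` (trapezoid rule).
#'
#' @param track a `coverage_track` with positive total reads.
#' @return list with `lorenz` (tibble `cum_genome_fraction`,
#'   `cum_read_fraction`, starting at (0,0) and ending at (1,1)) and `gini`.
#' @export
lorenz_gini <- function(track) {
  reads <- .track_reads(track)
  width <- track$end - track$start
  .assert(sum(reads) > 0, "all-zero track: Lorenz curve undefined")
  o <- order(track$depth)
  cg <- c(0, cumsum(width[o]) / sum(width))
  cr <- c(0, cumsum(reads[o]) / sum(reads))
  auc <- sum(diff(cg) * (head(cr, -1) + tail(cr, -1)) / 2)
  list(lorenz = tibble(cum_genome_fraction = cg, cum_read_fraction = cr),
       gini = 1 - 2 * auc)
}

#' Uniformity report for one sample
#'
#' Convenience wrapper bundling MAPD, MDAD and Lorenz/Gini for a sample
#' over reference-derived equal-read bins.
#'
#' @param sample_id label for the report.
#' @param sample,reference `coverage_track`s.
#' @param bins equal-read bin boundaries (default: computed from the
#'   reference at 500 kb).
#' @param sex_correction passed to [normalized_log2()].
#' @return a `uniformity_report` list: `sample_id`, `mapd`, `mdad`, `gini`,
#'   `lorenz_curve`, `bin_scheme`.
#' @export
uniformity_report <- function(sample_id, sample, reference, bins = NULL,
                              sex_correction = list(chrX_to_own_median = FALSE,
                                                    chrY_zero = FALSE)) {
  if (is.null(bins)) bins <- equal_read_bins(reference)
  lr <- normalized_log2(sample, reference, bins,
                        sex_correction = sex_correction)
  lz <- lorenz_gini(sample)
  structure(list(sample_id = sample_id, mapd = mapd(lr), mdad = mdad(lr),
                 gini = lz$gini, lorenz_curve = lz$lorenz,
                 bin_scheme = sprintf("equal-read, %d bins", nrow(bins))),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("<uniformity %s: MAPD=%.3f MDAD=%.3f Gini=%.3f (%s)>\n",
              x$sample_id, x$mapd, x$mdad, x$gini, x$bin_scheme))
  invisible(x)
}

#' Welch power spectral density of binned read depth
#'
#' Averaged periodogram over mean-detrended, Hann-windowed segments with
#' 50% overlap. Frequencies are in cycles per bp up to the Nyquist
#' frequency `1 / (2 * bin_bp)`; the one-sided power is normalised so that
#' `sum(power)` equals the track variance (Parseval) up to the discarded DC
#' term.
#'
#' @param track a `coverage_track` of contiguous fixed-width bins.
#' @param segment_bins Welch segment length in bins (default `2^14`;
#'   shorter tracks must pass a smaller value — a track shorter than one
#'   segment is an error).
#' @param overlap fractional segment overlap (default 0.5).
#' @return a `spectral_density` tibble (`frequency`, `power`) with
#'   attributes `bin_bp`, `segment_bins`, `n_segments`, `window`.
#' @export
power_spectral_density <- function(track, segment_bins = 2^14,
                                   overlap = 0.5) {
  widths <- track$end - track$start
  .assert(length(unique(widths)) == 1, "PSD needs fixed-width bins")
  bin_bp <- widths[[1]]
  .assert(all(track$contig == track$contig[[1]]) ||
            dplyr::n_distinct(track$contig) >= 1, "invalid track")
  n <- as.integer(segment_bins)
  .assert(n >= 8, "segment_bins too small")
  step <- max(1L, as.integer(round(n * (1 - overlap))))
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))  # periodic Hann
  wnorm <- sum(w^2)
  half <- n %/% 2

  acc <- numeric(half)
  n_seg <- 0L
  for (x_ct in split(track$depth, track$contig)) {
    len <- length(x_ct)
    if (len < n) next
    starts <- seq(1L, len - n + 1L, by = step)
    for (s0 in starts) {
      xs <- x_ct[s0:(s0 + n - 1L)]
      xs <- xs - mean(xs)
      X <- fft(xs * w)
      p_full <- Mod(X)^2 / (n * wnorm)
      p_one <- p_full[2:(half + 1)]
      scale2 <- rep(2, half)
      if (n %% 2 == 0) scale2[half] <- 1  # Nyquist bin not doubled
      acc <- acc + p_one * scale2
      n_seg <- n_seg + 1L
    }
  }
  .assert(n_seg >= 1, "track shorter than one PSD segment")
  out <- tibble(frequency = (1:half) / (n * bin_bp), power = acc / n_seg)
  structure(out, bin_bp = bin_bp, segment_bins = n, n_segments = n_seg,
            window = "hann", class = c("spectral_density", class(out)))
}

#' Total spectral power in a frequency band
#' @param psd a `spectral_density`.
#' @param fmin,fmax band limits in cycles/bp (half-open `(fmin, fmax]`;
#'   defaults span everything).
#' @return sum of one-sided power over the band.
#' @export
band_power <- function(psd, fmin = 0, fmax = Inf) {
  sum(psd$power[psd$frequency > fmin & psd$frequency <= fmax])
}

#' Randomly subsample a coverage track
#'
#' Binomial thinning of per-bin read counts: each read is kept independently
#' with probability `fraction`. `fraction = 1` returns the track unchanged.
#'
#' @param track a `coverage_track` with (near-)integer read counts.
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed (required unless `fraction = 1`).
#' @return a `coverage_track`.
#' @export
subsample_track <- function(track, fraction, seed = NULL) {
  .assert(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  if (fraction == 1) return(track)
  .assert(!is.null(seed), "a seed is required: subsampling must be reproducible")
  depth <- with_stream(seed, "subsample", {
    rbinom(nrow(track), size = as.integer(round(track$depth)),
           prob = fraction)
  })
  coverage_track(tibble(contig = track$contig, start = track$start,
                        end = track$end, depth = as.numeric(depth)),
                 bin_scheme = attr(track, "bin_scheme") %||% "fixed_width",
                 provenance = sprintf("%s|subsample(%.3f)",
                                      attr(track, "provenance") %||% "?",
                                      fraction))
}

#' Pool coverage tracks
#'
#' Per-bin mean depth across tracks sharing identical bins — the in-silico
#' analogue of pooling cells: stochastic per-cell noise averages out
#' (white power shrinks roughly as 1/K) while systematic amplification
#' structure shared across cells is preserved.
#'
#' @param tracks list of `coverage_track`s with identical bins.
#' @return a `coverage_track` of mean depths.
#' @export
pool_tracks <- function(tracks) {
  .assert(length(tracks) >= 1, "need at least one track")
  base <- tracks[[1]]
  for (t in tracks[-1]) {
    .assert(identical(t$start, base$start) &&
              identical(t$contig, base$contig),
            "tracks must share identical bins")
  }
  depth <- Reduce(`+`, lapply(tracks, function(t) t$depth)) / length(tracks)
  coverage_track(tibble(contig = base$contig, start = base$start,
                        end = base$end, depth = depth),
                 bin_scheme = attr(base, "bin_scheme") %||% "fixed_width",
                 provenance = sprintf("pool(%d)", length(tracks)))
}
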