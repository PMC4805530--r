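#' Per-sample read-count histograms
#'
#' Read-count histograms count every (sample, locus) call once — an
#' insertion seen in three cells contributes three entries — which controls
#' for recurrence across samples. Germline KNR dropouts (a gold locus with
#' no call in a cell) contribute nothing: dropout affects germline and
#' somatic insertions alike, so it is excluded from the signal model.
#'
#' @param calls call tibble (schema of [read_call_table()]).
#' @param population one of `knr_single_cell`, `knr_bulk`,
#'   `somatic_single_cell`, `somatic_bulk`.
#' @param reference_set a [gold-standard] set; required for the `knr_*`
#'   populations (calls are restricted to its loci), must be omitted for
#'   `somatic_*` populations.
#' @return a `readcount_histogram`: list with `counts` (tibble `read_count`,
#'   `n`), `population`, `n_total`.
#' @export
per_sample_histogram <- function(calls, population = c("knr_single_cell",
                                                       "knr_bulk",
                                                       "somatic_single_cell",
                                                       "somatic_bulk"),
                                 reference_set = NULL) {
  population <- match.arg(population)
  material <- if (grepl("single_cell$", population)) "single_cell" else "bulk"
  is_knr <- grepl("^knr", population)
  if (is_knr) {
    .assert(inherits(reference_set, "gold_standard_set"),
            "population %s requires a gold-standard reference_set", population)
  } else {
    .assert(is.null(reference_set),
            "somatic populations take no gold-standard reference_set")
  }
  sel <- calls[calls$material == material &
                 calls$candidate_class ==
                 (if (is_knr) "knr_call" else "somatic_candidate"), ,
               drop = FALSE]
  if (is_knr) {
    gold_keys <- paste(reference_set$loci$individual_id,
                       .locus_key(reference_set$loci$contig,
                                  reference_set$loci$start,
                                  reference_set$loci$end))
    keys <- paste(sel$individual_id,
                  .locus_key(sel$contig, sel$start, sel$end))
    sel <- sel[keys %in% gold_keys, , drop = FALSE]
  }
  readcount_histogram(sel$read_count, population)
}

#' Build a read-count histogram from a vector of counts
#' @param read_counts integer vector of per-call read counts (all >= 1).
#' @param population population label (see [per_sample_histogram()]).
#' @return a `readcount_histogram`.
#' @export
readcount_histogram <- function(read_counts, population) {
  .assert(all(read_counts >= 1), "read counts must be >= 1")
  tab <- as_tibble(table(read_count = read_counts)) |>
    mutate(read_count = as.integer(.data$read_count),
           n = as.integer(.data$n)) |>
    arrange(.data$read_count)
  structure(list(counts = tab, population = population,
                 n_total = sum(tab$n)),
            class = "readcount_histogram")
}

#' @export
print.readcount_histogram <- function(x, ...) {
  cat(sprintf("<readcount_histogram %s: %d calls, counts %d..%d>\n",
              x$population, x$n_total, min(x$counts$read_count),
              max(x$counts$read_count)))
  invisible(x)
}

.expand_histogram <- function(hist) {
  rep(hist$counts$read_count, hist$counts$n)
}

# observed-data log likelihood of the two-component mixture on collapsed
# (k, n_k) data
.mix_loglik <- function(k, nk, w_high, p_low, mu, size) {
  f <- (1 - w_high) * dztgeom(k, p_low) + w_high * dztnbinom(k, mu, size)
  sum(nk * log(pmax(f, 1e-300)))
}

#' Fit a two-component read-count mixture by EM
#'
#' Models zero-truncated per-call read counts as a mixture of a low mode
#' (zero-truncated geometric — amplification dropout pushes true insertions
#' toward single-read detection) and a high mode (zero-truncated negative
#' binomial — well-amplified loci). Initialisation is deterministic: calls
#' are moment-split at read count 3. EM stops when the relative log
#' likelihood change falls below `tol` or after `max_iter` iterations; the
#' log likelihood is non-decreasing across iterations (the numeric
#' M-step for the high component only ever accepts improvements).
#'
#' Degenerate data (no mass on one side of the split, or a single distinct
#' count) fall back to a flagged single-component fit with `weight_high`
#' pinned to 0 or 1.
#'
#' @param hist a `readcount_histogram` (or bare integer vector of counts)
#'   with at least 50 calls.
#' @param fixed_high optional list `list(mu=, size=)`: freeze the high
#'   component (used when scoring somatic candidates against the KNR-derived
#'   high mode) and estimate only the weight and the low component.
#' @param max_iter,tol EM controls.
#' @return a `mixture_fit`: list with `weight_low`, `weight_high`,
#'   `low_params` (`prob`), `high_params` (`mu`, `size`), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `single_component`.
#' @export
fit_two_component_mixture <- function(hist, fixed_high = NULL,
                                      max_iter = 500, tol = 1e-8) {
  if (!inherits(hist, "readcount_histogram")) {
    hist <- readcount_histogram(hist, population = "knr_single_cell")
  }
  .assert(hist$n_total >= 50, "need at least 50 calls to fit the mixture")
  k <- hist$counts$read_count
  nk <- hist$counts$n
  N <- sum(nk)

  fit <- function(w_high, p_low, mu, size, single = FALSE, conv = TRUE,
                  trace = numeric(0), iters = 0L) {
    structure(list(weight_low = 1 - w_high, weight_high = w_high,
                   low_params = list(prob = p_low),
                   high_params = list(mu = mu, size = size),
                   loglik = .mix_loglik(k, nk, w_high, p_low, mu, size),
                   loglik_trace = trace, n_iter = iters,
                   converged = conv, single_component = single),
              class = "mixture_fit")
  }

  # deterministic moment split at read count 3
  low_mask <- k <= 3
  n_low <- sum(nk[low_mask])
  n_high <- N - n_low
  mean_or <- function(x, w, d) if (sum(w) > 0) sum(w * x) / sum(w) else d

  if (length(k) == 1 || n_high == 0) {
    # all-low degenerate data: single ZT-geometric
    p_low <- min(1, 1 / mean_or(k, nk, 1))
    return(fit(0, p_low, mu = max(mean(k), 2), size = 1, single = TRUE))
  }
  if (n_low == 0 && !is.null(fixed_high)) {
    return(fit(1, 0.5, fixed_high$mu, fixed_high$size, single = TRUE))
  }

  p_low <- min(1, 1 / mean_or(k[low_mask], nk[low_mask], 1))
  if (is.null(fixed_high)) {
    mu <- mean_or(k[!low_mask], nk[!low_mask], 10)
    size <- 2
  } else {
    mu <- fixed_high$mu
    size <- fixed_high$size
  }
  w_high <- n_high / N

  ll_old <- .mix_loglik(k, nk, w_high, p_low, mu, size)
  trace <- ll_old
  conv <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step
    fh <- dztnbinom(k, mu, size)
    fl <- dztgeom(k, p_low)
    denom <- pmax((1 - w_high) * fl + w_high * fh, 1e-300)
    rh <- w_high * fh / denom
    # M-step
    w_high_new <- sum(nk * rh) / N
    wl <- nk * (1 - rh)
    p_low_new <- if (sum(wl) > 0) min(1, sum(wl) / sum(wl * k)) else p_low
    mu_new <- mu
    size_new <- size
    if (is.null(fixed_high) && sum(nk * rh) > 0) {
      wh <- nk * rh
      q <- function(par) {
        -sum(wh * dztnbinom(k, mu = exp(par[1]), size = exp(par[2]),
                            log = TRUE))
      }
      start <- c(log(mu), log(size))
      opt <- tryCatch(optim(start, q, method = "Nelder-Mead",
                            control = list(maxit = 200)),
                      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value <= q(start)) {
        mu_new <- exp(opt$par[1])
        size_new <- min(exp(opt$par[2]), 1e6)
      }
    }
    ll_new <- .mix_loglik(k, nk, w_high_new, p_low_new, mu_new, size_new)
    if (!is.finite(ll_new) || ll_new < ll_old) break  # never step downhill
    w_high <- w_high_new
    p_low <- p_low_new
    mu <- mu_new
    size <- size_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + tol)) {
      conv <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  # identifiability guard: when both components converge onto the same
  # region (the NB can mimic a geometric), a two-component reading of the
  # data is meaningless — collapse to the better single-component fit
  if (is.null(fixed_high)) {
    mean_low <- 1 / p_low
    mean_high <- ztnbinom_mean(mu, size)
    if (mean_high <= 1.2 * mean_low) {
      p_all <- min(1, N / sum(nk * k))
      ll_low <- .mix_loglik(k, nk, 0, p_all, mu, size)
      q_all <- function(par) {
        -sum(nk * dztnbinom(k, mu = exp(par[1]), size = exp(par[2]),
                            log = TRUE))
      }
      opt <- tryCatch(optim(c(log(max(mean(rep(k, nk)), 1.1)), 0), q_all,
                            method = "Nelder-Mead"),
                      error = function(e) NULL)
      # the NB nests the geometric, so demand a BIC-sized margin for its
      # extra parameter before preferring the overdispersed reading
      if (!is.null(opt) && is.finite(opt$value) &&
          -opt$value > ll_low + log(N) / 2) {
        return(fit(1, p_all, exp(opt$par[1]), min(exp(opt$par[2]), 1e6),
                   single = TRUE, trace = trace, iters = it))
      }
      return(fit(0, p_all, mu, size, single = TRUE, trace = trace,
                 iters = it))
    }
  }
  fit(w_high, p_low, mu, size, conv = conv, trace = trace, iters = it)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit: w_low=%.3f w_high=%.3f | low geom ",
                     "p=%.3f | high NB mu=%.1f size=%.2f | loglik=%.2f ",
                     "(%d it, converged=%s)>\n"),
              x$weight_low, x$weight_high, x$low_params$prob,
              x$high_params$mu, x$high_params$size, x$loglik, x$n_iter,
              x$converged))
  invisible(x)
}

#' Estimate the true-somatic fraction among candidate calls
#'
#' Fits the two-component mixture to somatic-candidate read counts with the
#' high component frozen to the gold-standard KNR fit's high mode, so the
#' estimated high-mode weight is the fraction of candidates drawn from the
#' true-insertion signal distribution. A bootstrap over calls supplies a
#' confidence interval.
#'
#' @param somatic_hist `readcount_histogram` of somatic candidates.
#' @param gold_fit converged `mixture_fit` of gold-standard KNR calls.
#' @param n_boot bootstrap replicates (0 skips the CI).
#' @param conf CI level.
#' @param seed seed for the bootstrap resampling.
#' @return list with `fraction` (estimated true fraction), `ci` (length-2 or
#'   `NULL`), and `fit` (the constrained `mixture_fit`).
#' @export
estimate_true_fraction <- function(somatic_hist, gold_fit, n_boot = 200,
                                   conf = 0.95, seed = 1) {
  .assert(inherits(gold_fit, "mixture_fit") && isTRUE(gold_fit$converged),
          "gold_fit must be a converged mixture_fit")
  fixed <- gold_fit$high_params
  f0 <- fit_two_component_mixture(somatic_hist, fixed_high = fixed)
  ci <- NULL
  if (n_boot > 0) {
    counts <- .expand_histogram(somatic_hist)
    boots <- with_stream(seed, "true_fraction_boot", {
      vapply(seq_len(n_boot), function(i) {
        res <- sample(counts, length(counts), replace = TRUE)
        fit_two_component_mixture(
          readcount_histogram(res, somatic_hist$population),
          fixed_high = fixed)$weight_high
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  }
  list(fraction = f0$weight_high, ci = ci, fit = f0)
}

#' Sensitivity / specificity table over read-count thresholds
#'
#' For every inclusive threshold `min_reads` in `1..max_min_reads` computes:
#' `call_sensitivity`, the fraction of gold-standard KNR calls (across all
#' single cells; dropouts excluded by construction) retained;
#' `mean_per_cell_sensitivity`, the mean over cells of the fraction of the
#' individual's gold loci detected in that cell at or above the threshold;
#' and `fp_retained`, the fraction of somatic-candidate calls retained
#' (nearly all being false positives, this tracks specificity).
#'
#' A threshold printed as "> 2 reads" corresponds to `min_reads = 3`.
#'
#' @param calls call tibble (single-cell rows are used).
#' @param gold a `gold_standard_set` covering the cohort's individuals.
#' @param max_min_reads largest threshold scanned.
#' @return a `threshold_table` tibble with columns `min_reads`,
#'   `call_sensitivity`, `mean_per_cell_sensitivity`, `fp_retained`.
#' @export
threshold_table <- function(calls, gold, max_min_reads = 6) {
  .assert(inherits(gold, "gold_standard_set"), "gold must be a gold_standard_set")
  sc <- calls[calls$material == "single_cell", , drop = FALSE]
  gold_loci <- gold$loci |>
    mutate(key = paste(.data$individual_id,
                       .locus_key(.data$contig, .data$start, .data$end)))
  gold_n <- gold_loci |> count(.data$individual_id, name = "n_gold")

  knr <- sc[sc$candidate_class == "knr_call", , drop = FALSE]
  knr_keys <- paste(knr$individual_id,
                    .locus_key(knr$contig, knr$start, knr$end))
  gold_calls <- knr[knr_keys %in% gold_loci$key, , drop = FALSE]
  som_calls <- sc[sc$candidate_class == "somatic_candidate", , drop = FALSE]
  .assert(nrow(gold_calls) > 0, "no gold-standard KNR calls in scope")

  cells <- unique(sc[, c("sample_id", "individual_id")])
  covered <- cells$individual_id %in%
    gold_n$individual_id[gold_n$n_gold > 0]
  if (any(!covered)) {
    warning(sprintf("%d cell(s) skipped: individual has an empty gold set",
                    sum(!covered)))
    cells <- cells[covered, , drop = FALSE]
  }
  cells <- dplyr::left_join(cells, gold_n, by = "individual_id")

  per_cell_detect <- gold_calls |>
    group_by(.data$sample_id) |>
    summarise(rc = list(.data$read_count), .groups = "drop")
  cells <- dplyr::left_join(cells, per_cell_detect, by = "sample_id")

  rows <- lapply(seq_len(max_min_reads), function(m) {
    per_cell <- vapply(seq_len(nrow(cells)), function(i) {
      rc <- cells$rc[[i]]
      n_det <- if (is.null(rc)) 0L else sum(rc >= m)
      n_det / cells$n_gold[[i]]
    }, numeric(1))
    tibble(
      min_reads = m,
      call_sensitivity = mean(gold_calls$read_count >= m),
      mean_per_cell_sensitivity = mean(per_cell),
      fp_retained = if (nrow(som_calls) > 0) {
        mean(som_calls$read_count >= m)
      } else 0
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("threshold_table", class(out))
  out
}

#' Choose a read-count threshold from a threshold table
#'
#' Implements the diminishing-returns argument: raise the threshold while
#' each single-step increase still buys a large reduction in retained false
#' positives per unit of sensitivity lost. The chosen threshold is the
#' smallest `min_reads` whose arriving step (from `min_reads - 1`) delivers
#' less than `knee_ratio` percentage points of false-positive reduction per
#' percentage point of call-sensitivity loss; if every step stays above the
#' knee the table maximum is returned, and if no false positives are ever
#' retained the smallest threshold is returned (raising it buys nothing).
#' Ties break toward the smaller threshold by construction.
#'
#' @param table a [threshold_table()].
#' @param knee_ratio knee in (pp fp reduction) / (pp sensitivity loss);
#'   default 0.5.
#' @return the selected `min_reads` (integer). `min_reads = 3` corresponds
#'   to a "> 2 reads" rule.
#' @export
choose_threshold <- function(table, knee_ratio = 0.5) {
  .assert(nrow(table) > 0, "threshold table is empty")
  .assert(is.numeric(knee_ratio) && length(knee_ratio) == 1 &&
            knee_ratio > 0, "knee_ratio must be a positive number")
  tab <- table[order(table$min_reads), , drop = FALSE]
  if (all(tab$fp_retained == 0)) return(tab$min_reads[[1]])
  if (nrow(tab) == 1) return(tab$min_reads[[1]])
  d_fp <- -diff(tab$fp_retained)
  d_sens <- -diff(tab$call_sensitivity)
  ratio <- ifelse(d_sens <= 0, ifelse(d_fp > 0, Inf, 0), d_fp / d_sens)
  below <- which(ratio < knee_ratio)
  if (length(below) == 0) return(tab$min_reads[[nrow(tab)]])
  tab$min_reads[[below[[1]] + 1]]
}
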