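#' Simulate annotated candidate insertion contigs
#'
#' Generates per-candidate contig annotations of the kind produced by
#' sequence analysis of insertion junction contigs (source element subfamily
#' and its retrotransposition-competence, poly-A tail, flank alignments
#' implying a target-site duplication, 3'-transduction tracing), together
#' with ground-truth class labels, for exercising the chimera rule engine.
#'
#' Classes:
#' * `true_insertion`: active-subfamily source, poly-A tail, TSD <= 20 bp,
#'   single source element, transduction traceable;
#' * `inactive_source_chimera`: junction traces immediately downstream of a
#'   retrotransposition-incompetent (older-subfamily) element;
#' * `no_polyA_chimera`: 3' junction without any poly-A tail;
#' * `split_source_chimera`: 5' and 3' junctions trace to two distinct
#'   source elements misinterpreted as two ends of one insertion;
#' * `large_TSD_artifact`: two independent junctions aligning to the same
#'   locus so the implied "TSD" is > 50 bp; otherwise clean.
#'
#' @param n number of contigs.
#' @param class_mix named probabilities over the five classes; must sum to 1.
#' @param seed integer seed (required).
#' @return list with `contigs` (one row per contig; columns `contig_id`,
#'   `junction_side`, `polyA_length`, `tsd_bp`, `source_subfamily`,
#'   `source_active`, `source_5p_id`, `source_3p_id`,
#'   `junction_in_l1_body`, `junction_in_polyA_tract`,
#'   `transduction_traced`) and `truth` (`contig_id`, `class`).
#' @export
simulate_candidate_contigs <- function(n,
                                       class_mix = c(
                                         true_insertion = 0.4,
                                         inactive_source_chimera = 0.2,
                                         no_polyA_chimera = 0.15,
                                         split_source_chimera = 0.15,
                                         large_TSD_artifact = 0.1),
                                       seed = NULL) {
  .assert(!is.null(seed), "a seed is required: simulations must be reproducible")
  known <- c("true_insertion", "inactive_source_chimera", "no_polyA_chimera",
             "split_source_chimera", "large_TSD_artifact")
  .assert(all(names(class_mix) %in% known), "unknown contig class in class_mix")
  .assert(abs(sum(class_mix) - 1) < 1e-9, "class_mix must sum to 1")
  .assert(n >= 1, "n must be >= 1")

  active_subs <- c("L1Hs")
  inactive_subs <- paste0("L1PA", 2:8)

  with_stream(seed, "contigs", {
    cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    id <- sprintf("contig%04d", seq_len(n))
    src <- function(k) sprintf("srcL1_%d", sample.int(5000, k))

    rows <- lapply(seq_len(n), function(i) {
      cl <- cls[[i]]
      base <- tibble(
        contig_id = id[[i]],
        junction_side = "both",
        polyA_length = sample(15:40, 1),
        tsd_bp = sample(5:20, 1),
        source_subfamily = active_subs,
        source_active = TRUE,
        source_5p_id = NA_character_,
        source_3p_id = NA_character_,
        junction_in_l1_body = FALSE,
        junction_in_polyA_tract = FALSE,
        transduction_traced = runif(1) < 0.5
      )
      s <- src(2)
      switch(
        cl,
        true_insertion = {
          base$source_5p_id <- s[[1]]
          base$source_3p_id <- s[[1]]
          base
        },
        inactive_source_chimera = {
          base$source_subfamily <- sample(inactive_subs, 1)
          base$source_active <- FALSE
          base$junction_side <- sample(c("five_prime", "both"), 1)
          base$source_5p_id <- s[[1]]
          base$source_3p_id <- if (base$junction_side == "both") s[[1]] else
            NA_character_
          base
        },
        no_polyA_chimera = {
          base$polyA_length <- 0L
          base$junction_side <- sample(c("three_prime", "both"), 1)
          base$source_5p_id <- if (base$junction_side == "both") s[[1]] else
            NA_character_
          base$source_3p_id <- s[[1]]
          base
        },
        split_source_chimera = {
          base$source_5p_id <- s[[1]]
          base$source_3p_id <- s[[2]]
          base
        },
        large_TSD_artifact = {
          base$tsd_bp <- sample(51:200, 1)
          base$source_5p_id <- s[[1]]
          base$source_3p_id <- s[[1]]
          base
        }
      )
    })
    contigs <- bind_rows(rows)
    list(contigs = contigs, truth = tibble(contig_id = id, class = cls))
  })
}
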