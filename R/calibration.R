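# Replicate-level simulation studies of the association test: type-I
# error calibration under no enrichment and power under a planted
# enrichment, at the package's desk-scale study geometry.

#' Replicate association tests on fresh synthetic datasets
#'
#' For each replicate, generates a synthetic genome, annotation, and gap
#' track from a derived seed, scans for motif hits, and runs the
#' shuffle-based lncRNA association test at the spec's enrichment-window
#' cutoff. With `rho = 0` the resulting p-values probe type-I
#' calibration; with `rho > 0` the rejection fraction measures power.
#'
#' @param n_replicates Number of independent synthetic datasets.
#' @param rho ncRNA enrichment probability passed to [synthetic_spec()].
#' @param n_shuffles Shuffles per association test.
#' @param seed Root seed; replicate seeds are derived from it.
#' @param class_label Gene class tested (default `"lncRNA"`).
#' @param ... Further overrides passed to [synthetic_spec()].
#' @return `data.frame`, one row per replicate: `replicate`, `observed`,
#'   `expected`, `n_total`, `chi2`, `p_value`, `flagged`.
#' @export
replicate_association_pvalues <- function(n_replicates, rho,
                                          n_shuffles = 200L, seed = 1L,
                                          class_label = "lncRNA", ...) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    rseed <- (seed + 7919L * i) %% 2147483647L
    spec <- synthetic_spec(enrichment_rho = rho, seed = rseed, ...)
    b <- simulate_dataset(spec)
    hits <- scan_genome(b$genome, spec$pattern)
    res <- run_association_suite(
      hits, b$genes, b$chrom_sizes, b$gaps, mode = "genome_wide",
      classes = class_label, cutoff = spec$enrichment_window,
      n_shuffles = n_shuffles, seed = rseed + 1L)
    rows[[i]] <- data.frame(replicate = i, observed = res$observed,
                            expected = res$expected,
                            n_total = res$n_total, chi2 = res$chi2,
                            p_value = res$p_value, flagged = res$flagged,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Empirical rejection fraction of the association test
#'
#' @inheritParams replicate_association_pvalues
#' @param alpha Nominal test level.
#' @return Fraction of replicates with `p < alpha` (flagged/degenerate
#'   replicates count as non-rejections).
#' @export
association_rejection_rate <- function(n_replicates, rho, alpha = 0.05,
                                       n_shuffles = 200L, seed = 1L, ...) {
  pv <- replicate_association_pvalues(n_replicates, rho,
                                      n_shuffles = n_shuffles,
                                      seed = seed, ...)
  mean(!is.na(pv$p_value) & pv$p_value < alpha)
}
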