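# Permutation catalogues, cross-species motif-set comparison, position
# frequency matrices, information content, and IUPAC consensus calls.

#' Catalogue motif permutations from a hit set
#'
#' Groups hits by their matched concrete sequence ("permutation") and
#' tabulates frequencies, exposing the top-k table sorted by count
#' (ties by sequence).
#'
#' @param hits Hit `data.frame` from [scan_genome()]; all `matched_seq`
#'   must share one length.
#' @return Object of class `perm_catalog`: list with `counts` (named
#'   integer vector, permutation -> count, sorted by count descending
#'   then sequence), `loci` (list of hit data.frames per permutation),
#'   `total_loci`, `total_permutations`.
#' @export
catalog_permutations <- function(hits) {
  if (nrow(hits) && length(unique(nchar(hits$matched_seq))) > 1L)
    stop("hits mix matched_seq lengths")
  counts <- table(hits$matched_seq)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (length(counts)) counts <- counts[order(-counts, names(counts))]
  loci <- if (nrow(hits)) split(hits, hits$matched_seq) else list()
  structure(list(counts = counts, loci = loci,
                 total_loci = nrow(hits),
                 total_permutations = length(counts)),
            class = "perm_catalog")
}

#' @export
print.perm_catalog <- function(x, top = 10L, ...) {
  cat(sprintf("Permutation catalog: %d permutations over %d loci\n",
              x$total_permutations, x$total_loci))
  if (x$total_permutations) {
    cat("Most frequent:\n")
    print(utils::head(x$counts, top))
  }
  invisible(x)
}

#' Three-way exclusive region counts (Venn) for permutation sets
#'
#' @param a,b,c Character vectors of concrete motif sequences (one set
#'   per species).
#' @return Named integer vector with the 7 exclusive Venn regions:
#'   `a_only`, `b_only`, `c_only`, `ab_only`, `ac_only`, `bc_only`,
#'   `abc`.
#' @export
compare_permutation_sets <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  c(a_only  = sum(ina & !inb & !inc),
    b_only  = sum(!ina & inb & !inc),
    c_only  = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc     = sum(ina & inb & inc))
}

#' Position frequency matrix from aligned motif sequences
#'
#' One observation per sequence: to weight by genomic locus pass every
#' hit's matched_seq; to weight by distinct permutation pass
#' `unique(...)` first.
#'
#' @param sequences Equal-length DNA strings over ACGT.
#' @return Integer matrix, positions in rows and bases A, C, G, T in
#'   columns, with attribute `n_sequences`; every row sums to the number
#'   of sequences.
#' @export
build_pfm <- function(sequences) {
  if (!length(sequences)) stop("no sequences supplied")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  if (!all(mat %in% c("A", "C", "G", "T")))
    stop("sequences must contain only A, C, G, T")
  pfm <- t(apply(mat, 2, function(col)
    table(factor(col, levels = c("A", "C", "G", "T")))))
  pfm <- matrix(as.integer(pfm), nrow = L, ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  attr(pfm, "n_sequences") <- length(sequences)
  pfm
}

#' Per-position information content of a PFM, in bits
#'
#' IC(pos) = 2 - H(pos), with H the Shannon entropy (base 2) of the
#' position's empirical base frequencies. No small-sample correction is
#' applied, so values are deterministic functions of the frequencies
#' (this deliberately diverges from WebLogo's corrected letter heights).
#'
#' @param pfm Matrix from [build_pfm()].
#' @return Numeric vector, one value in [0, 2] per position.
#' @export
information_content <- function(pfm) {
  n <- rowSums(pfm)
  if (any(n == 0)) stop("PFM has empty positions")
  f <- pfm / n
  h <- apply(f, 1, function(p) { p <- p[p > 0]; -sum(p * log2(p)) })
  unname(2 - h)
}

#' IUPAC consensus string from a PFM
#'
#' Per position, takes the set of bases whose frequency is at least
#' `tau` and reports the minimal IUPAC code covering it; positions where
#' no base reaches `tau` are written N.
#'
#' @param pfm Matrix from [build_pfm()].
#' @param tau Frequency threshold in (0, 1]; default 0.25.
#' @return IUPAC consensus string, one code per PFM position.
#' @export
consensus_from_pfm <- function(pfm, tau = 0.25) {
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  f <- pfm / rowSums(pfm)
  codes <- apply(f, 1, function(p) {
    bases <- colnames(pfm)[p >= tau]
    if (!length(bases)) return("N")
    .SET_TO_CODE[[paste(sort(bases), collapse = "")]]
  })
  paste(codes, collapse = "")
}

#' Chi-square comparison of two motif sets at one position
#'
#' Pearson chi-square (no continuity correction) on the 2 x k
#' contingency table of base counts at the given position, where k is
#' the number of base categories with a nonzero column total across the
#' two sets; df = k - 1.
#'
#' @param pfm_a,pfm_b PFMs from [build_pfm()] over the same positions.
#' @param position 1-based position index.
#' @return List: `statistic`, `df`, `p_value`, `table` (the 2 x k
#'   table), `flagged` (`TRUE` when fewer than 2 nonzero base categories
#'   make the test undefined; statistic and p are then `NA`).
#' @export
position_chisq <- function(pfm_a, pfm_b, position) {
  tab <- rbind(a = pfm_a[position, ], b = pfm_b[position, ])
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0))
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, table = tab, flagged = TRUE))
  if (all(tab["a", ] / sum(tab["a", ]) == tab["b", ] / sum(tab["b", ]))) {
    # identical composition: statistic exactly 0, avoid chisq.test noise
    return(list(statistic = 0, df = ncol(tab) - 1L, p_value = 1,
                table = tab, flagged = FALSE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab, flagged = FALSE)
}
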