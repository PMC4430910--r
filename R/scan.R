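# Exact degenerate-motif scanning over both strands.
#
# The scanner encodes sequence and pattern as 4-bit base masks and slides
# the pattern with vectorised bitwise AND; it is exactly equivalent to a
# naive character-by-character sliding-window matcher (asserted in the
# test suite against an independent oracle).

# 0-based start positions where the mask vector matches; pattern
# positions are applied most-selective first so the candidate set
# shrinks geometrically
.match_starts <- function(bits, masks) {
  n <- length(bits)
  L <- length(masks)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  ord <- order(vapply(masks, function(m)
    sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), integer(1)))
  j1 <- ord[1]
  cand <- which(bitwAnd(bits[j1:(j1 + nw - 1L)], masks[j1]) > 0L)
  for (j in ord[-1]) {
    if (!length(cand)) return(integer(0))
    cand <- cand[bitwAnd(bits[cand + (j - 1L)], masks[j]) > 0L]
  }
  sort(cand) - 1L
}

.empty_hits <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), matched_seq = character(0),
             stringsAsFactors = FALSE)
}

.order_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$start, match(hits$strand, c("+", "-")))
  out <- hits[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan one sequence for a degenerate motif on both strands
#'
#' Reports every window matching the IUPAC pattern on the forward strand
#' (strand `+`) and every window whose reverse complement matches
#' (strand `-`). Matching is case-insensitive; ambiguous genome bases
#' (N etc.) never match. Overlapping hits are all reported. If one
#' interval matches in both orientations (possible through N positions)
#' a single `+` record is emitted and a note is logged, so each genomic
#' locus is counted once.
#'
#' @param seq DNA sequence as a single string (may contain non-ACGT).
#' @param pattern IUPAC pattern, default the 17-bp NRSE consensus.
#' @param chrom Chromosome name recorded in the output.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `matched_seq` (the concrete 17-mer in pattern
#'   orientation; for `-` hits, the reverse complement of the forward
#'   genomic slice). Sorted by (start, strand). The `matched_seq` doubles
#'   as the permutation id.
#' @export
scan_sequence <- function(seq, pattern = NRSE_PATTERN, chrom = "chr") {
  chars <- .check_iupac(pattern)
  masks <- unname(.IUPAC_MASKS[chars])
  L <- length(masks)
  if (!is.character(seq) || length(seq) != 1L)
    stop("seq must be a single string")
  n <- nchar(seq)
  if (n < L) return(.empty_hits())

  bits <- .encode_bases(seq)
  fwd <- .match_starts(bits, masks)

  # a window is a minus-strand hit iff its forward slice satisfies the
  # reverse-complemented pattern; no reverse-complement sequence needed
  rc_masks <- rev(.comp_mask(masks))
  rev_start <- .match_starts(bits, rc_masks)

  dual <- intersect(fwd, rev_start)
  if (length(dual)) {
    message(sprintf(
      "%d interval(s) on %s match in both orientations; kept once as '+'",
      length(dual), chrom))
    rev_start <- setdiff(rev_start, dual)
  }

  fwd_df <- if (length(fwd)) {
    data.frame(chrom = chrom, start = fwd, end = fwd + L, strand = "+",
               matched_seq = toupper(substring(seq, fwd + 1L, fwd + L)),
               stringsAsFactors = FALSE)
  } else .empty_hits()
  rev_df <- if (length(rev_start)) {
    data.frame(chrom = chrom, start = rev_start, end = rev_start + L,
               strand = "-",
               matched_seq = revcomp(toupper(
                 substring(seq, rev_start + 1L, rev_start + L))),
               stringsAsFactors = FALSE)
  } else .empty_hits()
  hits <- rbind(fwd_df, rev_df)
  hits <- unique(hits)
  rownames(hits) <- NULL
  .order_hits(hits)
}

#' Scan a multi-chromosome genome for a degenerate motif
#'
#' @param genome Path to a FASTA file (wrapped or unwrapped) or a
#'   [Biostrings::DNAStringSet]. Record names are truncated at the first
#'   whitespace; duplicates are rejected.
#' @param pattern IUPAC pattern string.
#' @return Hit `data.frame` as in [scan_sequence()], concatenated in the
#'   genome's chromosome order, each chromosome sorted by coordinate.
#' @export
scan_genome <- function(genome, pattern = NRSE_PATTERN) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a FASTA path or a DNAStringSet")
  nms <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(nms))
    stop(sprintf("duplicate chromosome name: %s",
                 nms[duplicated(nms)][1]))
  if (!length(genome)) return(.empty_hits())
  out <- lapply(seq_along(genome), function(i) {
    scan_sequence(as.character(genome[[i]]), pattern, chrom = nms[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find partial (half-site) and bipartite motif occurrences
#'
#' The NRSE consensus splits into a conserved 5' half (positions 1-9), a
#' 2-nt linker, and a conserved 3' half (positions 12-17). Half-site hits
#' match one half alone; bipartite hits are a 5' half and a 3' half on
#' the same strand separated by a linker of more than 2 nt.
#'
#' @param seq DNA sequence string.
#' @param pattern Full IUPAC pattern (default NRSE consensus).
#' @param kinds Subset of `c("five_prime_half", "three_prime_half",
#'   "bipartite")`; must be non-empty.
#' @param max_linker Maximum bipartite linker length in nt (>= 3 when
#'   bipartite hits are requested).
#' @param chrom Chromosome name for the output.
#' @param linker_positions 1-based positions of the linker within
#'   `pattern` (default `c(10, 11)`).
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`, `kind`,
#'   `linker_length` (`NA` for half-site hits), `matched_seq`.
#' @export
find_partial_motifs <- function(seq, pattern = NRSE_PATTERN,
                                kinds = c("five_prime_half",
                                          "three_prime_half", "bipartite"),
                                max_linker = 10L, chrom = "chr",
                                linker_positions = NRSE_LINKER) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (!length(kinds)) stop("kinds must be non-empty")
  chars <- .check_iupac(pattern)
  L <- length(chars)
  lp <- as.integer(linker_positions)
  if (lp[1] < 2L || lp[2] >= L || lp[2] != lp[1] + 1L)
    stop("linker_positions must be an adjacent pair inside the pattern")
  if ("bipartite" %in% kinds && max_linker < 3L)
    stop("max_linker must be >= 3 when bipartite hits are requested")

  half5 <- unname(.IUPAC_MASKS[chars[seq_len(lp[1] - 1L)]])
  half3 <- unname(.IUPAC_MASKS[chars[(lp[2] + 1L):L]])
  n5 <- length(half5)
  n3 <- length(half3)
  n <- nchar(seq)

  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kind = character(0), linker_length = integer(0),
                      matched_seq = character(0), stringsAsFactors = FALSE)
  if (n < min(n5, n3)) return(empty)

  one_orientation <- function(s, strand) {
    bits <- .encode_bases(s)
    s5 <- .match_starts(bits, half5)
    s3 <- .match_starts(bits, half3)
    rows <- list()
    flip <- function(st, en) {
      if (strand == "+") cbind(st, en) else cbind(n - en, n - st)
    }
    if ("five_prime_half" %in% kinds && length(s5)) {
      iv <- flip(s5, s5 + n5)
      rows$h5 <- data.frame(chrom = chrom, start = iv[, 1], end = iv[, 2],
                            strand = strand, kind = "five_prime_half",
                            linker_length = NA_integer_,
                            matched_seq = substring(s, s5 + 1L, s5 + n5),
                            stringsAsFactors = FALSE)
    }
    if ("three_prime_half" %in% kinds && length(s3)) {
      iv <- flip(s3, s3 + n3)
      rows$h3 <- data.frame(chrom = chrom, start = iv[, 1], end = iv[, 2],
                            strand = strand, kind = "three_prime_half",
                            linker_length = NA_integer_,
                            matched_seq = substring(s, s3 + 1L, s3 + n3),
                            stringsAsFactors = FALSE)
    }
    if ("bipartite" %in% kinds && length(s5) && length(s3)) {
      pairs <- expand.grid(a = s5, b = s3)
      pairs$linker <- pairs$b - (pairs$a + n5)
      pairs <- pairs[pairs$linker >= 3L & pairs$linker <= max_linker, ,
                     drop = FALSE]
      if (nrow(pairs)) {
        iv <- flip(pairs$a, pairs$b + n3)
        rows$bp <- data.frame(
          chrom = chrom, start = iv[, 1], end = iv[, 2], strand = strand,
          kind = "bipartite", linker_length = as.integer(pairs$linker),
          matched_seq = substring(s, pairs$a + 1L, pairs$b + n3),
          stringsAsFactors = FALSE)
      }
    }
    rows
  }

  useq <- toupper(seq)
  parts <- c(one_orientation(useq, "+"),
             one_orientation(revcomp(useq), "-"))
  if (!length(parts)) return(empty)
  out <- do.call(rbind, unname(parts))
  out <- out[order(out$start, out$kind, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
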