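# IUPAC nucleotide ambiguity codes as base sets and 4-bit masks
# (A=1, C=2, G=4, T=8). Non-ACGT genome bases encode to 0 and therefore
# match no pattern code, including N.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_MASKS <- vapply(.IUPAC_SETS, function(s) sum(.BASE_BITS[s]), integer(1))

# minimal IUPAC code for each non-empty subset of {A,C,G,T}, keyed by the
# sorted, concatenated base string ("AG" -> "R", ...)
.SET_TO_CODE <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
                 character(1))
  stats::setNames(names(.IUPAC_SETS), keys)
})

#' Default degenerate NRSE/RE1 consensus pattern
#'
#' The 17-bp degenerate consensus for the neuron-restrictive silencer
#' element: a conserved 5' half (positions 1-9) and 3' half (positions
#' 12-17) separated by a 2-nt poorly conserved linker (positions 10-11).
#' @export
NRSE_PATTERN <- "NTYAGMRCCNNRGMSAG"

#' Positions of the NRSE linker region (1-based)
#' @export
NRSE_LINKER <- c(10L, 11L)

.check_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a single non-empty string")
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(.IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' at position %d", chars[bad[1]],
                 bad[1]))
  chars
}

#' Expand a degenerate IUPAC pattern into all concrete DNA sequences
#'
#' Each IUPAC ambiguity code is replaced by every base in its degeneracy
#' set; the result enumerates the full cross-product. The default NRSE
#' consensus expands to 4096 concrete 17-mers (the per-position degeneracy
#' product 4*1*2*1*1*2*2*1*1*4*4*2*1*2*2*1*1).
#'
#' @param pattern A string over the IUPAC alphabet (ACGTRYSWKMBDHVN).
#' @return Character vector of all concrete sequences matching `pattern`,
#'   in lexicographic order.
#' @examples
#' expand_iupac("RY")   # "AC" "AT" "GC" "GT"
#' length(expand_iupac(NRSE_PATTERN))  # 4096
#' @export
expand_iupac <- function(pattern) {
  chars <- .check_iupac(pattern)
  sets <- .IUPAC_SETS[chars]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Number of concrete sequences a degenerate pattern can produce
#' @param pattern IUPAC pattern string.
#' @return Integer: product of per-position degeneracy set sizes.
#' @export
iupac_cardinality <- function(pattern) {
  chars <- .check_iupac(pattern)
  prod(lengths(.IUPAC_SETS[chars]))
}

#' Test a fixed-length window against a degenerate pattern
#'
#' Position-wise IUPAC match. Ambiguous bases in the *window* (anything
#' other than A, C, G, T) never match, not even pattern code N: assembly
#' N-runs cannot produce motif hits.
#'
#' @param pattern IUPAC pattern string.
#' @param window DNA string of the same length (case-insensitive).
#' @return `TRUE` if every window base lies in the degeneracy set of the
#'   corresponding pattern code.
#' @export
iupac_match <- function(pattern, window) {
  chars <- .check_iupac(pattern)
  if (!is.character(window) || length(window) != 1L)
    stop("window must be a single string")
  if (nchar(window) != length(chars))
    stop(sprintf("window length %d does not match pattern length %d",
                 nchar(window), length(chars)))
  wb <- .encode_bases(window)
  all(bitwAnd(.IUPAC_MASKS[chars], wb) > 0L)
}

# encode a DNA string as per-base bitmasks; non-ACGT -> 0
.ENCODE_TAB <- local({
  tab <- integer(256)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 4L; tab[utf8ToInt("g")] <- 4L
  tab[utf8ToInt("T")] <- 8L; tab[utf8ToInt("t")] <- 8L
  tab
})

.encode_bases <- function(seq) {
  .ENCODE_TAB[utf8ToInt(seq)]
}

# bitmask of the complementary base set (A<->T, C<->G)
.comp_mask <- function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L),
                bitwShiftR(bitwAnd(m, 8L), 3L)),
         bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L),
                bitwShiftR(bitwAnd(m, 4L), 1L)))
}

#' Reverse complement of a DNA/IUPAC string
#'
#' Complements all 15 IUPAC codes (R<->Y, K<->M, B<->V, D<->H; S, W, N
#' self-complementary) and reverses. Case is preserved.
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
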