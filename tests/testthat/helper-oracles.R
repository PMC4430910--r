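# Independent oracles for the scanner and statistics, deliberately
# implemented with different machinery than the package (character sets
# and %in% rather than bitmasks; recursion rather than expand.grid).

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(s) {
  ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
  mapped <- ORACLE_COMP[ch]
  mapped[is.na(mapped)] <- "N"
  paste(mapped, collapse = "")
}

# recursive enumeration of all concrete strings matching a pattern
oracle_expand <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  rec <- function(i) {
    if (i > length(ch)) return("")
    tails <- rec(i + 1)
    unlist(lapply(ORACLE_SETS[[ch[i]]], function(b) paste0(b, tails)))
  }
  sort(rec(1))
}

# naive sliding-window matcher: per pattern position, character-set
# membership over all windows; returns 0-based starts
oracle_match_starts <- function(chars, pat_chars) {
  L <- length(pat_chars)
  n <- length(chars)
  if (n < L) return(integer(0))
  nw <- n - L + 1
  ok <- rep(TRUE, nw)
  for (j in seq_len(L))
    ok <- ok & chars[j:(j + nw - 1)] %in% ORACLE_SETS[[pat_chars[j]]]
  which(ok) - 1L
}

# both-strand naive scan, reproducing the scanner's output contract
# (dual-orientation intervals collapse to one '+' record)
oracle_scan <- function(seq, pattern) {
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(pat)
  n <- length(chars)
  fwd <- oracle_match_starts(chars, pat)
  rcc <- rev(unname(ifelse(is.na(ORACLE_COMP[chars]), "N",
                           ORACLE_COMP[chars])))
  rc <- oracle_match_starts(rcc, pat)
  rev_start <- n - (rc + L)
  rev_start <- setdiff(rev_start, fwd)
  rows <- list()
  if (length(fwd))
    rows$f <- data.frame(
      chrom = "chr", start = fwd, end = fwd + L, strand = "+",
      matched_seq = vapply(fwd, function(s)
        paste(chars[(s + 1):(s + L)], collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  if (length(rev_start))
    rows$r <- data.frame(
      chrom = "chr", start = rev_start, end = rev_start + L, strand = "-",
      matched_seq = vapply(rev_start, function(s) oracle_revcomp(
        paste(chars[(s + 1):(s + L)], collapse = "")), character(1)),
      stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matched_seq = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, unname(rows))
  out <- out[order(out$start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# chi-square df=1 survival function via the normal distribution,
# independent of pchisq
oracle_chisq1_sf <- function(x) 2 * pnorm(sqrt(x), lower.tail = FALSE)

# hand-rolled Pearson statistic on a contingency table
oracle_pearson <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# random DNA with optional lowercase and ambiguous bases
random_dna <- function(n, p_n = 0, lowercase = FALSE) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (p_n > 0) {
    amb <- runif(n) < p_n
    b[amb] <- "N"
  }
  if (lowercase) {
    lc <- runif(n) < 0.5
    b[lc] <- tolower(b[lc])
  }
  paste(b, collapse = "")
}

# plant a concrete motif instance into a sequence string at a 0-based
# offset; strand "-" inserts the reverse complement
plant <- function(seq, motif, at, strand = "+") {
  ins <- if (strand == "-") oracle_revcomp(motif) else motif
  paste0(substr(seq, 1, at), ins, substr(seq, at + nchar(ins) + 1,
                                         nchar(seq)))
}

# brute-force association count: hits within D of any gene by pairwise
# gap distance
oracle_assoc_count <- function(hits, genes, cutoff) {
  if (!nrow(hits) || !nrow(genes)) return(0L)
  sum(vapply(seq_len(nrow(hits)), function(i) {
    any(vapply(seq_len(nrow(genes)), function(j) {
      if (hits$chrom[i] != genes$chrom[j]) return(FALSE)
      gap <- max(max(hits$start[i], genes$start[j]) -
                 min(hits$end[i], genes$end[j]), 0)
      gap < cutoff
    }, logical(1)))
  }, logical(1)))
}
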