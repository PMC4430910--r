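# Gap-aware within-chromosome interval shuffling and chi-square
# association tests against the shuffle-derived expected counts.
#
# Placement is exactly uniform over the feasible start positions: the
# excluded regions (assembly gaps; plus extended protein-coding genes in
# gene-distant mode) are expanded by interval length - 1 on the left,
# complemented within [0, chrom_size - length], and starts are drawn
# from the resulting allowed windows by inverse lookup on cumulative
# widths. Infeasible chromosomes are detected exactly (no retry loop).

# merge 0-based half-open intervals; returns list(start, end) sorted
.merge_intervals <- function(start, end) {
  if (!length(start)) return(list(start = numeric(0), end = numeric(0)))
  r <- IRanges::reduce(.ir0(start, end))
  list(start = IRanges::start(r) - 1, end = IRanges::end(r))
}

# allowed 0-based start windows for an interval of length len on a
# chromosome of size size, given merged excluded intervals
.allowed_starts <- function(size, len, excl_start, excl_end) {
  lo <- 0; hi <- size - len
  if (hi < lo) return(list(start = numeric(0), end = numeric(0)))
  if (!length(excl_start)) return(list(start = lo, end = hi + 1))
  # a start s collides iff [s, s+len) overlaps an excluded interval,
  # i.e. s in [excl_start - len + 1, excl_end)
  fs <- pmax(excl_start - len + 1, lo)
  fe <- pmin(excl_end, hi + 1)
  keep <- fs < fe
  fs <- fs[keep]; fe <- fe[keep]
  if (!length(fs)) return(list(start = lo, end = hi + 1))
  forb <- .merge_intervals(fs, fe)
  gaps <- IRanges::gaps(.ir0(forb$start, forb$end), start = lo + 1,
                        end = hi + 1)
  list(start = IRanges::start(gaps) - 1, end = IRanges::end(gaps))
}

# vectorised "does [s,e) overlap any merged interval" on plain vectors
.overlaps_merged <- function(s, e, mstart, mend) {
  if (!length(mstart)) return(rep(FALSE, length(s)))
  idx <- findInterval(s, mstart)
  left <- idx >= 1 & ifelse(idx >= 1, mend[pmax(idx, 1)] > s, FALSE)
  nxt <- idx + 1
  right <- nxt <= length(mstart) &
    ifelse(nxt <= length(mstart), mstart[pmin(nxt, length(mstart))] < e,
           FALSE)
  left | right
}

#' Precompute a shuffler for repeated interval shuffling
#'
#' Builds, per chromosome and interval length, the feasible start
#' windows given the excluded regions. A hard error names any
#' chromosome where an interval has no feasible placement.
#'
#' @param hits Intervals to shuffle (`chrom`, `start`, `end`).
#' @param chrom_sizes `data.frame` with `chrom`, `size`.
#' @param excluded Optional `data.frame` of excluded intervals
#'   (`chrom`, `start`, `end`), e.g. assembly gaps.
#' @return Object of class `nrse_shuffler` for [shuffle_intervals()].
#' @export
make_shuffler <- function(hits, chrom_sizes, excluded = NULL) {
  sizes <- stats::setNames(chrom_sizes$size, chrom_sizes$chrom)
  miss <- setdiff(unique(hits$chrom), names(sizes))
  if (length(miss))
    stop("chromosome(s) missing from chrom_sizes: ",
         paste(miss, collapse = ", "))
  per_chrom <- list()
  for (ch in unique(hits$chrom)) {
    hi <- which(hits$chrom == ch)
    ex <- if (!is.null(excluded) && nrow(excluded)) {
      ei <- excluded$chrom == ch
      .merge_intervals(excluded$start[ei], excluded$end[ei])
    } else list(start = numeric(0), end = numeric(0))
    lens <- hits$end[hi] - hits$start[hi]
    tabs <- list()
    for (len in unique(lens)) {
      al <- .allowed_starts(sizes[[ch]], len, ex$start, ex$end)
      total <- sum(al$end - al$start)
      if (total <= 0)
        stop(sprintf(
          "no feasible placement for a %d bp interval on chromosome %s",
          len, ch))
      tabs[[as.character(len)]] <- list(
        start = al$start, cum = cumsum(al$end - al$start), total = total)
    }
    per_chrom[[ch]] <- list(idx = hi, lens = lens, tabs = tabs,
                            excl = ex)
  }
  structure(list(hits = hits, per_chrom = per_chrom, sizes = sizes),
            class = "nrse_shuffler")
}

# draw k uniform starts from an allowed-window table
.draw_starts <- function(tab, k) {
  u <- floor(stats::runif(k) * tab$total)  # 0 .. total-1
  w <- findInterval(u, c(0, tab$cum), rightmost.closed = FALSE)
  offset <- u - c(0, tab$cum)[w]
  tab$start[w] + offset
}

#' Shuffle intervals within chromosomes, avoiding excluded regions
#'
#' Each interval is re-placed on its own chromosome, keeping its length,
#' uniformly over all start positions at which it would overlap no
#' excluded region. Shuffled intervals may overlap one another. With a
#' fixed seed the output is reproducible.
#'
#' @param shuffler Either an `nrse_shuffler` from [make_shuffler()] or a
#'   hit `data.frame` (then `chrom_sizes`/`excluded` are required).
#' @param chrom_sizes,excluded Passed to [make_shuffler()] when
#'   `shuffler` is a plain `data.frame`.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so identical seeds give identical output.
#' @return `data.frame` with `chrom`, `start`, `end`, `strand` — one
#'   shuffled interval per input interval, in input order.
#' @export
shuffle_intervals <- function(shuffler, chrom_sizes = NULL, excluded = NULL,
                              seed = NULL) {
  if (is.data.frame(shuffler))
    shuffler <- make_shuffler(shuffler, chrom_sizes, excluded)
  if (!inherits(shuffler, "nrse_shuffler")) stop("not a shuffler")
  if (!is.null(seed)) set.seed(seed)
  hits <- shuffler$hits
  out_start <- numeric(nrow(hits))
  for (pc in shuffler$per_chrom) {
    for (len in unique(pc$lens)) {
      sel <- pc$idx[pc$lens == len]
      out_start[sel] <- .draw_starts(pc$tabs[[as.character(len)]],
                                     length(sel))
    }
  }
  data.frame(chrom = hits$chrom, start = out_start,
             end = out_start + (hits$end - hits$start),
             strand = if (!is.null(hits$strand)) hits$strand else "+",
             stringsAsFactors = FALSE)
}

# per-chromosome merged cutoff-extended class-gene intervals, for fast
# per-shuffle counting
.extended_class_index <- function(genes, cutoff, sizes = NULL) {
  idx <- list()
  for (ch in unique(genes$chrom)) {
    gi <- genes$chrom == ch
    m <- .merge_intervals(pmax(genes$start[gi] - cutoff, 0),
                          genes$end[gi] + cutoff)
    idx[[ch]] <- m
  }
  idx
}

.count_within <- function(intervals, class_index) {
  total <- 0L
  for (ch in unique(intervals$chrom)) {
    m <- class_index[[ch]]
    if (is.null(m)) next
    sel <- intervals$chrom == ch
    total <- total +
      sum(.overlaps_merged(intervals$start[sel], intervals$end[sel],
                           m$start, m$end))
  }
  total
}

#' Shuffle-derived expected association count
#'
#' Runs `n_shuffles` independent within-chromosome shuffles of the hits
#' and, for each, counts the shuffled intervals within `cutoff` bp of at
#' least one class gene. The mean over shuffles is the expected count
#' for the chi-square association test. Per-shuffle child seeds are
#' derived from `seed` by shuffle index, so results are reproducible and
#' order-independent.
#'
#' @param hits Hit `data.frame`.
#' @param class_genes Genes of one class.
#' @param chrom_sizes `data.frame` with `chrom`, `size`.
#' @param excluded Excluded regions for the shuffle (gaps, etc.).
#' @param cutoff Association distance in bp.
#' @param n_shuffles Number of shuffles (>= 1).
#' @param seed Root integer seed.
#' @return List: `expected` (mean count), `per_shuffle_counts`.
#' @export
expected_count <- function(hits, class_genes, chrom_sizes, excluded = NULL,
                           cutoff = 100000L, n_shuffles = 1000L,
                           seed = 1L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  shuffler <- make_shuffler(hits, chrom_sizes, excluded)
  cidx <- .extended_class_index(class_genes, cutoff)
  counts <- integer(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    s <- shuffle_intervals(shuffler, seed = (seed + i) %% 2147483647L)
    counts[i] <- .count_within(s, cidx)
  }
  list(expected = mean(counts), per_shuffle_counts = counts)
}

#' Two-cell goodness-of-fit chi-square for an association count
#'
#' Compares an observed count against a shuffle-derived expectation:
#' chi2 = (O-E)^2/E + ((N-O)-(N-E))^2/(N-E), df = 1. The form is
#' two-sided: depletion and enrichment of equal size give the same
#' statistic.
#'
#' @param observed Observed count O.
#' @param expected Expected count E (0 < E < N for a defined test).
#' @param n_total Total number of hits N.
#' @return List: `chi2`, `p_value`, `flagged` (`TRUE` with `NA` values
#'   when E is 0 or N, where the statistic is undefined).
#' @export
chi_square_association <- function(observed, expected, n_total) {
  if (expected <= 0 || expected >= n_total)
    return(list(chi2 = NA_real_, p_value = NA_real_, flagged = TRUE))
  chi2 <- (observed - expected)^2 / expected +
    ((n_total - observed) - (n_total - expected))^2 / (n_total - expected)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       flagged = FALSE)
}

#' Run the full shuffle-based association test suite
#'
#' Tests the association of motif hits with each gene class, genome-wide
#' or restricted to gene-distant regions. In `gene_distant` mode the
#' hits are first reduced to the subset farther than `cutoff` from any
#' protein-coding gene and the shuffle excludes, in addition to `gaps`,
#' all cutoff-extended protein-coding gene intervals (shuffled motifs
#' must stay gene-distant). One result per class; no multiple-testing
#' correction is applied unless `bonferroni = TRUE`.
#'
#' @param hits Hit `data.frame`.
#' @param genes Gene `data.frame` covering protein_coding and the ncRNA
#'   classes.
#' @param chrom_sizes `data.frame` with `chrom`, `size`.
#' @param gaps Assembly-gap intervals (`chrom`, `start`, `end`) or NULL.
#' @param mode `"genome_wide"` or `"gene_distant"`.
#' @param classes Gene classes to test.
#' @param cutoff Association distance in bp (default 100 kb).
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Root seed.
#' @param bonferroni Add a Bonferroni-adjusted p-value column.
#' @return `data.frame`, one row per class: `class_label`, `mode`,
#'   `observed`, `expected`, `n_total`, `chi2`, `p_value`, `flagged`,
#'   `n_shuffles`, `seed`; attribute `per_shuffle_counts` holds the
#'   n_shuffles x classes count matrix for audit.
#' @export
run_association_suite <- function(hits, genes, chrom_sizes, gaps = NULL,
                                  mode = c("genome_wide", "gene_distant"),
                                  classes = c("lncRNA", "miRNA", "rRNA",
                                              "snRNA", "snoRNA",
                                              "protein_coding"),
                                  cutoff = 100000L, n_shuffles = 1000L,
                                  seed = 1L, bonferroni = FALSE) {
  mode <- match.arg(mode)
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  excluded <- gaps
  if (mode == "gene_distant") {
    hits <- gene_distant_subset(hits, pc, cutoff)
    ext <- data.frame(chrom = pc$chrom,
                      start = pmax(pc$start - cutoff, 0),
                      end = pc$end + cutoff, stringsAsFactors = FALSE)
    excluded <- if (is.null(gaps)) ext
                else rbind(gaps[, c("chrom", "start", "end")], ext)
  }
  n_total <- nrow(hits)
  degenerate <- n_total == 0L
  if (!degenerate) {
    shuffler <- make_shuffler(hits, chrom_sizes, excluded)
    cidx <- lapply(classes, function(cl)
      .extended_class_index(genes[genes$biotype == cl, , drop = FALSE],
                            cutoff))
    names(cidx) <- classes
    counts <- matrix(0L, nrow = n_shuffles, ncol = length(classes),
                     dimnames = list(NULL, classes))
    for (i in seq_len(n_shuffles)) {
      s <- shuffle_intervals(shuffler, seed = (seed + i) %% 2147483647L)
      for (cl in classes) counts[i, cl] <- .count_within(s, cidx[[cl]])
    }
  }
  rows <- lapply(classes, function(cl) {
    if (degenerate)
      return(data.frame(class_label = cl, mode = mode, observed = 0L,
                        expected = NA_real_, n_total = 0L,
                        chi2 = NA_real_, p_value = NA_real_,
                        flagged = TRUE, n_shuffles = n_shuffles,
                        seed = seed, stringsAsFactors = FALSE))
    cg <- genes[genes$biotype == cl, , drop = FALSE]
    obs <- sum(.within_any(hits, cg, cutoff))
    ex <- mean(counts[, cl])
    ch <- chi_square_association(obs, ex, n_total)
    data.frame(class_label = cl, mode = mode, observed = obs,
               expected = ex, n_total = n_total, chi2 = ch$chi2,
               p_value = ch$p_value, flagged = ch$flagged,
               n_shuffles = n_shuffles, seed = seed,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (bonferroni)
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  if (!degenerate) attr(res, "per_shuffle_counts") <- counts
  res
}
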