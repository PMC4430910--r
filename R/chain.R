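# UCSC chain alignment parsing and cross-species motif co-occurrence.
#
# Chain coordinates are 0-based half-open in a strand-local frame: for a
# '-' strand sequence, positions are measured from the end of the
# sequence, and forward-strand coordinates are recovered as
# size - strand_local_end .. size - strand_local_start.

#' Parse a UCSC chain alignment file
#'
#' Reads plain or gzip chain text into a list of chain records and
#' verifies the block arithmetic of each chain (block sizes plus gaps
#' must span exactly the target and query extents; only the final block
#' may omit the gap fields).
#'
#' @param path Path to a `.chain` or `.chain.gz` file, or a character
#'   vector of lines.
#' @return List of chains, each a list with `score`, `chain_id`,
#'   `target` and `query` (lists: `name`, `size`, `strand`, `start`,
#'   `end`), and `blocks` (`data.frame` with `size`, `dt`, `dq`; the
#'   final row has `dt = dq = 0`).
#' @export
parse_chain <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else as.character(path)
  lines <- trimws(lines)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "\\s+")[[1]]
    if (f[1] != "chain" || length(f) < 12L)
      stop(sprintf("malformed chain header at line %d", i))
    hdr <- list(
      score = as.numeric(f[2]),
      target = list(name = f[3], size = as.numeric(f[4]), strand = f[5],
                    start = as.numeric(f[6]), end = as.numeric(f[7])),
      query = list(name = f[8], size = as.numeric(f[9]), strand = f[10],
                   start = as.numeric(f[11]), end = as.numeric(f[12])),
      chain_id = if (length(f) >= 13L) as.integer(f[13]) else NA_integer_)
    if (!hdr$target$strand %in% c("+", "-") ||
        !hdr$query$strand %in% c("+", "-"))
      stop(sprintf("invalid strand in chain header at line %d", i))
    i <- i + 1L
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    closed <- FALSE
    while (i <= n && nzchar(lines[i])) {
      b <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (anyNA(b) || !length(b) %in% c(1L, 3L))
        stop(sprintf("malformed block line %d in chain %s", i,
                     hdr$chain_id))
      sizes <- c(sizes, b[1])
      if (length(b) == 3L) { dts <- c(dts, b[2]); dqs <- c(dqs, b[3]) }
      else { dts <- c(dts, 0); dqs <- c(dqs, 0); closed <- TRUE }
      i <- i + 1L
      if (closed) break
    }
    if (!closed)
      stop(sprintf("truncated chain %s: no terminal block line",
                   hdr$chain_id))
    tspan <- sum(sizes) + sum(dts)
    qspan <- sum(sizes) + sum(dqs)
    if (tspan != hdr$target$end - hdr$target$start ||
        qspan != hdr$query$end - hdr$query$start)
      stop(sprintf(
        "block arithmetic inconsistent in chain %s: target %g vs %g, query %g vs %g",
        hdr$chain_id, tspan, hdr$target$end - hdr$target$start,
        qspan, hdr$query$end - hdr$query$start))
    hdr$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    chains[[length(chains) + 1L]] <- hdr
  }
  chains
}

#' Filter chains by alignment score
#'
#' @param chains List from [parse_chain()].
#' @param min_score Minimum score to keep (paper-scale screens use
#'   5000).
#' @return Filtered list.
#' @export
filter_chains <- function(chains, min_score) {
  Filter(function(ch) ch$score >= min_score, chains)
}

#' Ungapped alignment blocks in forward-strand coordinates
#'
#' Walks a chain's block list and reports each ungapped block's target
#' and query interval in forward-strand (plus-strand) coordinates,
#' converting any '-' strand side via `forward_start = size -
#' strand_local_end`.
#'
#' @param chain One chain record from [parse_chain()].
#' @return `data.frame`: `t_chrom`, `t_start`, `t_end`, `q_chrom`,
#'   `q_start`, `q_end`, `q_strand`, `size`, `chain_id`.
#' @export
blocks_to_forward_intervals <- function(chain) {
  b <- chain$blocks
  toff <- chain$target$start + c(0, cumsum(b$size + b$dt))[seq_len(nrow(b))]
  qoff <- chain$query$start + c(0, cumsum(b$size + b$dq))[seq_len(nrow(b))]
  t_start <- toff; t_end <- toff + b$size
  q_start <- qoff; q_end <- qoff + b$size
  if (chain$target$strand == "-") {
    tmp <- chain$target$size - t_end
    t_end <- chain$target$size - t_start
    t_start <- tmp
  }
  if (chain$query$strand == "-") {
    tmp <- chain$query$size - q_end
    q_end <- chain$query$size - q_start
    q_start <- tmp
  }
  data.frame(t_chrom = chain$target$name, t_start = t_start, t_end = t_end,
             q_chrom = chain$query$name, q_start = q_start, q_end = q_end,
             q_strand = chain$query$strand, size = b$size,
             chain_id = chain$chain_id, stringsAsFactors = FALSE)
}

#' Cross-species motif co-occurrence in homologous regions
#'
#' A "homologous region" is an ungapped aligned block of a
#' score-filtered chain (block scale matches the region sizes a
#' chain-based screen reports; whole chains span far more). Blocks
#' overlapping at least one species-1 motif hit are reported as regions;
#' each region's `has_nrse_query` flag records whether its query
#' interval overlaps a species-2 hit. Blocks overlapping on species-1
#' coordinates (from different chains) are merged first so a locus is
#' not double-counted.
#'
#' @param hits_sp1,hits_sp2 Hit `data.frame`s on the target and query
#'   assemblies of the chains.
#' @param chains List from [parse_chain()].
#' @param min_score Chain score cutoff (default 5000).
#' @param merge Merge target-overlapping blocks across chains
#'   (default `TRUE`).
#' @return List with `regions` (`data.frame`: target interval, query
#'   intervals, chain ids, `has_nrse_target` (always `TRUE`),
#'   `has_nrse_query`, `length`) and `summary` (list: `n_regions`,
#'   `n_both`, `min_size`, `max_size`, `total_aligned_bp` — the summed
#'   merged aligned length over all filtered chains).
#' @export
nrse_cooccurrence <- function(hits_sp1, hits_sp2, chains,
                              min_score = 5000, merge = TRUE) {
  chains <- filter_chains(chains, min_score)
  blocks <- if (length(chains))
    do.call(rbind, lapply(chains, blocks_to_forward_intervals))
  else NULL
  empty_sum <- list(n_regions = 0L, n_both = 0L, min_size = NA_real_,
                    max_size = NA_real_, total_aligned_bp = 0)
  if (is.null(blocks) || !nrow(blocks))
    return(list(regions = NULL, summary = empty_sum))

  # total aligned length: merged per target chromosome
  total_aligned <- 0
  for (ch in unique(blocks$t_chrom)) {
    sel <- blocks$t_chrom == ch
    m <- .merge_intervals(blocks$t_start[sel], blocks$t_end[sel])
    total_aligned <- total_aligned + sum(m$end - m$start)
  }

  overlaps_hits <- function(chrom, s, e, hits) {
    out <- logical(length(s))
    if (!nrow(hits)) return(out)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      hi <- hits$chrom == ch
      if (!any(hi)) next
      m <- .merge_intervals(hits$start[hi], hits$end[hi])
      out[sel] <- .overlaps_merged(s[sel], e[sel], m$start, m$end)
    }
    out
  }

  blocks$has1 <- overlaps_hits(blocks$t_chrom, blocks$t_start,
                               blocks$t_end, hits_sp1)
  keep <- blocks[blocks$has1, , drop = FALSE]
  if (!nrow(keep)) {
    empty_sum$total_aligned_bp <- total_aligned
    return(list(regions = NULL, summary = empty_sum))
  }
  keep$has2 <- overlaps_hits(keep$q_chrom, keep$q_start, keep$q_end,
                             hits_sp2)

  if (merge) {
    regions <- list()
    for (ch in unique(keep$t_chrom)) {
      sel <- which(keep$t_chrom == ch)
      r <- IRanges::reduce(.ir0(keep$t_start[sel], keep$t_end[sel]))
      hit_of <- IRanges::findOverlaps(
        .ir0(keep$t_start[sel], keep$t_end[sel]), r)
      grp <- split(sel[S4Vectors::queryHits(hit_of)],
                   S4Vectors::subjectHits(hit_of))
      regions[[ch]] <- data.frame(
        t_chrom = ch, t_start = IRanges::start(r) - 1,
        t_end = IRanges::end(r),
        q_intervals = vapply(grp, function(g) paste(
          sprintf("%s:%g-%g", keep$q_chrom[g], keep$q_start[g],
                  keep$q_end[g]), collapse = ","), character(1)),
        chain_ids = vapply(grp, function(g)
          paste(unique(keep$chain_id[g]), collapse = ","), character(1)),
        has_nrse_target = TRUE,
        has_nrse_query = vapply(grp, function(g) any(keep$has2[g]),
                                logical(1)),
        stringsAsFactors = FALSE)
    }
    regions <- do.call(rbind, regions)
  } else {
    regions <- data.frame(
      t_chrom = keep$t_chrom, t_start = keep$t_start, t_end = keep$t_end,
      q_intervals = sprintf("%s:%g-%g", keep$q_chrom, keep$q_start,
                            keep$q_end),
      chain_ids = as.character(keep$chain_id),
      has_nrse_target = TRUE, has_nrse_query = keep$has2,
      stringsAsFactors = FALSE)
  }
  regions$length <- regions$t_end - regions$t_start
  rownames(regions) <- NULL
  list(regions = regions,
       summary = list(n_regions = nrow(regions),
                      n_both = sum(regions$has_nrse_query),
                      min_size = min(regions$length),
                      max_size = max(regions$length),
                      total_aligned_bp = total_aligned))
}
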