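# Synthetic genomes with planted motifs, gene annotations with
# controllable ncRNA enrichment, assembly-gap tracks, and toy chain
# alignments — all with recorded ground truth, so every pipeline stage
# can be validated end-to-end without external downloads.

#' Specification for a synthetic dataset
#'
#' Defaults describe the desk-scale study geometry used throughout the
#' package's validation: a 2 Mb genome in 3 chromosomes, 40 planted
#' motif instances, 20 protein-coding genes, 30 lncRNAs plus small
#' numbers of the other ncRNA classes, and a 10 kb enrichment window
#' (the association cutoff used with synthetic data; see the methods
#' vignette for the scaling rationale).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Lengths in bp (recycled to
#'   `n_chromosomes`).
#' @param gc_content Background GC fraction.
#' @param n_planted_motifs Motif instances planted genome-wide.
#' @param planted_permutations Concrete motif sequences to plant;
#'   `NULL` samples them from `expand_iupac(pattern)`.
#' @param pattern Degenerate pattern the planted sequences instantiate.
#' @param strand_probability Probability a planted instance is on `+`.
#' @param n_protein_coding Number of protein-coding genes.
#' @param n_per_ncrna_class Named integer vector of gene counts per
#'   ncRNA biotype.
#' @param enrichment_rho Probability an ncRNA gene is placed within
#'   `enrichment_window` of a random planted motif rather than
#'   uniformly.
#' @param enrichment_window Half-width in bp of the near-motif placement
#'   window; also the natural association cutoff for synthetic data.
#' @param gap_fraction Fraction of each chromosome covered by assembly
#'   gaps.
#' @param pc_size_range,nc_size_range Gene length ranges (bp).
#' @param seed Integer seed; all generators derive child seeds from it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chromosomes = 3L,
                           chromosome_lengths = c(8e5, 7e5, 5e5),
                           gc_content = 0.4,
                           n_planted_motifs = 40L,
                           planted_permutations = NULL,
                           pattern = NRSE_PATTERN,
                           strand_probability = 0.5,
                           n_protein_coding = 20L,
                           n_per_ncrna_class = c(lncRNA = 30L, miRNA = 5L,
                                                 rRNA = 3L, snRNA = 3L,
                                                 snoRNA = 3L),
                           enrichment_rho = 0,
                           enrichment_window = 10000L,
                           gap_fraction = 0.05,
                           pc_size_range = c(1000L, 10000L),
                           nc_size_range = c(200L, 2000L),
                           seed = 1L) {
  chromosome_lengths <- rep_len(chromosome_lengths, n_chromosomes)
  if (any(chromosome_lengths < nchar(pattern)))
    stop("chromosome_lengths must exceed the pattern length")
  if (enrichment_rho < 0 || enrichment_rho > 1)
    stop("enrichment_rho must be in [0, 1]")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)")
  structure(list(
    n_chromosomes = n_chromosomes,
    chromosome_lengths = as.numeric(chromosome_lengths),
    gc_content = gc_content, n_planted_motifs = n_planted_motifs,
    planted_permutations = planted_permutations, pattern = pattern,
    strand_probability = strand_probability,
    n_protein_coding = n_protein_coding,
    n_per_ncrna_class = n_per_ncrna_class,
    enrichment_rho = enrichment_rho,
    enrichment_window = as.integer(enrichment_window),
    gap_fraction = gap_fraction,
    pc_size_range = pc_size_range, nc_size_range = nc_size_range,
    seed = as.integer(seed)), class = "synthetic_spec")
}

# place n non-overlapping intervals of the given lengths uniformly on
# the chromosomes, avoiding `avoid` intervals; returns df(chrom, start,
# end). Weights chromosomes by length.
.place_nonoverlapping <- function(lens, chrom_sizes, avoid = NULL,
                                  max_attempts = 1000L) {
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  for (len in lens) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      ch <- sample(chrom_sizes$chrom, 1L, prob = chrom_sizes$size)
      size <- chrom_sizes$size[chrom_sizes$chrom == ch]
      if (size < len) next
      s <- floor(stats::runif(1) * (size - len + 1))
      block <- rbind(placed, if (!is.null(avoid)) avoid[, c("chrom",
                     "start", "end")])
      sel <- block$chrom == ch
      if (!any(sel) || all(block$end[sel] <= s | block$start[sel] >= s + len)) {
        placed <- rbind(placed, data.frame(chrom = ch, start = s,
                                           end = s + len,
                                           stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place interval without overlap")
  }
  placed
}

#' Generate a synthetic genome with planted motif instances
#'
#' Draws i.i.d. background bases at the configured GC content and writes
#' motif instances (concrete permutations of the pattern) at
#' non-overlapping positions with sampled strands; a `-` strand instance
#' is written as the reverse complement. Each planted record is verified
#' against the pattern after writing. Background matches can arise by
#' chance; scan-level ground truth is therefore defined as the scanner
#' oracle's output on the emitted sequence, with the planted loci
#' guaranteed to be a subset.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `genome` ([Biostrings::DNAStringSet]), `chrom_sizes`
#'   (`data.frame` `chrom`, `size`), `truth` (list with `planted_hits`).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  p <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
         spec$gc_content / 2, (1 - spec$gc_content) / 2)
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  chrom_sizes <- data.frame(chrom = chroms,
                            size = spec$chromosome_lengths,
                            stringsAsFactors = FALSE)
  seqs <- lapply(spec$chromosome_lengths, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p))
  names(seqs) <- chroms

  L <- nchar(spec$pattern)
  perms_pool <- if (is.null(spec$planted_permutations))
    expand_iupac(spec$pattern) else spec$planted_permutations
  planted <- .empty_hits()
  if (spec$n_planted_motifs > 0) {
    sites <- .place_nonoverlapping(rep(L, spec$n_planted_motifs),
                                   chrom_sizes)
    perms <- sample(perms_pool, spec$n_planted_motifs, replace = TRUE)
    strands <- ifelse(stats::runif(spec$n_planted_motifs) <
                        spec$strand_probability, "+", "-")
    for (i in seq_len(spec$n_planted_motifs)) {
      ins <- if (strands[i] == "+") perms[i] else revcomp(perms[i])
      idx <- (sites$start[i] + 1):(sites$start[i] + L)
      seqs[[sites$chrom[i]]][idx] <- strsplit(ins, "", fixed = TRUE)[[1]]
    }
    planted <- data.frame(chrom = sites$chrom, start = sites$start,
                          end = sites$end, strand = strands,
                          matched_seq = perms, stringsAsFactors = FALSE)
    stopifnot(all(vapply(seq_len(nrow(planted)), function(i) {
      slice <- paste(seqs[[planted$chrom[i]]][
        (planted$start[i] + 1):(planted$end[i])], collapse = "")
      if (planted$strand[i] == "-") slice <- revcomp(slice)
      iupac_match(spec$pattern, slice)
    }, logical(1))))
  }
  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  list(genome = genome, chrom_sizes = chrom_sizes,
       truth = list(planted_hits = planted))
}

#' Generate a gene annotation with controllable ncRNA enrichment
#'
#' Protein-coding genes are placed uniformly without overlap. Each ncRNA
#' gene is, with probability `enrichment_rho`, placed uniformly within
#' `enrichment_window` bp of a randomly chosen planted motif (clipped to
#' the chromosome), otherwise uniformly on a length-weighted random
#' chromosome.
#'
#' @param spec A [synthetic_spec()].
#' @param genome Result of [generate_genome()] for the same spec.
#' @return Gene `data.frame` as from [load_genes()], with an extra
#'   logical column `near_motif_truth` (`NA` for protein-coding genes)
#'   recording the placement mixture component.
#' @export
generate_annotation <- function(spec, genome) {
  set.seed(spec$seed + 1L)
  cs <- genome$chrom_sizes
  planted <- genome$truth$planted_hits
  genes <- list()

  if (spec$n_protein_coding > 0) {
    lens <- floor(stats::runif(spec$n_protein_coding,
                               spec$pc_size_range[1],
                               spec$pc_size_range[2] + 1))
    pl <- .place_nonoverlapping(lens, cs)
    genes$pc <- data.frame(
      gene_id = sprintf("pc_%03d", seq_len(nrow(pl))),
      name = sprintf("pc_%03d", seq_len(nrow(pl))),
      chrom = pl$chrom, start = pl$start, end = pl$end,
      strand = sample(c("+", "-"), nrow(pl), replace = TRUE),
      biotype = "protein_coding", near_motif_truth = NA,
      stringsAsFactors = FALSE)
  }

  for (cls in names(spec$n_per_ncrna_class)) {
    ncls <- spec$n_per_ncrna_class[[cls]]
    if (ncls < 1) next
    lens <- floor(stats::runif(ncls, spec$nc_size_range[1],
                               spec$nc_size_range[2] + 1))
    rows <- lapply(seq_len(ncls), function(i) {
      near <- nrow(planted) > 0 &&
        stats::runif(1) < spec$enrichment_rho
      if (near) {
        m <- planted[sample.int(nrow(planted), 1L), ]
        size <- cs$size[cs$chrom == m$chrom]
        lo <- max(m$start - spec$enrichment_window, 0)
        hi <- min(m$end + spec$enrichment_window, size) - lens[i]
        # clamp at chromosome bounds; the gene stays within the window
        # of the motif (or overlaps it) in every clipped case
        s <- if (hi < lo) min(lo, size - lens[i])
             else floor(stats::runif(1, lo, hi + 1))
        return(data.frame(chrom = m$chrom, start = s, end = s + lens[i],
                          near = TRUE, stringsAsFactors = FALSE))
      }
      ch <- sample(cs$chrom, 1L, prob = cs$size)
      size <- cs$size[cs$chrom == ch]
      s <- floor(stats::runif(1) * (size - lens[i] + 1))
      data.frame(chrom = ch, start = s, end = s + lens[i], near = FALSE,
                 stringsAsFactors = FALSE)
    })
    pl <- do.call(rbind, rows)
    genes[[cls]] <- data.frame(
      gene_id = sprintf("%s_%03d", cls, seq_len(nrow(pl))),
      name = sprintf("%s_%03d", cls, seq_len(nrow(pl))),
      chrom = pl$chrom, start = pl$start, end = pl$end,
      strand = sample(c("+", "-"), nrow(pl), replace = TRUE),
      biotype = cls, near_motif_truth = pl$near,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(genes))
  rownames(out) <- NULL
  out
}

#' Generate an assembly-gap track
#'
#' Emits non-overlapping gap intervals totalling `gap_fraction` of each
#' chromosome, never overlapping a planted motif (gaps are N-runs in a
#' real assembly, which cannot contain motif instances).
#'
#' @param spec A [synthetic_spec()].
#' @param genome Result of [generate_genome()].
#' @param gap_len_range Individual gap lengths in bp.
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
generate_gaps <- function(spec, genome, gap_len_range = c(500L, 5000L)) {
  set.seed(spec$seed + 2L)
  cs <- genome$chrom_sizes
  planted <- genome$truth$planted_hits
  out <- list()
  if (spec$gap_fraction <= 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  for (i in seq_len(nrow(cs))) {
    ch <- cs$chrom[i]; size <- cs$size[i]
    target <- round(spec$gap_fraction * size)
    got <- 0
    avoid <- planted[planted$chrom == ch, c("start", "end"), drop = FALSE]
    gaps <- data.frame(start = numeric(0), end = numeric(0))
    guard <- 0L
    while (got < target && guard < 10000L) {
      guard <- guard + 1L
      len <- min(floor(stats::runif(1, gap_len_range[1],
                                    gap_len_range[2] + 1)),
                 target - got)
      if (len < 1) break
      excl <- rbind(avoid, gaps)
      al <- .allowed_starts(size, len, sort(excl$start),
                            excl$end[order(excl$start)])
      total <- sum(al$end - al$start)
      if (total <= 0) break
      s <- .draw_starts(list(start = al$start,
                             cum = cumsum(al$end - al$start),
                             total = total), 1L)
      gaps <- rbind(gaps, data.frame(start = s, end = s + len))
      got <- got + len
    }
    if (nrow(gaps))
      out[[ch]] <- data.frame(chrom = ch, start = gaps$start,
                              end = gaps$end, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, unname(out))
         else data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Generate a homologous second genome and its chain alignment
#'
#' Copies planned target-genome segments into a new single-chromosome
#' query genome (in order, separated by random spacer sequence), applies
#' point substitutions at the given divergence rate, and emits valid
#' chain records mapping each copied segment as one ungapped block.
#' Segments may be copied in reverse-complement orientation
#' (`q_strand = "-"`), and a contained planted motif can be deliberately
#' destroyed by a targeted substitution at a non-degenerate pattern
#' position.
#'
#' @param spec A [synthetic_spec()] (supplies pattern and seed).
#' @param genome Result of [generate_genome()].
#' @param plan `data.frame` with columns `chrom`, `start`, `end`,
#'   optional `q_strand` (`"+"`/`"-"`, default `"+"`) and
#'   `destroy_motif` (default `FALSE`).
#' @param divergence Per-base substitution probability in the copy.
#' @param score Chain score to record.
#' @param spacer_len Random spacer length between copied segments.
#' @return List: `query_genome` (DNAStringSet, one sequence `q1`),
#'   `chain_lines` (character vector in UCSC chain format), `chains`
#'   (parsed records), `truth` (`data.frame` per segment: target/query
#'   intervals and `motif_target`/`motif_query` flags from scanning each
#'   side).
#' @export
generate_chain_pair <- function(spec, genome, plan, divergence = 0,
                                score = 9000, spacer_len = 100L) {
  set.seed(spec$seed + 3L)
  if (is.null(plan) || !nrow(plan))
    return(list(query_genome = Biostrings::DNAStringSet(),
                chain_lines = character(0), chains = list(),
                truth = data.frame()))
  if (is.null(plan$q_strand)) plan$q_strand <- "+"
  if (is.null(plan$destroy_motif)) plan$destroy_motif <- FALSE
  pat_chars <- .check_iupac(spec$pattern)
  L <- length(pat_chars)
  planted <- genome$truth$planted_hits

  qparts <- character(0)
  qpos <- 0
  seg <- list()
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
  for (i in seq_len(nrow(plan))) {
    src <- as.character(Biostrings::subseq(
      genome$genome[[plan$chrom[i]]], plan$start[i] + 1, plan$end[i]))
    len <- nchar(src)
    copy <- strsplit(src, "", fixed = TRUE)[[1]]
    if (divergence > 0) {
      mut <- which(stats::runif(len) < divergence)
      for (m in mut)
        copy[m] <- sample(setdiff(c("A", "C", "G", "T"), copy[m]), 1L)
    }
    if (isTRUE(plan$destroy_motif[i]) && nrow(planted)) {
      inside <- planted$chrom == plan$chrom[i] &
        planted$start >= plan$start[i] & planted$end <= plan$end[i]
      for (k in which(inside)) {
        off <- planted$start[k] - plan$start[i]
        # hit a position whose degeneracy set excludes some base
        for (j in seq_len(L)) {
          allowed <- .IUPAC_SETS[[pat_chars[if (planted$strand[k] == "+")
            j else L - j + 1L]]]
          if (planted$strand[k] == "-")
            allowed <- chartr("ACGT", "TGCA", allowed)
          if (length(allowed) < 4L) {
            copy[off + j] <- setdiff(c("A", "C", "G", "T"), allowed)[1]
            break
          }
        }
      }
    }
    copy <- paste(copy, collapse = "")
    placed <- if (plan$q_strand[i] == "-") revcomp(copy) else copy
    pad <- spacer(spacer_len)
    qparts <- c(qparts, pad, placed)
    qstart <- qpos + spacer_len
    seg[[i]] <- data.frame(
      t_chrom = plan$chrom[i], t_start = plan$start[i],
      t_end = plan$end[i], q_start = qstart, q_end = qstart + len,
      q_strand = plan$q_strand[i], stringsAsFactors = FALSE)
    qpos <- qstart + len
  }
  qparts <- c(qparts, spacer(spacer_len))
  qseq <- paste(qparts, collapse = "")
  qsize <- nchar(qseq)
  segs <- do.call(rbind, seg)

  tsizes <- stats::setNames(genome$chrom_sizes$size,
                            genome$chrom_sizes$chrom)
  chain_lines <- character(0)
  for (i in seq_len(nrow(segs))) {
    len <- segs$t_end[i] - segs$t_start[i]
    if (segs$q_strand[i] == "+") {
      qs <- segs$q_start[i]; qe <- segs$q_end[i]
    } else {  # strand-local coordinates measured from the sequence end
      qs <- qsize - segs$q_end[i]; qe <- qsize - segs$q_start[i]
    }
    chain_lines <- c(chain_lines, sprintf(
      "chain %.0f %s %.0f + %.0f %.0f q1 %.0f %s %.0f %.0f %d",
      score, segs$t_chrom[i], tsizes[[segs$t_chrom[i]]],
      segs$t_start[i], segs$t_end[i], qsize, segs$q_strand[i],
      qs, qe, i), sprintf("%.0f", len), "")
  }
  chains <- parse_chain(chain_lines)

  has_motif <- function(s) nrow(scan_sequence(s, spec$pattern)) > 0
  segs$motif_target <- vapply(seq_len(nrow(segs)), function(i)
    has_motif(as.character(Biostrings::subseq(
      genome$genome[[segs$t_chrom[i]]], segs$t_start[i] + 1,
      segs$t_end[i]))), logical(1))
  segs$motif_query <- vapply(seq_len(nrow(segs)), function(i)
    has_motif(substr(qseq, segs$q_start[i] + 1, segs$q_end[i])),
    logical(1))

  list(query_genome = Biostrings::DNAStringSet(c(q1 = qseq)),
       chain_lines = chain_lines, chains = chains, truth = segs)
}

#' Generate and write a complete synthetic bundle
#'
#' Runs all generators for one spec and writes `genome.fa`,
#' `genes.gtf`, `gaps.bed`, `chrom.sizes`, and truth TSVs to `outdir`;
#' returns the in-memory objects invisibly.
#'
#' @param spec A [synthetic_spec()].
#' @param outdir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return (Invisibly) list: `genome`, `chrom_sizes`, `truth`, `genes`,
#'   `gaps`.
#' @export
simulate_dataset <- function(spec, outdir = NULL) {
  g <- generate_genome(spec)
  genes <- generate_annotation(spec, g)
  gaps <- generate_gaps(spec, g)
  bundle <- list(genome = g$genome, chrom_sizes = g$chrom_sizes,
                 truth = g$truth, genes = genes, gaps = gaps)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(g$genome, file.path(outdir, "genome.fa"))
    write_genes_gtf(genes, file.path(outdir, "genes.gtf"))
    write_bed(gaps, file.path(outdir, "gaps.bed"))
    utils::write.table(g$chrom_sizes, file.path(outdir, "chrom.sizes"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(g$truth$planted_hits,
                       file.path(outdir, "truth_planted_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(genes, file.path(outdir, "truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bundle)
}
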