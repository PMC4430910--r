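# Gene-model loading and motif-to-gene distance annotation.
#
# All coordinates are 0-based half-open internally (BED convention);
# GTF input is converted on read. "Within D bp" of a gene means the
# interval gap to the gene body is strictly less than D, which is
# exactly overlap with the gene interval extended by D on each side
# under half-open semantics (the bedtools-style extend-and-intersect
# used throughout).

.ir0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Load gene models from a GTF annotation
#'
#' Keeps only `gene` features so that genes with multiple transcripts are
#' counted once. GTF 1-based inclusive coordinates are converted to
#' 0-based half-open. Both the Ensembl `gene_biotype` and GENCODE
#' `gene_type` attribute keys are recognised; genes with neither are
#' assigned biotype `"other"`.
#'
#' @param path GTF file path (Ensembl dialect).
#' @param biotypes Optional character vector; if given, only genes whose
#'   biotype is in this set are returned.
#' @return `data.frame` with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`.
#' @export
load_genes <- function(path, biotypes = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) gr <- gr[as.character(mc$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  biotype <- rep(NA_character_, length(gr))
  if (!is.null(mc$gene_biotype)) biotype <- as.character(mc$gene_biotype)
  if (!is.null(mc$gene_type)) {
    alt <- as.character(mc$gene_type)
    biotype[is.na(biotype)] <- alt[is.na(biotype)]
  }
  biotype[is.na(biotype) | biotype == ""] <- "other"
  gene_id <- if (!is.null(mc$gene_id)) as.character(mc$gene_id)
             else stop("GTF gene features lack a gene_id attribute")
  name <- if (!is.null(mc$gene_name)) as.character(mc$gene_name) else gene_id
  name[is.na(name)] <- gene_id[is.na(name)]
  out <- data.frame(
    gene_id = gene_id, name = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype, stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  if (!is.null(biotypes)) out <- out[out$biotype %in% biotypes, ,
                                     drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gap distance between genomic intervals
#'
#' Strand-agnostic gene-body distance: 0 if the intervals overlap,
#' otherwise the number of bases strictly between them; `Inf` for
#' intervals on different chromosomes. Vectorised with recycling.
#'
#' @param hit,gene `data.frame`s (or single rows) with `chrom`, `start`,
#'   `end` columns, 0-based half-open.
#' @return Numeric vector of distances in bp.
#' @export
interval_distance <- function(hit, gene) {
  d <- pmax(pmax(hit$start, gene$start) - pmin(hit$end, gene$end), 0)
  d[as.character(hit$chrom) != as.character(gene$chrom)] <- Inf
  d
}

# logical: for each hit, does it lie within `cutoff` bp of any gene
# (gap < cutoff, i.e. overlap with the cutoff-extended gene interval)?
.within_any <- function(hits, genes, cutoff) {
  out <- logical(nrow(hits))
  if (!nrow(hits) || !nrow(genes)) return(out)
  for (ch in unique(hits$chrom)) {
    hi <- which(hits$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    ext <- .ir0(pmax(genes$start[gi] - cutoff, 0), genes$end[gi] + cutoff)
    out[hi] <- IRanges::overlapsAny(.ir0(hits$start[hi], hits$end[hi]), ext)
  }
  out
}

#' Annotate motif hits with nearest-gene distances and location bins
#'
#' For each hit, finds the nearest gene by gap distance (ties broken by
#' smaller gene start, then gene_id), assigns a location bin, and lists
#' all genes within `cutoff` bp. Bins: `intragenic` (hit overlaps the
#' gene body), `flank_0_20kb` (gap < `bin_edge`), `flank_20_100kb`
#' (`bin_edge` <= gap < `cutoff`), `gene_distant` (gap >= `cutoff`, or no
#' gene on the chromosome).
#'
#' @param hits Hit `data.frame` from [scan_genome()].
#' @param genes Gene `data.frame` (typically protein-coding only).
#' @param cutoff Gene-distant threshold in bp (default 100 kb).
#' @param bin_edge Near/far flank boundary in bp (default 20 kb).
#' @return `hits` with added columns `nearest_gene`, `distance_bp`,
#'   `location_bin`, and list-column `genes_within_cutoff`.
#' @export
annotate_hits <- function(hits, genes, cutoff = 100000L, bin_edge = 20000L) {
  n <- nrow(hits)
  nearest <- rep(NA_character_, n)
  dist <- rep(Inf, n)
  within <- vector("list", n)
  overlap <- logical(n)
  for (ch in unique(hits$chrom)) {
    hi <- which(hits$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) { within[hi] <- list(character(0)); next }
    gs <- genes$start[gi]; ge <- genes$end[gi]
    for (k in hi) {
      d <- pmax(pmax(hits$start[k], gs) - pmin(hits$end[k], ge), 0)
      dmin <- min(d)
      cand <- which(d == dmin)
      cand <- cand[order(gs[cand], genes$gene_id[gi][cand])]
      nearest[k] <- genes$gene_id[gi][cand[1]]
      dist[k] <- dmin
      overlap[k] <- dmin == 0 &&
        hits$start[k] < genes$end[gi][cand[1]] &&
        hits$end[k] > genes$start[gi][cand[1]]
      within[[k]] <- genes$gene_id[gi][d < cutoff]
    }
  }
  bin <- ifelse(overlap, "intragenic",
         ifelse(dist < bin_edge, "flank_0_20kb",
         ifelse(dist < cutoff, "flank_20_100kb", "gene_distant")))
  out <- hits
  out$nearest_gene <- nearest
  out$distance_bp <- dist
  out$location_bin <- bin
  out$genes_within_cutoff <- within
  out
}

#' Count motifs within a cutoff of each gene
#'
#' A hit counts for every gene whose `cutoff`-extended interval it
#' overlaps (a hit may serve several genes). Genes with zero hits are
#' omitted from the counts.
#'
#' @inheritParams annotate_hits
#' @return List with `counts` (named integer vector, gene_id -> motif
#'   count) and `histogram` (counts of genes with 1, 2, and >= 3 motifs).
#' @export
motifs_per_gene <- function(hits, genes, cutoff = 100000L) {
  counts <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    hi <- which(hits$chrom == ch)
    if (!length(hi)) next
    ext <- .ir0(pmax(genes$start[gi] - cutoff, 0), genes$end[gi] + cutoff)
    counts[gi] <- IRanges::countOverlaps(ext, .ir0(hits$start[hi],
                                                   hits$end[hi]))
  }
  names(counts) <- genes$gene_id
  counts <- counts[counts > 0L]
  hist <- c(`1` = sum(counts == 1L), `2` = sum(counts == 2L),
            `>=3` = sum(counts >= 3L))
  list(counts = counts, histogram = hist)
}

#' Motif hits in gene-distant regions
#'
#' Returns the hits that do not overlap any `cutoff`-extended
#' protein-coding gene interval (the bedtools `intersect -v` step of the
#' screen): the "gene-distant" (GD) subset, > 100 kb from every
#' protein-coding gene at the default cutoff.
#'
#' @inheritParams annotate_hits
#' @return Subset of `hits` (the complement of the within-cutoff hits).
#' @export
gene_distant_subset <- function(hits, genes, cutoff = 100000L) {
  out <- hits[!.within_any(hits, genes, cutoff), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count hits associated with a gene class
#'
#' Counts each hit once if it lies within `cutoff` bp of at least one
#' gene of the class (bedtools `intersect -u` semantics against
#' cutoff-extended gene intervals).
#'
#' @param hits Hit `data.frame`.
#' @param class_genes Genes of a single biotype.
#' @param cutoff Association distance in bp.
#' @param class_label Label recorded in the result.
#' @param mode `"genome_wide"` or `"gene_distant"`, recorded only.
#' @return One-row `data.frame`: `class_label`, `mode`, `n_hits_total`,
#'   `n_hits_within`.
#' @export
associate_with_class <- function(hits, class_genes, cutoff = 100000L,
                                 class_label = class_genes$biotype[1],
                                 mode = "genome_wide") {
  if (is.null(class_label) || is.na(class_label)) class_label <- "unknown"
  data.frame(class_label = class_label, mode = mode,
             n_hits_total = nrow(hits),
             n_hits_within = sum(.within_any(hits, class_genes, cutoff)),
             stringsAsFactors = FALSE)
}

#' Drop hits on unplaced scaffolds
#'
#' Removes hits whose chromosome name matches any of the given regular
#' expressions (e.g. `"^GL"`, `"random"`), mirroring the exclusion of
#' unassigned scaffolds from distance analyses.
#'
#' @param hits Hit `data.frame`.
#' @param patterns Character vector of regexes for scaffold names.
#' @return Filtered hits.
#' @export
exclude_unplaced <- function(hits, patterns) {
  if (!length(patterns) || !nrow(hits)) return(hits)
  bad <- Reduce(`|`, lapply(patterns, grepl, x = hits$chrom))
  out <- hits[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}
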