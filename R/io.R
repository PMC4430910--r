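# File-format glue: BED6 hits, GTF gene models, chrom.sizes tables.
# All on-disk coordinates follow the native conventions (BED 0-based
# half-open, GTF 1-based inclusive); in-memory data.frames are always
# 0-based half-open.

.hits_to_granges <- function(hits) {
  GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = .ir0(hits$start, hits$end),
    strand = if (!is.null(hits$strand)) hits$strand else "*",
    name = if (!is.null(hits$matched_seq)) hits$matched_seq else ".",
    score = 0L)
}

#' Write motif hits as BED6
#'
#' Name column carries the permutation id (the matched concrete
#' sequence); score is 0.
#' @param hits Hit `data.frame`.
#' @param path Output BED path.
#' @export
write_hits_bed <- function(hits, path) {
  if (!nrow(hits)) { file.create(path); return(invisible(path)) }
  rtracklayer::export(.hits_to_granges(hits), path, format = "bed")
  invisible(path)
}

#' Read motif hits from BED
#'
#' @param path BED file path.
#' @return Hit `data.frame` (`chrom`, `start`, `end`, `strand`,
#'   `matched_seq` from the name column).
#' @export
read_hits_bed <- function(path) {
  if (file.size(path) == 0) return(.empty_hits())
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  nm <- S4Vectors::mcols(gr)$name
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), strand = strand,
             matched_seq = if (is.null(nm)) NA_character_
                           else as.character(nm),
             stringsAsFactors = FALSE)
}

#' Write plain intervals (e.g. assembly gaps) as BED3
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (!nrow(intervals)) { file.create(path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               .ir0(intervals$start, intervals$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED3 intervals
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write gene models as Ensembl-dialect GTF (gene features only)
#' @param genes Gene `data.frame` from [load_genes()] or
#'   [generate_annotation()].
#' @param path Output GTF path.
#' @export
write_genes_gtf <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom, ranges = .ir0(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "nrsescan", type = "gene", gene_id = genes$gene_id,
    gene_name = genes$name, gene_biotype = genes$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a two-column chrom.sizes table
#' @param path TSV path (`chrom`, `size`, no header).
#' @return `data.frame` with `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  df
}

#' Write a position frequency matrix as TSV
#' @param pfm Matrix from [build_pfm()] (positions x A,C,G,T).
#' @param path Output path.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(position = seq_len(nrow(pfm)), pfm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
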