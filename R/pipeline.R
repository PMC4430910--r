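# Orchestration of the full screen: scan -> annotate -> statistics ->
# association -> homology, from one validated configuration, with a
# machine-readable report of every constant actually used.

#' Configuration for a full NRSE screen
#'
#' Defaults are the screen's canonical constants: the 17-bp degenerate
#' consensus, 100 kb association cutoff, 20 kb near/far flank edge,
#' chain score cutoff 5000, and 1000 shuffles for the null model.
#'
#' @param fasta Genome FASTA path (required for [run_screen()]).
#' @param gtf Gene annotation GTF path, or `NULL` to skip annotation and
#'   association stages.
#' @param gaps_bed Assembly-gap BED path or `NULL`.
#' @param chrom_sizes Path to a chrom.sizes TSV or `NULL` (derived from
#'   the FASTA when absent).
#' @param chain Chain alignment path (+ `hits2_bed`) or `NULL` to skip
#'   homology.
#' @param hits2_bed BED of second-species hits for homology.
#' @param pattern Degenerate IUPAC pattern.
#' @param distance_cutoff Association/gene-distant cutoff in bp.
#' @param bin_edge Near/far flank boundary in bp.
#' @param chain_min_score Chain score cutoff.
#' @param n_shuffles Shuffle count for the null model (>= 1).
#' @param seed Root seed for all stochastic stages.
#' @param ncrna_classes ncRNA biotypes to test.
#' @param unplaced_patterns Regexes naming unplaced scaffolds to drop
#'   from distance analyses.
#' @param outdir Output directory.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(fasta = NULL, gtf = NULL, gaps_bed = NULL,
                          chrom_sizes = NULL, chain = NULL,
                          hits2_bed = NULL,
                          pattern = NRSE_PATTERN,
                          distance_cutoff = 100000L, bin_edge = 20000L,
                          chain_min_score = 5000, n_shuffles = 1000L,
                          seed = 1L,
                          ncrna_classes = c("lncRNA", "miRNA", "rRNA",
                                            "snRNA", "snoRNA"),
                          unplaced_patterns = character(0),
                          outdir = tempfile("nrse_screen_")) {
  if (distance_cutoff <= 0 || bin_edge <= 0)
    stop("cutoffs must be positive")
  if (bin_edge >= distance_cutoff)
    stop("bin_edge must be smaller than distance_cutoff")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  .check_iupac(pattern)
  structure(list(fasta = fasta, gtf = gtf, gaps_bed = gaps_bed,
                 chrom_sizes = chrom_sizes, chain = chain,
                 hits2_bed = hits2_bed, pattern = pattern,
                 distance_cutoff = as.integer(distance_cutoff),
                 bin_edge = as.integer(bin_edge),
                 chain_min_score = chain_min_score,
                 n_shuffles = as.integer(n_shuffles),
                 seed = as.integer(seed),
                 ncrna_classes = ncrna_classes,
                 unplaced_patterns = unplaced_patterns,
                 outdir = outdir),
            class = "screen_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full screen described by a configuration
#'
#' Executes scan, annotation, motif statistics, shuffle association
#' (genome-wide and gene-distant), and chain homology in order, writing
#' each stage's outputs under `config$outdir` plus a `report.json` that
#' records every constant, seed, and row count used. Stages whose
#' inputs are not configured are skipped; a failing stage aborts with
#' its name.
#'
#' @param config A [screen_config()].
#' @return List with elements `hits`, `annotated`, `catalog`, `pfm`,
#'   `information_content`, `consensus`, `association` (both modes, if
#'   run), `homology` (if run), and `report`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  for (p in c("fasta", "gtf", "gaps_bed", "chain", "hits2_bed",
              "chrom_sizes")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop(sprintf("input '%s' does not exist: %s", p, config[[p]]))
  }
  if (is.null(config$fasta)) stop("config$fasta is required")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(pattern = config$pattern,
                 distance_cutoff = config$distance_cutoff,
                 bin_edge = config$bin_edge,
                 chain_min_score = config$chain_min_score,
                 n_shuffles = config$n_shuffles, seed = config$seed,
                 ncrna_classes = config$ncrna_classes)
  out <- list()

  genome <- .stage("read_genome",
                   Biostrings::readDNAStringSet(config$fasta))
  chrom_sizes <- .stage("chrom_sizes", {
    if (!is.null(config$chrom_sizes)) read_chrom_sizes(config$chrom_sizes)
    else data.frame(chrom = sub("\\s.*$", "", names(genome)),
                    size = Biostrings::width(genome),
                    stringsAsFactors = FALSE)
  })

  out$hits <- .stage("scan", {
    h <- scan_genome(genome, config$pattern)
    h <- exclude_unplaced(h, config$unplaced_patterns)
    write_hits_bed(h, file.path(config$outdir, "hits.bed"))
    utils::write.table(h, file.path(config$outdir, "hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    h
  })
  report$n_hits <- nrow(out$hits)

  out$catalog <- .stage("stats", catalog_permutations(out$hits))
  report$n_permutations <- out$catalog$total_permutations
  if (nrow(out$hits)) {
    out$pfm <- .stage("stats", build_pfm(out$hits$matched_seq))
    out$information_content <- information_content(out$pfm)
    out$consensus <- consensus_from_pfm(out$pfm)
    write_pfm_tsv(out$pfm, file.path(config$outdir, "pfm.tsv"))
    report$consensus <- out$consensus
  }

  if (!is.null(config$gtf)) {
    genes <- .stage("load_genes", load_genes(config$gtf))
    pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
    out$annotated <- .stage("annotate",
      annotate_hits(out$hits, pc, cutoff = config$distance_cutoff,
                    bin_edge = config$bin_edge))
    ann_flat <- out$annotated
    ann_flat$genes_within_cutoff <- vapply(
      ann_flat$genes_within_cutoff, paste, character(1), collapse = ",")
    utils::write.table(ann_flat,
                       file.path(config$outdir, "hits_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$location_bins <- as.list(table(out$annotated$location_bin))
    out$motifs_per_gene <- motifs_per_gene(out$hits, pc,
                                           config$distance_cutoff)

    gaps <- if (!is.null(config$gaps_bed)) read_bed(config$gaps_bed)
            else NULL
    out$association <- .stage("assoc", {
      gw <- run_association_suite(
        out$hits, genes, chrom_sizes, gaps, mode = "genome_wide",
        classes = c(config$ncrna_classes, "protein_coding"),
        cutoff = config$distance_cutoff,
        n_shuffles = config$n_shuffles, seed = config$seed)
      gd <- run_association_suite(
        out$hits, genes, chrom_sizes, gaps, mode = "gene_distant",
        classes = config$ncrna_classes,
        cutoff = config$distance_cutoff,
        n_shuffles = config$n_shuffles, seed = config$seed)
      res <- rbind(gw, gd)
      utils::write.table(res,
                         file.path(config$outdir, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  if (!is.null(config$chain) && !is.null(config$hits2_bed)) {
    out$homology <- .stage("homology", {
      chains <- parse_chain(config$chain)
      hits2 <- read_hits_bed(config$hits2_bed)
      hom <- nrse_cooccurrence(out$hits, hits2, chains,
                               min_score = config$chain_min_score)
      if (!is.null(hom$regions))
        utils::write.table(hom$regions,
                           file.path(config$outdir, "homology.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      hom
    })
    report$homology_summary <- out$homology$summary
  }

  out$report <- report
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out
}
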