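small_spec <- function(...) {
  defaults <- list(n_chromosomes = 2L, chromosome_lengths = c(5e4, 3e4),
                   n_planted_motifs = 8L, n_protein_coding = 4L,
                   n_per_ncrna_class = c(lncRNA = 5L, miRNA = 2L),
                   gap_fraction = 0.05, seed = 7L)
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

test_that("genome generation is seed-deterministic and verifies plantings", {
  b1 <- generate_genome(small_spec())
  b2 <- generate_genome(small_spec())
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$truth$planted_hits, b2$truth$planted_hits)

  pl <- b1$truth$planted_hits
  expect_equal(nrow(pl), 8L)
  # every planted locus is recovered by the scanner with identical
  # coordinates, strand and permutation id
  h <- scan_genome(b1$genome)
  key <- function(d) sprintf("%s:%d-%d:%s:%s", d$chrom, d$start, d$end,
                             d$strand, d$matched_seq)
  expect_true(all(key(pl) %in% key(h)))
})

test_that("zero plantings yield a background-only genome of the right size", {
  spec <- synthetic_spec(n_chromosomes = 1L, chromosome_lengths = 1000,
                         n_planted_motifs = 0L, gap_fraction = 0,
                         seed = 3L)
  b <- generate_genome(spec)
  expect_equal(Biostrings::width(b$genome), 1000)
  expect_equal(nrow(b$truth$planted_hits), 0L)
  # scan truth is whatever the oracle finds (usually nothing at 1 kb)
  h <- scan_genome(b$genome)
  expect_equal(h, oracle_scan(as.character(b$genome[[1]]), NRSE_PATTERN),
               ignore_attr = TRUE)
})

test_that("planting specific permutations places them with correct strands", {
  spec <- synthetic_spec(n_chromosomes = 1L, chromosome_lengths = 2e4,
                         n_planted_motifs = 5L,
                         planted_permutations = "ATCAGAACCAAAGACAG",
                         gap_fraction = 0, seed = 5L)
  b <- generate_genome(spec)
  pl <- b$truth$planted_hits
  expect_equal(nrow(pl), 5L)
  expect_true(all(pl$matched_seq == "ATCAGAACCAAAGACAG"))
  h <- scan_genome(b$genome)
  m <- merge(h, pl, by = c("chrom", "start", "end", "strand",
                           "matched_seq"))
  expect_equal(nrow(m), 5L)
})

test_that("ncRNA enrichment rho=1 places every ncRNA near a planted motif", {
  spec <- small_spec(enrichment_rho = 1)
  b <- generate_genome(spec)
  genes <- generate_annotation(spec, b)
  lnc <- genes[genes$biotype == "lncRNA", ]
  expect_true(all(lnc$near_motif_truth))
  # verified independently through the association machinery
  motifs <- b$truth$planted_hits
  d <- vapply(seq_len(nrow(lnc)), function(i) {
    min(interval_distance(motifs,
                          lnc[rep(i, nrow(motifs)), , drop = FALSE]))
  }, numeric(1))
  expect_true(all(d <= spec$enrichment_window))
})

test_that("class counts honour the spec, including empty classes", {
  spec <- small_spec()
  b <- generate_genome(spec)
  genes <- generate_annotation(spec, b)
  expect_equal(sum(genes$biotype == "protein_coding"), 4L)
  expect_equal(sum(genes$biotype == "lncRNA"), 5L)
  expect_equal(sum(genes$biotype == "miRNA"), 2L)
  expect_equal(sum(genes$biotype == "rRNA"), 0L)
})

test_that("gap tracks meet the target fraction and avoid planted motifs", {
  spec0 <- small_spec(gap_fraction = 0)
  b0 <- generate_genome(spec0)
  expect_equal(nrow(generate_gaps(spec0, b0)), 0L)

  spec <- synthetic_spec(n_chromosomes = 1L, chromosome_lengths = 1e5,
                         n_planted_motifs = 10L, gap_fraction = 0.2,
                         seed = 9L)
  b <- generate_genome(spec)
  gaps <- generate_gaps(spec, b)
  expect_equal(sum(gaps$end - gaps$start), 0.2 * 1e5, tolerance = 0.01)
  pl <- b$truth$planted_hits
  for (i in seq_len(nrow(pl)))
    expect_false(any(gaps$chrom == pl$chrom[i] &
                       gaps$start < pl$end[i] & gaps$end > pl$start[i]))
})

test_that("chain pairs map copied segments and report motif flags truthfully", {
  spec <- synthetic_spec(n_chromosomes = 1L, chromosome_lengths = 2e4,
                         n_planted_motifs = 3L,
                         planted_permutations = "ATCAGAACCAAAGACAG",
                         gap_fraction = 0, seed = 13L)
  b <- generate_genome(spec)
  m <- b$truth$planted_hits[1, ]
  plan <- data.frame(chrom = m$chrom, start = max(m$start - 200, 0),
                     end = m$end + 200, q_strand = "+",
                     destroy_motif = FALSE, stringsAsFactors = FALSE)

  cp <- generate_chain_pair(spec, b, plan, divergence = 0)
  expect_true(cp$truth$motif_target)
  expect_true(cp$truth$motif_query)
  r <- nrse_cooccurrence(scan_genome(b$genome),
                         scan_genome(cp$query_genome), cp$chains,
                         min_score = 5000)
  expect_equal(r$summary$n_regions, 1L)
  expect_equal(r$summary$n_both, 1L)

  # targeted divergence destroys the query-side motif: flags (TRUE, FALSE)
  plan$destroy_motif <- TRUE
  cp2 <- generate_chain_pair(spec, b, plan, divergence = 0)
  expect_true(cp2$truth$motif_target)
  expect_false(cp2$truth$motif_query)
  r2 <- nrse_cooccurrence(scan_genome(b$genome),
                          scan_genome(cp2$query_genome), cp2$chains,
                          min_score = 5000)
  expect_equal(r2$summary$n_regions, 1L)
  expect_equal(r2$summary$n_both, 0L)

  # minus-strand copy still recovers the region via coordinate flips
  plan$destroy_motif <- FALSE
  plan$q_strand <- "-"
  cp3 <- generate_chain_pair(spec, b, plan, divergence = 0)
  expect_true(cp3$truth$motif_query)
  r3 <- nrse_cooccurrence(scan_genome(b$genome),
                          scan_genome(cp3$query_genome), cp3$chains,
                          min_score = 5000)
  expect_equal(r3$summary$n_both, 1L)

  empty <- generate_chain_pair(spec, b, plan[0, ], divergence = 0)
  expect_length(empty$chains, 0L)
})

test_that("emitted files parse back through the package's own readers", {
  outdir <- tempfile("bundle_")
  spec <- small_spec()
  b <- simulate_dataset(spec, outdir = outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("genome.fa", "genes.gtf", "gaps.bed", "chrom.sizes")))))

  genome <- Biostrings::readDNAStringSet(file.path(outdir, "genome.fa"))
  expect_identical(as.character(genome), as.character(b$genome))
  cs <- read_chrom_sizes(file.path(outdir, "chrom.sizes"))
  expect_equal(cs$size, b$chrom_sizes$size)

  genes <- load_genes(file.path(outdir, "genes.gtf"))
  expect_equal(nrow(genes), nrow(b$genes))
  expect_setequal(genes$gene_id, b$genes$gene_id)
  g <- genes[order(genes$gene_id), ]
  g0 <- b$genes[order(b$genes$gene_id), ]
  expect_equal(g$start, g0$start)
  expect_equal(g$end, g0$end)
  expect_equal(g$biotype, g0$biotype)

  gaps <- read_bed(file.path(outdir, "gaps.bed"))
  expect_equal(sum(gaps$end - gaps$start),
               sum(b$gaps$end - b$gaps$start))

  # hits round-trip through BED6
  h <- scan_genome(b$genome)
  bed <- file.path(outdir, "hits.bed")
  write_hits_bed(h, bed)
  h2 <- read_hits_bed(bed)
  expect_equal(h2[, c("chrom", "start", "end", "strand", "matched_seq")],
               h[, c("chrom", "start", "end", "strand", "matched_seq")],
               ignore_attr = TRUE)
})
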