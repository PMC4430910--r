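# in-code GTF fixture: one protein-coding gene with two transcripts,
# one lncRNA (GENCODE gene_type key), one gene with no biotype
make_toy_gtf <- function() {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1\tens\tgene\t1001\t2000\t.\t+\t.",
          'gene_id "g1"; gene_name "PC1"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1\tens\ttranscript\t1001\t1500\t.\t+\t.",
          'gene_id "g1"; transcript_id "g1.t1";', sep = "\t"),
    paste("chr1\tens\ttranscript\t1201\t2000\t.\t+\t.",
          'gene_id "g1"; transcript_id "g1.t2";', sep = "\t"),
    paste("chr2\tens\tgene\t501\t900\t.\t-\t.",
          'gene_id "g2"; gene_type "lncRNA";', sep = "\t"),
    paste("chr2\tens\tgene\t5001\t5400\t.\t+\t.",
          'gene_id "g3";', sep = "\t")), path)
  path
}

test_that("load_genes keeps gene features only and converts coordinates", {
  g <- load_genes(make_toy_gtf())
  expect_equal(nrow(g), 3L)             # transcripts dropped
  expect_equal(g$start[g$gene_id == "g1"], 1000)  # 1-based -> 0-based
  expect_equal(g$end[g$gene_id == "g1"], 2000)
  expect_equal(g$biotype[g$gene_id == "g2"], "lncRNA")  # gene_type key
  expect_equal(g$biotype[g$gene_id == "g3"], "other")   # missing biotype
  expect_equal(g$name[g$gene_id == "g1"], "PC1")

  lnc <- load_genes(make_toy_gtf(), biotypes = "lncRNA")
  expect_equal(lnc$gene_id, "g2")
  expect_error(suppressWarnings(load_genes(tempfile())),
               "failed to parse")
})

test_that("gene GTF writing round-trips through load_genes", {
  genes <- data.frame(
    gene_id = c("a", "b"), name = c("a", "b"), chrom = c("c1", "c2"),
    start = c(100, 0), end = c(400, 50), strand = c("+", "-"),
    biotype = c("protein_coding", "miRNA"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gtf")
  write_genes_gtf(genes, path)
  back <- load_genes(path)
  expect_equal(back[order(back$gene_id), names(genes)],
               genes[order(genes$gene_id), ], ignore_attr = TRUE)
})

test_that("interval_distance is gap distance with an Inf cross-chromosome sentinel", {
  expect_equal(interval_distance(
    data.frame(chrom = "c", start = 2500, end = 2517),
    data.frame(chrom = "c", start = 1000, end = 2000)), 500)
  expect_equal(interval_distance(
    data.frame(chrom = "c", start = 1500, end = 1517),
    data.frame(chrom = "c", start = 1000, end = 2000)), 0)
  expect_equal(interval_distance(
    data.frame(chrom = "c1", start = 0, end = 17),
    data.frame(chrom = "c2", start = 0, end = 17)), Inf)
  # boundary case: gap of exactly 100 kb is NOT "within 100 kb" under
  # half-open extension-overlap semantics
  h <- data.frame(chrom = "c", start = 0, end = 17)
  g <- data.frame(chrom = "c", start = 100017, end = 200000,
                  gene_id = "g", biotype = "protein_coding")
  expect_equal(interval_distance(h, g), 100000)
  expect_equal(associate_with_class(h, g, cutoff = 100000L,
                                    class_label = "x")$n_hits_within, 0L)
})

test_that("annotate_hits bins hits by distance and finds all nearby genes", {
  gene <- data.frame(gene_id = "g1", name = "g1", chrom = "c1",
                     start = 500000, end = 510000, strand = "+",
                     biotype = "protein_coding", stringsAsFactors = FALSE)
  offs <- c(0, 10000, 50000, 150000)  # intragenic + the three far bins
  hits <- do.call(rbind, lapply(offs, function(d) {
    s <- if (d == 0) 505000 else 510000 + d
    data.frame(chrom = "c1", start = s + 0:4 * 20, end = s + 0:4 * 20 + 17,
               strand = "+", matched_seq = "X", stringsAsFactors = FALSE)
  }))
  ann <- annotate_hits(hits, gene)
  expect_equal(as.integer(table(ann$location_bin)[c(
    "intragenic", "flank_0_20kb", "flank_20_100kb", "gene_distant")]),
    c(5L, 5L, 5L, 5L))
  expect_true(all(ann$nearest_gene == "g1"))
  expect_equal(sum(lengths(ann$genes_within_cutoff) > 0), 15L)
})

test_that("nearest-gene ties break deterministically by start then gene_id", {
  genes <- data.frame(
    gene_id = c("zz", "aa"), name = c("zz", "aa"), chrom = "c1",
    start = c(2000, 2000), end = c(3000, 3000), strand = "+",
    biotype = "protein_coding", stringsAsFactors = FALSE)
  hit <- data.frame(chrom = "c1", start = 1000, end = 1017, strand = "+",
                    matched_seq = "X", stringsAsFactors = FALSE)
  expect_equal(annotate_hits(hit, genes)$nearest_gene, "aa")
})

test_that("motifs_per_gene counts extension overlaps and histograms them", {
  # 8 genes with one motif nearby, 2 genes with two
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10), name = sprintf("g%02d", 1:10),
    chrom = "c1", start = seq(0, 9) * 1e6,
    end = seq(0, 9) * 1e6 + 1000, strand = "+",
    biotype = "protein_coding", stringsAsFactors = FALSE)
  starts <- c(genes$start[1:8] + 5000,
              genes$start[9:10] + 5000, genes$start[9:10] + 6000)
  hits <- data.frame(chrom = "c1", start = starts, end = starts + 17,
                     strand = "+", matched_seq = "X",
                     stringsAsFactors = FALSE)
  mpg <- motifs_per_gene(hits, genes, cutoff = 100000L)
  expect_equal(unname(mpg$histogram), c(8L, 2L, 0L))

  # one hit equidistant between two genes serves both
  g2 <- genes[1:2, ]
  g2$start <- c(0, 200000); g2$end <- c(1000, 201000)
  mid <- data.frame(chrom = "c1", start = 100490, end = 100507,
                    strand = "+", matched_seq = "X",
                    stringsAsFactors = FALSE)
  expect_equal(unname(motifs_per_gene(mid, g2, cutoff = 100000L)$counts),
               c(1L, 1L))
})

test_that("gene-distant subset partitions the hits and matches the bin", {
  set.seed(88)
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:5), name = sprintf("g%d", 1:5),
    chrom = "c1", start = sort(sample.int(5e6, 5)), end = NA,
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE)
  genes$end <- genes$start + 2000
  hits <- data.frame(chrom = "c1", start = sample.int(6e6, 200),
                     end = NA, strand = "+", matched_seq = "X",
                     stringsAsFactors = FALSE)
  hits$end <- hits$start + 17
  gd <- gene_distant_subset(hits, genes)
  ann <- annotate_hits(hits, genes)
  expect_setequal(gd$start, ann$start[ann$location_bin == "gene_distant"])
  expect_equal(nrow(gd) + sum(ann$location_bin != "gene_distant"),
               nrow(hits))
})

test_that("class association counts each hit once and matches brute force", {
  lnc <- data.frame(
    gene_id = c("l1", "l2", "l3"), name = c("l1", "l2", "l3"),
    chrom = "c1", start = c(100000, 110000, 120000),
    end = c(101000, 111000, 121000), strand = "+", biotype = "lncRNA",
    stringsAsFactors = FALSE)
  # 4 hits within 100 kb (the first is near all three genes), 6 far
  starts <- c(105000, 150000, 199000, 1000, 5e6 + 1:6 * 1000)
  hits <- data.frame(chrom = "c1", start = starts, end = starts + 17,
                     strand = "+", matched_seq = "X",
                     stringsAsFactors = FALSE)
  ac <- associate_with_class(hits, lnc, cutoff = 100000L)
  expect_equal(ac$n_hits_within, 4L)
  expect_equal(ac$n_hits_total, 10L)
  expect_equal(ac$class_label, "lncRNA")

  none <- lnc[0, ]
  expect_equal(associate_with_class(hits, none, cutoff = 100000L,
                                    class_label = "lncRNA")$n_hits_within,
               0L)

  # brute-force pairwise-distance oracle on random instances, plus
  # monotonicity in the cutoff
  set.seed(99)
  for (i in 1:10) {
    h <- data.frame(chrom = sample(c("c1", "c2"), 30, TRUE),
                    start = sample.int(2e5, 30))
    h$end <- h$start + 17
    g <- data.frame(gene_id = sprintf("g%d", 1:6),
                    chrom = sample(c("c1", "c2"), 6, TRUE),
                    start = sample.int(2e5, 6), biotype = "lncRNA")
    g$end <- g$start + 500
    prev <- -1L
    for (D in c(1000L, 10000L, 50000L)) {
      got <- associate_with_class(h, g, cutoff = D)$n_hits_within
      expect_equal(got, oracle_assoc_count(h, g, D))
      expect_gte(got, prev)
      prev <- got
    }
  }
})

test_that("association counts agree with bedtools intersect -u", {
  skip_if(Sys.which("bedtools") == "", "bedtools not on PATH")
  set.seed(123)
  hits <- data.frame(chrom = "c1", start = sort(sample.int(1e6, 50)))
  hits$end <- hits$start + 17
  genes <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "c1",
                      start = sort(sample.int(1e6, 8)),
                      biotype = "lncRNA")
  genes$end <- genes$start + 1000
  cutoff <- 20000L
  a <- tempfile(fileext = ".bed"); b <- tempfile(fileext = ".bed")
  writeLines(sprintf("c1\t%d\t%d", hits$start, hits$end), a)
  writeLines(sprintf("c1\t%d\t%d", pmax(genes$start - cutoff, 0),
                     genes$end + cutoff), b)
  out <- system2("bedtools", c("intersect", "-u", "-a", a, "-b", b),
                 stdout = TRUE)
  expect_equal(associate_with_class(hits, genes,
                                    cutoff = cutoff)$n_hits_within,
               length(out))
})

test_that("motifs_per_gene and genes_within lists are mutually consistent", {
  set.seed(17)
  genes <- data.frame(gene_id = sprintf("g%d", 1:10), name = "x",
                      chrom = "c1", start = sample.int(3e6, 10),
                      strand = "+", biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 1000
  hits <- data.frame(chrom = "c1", start = sample.int(3e6, 100))
  hits$end <- hits$start + 17
  ann <- annotate_hits(hits, genes)
  mpg <- motifs_per_gene(hits, genes)
  expect_equal(sum(mpg$counts), sum(lengths(ann$genes_within_cutoff)))
})

test_that("unplaced scaffolds are excluded by name pattern", {
  hits <- data.frame(chrom = c("chr1", "GL0001", "chr2_random"),
                     start = 0, end = 17, strand = "+",
                     matched_seq = "X", stringsAsFactors = FALSE)
  expect_equal(exclude_unplaced(hits, c("^GL", "random"))$chrom, "chr1")
  expect_equal(nrow(exclude_unplaced(hits, character(0))), 3L)
})
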