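test_that("interval validation enforces the half-open convention", {
  expect_error(genomic_interval("chr1", 10, 10), "start < end")
  expect_error(genomic_interval("chr1", -1, 10), ">= 0")
  expect_error(genomic_interval("chr1", 5, 10, "x"), "strand")
  x <- genomic_interval("chr1", c(0, 100), c(50, 200), c("+", "-"))
  expect_equal(nrow(x), 2)
})

test_that("overlap follows half-open semantics and matches brute force", {
  a <- genomic_interval("chr1", 10, 20)
  expect_false(gi_overlaps(a, genomic_interval("chr1", 20, 30)))  # bookended
  expect_true(gi_overlaps(a, genomic_interval("chr1", 19, 30)))   # 1 bp
  expect_false(gi_overlaps(a, genomic_interval("chr2", 10, 20)))  # other chrom

  set.seed(11)
  x <- random_intervals(100)
  y <- random_intervals(100)
  got <- gi_overlaps(x, y)
  want <- vapply(seq_len(100), function(i)
    bf_overlap(x$start[i], x$end[i], y$start[i], y$end[i]), logical(1))
  expect_equal(got, want)

  # symmetric, reflexive
  expect_equal(gi_overlaps(x, y), gi_overlaps(y, x))
  expect_true(all(gi_overlaps(x, x)))
})

test_that("gi_reduce agrees with IRanges::reduce", {
  skip_if_not_installed("IRanges")
  set.seed(12)
  for (rep in 1:20) {
    x <- random_intervals(15, max_coord = 80)
    got <- gi_reduce(x)
    ir <- IRanges::reduce(IRanges::IRanges(x$start + 1, x$end))
    expect_equal(got$start, IRanges::start(ir) - 1)
    expect_equal(got$end, IRanges::end(ir))
  }
})

test_that("locus domains extend the gene by the stated extents", {
  gp <- gene_model("G+", "chr1", "+", 100000, 110000)
  dp <- define_locus_domain(gp, 70000, 20000)
  expect_equal(c(dp$interval$start, dp$interval$end), c(30000, 130000))

  gm <- gene_model("G-", "chr1", "-", 120000, 130000)
  dm <- define_locus_domain(gm, 70000, 20000)
  expect_equal(c(dm$interval$start, dm$interval$end), c(100000, 200000))

  # clamped at the chromosome start (hand-computed)
  gc <- gene_model("Gc", "chr1", "+", 50000, 60000)
  dc <- define_locus_domain(gc, 70000, 20000, chrom_length = 1e6)
  expect_equal(c(dc$interval$start, dc$interval$end), c(0, 80000))

  # domain always contains the gene body; length additive unless clamped
  set.seed(13)
  for (i in 1:50) {
    s <- sample.int(2e5, 1) + 1e5; w <- sample.int(5e4, 1)
    g <- gene_model("g", "chr1", sample(c("+", "-"), 1), s, s + w)
    d <- define_locus_domain(g, 70000, 20000, chrom_length = 1e6)
    expect_true(d$interval$start <= s && d$interval$end >= s + w)
    expect_equal(d$interval$end - d$interval$start, 70000 + w + 20000)
  }
  expect_error(define_locus_domain(gc, 1, 1, chrom_length = 55000),
               "beyond chromosome")
})

test_that("gene models validate strand-aware TSS and exon structure", {
  g <- gene_model("g", "chr2", "-", 1000, 2000,
                  exon_starts = c(1000, 1700), exon_ends = c(1200, 2000))
  expect_equal(g$tss, 1999)
  expect_equal(g$polya_site, 1000)
  expect_error(gene_model("g", "chr2", "+", 1000, 2000,
                          exon_starts = c(1000, 1100), exon_ends = c(1200, 1300)),
               "overlapping exons")
  expect_error(gene_model("g", "chr2", "+", 1000, 2000,
                          exon_starts = 900, exon_ends = 1100), "contained")
})

test_that("positional annotation reproduces the published site archetypes", {
  # target gene with a neighbour whose intron hosts a far-upstream site
  klf1 <- gene_model("KLF1", "chr19", "+", 100000, 103000)
  rad23a <- gene_model("RAD23A", "chr19", "+", 30000, 42000,
                       exon_starts = c(30000, 41000), exon_ends = c(30500, 42000))
  site <- genomic_interval("chr19", 35000, 35400)  # intron of the neighbour
  ann <- annotate_position(site, klf1, list(klf1, rad23a))
  expect_equal(ann$genic_context, "intronic")
  expect_equal(ann$tss_relation, "far_distal")
  expect_lt(ann$signed_tss_distance, -60000)  # > 60 kb upstream

  # open intergenic space 70 kb upstream
  klf9 <- gene_model("KLF9", "chr9", "-", 500000, 530000)
  s9 <- genomic_interval("chr9", 599800, 600200)
  ann9 <- annotate_position(s9, klf9, list(klf9))
  expect_equal(ann9$genic_context, "intergenic")
  expect_equal(ann9$tss_relation, "far_distal")
  expect_lt(ann9$signed_tss_distance, 0)  # upstream on the minus strand

  # site spanning the TSS
  st <- genomic_interval("chr19", 99900, 100200)
  annt <- annotate_position(st, klf1, list(klf1))
  expect_equal(annt$genic_context, "exonic")
  expect_equal(annt$tss_relation, "contains_tss")

  expect_error(annotate_position(genomic_interval("chr1", 1, 10), klf1),
               "different chromosome")
})

test_that("distance classes partition sites and boundary points land as documented", {
  g <- gene_model("g", "chr1", "+", 50000, 60000)
  # boundary values 2000 and 10000 are distal (bins <2k, 2-10k, >10k)
  expect_equal(annotate_position(genomic_interval("chr1", 46000, 48001),
                                 g)$tss_relation, "distal")       # d = 2000
  expect_equal(annotate_position(genomic_interval("chr1", 60000, 60001),
                                 g)$tss_relation, "distal")       # d = 10000 dn
  expect_equal(annotate_position(genomic_interval("chr1", 38000, 38001),
                                 g)$tss_relation, "far_distal")   # d = 11999 up
  set.seed(14)
  for (i in 1:200) {
    s <- sample.int(120000, 1); w <- sample.int(3000, 1)
    ann <- annotate_position(genomic_interval("chr1", s, s + w), g)
    expect_equal(ann$tss_relation, bf_tss_relation(s, s + w, g$tss))
  }
})

test_that("genic context agrees with per-base enumeration on random cases", {
  set.seed(15)
  genes <- list(
    gene_model("a", "chr1", "+", 200, 900,
               exon_starts = c(200, 600), exon_ends = c(350, 900)),
    gene_model("b", "chr1", "-", 1200, 2400,
               exon_starts = c(1200, 2000), exon_ends = c(1500, 2400)))
  for (i in 1:300) {
    s <- sample.int(2800, 1); w <- sample.int(120, 1)
    ann <- annotate_position(genomic_interval("chr1", s, s + w), genes[[1]], genes)
    expect_equal(ann$genic_context, bf_genic_context(s, s + w, genes),
                 info = sprintf("site [%d,%d)", s, s + w))
  }
})
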