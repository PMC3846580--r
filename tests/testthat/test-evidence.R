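mk_sites <- function(starts, width = 400, chrom = "chr1") {
  data.frame(site_id = paste0("S", seq_along(starts)), chrom = chrom,
             start = starts, end = starts + width, strand = "*",
             stringsAsFactors = FALSE)
}

test_that("evidence join reports overlap, specificity upgrades and TF occupancy", {
  sites <- mk_sites(c(1000, 5000))
  tracks <- list(
    faire = data.frame(chrom = "chr1", start = 1100, end = 1200, strand = "*"),
    h3k4me1 = data.frame(chrom = "chr1", start = 900, end = 1500, strand = "*",
                         specific = TRUE),
    h3k27ac = data.frame(chrom = "chr1", start = 950, end = 1050, strand = "*",
                         specific = TRUE),
    tf = data.frame(chrom = "chr1", start = 1200, end = 1300, strand = "*",
                    name = "GATA-1", score = 700, cell_type = "K562"))
  got <- annotate_evidence(sites, tracks)
  # site 1: the KLF9-I-like pattern
  expect_equal(got$conserved[1], FALSE)
  expect_equal(got$faire[1], TRUE)
  expect_equal(got$h3k4me1[1], "present_target_specific")
  expect_equal(got$h3k27ac[1], "present_target_specific")
  expect_true(got$gata1[1]); expect_false(got$nfe2[1])
  # site 2 overlaps nothing: all absent
  expect_equal(got$h3k4me1[2], "absent")
  expect_false(any(got$conserved[2], got$faire[2], got$gata1[2], got$nfe2[2]))
  expect_equal(attr(got, "absent_tracks"), "conserved")

  # a TF cluster in another cell type does not count
  tracks$tf$cell_type <- "HepG2"
  expect_false(annotate_evidence(sites, tracks)$gata1[1])

  # monotonicity: adding elements never turns a present field absent
  tracks$conserved <- data.frame(chrom = "chr1", start = 1, end = 2000,
                                 strand = "*")
  got2 <- annotate_evidence(sites, tracks)
  expect_true(got2$conserved[1])
  expect_equal(got2$faire, got$faire)
})

test_that("evidence join agrees with a per-element brute-force oracle", {
  set.seed(51)
  for (rep in 1:5) {
    sites <- mk_sites(sample.int(3000, 30), width = 50)
    rand_track <- function(n, specific = FALSE) {
      s <- sample.int(3000, n)
      d <- data.frame(chrom = "chr1", start = s, end = s + sample.int(80, n,
                                                                      TRUE),
                      strand = "*", stringsAsFactors = FALSE)
      if (specific) d$specific <- stats::runif(n) < 0.5
      d
    }
    tracks <- list(conserved = rand_track(10), faire = rand_track(10),
                   h3k4me1 = rand_track(12, TRUE), h3k27ac = rand_track(12, TRUE),
                   tf = transform(rand_track(15), name = sample(c("GATA1", "NFE2", "SP1"),
                                                                15, TRUE),
                                  score = 500, cell_type = "K562"))
    got <- annotate_evidence(sites, tracks)
    for (i in seq_len(nrow(sites))) {
      bf <- function(tr) any(vapply(seq_len(nrow(tr)), function(j)
        bf_overlap(sites$start[i], sites$end[i], tr$start[j], tr$end[j]),
        logical(1)))
      expect_equal(got$conserved[i], bf(tracks$conserved))
      hk <- tracks$h3k4me1
      expect_equal(got$h3k4me1[i] != "absent", bf(hk))
      if (got$h3k4me1[i] == "present_target_specific")
        expect_true(bf(hk[hk$specific, , drop = FALSE]))
      expect_equal(got$gata1[i], bf(tracks$tf[tracks$tf$name == "GATA1", ]))
    }
  }
})

test_that("TF score matrix takes the max score per site and TF", {
  sites <- mk_sites(c(1000, 3000))
  tf <- data.frame(chrom = "chr1",
                   start = c(1100, 1150, 1200, 3100),
                   end = c(1180, 1250, 1300, 3200), strand = "*",
                   name = c("GATA1", "GATA1", "TAL1", "TAL1"),
                   score = c(300, 700, 800, 500), cell_type = "K562")
  m <- build_tf_matrix(sites, tf)
  expect_equal(m["S1", "GATA1"], 700)   # two clusters -> max
  expect_equal(m["S1", "TAL1"], 800)    # single element
  expect_equal(m["S2", "GATA1"], 0)
  expect_equal(build_tf_matrix(sites, tf, aggregate = "sum")["S1", "GATA1"], 1000)
  expect_error(build_tf_matrix(sites, transform(tf, score = 1200)), "1000")
  # other cell types are filtered out
  expect_equal(unname(build_tf_matrix(sites, tf, cell_type = "HeLa")["S1", "GATA1"]), 0)
})

test_that("TF score matrix equals the brute-force double loop", {
  set.seed(52)
  sites <- mk_sites(sample.int(5000, 25), width = 120)
  n <- 60
  s <- sample.int(5000, n)
  tf <- data.frame(chrom = "chr1", start = s, end = s + sample.int(200, n, TRUE),
                   strand = "*", name = sample(paste0("TF", 1:6), n, TRUE),
                   score = sample.int(1000, n), cell_type = "K562")
  m <- build_tf_matrix(sites, tf)
  for (i in seq_len(nrow(sites))) for (tfn in colnames(m)) {
    best <- 0
    for (j in which(tf$name == tfn))
      if (bf_overlap(sites$start[i], sites$end[i], tf$start[j], tf$end[j]))
        best <- max(best, tf$score[j])
    expect_equal(unname(m[i, tfn]), best)
  }
})

test_that("k-means classes are canonical, seed-stable and recover planted blobs", {
  set.seed(53)
  # two well-separated planted blobs, k = 2: recovery forced
  hi <- matrix(stats::rnorm(5 * 4, 900, 10), 5, 4)
  lo <- matrix(stats::rnorm(7 * 4, 50, 10), 7, 4)
  m <- rbind(hi, lo)
  rownames(m) <- paste0("r", 1:12); colnames(m) <- paste0("c", 1:4)
  km <- kmeans_classes(m, 2, seed = 5)
  expect_equal(unname(km$row_classes), rep(c(1L, 2L), c(5, 7)))  # class 1 = high mean

  # permuting rows changes nothing up to the relabelling
  p <- sample.int(12)
  km_p <- kmeans_classes(m[p, ], 2, seed = 5)
  expect_equal(km_p$row_classes[rownames(m)], km$row_classes)

  # identical repeat runs; k = 1 degenerate; k > n errors
  expect_equal(kmeans_classes(m, 2, seed = 5), km)
  expect_equal(unname(kmeans_classes(m, 1, seed = 5)$row_classes), rep(1L, 12))
  expect_error(kmeans_classes(m, 13, seed = 5), "exceeds")

  # within-cluster SS non-increasing in k, and better than random partitions
  wss <- vapply(1:4, function(k) kmeans_classes(m, k, seed = 5)$row_withinss,
                numeric(1))
  expect_true(all(diff(wss) <= 1e-8))
  rand_wss <- replicate(100, {
    cl <- sample(1:3, 12, replace = TRUE)
    sum(vapply(unique(cl), function(g) {
      x <- m[cl == g, , drop = FALSE]
      sum(scale(x, scale = FALSE)^2)
    }, numeric(1)))
  })
  expect_lte(kmeans_classes(m, 3, seed = 5)$row_withinss, min(rand_wss))
})

test_that("screen summary arithmetic matches an independent scan of the fixture", {
  rep1 <- replay_table1(read_table1())
  s <- rep1$summary

  # independent brute-force scan of the raw fixture rows
  raw <- utils::read.table(table1_path(), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ery <- raw$klfp_k562 == "Y" & raw$klfp_hela == "-" & raw$klfp_hek293 == "-"
  expect_equal(s$n_sites, nrow(raw))
  expect_equal(s$n_minP_enhancers, sum(raw$minp == "Y"))
  expect_equal(s$n_promoter_enhancers, sum(raw$klfp_k562 == "Y"))
  expect_equal(s$n_erythroid_specific, sum(ery))
  expect_equal(unname(s$evidence_over_specific["conserved"]),
               sum(raw$cs == "Y" & ery))
  expect_equal(unname(s$evidence_over_specific["histone_marked"]),
               sum((raw$h3k4me1 != "-" | raw$h3k27ac != "-") & ery))
  expect_equal(unname(s$evidence_over_specific["target_specific_marked"]),
               sum((raw$h3k4me1 == "Y*" | raw$h3k27ac == "Y*") & ery))
  expect_equal(unname(s$evidence_over_specific["tf_occupied"]),
               sum((raw$gata1 == "Y" | raw$nfe2 == "Y") & ery))

  # id mismatch is an error; empty input gives an all-zero summary
  expect_error(summarize_screen(rep1$calls[-1, ], rep1$evidence),
               "different site ids")
  empty <- summarize_screen(rep1$calls[0, ], rep1$evidence[0, ])
  expect_equal(empty$n_sites, 0)
  expect_equal(unname(empty$evidence_over_specific),
               c(0L, 0L, 0L, 0L), ignore_attr = TRUE)
})

test_that("fixture structure matches the published table layout", {
  tbl <- read_table1()
  expect_equal(nrow(tbl), 23)
  expect_equal(length(unique(tbl$gene)), 10)
  expect_equal(sum(tbl$gene == "KLF1"), 5)
  expect_equal(tbl$dhs_id[tbl$gene == "KLF1"], c("I", "II", "III", "IV", "V"))
  expect_true(tbl$klfp_hela[tbl$site_id == "KLF17-I"])
  # emit_table1_fixture writes a byte-identical copy
  out <- tempfile(fileext = ".tsv")
  emit_table1_fixture(out)
  expect_identical(readLines(out), readLines(table1_path()))
})
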