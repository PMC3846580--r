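panel <- erythroid_panel()

mk_site <- function(present, signals) {
  cells <- c(panel$target, panel$non_target)
  presence <- stats::setNames(cells %in% present, cells)
  signal <- stats::setNames(rep(0, length(cells)), cells)
  signal[names(signals)] <- signals
  list(presence = presence, signal = signal)
}

test_that("specificity labels follow the presence / subdued-signal rules", {
  # present only in primary erythroid cells
  s <- mk_site(c("ESER", "FLER", "PBER"),
               c(ESER = 50, FLER = 60, PBER = 40))
  expect_equal(classify_specificity(s$presence, s$signal, panel)$label,
               "target_specific")

  # all four erythroid plus a small HeLa peak below half the weakest
  s <- mk_site(c("ESER", "FLER", "PBER", "K562", "HeLa"),
               c(ESER = 50, FLER = 60, PBER = 40, K562 = 45, HeLa = 10))
  got <- classify_specificity(s$presence, s$signal, panel)
  expect_equal(got$label, "putative_target_specific")
  expect_equal(got$offending_cell_types, "HeLa")

  # HeLa peak at exactly the ratio boundary is NOT subdued (strict <)
  s$signal["HeLa"] <- 20
  expect_equal(classify_specificity(s$presence, s$signal, panel)$label,
               "non_specific")

  # no target presence at all
  s <- mk_site(c("HeLa", "BJ"), c(HeLa = 50, BJ = 50))
  expect_equal(classify_specificity(s$presence, s$signal, panel)$label,
               "non_specific")

  # three offending non-target cells exceed max_nontarget_presence = 2
  s <- mk_site(c("ESER", "HeLa", "BJ", "CACO2"),
               c(ESER = 100, HeLa = 1, BJ = 1, CACO2 = 1))
  expect_equal(classify_specificity(s$presence, s$signal, panel)$label,
               "non_specific")
})

test_that("classifier validates its inputs instead of imputing", {
  s <- mk_site("ESER", c(ESER = 10))
  expect_error(classify_specificity(s$presence[-1], s$signal, panel),
               "missing presence")
  bad <- s$presence; bad["BJ"] <- NA
  expect_error(classify_specificity(bad, s$signal, panel), "NA presence")
  sig <- s$signal; sig["ESER"] <- 0
  expect_error(classify_specificity(s$presence, sig, panel), "non-positive")
  expect_error(classify_specificity(s$presence, s$signal, panel,
                                    subdued_ratio = 1.5), "subdued_ratio")
})

test_that("classification is permutation-invariant, monotone, and collapses at limits", {
  set.seed(21)
  cells <- c(panel$target, panel$non_target)
  for (i in 1:100) {
    present <- sample(cells, sample.int(length(cells), 1))
    sig <- stats::setNames(round(stats::runif(length(cells), 1, 100), 1), cells)
    s <- mk_site(present, sig[present])
    base <- classify_specificity(s$presence, s$signal, panel)
    # permuting cell-type order never changes the label
    p <- sample(cells)
    expect_equal(classify_specificity(s$presence[p], s$signal[p], panel)$label,
                 base$label)
    # adding a non-target presence never moves toward target_specific
    if (base$label == "target_specific") {
      extra <- sample(panel$non_target, 1)
      pres2 <- s$presence; pres2[extra] <- TRUE
      sig2 <- s$signal; sig2[extra] <- 1
      expect_false(classify_specificity(pres2, sig2, panel)$label ==
                     "target_specific")
    }
    # subdued_ratio -> 0: putative collapses into non_specific
    r0 <- classify_specificity(s$presence, s$signal, panel,
                               subdued_ratio = 1e-12)
    expect_true(r0$label %in% c("target_specific", "non_specific"))
    # max_nontarget_presence = 0 leaves only the two extreme labels
    r1 <- classify_specificity(s$presence, s$signal, panel,
                               max_nontarget_presence = 0)
    expect_true(r1$label %in% c("target_specific", "non_specific"))
  }
})

test_that("screen_locus reproduces the five-site archetypal locus", {
  loc <- klf1_like_locus()
  got <- screen_locus(loc$domain, loc$peaks, panel)
  expect_equal(nrow(got$candidates), 5)
  expect_equal(got$sites$site_id, paste0("KLF1-", c("I", "II", "III", "IV", "V")))
  expect_equal(got$sites$label,
               c(rep("target_specific", 4), "putative_target_specific"))
  expect_false(got$presence["KLF1-I", "K562"])
  expect_true(all(got$presence["KLF1-I", c("ESER", "FLER", "PBER")]))
})

test_that("screen_locus handles empty input and merges co-located peaks", {
  gene <- gene_model("G", "chr5", "+", 100000, 110000)
  dom <- define_locus_domain(gene, 70000, 20000)
  empty <- screen_locus(dom, list(), panel)
  expect_equal(nrow(empty$sites), 0)
  expect_equal(nrow(empty$candidates), 0)

  # overlapping peaks from different cell types merge into one named site
  peaks <- list(
    ESER = data.frame(chrom = "chr5", start = 95000, end = 95400, score = 40),
    FLER = data.frame(chrom = "chr5", start = 95200, end = 95600, score = 30),
    K562 = data.frame(chrom = "chr5", start = 99000, end = 99300, score = 20))
  got <- screen_locus(dom, peaks, panel)
  expect_equal(nrow(got$sites), 2)
  expect_equal(got$sites$start, c(95000, 99000))
  expect_equal(got$sites$end, c(95600, 99300))
  expect_equal(got$sites$site_id, c("G-I", "G-II"))
  expect_equal(got$signal["G-I", "ESER"], 40)

  # minus-strand locus numbers sites 5' -> 3' (right to left)
  gm <- gene_model("H", "chr5", "-", 100000, 110000)
  dm <- define_locus_domain(gm, 70000, 20000)
  gotm <- screen_locus(dm, peaks, panel)
  expect_equal(gotm$sites$site_id, c("H-I", "H-II"))
  expect_equal(gotm$sites$start, c(99000, 95000))  # emitted 5' -> 3'
})

test_that("screen_locus rejects out-of-panel peak sets and unscored peaks", {
  loc <- klf1_like_locus()
  bad <- loc$peaks; names(bad)[1] <- "NOT_A_CELL"
  expect_error(screen_locus(loc$domain, bad, panel), "outside the panel")
  nos <- loc$peaks; nos$ESER$score <- NULL
  expect_error(screen_locus(loc$domain, nos, panel), "score")
})
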