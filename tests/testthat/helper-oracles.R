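# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles enumerate bases / elements directly and stay independent of the
# implementation paths they check.

# per-base membership overlap oracle (half-open intervals, small coords)
bf_overlap <- function(s1, e1, s2, e2) {
  length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1))) > 0
}

# distance-class oracle: minimum |base - tss| over all covered bases
bf_tss_relation <- function(start, end, tss) {
  bases <- seq(start, end - 1)
  if (tss %in% bases) return("contains_tss")
  d <- min(abs(bases - tss))
  if (d < 2000) "proximal" else if (d <= 10000) "distal" else "far_distal"
}

# genic-context oracle by per-base enumeration against gene/exon tables
bf_genic_context <- function(start, end, genes) {
  bases <- seq(start, end - 1)
  exonic <- FALSE; intronic <- FALSE
  for (g in genes) {
    gb <- seq(g$interval$start, g$interval$end - 1)
    if (!any(bases %in% gb)) next
    exb <- unlist(lapply(seq_len(nrow(g$exons)),
                         function(i) seq(g$exons$start[i], g$exons$end[i] - 1)))
    if (any(bases %in% exb)) exonic <- TRUE else intronic <- TRUE
  }
  if (exonic) "exonic" else if (intronic) "intronic" else "intergenic"
}

random_intervals <- function(n, max_coord = 60, chroms = "chrT") {
  s <- sample.int(max_coord - 2, n, replace = TRUE)
  w <- sample.int(10, n, replace = TRUE)
  genomic_interval(sample(chroms, n, replace = TRUE), s, pmin(s + w, max_coord))
}

# a locus emulating the published KLF1 presence pattern: five peak stacks,
# four erythroid-only and one with a small extra HeLa peak
klf1_like_locus <- function() {
  gene <- gene_model("KLF1", "chr19", "+", 100000, 103000)
  dom <- define_locus_domain(gene, 70000, 20000)
  centers <- c(35000, 95000, 99500, 104000, 110000)  # I..V along the domain
  mk <- function(cells, score, idx) {
    lapply(stats::setNames(cells, cells), function(ct)
      data.frame(chrom = "chr19", start = centers[idx], end = centers[idx] + 400,
                 score = score, stringsAsFactors = FALSE))
  }
  peaks <- list()
  add <- function(p) for (ct in names(p)) peaks[[ct]] <<- rbind(peaks[[ct]], p[[ct]])
  add(mk(c("ESER", "FLER", "PBER"), 60, 1))              # I: primary only
  for (i in 2:4) add(mk(c("ESER", "FLER", "PBER", "K562"), 55, i))
  add(mk(c("ESER", "FLER", "PBER", "K562"), 50, 5))      # V ...
  add(mk("HeLa", 10, 5))                                 # ... plus subdued HeLa
  list(gene = gene, domain = dom, peaks = peaks)
}
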