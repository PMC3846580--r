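#' Genomic intervals
#'
#' Construct a validated table of genomic intervals. The whole package uses
#' the BED convention: 0-based, half-open `[start, end)`. `start < end` and
#' `start >= 0` are enforced; empty intervals are rejected.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued vectors of 0-based offsets; `end` is
#'   exclusive.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr19", 12995237, 12998490)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  x <- data.frame(
    chrom  = rep_len(as.character(chrom), n),
    start  = rep_len(as.numeric(start), n),
    end    = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("missing interval columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  if (!"strand" %in% names(x)) x$strand <- "*"
  if (any(!x$strand %in% c("+", "-", "*")))
    stop(what, ": strand must be one of '+', '-', '*'")
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, ": NA coordinates")
  if (any(x$start < 0)) stop(what, ": start must be >= 0")
  if (any(x$start >= x$end)) stop(what, ": need start < end (half-open, non-empty)")
  invisible(x)
}

#' Pairwise interval overlap
#'
#' Strand-blind overlap of half-open intervals: `TRUE` iff the two intervals
#' are on the same chromosome and share at least one base. Bookended
#' intervals (`[10,20)` vs `[20,30)`) do not overlap.
#'
#' @param a,b Interval tables as built by [genomic_interval()]; rows are
#'   recycled to a common length and compared element-wise.
#' @return Logical vector.
#' @export
gi_overlaps <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ia] == b$chrom[ib] & a$start[ia] < b$end[ib] & b$start[ib] < a$end[ia]
}

#' Overlap of each query interval with any interval of a subject set
#'
#' @param x Query interval table.
#' @param set Subject interval table (may have zero rows).
#' @return Logical vector, one entry per row of `x`.
#' @export
gi_overlaps_any <- function(x, set) {
  validate_intervals(x)
  if (is.null(set) || nrow(set) == 0) return(rep(FALSE, nrow(x)))
  validate_intervals(set)
  vapply(seq_len(nrow(x)), function(i) {
    any(set$chrom == x$chrom[i] & set$start < x$end[i] & x$start[i] < set$end)
  }, logical(1))
}

#' Merge intervals into maximal connected runs
#'
#' Computes the union of covered bases per chromosome and returns it as a
#' sorted set of disjoint intervals. Touching intervals are merged (the
#' union of `[10,20)` and `[20,30)` covers `[10,30)`), matching
#' `bedtools merge` with distance 0.
#'
#' @param x Interval table.
#' @return Interval table of the merged runs, sorted by `(chrom, start)`,
#'   unstranded.
#' @export
gi_reduce <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(genomic_interval(character(), numeric(), numeric())[0, ])
  out <- lapply(split(x, x$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    ms <- d$start[1]; me <- d$end[1]
    starts <- numeric(); ends <- numeric()
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= me) {
        me <- max(me, d$end[i])
      } else {
        starts <- c(starts, ms); ends <- c(ends, me)
        ms <- d$start[i]; me <- d$end[i]
      }
    }
    data.frame(chrom = d$chrom[1], start = c(starts, ms), end = c(ends, me),
               strand = "*", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Gene model
#'
#' A gene body with transcription start site (TSS), poly(A) site and exon
#' structure in 0-based half-open coordinates. On the `+` strand the TSS is
#' `start` and the poly(A) site is `end - 1`; on the `-` strand they are
#' mirrored. When no exons are supplied the whole gene body is treated as a
#' single exon (exon structure unknown).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Gene body, half-open.
#' @param exon_starts,exon_ends Parallel vectors of exon coordinates;
#'   must be sorted, non-overlapping and contained in `[start, end)`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       exon_starts = NULL, exon_ends = NULL) {
  stopifnot(length(gene_id) == 1, strand %in% c("+", "-"))
  interval <- genomic_interval(chrom, start, end, strand)
  if (is.null(exon_starts) || length(exon_starts) == 0) {
    exon_starts <- start; exon_ends <- end
  }
  stopifnot(length(exon_starts) == length(exon_ends))
  exons <- genomic_interval(chrom, exon_starts, exon_ends, strand)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start < start) || any(exons$end > end))
    stop("gene_model: exons not contained in the gene interval")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("gene_model: overlapping exons")
  structure(list(
    gene_id = gene_id,
    interval = interval,
    tss = if (strand == "+") start else end - 1,
    polya_site = if (strand == "+") end - 1 else start,
    exons = exons
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s), TSS %d\n",
              x$gene_id, x$interval$chrom, x$interval$start, x$interval$end,
              x$interval$strand, nrow(x$exons), x$tss))
  invisible(x)
}

#' Locus domain around a gene
#'
#' The screened window for a gene: the gene body extended by `upstream`
#' bases on the 5' (TSS) side and `downstream` bases on the 3' (poly(A))
#' side, in transcription orientation, clamped to `[0, chrom_length)`.
#' Defaults follow the screen design: 70 kb upstream of the TSS to 20 kb
#' downstream of the poly(A) site.
#'
#' @param gene A [gene_model()].
#' @param upstream,downstream Non-negative extents in bp.
#' @param chrom_length Chromosome length used for clamping (`Inf` = none).
#' @return A list of class `locus_domain` with fields `gene_id`,
#'   `interval`, `upstream_extent`, `downstream_extent`.
#' @export
define_locus_domain <- function(gene, upstream = 70000, downstream = 20000,
                                chrom_length = Inf) {
  stopifnot(inherits(gene, "gene_model"), upstream >= 0, downstream >= 0)
  gi <- gene$interval
  if (gi$end > chrom_length)
    stop("define_locus_domain: gene interval beyond chromosome end")
  if (gi$strand == "+") {
    s <- gi$start - upstream; e <- gi$end + downstream
  } else {
    s <- gi$start - downstream; e <- gi$end + upstream
  }
  s <- max(0, s); e <- min(chrom_length, e)
  if (s >= e)
    stop("define_locus_domain: domain empty after clamping; inconsistent annotation")
  structure(list(
    gene_id = gene$gene_id,
    interval = genomic_interval(gi$chrom, s, e, gi$strand),
    upstream_extent = upstream,
    downstream_extent = downstream
  ), class = "locus_domain")
}

#' Positional annotation of a site relative to a gene
#'
#' Classifies the genic context of a site against all supplied gene models
#' (exonic if it overlaps any exon, else intronic if inside any gene body,
#' else intergenic; precedence exonic > intronic > intergenic) and its
#' TSS-distance class against one target gene. Distance is measured in bp
#' from the site edge nearest the TSS, signed negative when the site lies
#' upstream of the TSS in gene orientation. Classes: `contains_tss` when
#' the TSS falls inside the site, `proximal` (< 2 kb), `distal`
#' (2-10 kb inclusive), `far_distal` (> 10 kb).
#'
#' @param site One-row interval table.
#' @param gene Target [gene_model()] (same chromosome as `site`).
#' @param all_genes List of gene models used for the genic context;
#'   defaults to just `gene`.
#' @return List with `genic_context`, `tss_relation`,
#'   `signed_tss_distance`.
#' @export
annotate_position <- function(site, gene, all_genes = list(gene)) {
  validate_intervals(site)
  stopifnot(nrow(site) == 1, inherits(gene, "gene_model"))
  if (site$chrom != gene$interval$chrom)
    stop("annotate_position: site and gene on different chromosomes")

  context <- "intergenic"
  for (g in all_genes) {
    if (!inherits(g, "gene_model")) stop("all_genes must be gene_model objects")
    if (g$interval$chrom != site$chrom) next
    if (!gi_overlaps(site, g$interval)) next
    if (any(gi_overlaps(site, g$exons))) { context <- "exonic"; break }
    context <- "intronic"
  }

  tss <- gene$tss
  if (tss >= site$start && tss < site$end) {
    relation <- "contains_tss"; d <- 0
  } else {
    d <- if (tss < site$start) site$start - tss else tss - (site$end - 1)
    # upstream (5' of the TSS in transcription orientation) is negative
    left_of_tss <- site$end <= tss
    upstream <- if (gene$interval$strand == "+") left_of_tss else !left_of_tss
    if (upstream) d <- -d
    relation <- if (abs(d) < 2000) "proximal"
    else if (abs(d) <= 10000) "distal"
    else "far_distal"
  }
  list(genic_context = context, tss_relation = relation,
       signed_tss_distance = d)
}
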