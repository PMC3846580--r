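#' Read a BED3+ file
#'
#' Reads BED with at least chrom/start/end; column 4 is taken as `name`,
#' column 5 as `score`, column 6 as `strand` when present. Extra columns
#' are kept under their supplied header names if the optional
#' `track`-style header is absent (plain BED has no header).
#'
#' @param path File path.
#' @param extra_cols Optional character vector naming columns 7+.
#' @return Interval `data.frame` (0-based half-open, BED-native).
#' @export
read_bed <- function(path, extra_cols = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         quote = "")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  nm <- c(base[seq_len(min(ncol(d), 6))], extra_cols)
  names(d) <- c(nm, paste0("V", seq_len(max(0, ncol(d) - length(nm)))))[seq_len(ncol(d))]
  if (!"strand" %in% names(d)) d$strand <- "*"
  d$strand[d$strand == "."] <- "*"
  validate_intervals(d, what = path)
  d
}

#' Write intervals as BED
#'
#' @param x Interval table; `name` and `score` columns are emitted when
#'   present, plus any columns named in `extra_cols`.
#' @param path Output path.
#' @param extra_cols Extra columns (written after strand, BED4+ style).
#' @export
write_bed <- function(x, path, extra_cols = NULL) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(x)) cols <- c(cols, "name")
  if ("score" %in% names(x)) {
    if (!"name" %in% names(x)) x$name <- "."
    cols <- union(c(cols, "name"), "score")
  }
  if (!is.null(extra_cols)) {
    if (!all(c("name", "score") %in% cols)) {
      if (!"name" %in% names(x)) x$name <- "."
      if (!"score" %in% names(x)) x$score <- 0
    }
    x$strand[x$strand == "*"] <- "."
    cols <- c("chrom", "start", "end", "name", "score", "strand", extra_cols)
  }
  utils::write.table(format(x[, cols, drop = FALSE], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from the simple TSV format
#'
#' Expected columns: `gene_id`, `chrom`, `strand`, `start`, `end`,
#' `exon_starts`, `exon_ends` (comma-separated lists, 0-based half-open).
#'
#' @param path File path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(d)))
    stop(path, ": gene model table needs columns ", paste(need, collapse = ", "))
  parse_list <- function(s) if (is.na(s) || s == "" || s == ".") numeric() else
    as.numeric(strsplit(s, ",")[[1]])
  genes <- lapply(seq_len(nrow(d)), function(i) {
    gene_model(d$gene_id[i], d$chrom[i], d$strand[i], d$start[i], d$end[i],
               exon_starts = if ("exon_starts" %in% names(d)) parse_list(d$exon_starts[i]),
               exon_ends   = if ("exon_ends" %in% names(d)) parse_list(d$exon_ends[i]))
  })
  names(genes) <- d$gene_id
  genes
}

#' Write gene models to the simple TSV format
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  d <- do.call(rbind, lapply(genes, function(g) data.frame(
    gene_id = g$gene_id, chrom = g$interval$chrom, strand = g$interval$strand,
    start = g$interval$start, end = g$interval$end,
    exon_starts = paste(format(g$exons$start, scientific = FALSE, trim = TRUE), collapse = ","),
    exon_ends = paste(format(g$exons$end, scientific = FALSE, trim = TRUE), collapse = ","),
    stringsAsFactors = FALSE)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF subset
#'
#' Consumes `exon` features of a GTF-like file (1-based closed
#' coordinates, converted to 0-based half-open on read); the gene body is
#' the span of its exons. Only the `gene_id` attribute is used.
#'
#' @param path File path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gtf_genes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  names(d)[1:9] <- c("chrom", "source", "feature", "start", "end", "score",
                     "strand", "frame", "attributes")
  d <- d[d$feature == "exon", , drop = FALSE]
  if (nrow(d) == 0) stop(path, ": no exon features")
  m <- regmatches(d$attributes, regexpr('gene_id "[^"]+"', d$attributes))
  if (length(m) != nrow(d)) stop(path, ": exon feature without gene_id attribute")
  d$gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
  d$start <- d$start - 1L  # GTF is 1-based closed
  genes <- lapply(split(d, d$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    gene_model(e$gene_id[1], e$chrom[1], e$strand[1],
               min(e$start), max(e$end),
               exon_starts = e$start, exon_ends = e$end)
  })
  genes[order(names(genes))]
}

#' Read a count matrix with gene lengths and library sizes
#'
#' TSV layout: a commented first line `#total_mapped_reads<TAB>s1=N...` is
#' accepted, or a `total_mapped_reads` row; otherwise columns `gene_id`,
#' `length` and one column per sample, with library sizes supplied
#' separately.
#'
#' @param path File path.
#' @return List with `counts` (matrix), `lengths`, `totals`.
#' @export
read_count_matrix <- function(path) {
  first <- readLines(path, n = 1)
  totals <- NULL
  if (startsWith(first, "#total_mapped_reads")) {
    kv <- strsplit(strsplit(sub("^#total_mapped_reads\t", "", first), "\t")[[1]], "=")
    totals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                              vapply(kv, `[`, "", 1))
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("gene_id", "length") %in% names(d)))
  samples <- setdiff(names(d), c("gene_id", "length"))
  counts <- as.matrix(d[, samples, drop = FALSE])
  rownames(counts) <- d$gene_id
  if (is.null(totals)) totals <- colSums(counts)
  list(counts = counts, lengths = stats::setNames(d$length, d$gene_id),
       totals = totals[samples])
}

#' Write a count matrix in the format read by [read_count_matrix()]
#' @param counts gene x sample matrix; @param lengths per-gene bp;
#' @param totals per-sample library sizes; @param path output path.
#' @export
write_count_matrix <- function(counts, lengths, totals, path) {
  hdr <- paste0("#total_mapped_reads\t",
                paste(names(totals), format(totals, scientific = FALSE, trim = TRUE),
                      sep = "=", collapse = "\t"))
  d <- data.frame(gene_id = rownames(counts), length = lengths[rownames(counts)],
                  counts, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format qPCR Ct table
#'
#' Columns: `gene`, `condition`, `replicate`, `ct`.
#' @param path File path.
#' @return `data.frame`.
#' @export
read_ct_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(d)))
    stop(path, ": Ct table needs columns ", paste(need, collapse = ", "))
  if (any(!is.finite(d$ct)) || any(d$ct <= 0))
    stop(path, ": Ct values must be finite and positive")
  d
}

#' Read a dual-luciferase plate table
#'
#' Columns: `construct_id`, `promoter`, `insert`, `cell_line`, `batch`,
#' `replicate`, `firefly`, `renilla`.
#' @param path File path.
#' @return `data.frame`.
#' @export
read_plate <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("construct_id", "promoter", "insert", "cell_line", "batch",
            "replicate", "firefly", "renilla")
  if (!all(need %in% names(d)))
    stop(path, ": plate table needs columns ", paste(need, collapse = ", "))
  if (any(d$renilla <= 0)) stop(path, ": renilla must be positive")
  if (any(d$firefly < 0)) stop(path, ": firefly must be non-negative")
  d
}

#' Read evidence tracks from a directory
#'
#' Expects any of `conserved.bed`, `faire.bed`, `h3k4me1.bed`,
#' `h3k27ac.bed`, `tf.bed` (BED6+ with extra columns `cell_type` and,
#' for histone tracks, `specific` in {0,1}). Absent files yield absent
#' tracks (recorded by the caller's audit, not an error).
#'
#' @param dir Directory path.
#' @return Named list of interval tables (possibly empty).
#' @export
read_evidence_tracks <- function(dir) {
  tracks <- list()
  for (t in c("conserved", "faire", "h3k4me1", "h3k27ac", "tf")) {
    f <- file.path(dir, paste0(t, ".bed"))
    if (!file.exists(f)) next
    extra <- switch(t, h3k4me1 = , h3k27ac = c("cell_type", "specific"),
                    tf = c("cell_type"), c("cell_type"))
    b <- read_bed(f, extra_cols = extra)
    if ("specific" %in% names(b)) b$specific <- b$specific == 1 | b$specific == "1"
    tracks[[t]] <- b
  }
  tracks
}

#' Write evidence tracks produced by the simulator
#' @param tracks Named list of interval tables.
#' @param dir Output directory.
#' @export
write_evidence_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(tracks)) {
    b <- tracks[[t]]
    if (!"name" %in% names(b)) b$name <- t
    if (!"score" %in% names(b)) b$score <- 0
    if ("specific" %in% names(b)) b$specific <- as.integer(b$specific)
    extra <- intersect(c("cell_type", "specific"), names(b))
    write_bed(b, file.path(dir, paste0(t, ".bed")), extra_cols = extra)
  }
  invisible(dir)
}
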