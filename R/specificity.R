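#' Cell-type panel
#'
#' The grouping of cell types into the target lineage (here: erythroid)
#' and the non-target control set that drives specificity classification.
#'
#' @param target,non_target Character vectors of cell-type names; at least
#'   one of each, all names unique.
#' @return Object of class `cell_type_panel`.
#' @examples
#' erythroid_panel()
#' @export
cell_type_panel <- function(target, non_target) {
  stopifnot(length(target) >= 1, length(non_target) >= 1)
  if (anyDuplicated(c(target, non_target)))
    stop("cell_type_panel: cell-type names must be unique")
  structure(list(target = as.character(target),
                 non_target = as.character(non_target)),
            class = "cell_type_panel")
}

#' @describeIn cell_type_panel The published erythroid screen panel: four
#'   erythroid cell types (ESER, FLER, PBER, K562) against seven
#'   non-erythroid ones.
#' @export
erythroid_panel <- function() {
  cell_type_panel(
    target = c("ESER", "FLER", "PBER", "K562"),
    non_target = c("HESC", "GM12878", "hTH2", "HeLa", "HepG2", "CACO2", "BJ"))
}

panel_cells <- function(panel) c(panel$target, panel$non_target)

#' Classify the cell-type specificity of one DHS
#'
#' A site is `target_specific` when its peak is present in at least one
#' target cell type and in no non-target cell type;
#' `putative_target_specific` when present in 1..`max_nontarget_presence`
#' non-target cell types whose peak signals are all much subdued --
#' quantified as below `subdued_ratio` times the weakest present target
#' signal; `non_specific` otherwise (including no target presence at all).
#'
#' @param presence Named logical vector (peak called at the upstream FDR),
#'   one entry per panel cell type. Missing entries are an error; peak
#'   presence is an upstream input property and is never imputed here.
#' @param signal Named non-negative numeric vector of peak signals;
#'   must be positive wherever `presence` is `TRUE`.
#' @param panel A [cell_type_panel()].
#' @param subdued_ratio Fraction in (0,1); default 0.5.
#' @param max_nontarget_presence Maximum tolerated non-target presences
#'   for a putative call; default 2 ("one or two" control cell types).
#' @return List with `label` and `offending_cell_types` (non-target cell
#'   types with presence).
#' @export
classify_specificity <- function(presence, signal, panel,
                                 subdued_ratio = 0.5,
                                 max_nontarget_presence = 2) {
  stopifnot(inherits(panel, "cell_type_panel"),
            subdued_ratio > 0, subdued_ratio < 1,
            max_nontarget_presence >= 0)
  cells <- panel_cells(panel)
  miss <- setdiff(cells, names(presence))
  if (length(miss))
    stop("classify_specificity: missing presence for ", paste(miss, collapse = ", "))
  miss <- setdiff(cells, names(signal))
  if (length(miss))
    stop("classify_specificity: missing signal for ", paste(miss, collapse = ", "))
  if (any(is.na(presence[cells])))
    stop("classify_specificity: NA presence entry")
  if (any(presence[cells] & !(signal[cells] > 0)))
    stop("classify_specificity: presence with non-positive signal")

  pt <- panel$target[presence[panel$target]]
  pn <- panel$non_target[presence[panel$non_target]]
  label <- if (length(pt) == 0) {
    "non_specific"
  } else if (length(pn) == 0) {
    "target_specific"
  } else if (length(pn) <= max_nontarget_presence &&
             all(signal[pn] < subdued_ratio * min(signal[pt]))) {
    "putative_target_specific"
  } else {
    "non_specific"
  }
  list(label = label, offending_cell_types = pn)
}

#' Screen a locus domain for candidate cell-type-specific DHSs
#'
#' Takes one peak set per panel cell type, restricts to peaks overlapping
#' the locus domain, merges the cross-cell-type union into maximal
#' connected intervals (one named DHS per co-located peak stack), clips
#' them to the domain, assigns Roman-numeral identifiers 5' to 3' in
#' locus orientation, and classifies each site with
#' [classify_specificity()]. Peak presence per site and cell type is "any
#' peak of that cell type overlaps the merged site"; the site's signal in
#' that cell type is the maximum overlapping peak score.
#'
#' @param domain A `locus_domain` from [define_locus_domain()].
#' @param peaks Named list (by cell type) of interval tables carrying a
#'   `score` column. Cell types absent from the list have no peaks.
#' @param panel A [cell_type_panel()].
#' @param subdued_ratio,max_nontarget_presence Passed to
#'   [classify_specificity()].
#' @return List with `sites` (audit channel: every merged site with its
#'   label), `candidates` (sites with label != `non_specific`),
#'   `presence` and `signal` (site x cell-type matrices).
#' @export
screen_locus <- function(domain, peaks, panel,
                         subdued_ratio = 0.5, max_nontarget_presence = 2) {
  stopifnot(inherits(domain, "locus_domain"), inherits(panel, "cell_type_panel"))
  cells <- panel_cells(panel)
  unknown <- setdiff(names(peaks), cells)
  if (length(unknown))
    stop("screen_locus: peak sets for cell types outside the panel: ",
         paste(unknown, collapse = ", "))
  empty <- list(
    sites = data.frame(site_id = character(), chrom = character(),
                       start = numeric(), end = numeric(), strand = character(),
                       label = character(), offending_cell_types = character(),
                       stringsAsFactors = FALSE),
    candidates = NULL, presence = NULL, signal = NULL)
  empty$candidates <- empty$sites

  dom <- domain$interval
  inside <- lapply(peaks, function(p) {
    if (is.null(p) || nrow(p) == 0) return(p[0, , drop = FALSE])
    validate_intervals(p)
    if (!"score" %in% names(p)) stop("screen_locus: peaks need a score column")
    p[gi_overlaps(p, dom), , drop = FALSE]
  })
  pooled <- do.call(rbind, lapply(inside, function(p)
    if (is.null(p) || nrow(p) == 0) NULL else p[, c("chrom", "start", "end")]))
  if (is.null(pooled) || nrow(pooled) == 0) return(empty)
  pooled$strand <- "*"
  merged <- gi_reduce(pooled)
  merged$start <- pmax(merged$start, dom$start)
  merged$end <- pmin(merged$end, dom$end)

  n <- nrow(merged)
  presence <- matrix(FALSE, n, length(cells), dimnames = list(NULL, cells))
  signal <- matrix(0, n, length(cells), dimnames = list(NULL, cells))
  for (ct in cells) {
    p <- inside[[ct]]
    if (is.null(p) || nrow(p) == 0) next
    for (i in seq_len(n)) {
      hit <- p$start < merged$end[i] & merged$start[i] < p$end
      if (any(hit)) {
        presence[i, ct] <- TRUE
        signal[i, ct] <- max(p$score[hit])
      }
    }
  }

  # Roman-numeral ids run 5'->3' in locus orientation
  ord <- if (dom$strand == "-") order(-merged$start) else order(merged$start)
  rank <- match(seq_len(n), ord)
  site_id <- paste0(domain$gene_id, "-", as.character(utils::as.roman(rank)))

  calls <- lapply(seq_len(n), function(i)
    classify_specificity(presence[i, ], signal[i, ], panel,
                         subdued_ratio, max_nontarget_presence))
  sites <- data.frame(
    site_id = site_id, chrom = merged$chrom,
    start = merged$start, end = merged$end, strand = dom$strand,
    label = vapply(calls, `[[`, "", "label"),
    offending_cell_types = vapply(calls, function(x)
      paste(x$offending_cell_types, collapse = ","), ""),
    stringsAsFactors = FALSE)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  presence <- presence[ord, , drop = FALSE]
  signal <- signal[ord, , drop = FALSE]
  rownames(presence) <- rownames(signal) <- sites$site_id

  list(sites = sites,
       candidates = sites[sites$label != "non_specific", , drop = FALSE],
       presence = presence, signal = signal)
}
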