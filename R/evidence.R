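#' Join evidence tracks onto candidate sites
#'
#' For each site, overlap (half-open, strand-blind) with the supplied
#' tracks yields a Table-1-style evidence record: conservation
#' (placental-mammal element), FAIRE, H3K4me1/H3K27ac (three-level:
#' `absent`, `present`, `present_target_specific` when the overlapping
#' element carries the target-specificity flag), and GATA-1/NF-E2
#' occupancy from the TF ChIP track. Absent tracks produce all-absent
#' columns and are listed in the `absent_tracks` attribute. Adding track
#' elements can never turn a present field absent (monotonicity).
#'
#' @param sites Interval table with a `site_id` column.
#' @param tracks Named list of interval tables: `conserved`, `faire`,
#'   `h3k4me1`, `h3k27ac` (histone tracks carry a logical `specific`
#'   column), `tf` (columns `name`, `score`, `cell_type`).
#' @param target_cell Cell type whose TF occupancy is reported (default
#'   `"K562"`); rows of `tf` without a `cell_type` column count for any
#'   cell.
#' @return `data.frame` with columns `site_id`, `conserved`, `faire`,
#'   `h3k4me1`, `h3k27ac`, `gata1`, `nfe2`.
#' @export
annotate_evidence <- function(sites, tracks, target_cell = "K562") {
  validate_intervals(sites)
  stopifnot("site_id" %in% names(sites))
  n <- nrow(sites)
  hit <- function(track) {
    if (is.null(track) || nrow(track) == 0) return(rep(FALSE, n))
    gi_overlaps_any(sites, track)
  }
  histone <- function(track) {
    out <- rep("absent", n)
    if (is.null(track) || nrow(track) == 0) return(out)
    out[gi_overlaps_any(sites, track)] <- "present"
    if ("specific" %in% names(track)) {
      sp <- track[isTRUE_v(track$specific), , drop = FALSE]
      out[gi_overlaps_any(sites, sp)] <- "present_target_specific"
    }
    out
  }
  tf <- tracks$tf
  tf_hit <- function(tf_name) {
    if (is.null(tf)) return(rep(FALSE, n))
    sel <- normalize_tf(tf$name) == tf_name
    if ("cell_type" %in% names(tf)) sel <- sel & tf$cell_type == target_cell
    hit(tf[sel, , drop = FALSE])
  }
  out <- data.frame(
    site_id = sites$site_id,
    conserved = hit(tracks$conserved),
    faire = hit(tracks$faire),
    h3k4me1 = histone(tracks$h3k4me1),
    h3k27ac = histone(tracks$h3k27ac),
    gata1 = tf_hit("GATA1"),
    nfe2 = tf_hit("NFE2"),
    stringsAsFactors = FALSE)
  attr(out, "absent_tracks") <-
    setdiff(c("conserved", "faire", "h3k4me1", "h3k27ac", "tf"), names(tracks))
  out
}

isTRUE_v <- function(x) !is.na(x) & (x == TRUE)

normalize_tf <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

#' Site-by-TF cluster-score matrix
#'
#' Entry `[site, tf]` is the maximum ChIP cluster score (0-1000) of that
#' TF overlapping the site in the requested cell type, 0 when none
#' overlaps. Duplicate overlaps of the same TF are resolved by `max`
#' (default) or `sum`.
#'
#' @param sites Interval table with `site_id`.
#' @param tf_clusters Interval table with `name` (TF), `score`, and
#'   optionally `cell_type`.
#' @param cell_type Cell type filter (default `"K562"`).
#' @param aggregate `"max"` (default) or `"sum"`.
#' @return Numeric matrix, rows = site ids, columns = TF names.
#' @export
build_tf_matrix <- function(sites, tf_clusters, cell_type = "K562",
                            aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  validate_intervals(sites)
  stopifnot("site_id" %in% names(sites),
            all(c("name", "score") %in% names(tf_clusters)))
  if (any(tf_clusters$score < 0 | tf_clusters$score > 1000))
    stop("build_tf_matrix: cluster scores must lie in [0, 1000]")
  tfs <- sort(unique(tf_clusters$name))  # columns stable across cell types
  if ("cell_type" %in% names(tf_clusters))
    tf_clusters <- tf_clusters[tf_clusters$cell_type == cell_type, , drop = FALSE]
  m <- matrix(0, nrow(sites), length(tfs),
              dimnames = list(sites$site_id, tfs))
  agg <- if (aggregate == "max") max else sum
  for (j in seq_along(tfs)) {
    tr <- tf_clusters[tf_clusters$name == tfs[j], , drop = FALSE]
    for (i in seq_len(nrow(sites))) {
      ov <- tr$chrom == sites$chrom[i] & tr$start < sites$end[i] &
        sites$start[i] < tr$end
      if (any(ov)) m[i, j] <- agg(tr$score[ov])
    }
  }
  m
}

#' K-means classes of a score matrix, applied to rows and columns
#'
#' Lloyd's algorithm with `n_init` random restarts under a fixed seed,
#' run independently on the rows and on the columns. Cluster labels are
#' relabelled canonically by descending cluster mean score, so the output
#' is stable for a given seed and invariant to row permutation up to that
#' relabelling.
#'
#' @param mat Numeric matrix (e.g., from [build_tf_matrix()]).
#' @param k Number of classes; must not exceed the number of rows
#'   (respectively columns).
#' @param seed RNG seed.
#' @param n_init Random restarts (default 25).
#' @return List with `row_classes` and `col_classes` (named integer
#'   vectors, class 1 = highest mean score) and the within-cluster sums
#'   of squares `row_withinss`/`col_withinss`.
#' @export
kmeans_classes <- function(mat, k, seed = 1, n_init = 25) {
  stopifnot(is.matrix(mat), k >= 1)
  if (k > nrow(mat) || k > ncol(mat))
    stop("kmeans_classes: k exceeds the matrix dimension")
  one <- function(x, k) {
    if (k == 1)
      return(list(cl = stats::setNames(rep(1L, nrow(x)), rownames(x)),
                  wss = sum(scale(x, scale = FALSE)^2)))
    km <- stats::kmeans(x, centers = k, nstart = n_init,
                        iter.max = 100, algorithm = "Lloyd")
    # canonical relabelling: class 1 has the highest mean score
    ord <- order(rowMeans(km$centers), decreasing = TRUE)
    relabel <- match(seq_len(k), ord)
    list(cl = stats::setNames(relabel[km$cluster], rownames(x)),
         wss = sum(km$withinss))
  }
  res <- with_seed_(seed, {
    r <- one(mat, k)
    cl <- one(t(mat), k)
    list(r = r, cl = cl)
  })
  list(row_classes = res$r$cl, col_classes = res$cl$cl,
       row_withinss = res$r$wss, col_withinss = res$cl$wss)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Summarize a screen: decision-tree counts, evidence cross-tabulation,
#' positional histograms
#'
#' Reproduces the screen's summary arithmetic: counts of minP enhancers,
#' target-line promoter enhancers and target-specific enhancers over all
#' candidate sites, and -- over the target-specific set -- how many are
#' conserved, carry H3K4me1 and/or H3K27ac (literal disjunction), carry a
#' target-specific (asterisked) histone mark, and are occupied by GATA-1
#' and/or NF-E2.
#'
#' @param calls `data.frame` with columns `site_id`, `minP_enhancer`,
#'   `promoter_enhancer_<target>` (or `promoter_enhancer`),
#'   `erythroid_specific`, `category`.
#' @param evidence `data.frame` from [annotate_evidence()], covering
#'   exactly the same site ids.
#' @param positions Optional `data.frame` with `site_id`,
#'   `genic_context`, `tss_relation` for positional histograms.
#' @param target_line Target cell line name (default `"K562"`).
#' @return List of class `screen_summary`.
#' @export
summarize_screen <- function(calls, evidence, positions = NULL,
                             target_line = "K562") {
  stopifnot("site_id" %in% names(calls), "site_id" %in% names(evidence))
  if (!setequal(calls$site_id, evidence$site_id) ||
      nrow(calls) != nrow(evidence))
    stop("summarize_screen: calls and evidence cover different site ids")
  if (!is.null(positions) &&
      (!setequal(calls$site_id, positions$site_id)))
    stop("summarize_screen: positions cover different site ids")
  ev <- evidence[match(calls$site_id, evidence$site_id), , drop = FALSE]

  pcol <- paste0("promoter_enhancer_", target_line)
  if (!pcol %in% names(calls)) pcol <- "promoter_enhancer"
  spec <- isTRUE_v(calls$erythroid_specific)
  evs <- ev[spec, , drop = FALSE]
  histone_marked <- evs$h3k4me1 != "absent" | evs$h3k27ac != "absent"
  specific_marked <- evs$h3k4me1 == "present_target_specific" |
    evs$h3k27ac == "present_target_specific"

  hist_over <- function(sel) {
    if (is.null(positions)) return(NULL)
    p <- positions[match(calls$site_id[sel], positions$site_id), , drop = FALSE]
    list(genic_context = table(factor(p$genic_context,
                                      c("intergenic", "intronic", "exonic"))),
         tss_relation = table(factor(p$tss_relation,
                                     c("contains_tss", "proximal", "distal",
                                       "far_distal"))))
  }
  structure(list(
    n_sites = nrow(calls),
    n_minP_enhancers = sum(isTRUE_v(calls$minP_enhancer)),
    n_promoter_enhancers = sum(isTRUE_v(calls[[pcol]])),
    n_erythroid_specific = sum(spec),
    categories = table(factor(calls$category,
                              c("non_enhancer", "minP_only", "promoter_only", "dual"))),
    evidence_over_specific = c(
      conserved = sum(evs$conserved),
      histone_marked = sum(histone_marked),
      target_specific_marked = sum(specific_marked),
      tf_occupied = sum(evs$gata1 | evs$nfe2)),
    positional = list(
      all = hist_over(rep(TRUE, nrow(calls))),
      minP_enhancers = hist_over(isTRUE_v(calls$minP_enhancer)),
      promoter_enhancers = hist_over(isTRUE_v(calls[[pcol]])),
      erythroid_specific = hist_over(spec))
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary>\n")
  cat(sprintf("  sites: %d\n", x$n_sites))
  cat(sprintf("  minP enhancers (fold >= threshold): %d\n", x$n_minP_enhancers))
  cat(sprintf("  promoter enhancers in target line:  %d\n", x$n_promoter_enhancers))
  cat(sprintf("  target-specific enhancers:          %d\n", x$n_erythroid_specific))
  ev <- x$evidence_over_specific
  cat(sprintf("  over the target-specific set: %d conserved, %d histone-marked,\n",
              ev["conserved"], ev["histone_marked"]))
  cat(sprintf("    %d with target-specific marks, %d GATA-1/NF-E2 occupied\n",
              ev["target_specific_marked"], ev["tf_occupied"]))
  invisible(x)
}

#' Serialize a screen summary as JSON
#' @param x A `screen_summary`.
#' @param path Output path.
#' @export
write_screen_summary <- function(x, path) {
  y <- unclass(x)
  y$categories <- as.list(y$categories)
  y$evidence_over_specific <- as.list(y$evidence_over_specific)
  y$positional <- lapply(y$positional, function(p)
    if (is.null(p)) NULL else lapply(p, as.list))
  jsonlite::write_json(y, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
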