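#' RPKM normalization
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `rpkm[g, s] = counts[g, s] / ((length_g / 1e3) * (totals_s / 1e6))`.
#'
#' @param counts Non-negative integer gene x sample matrix.
#' @param lengths Per-gene lengths in bp (> 0), named or in row order.
#' @param totals Per-sample total mapped reads; must be positive and at
#'   least the column sums of `counts`.
#' @return gene x sample numeric matrix.
#' @export
rpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (!is.null(names(totals)) && !is.null(colnames(counts)))
    totals <- totals[colnames(counts)]
  stopifnot(length(lengths) == nrow(counts), length(totals) == ncol(counts))
  if (any(counts < 0)) stop("rpkm: negative counts")
  if (any(lengths <= 0)) stop("rpkm: gene lengths must be positive")
  if (any(totals <= 0)) stop("rpkm: zero or negative library size")
  if (any(colSums(counts) > totals + 1e-8))
    stop("rpkm: total mapped reads below the column sum of counts")
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, totals / 1e6, "/")
}

#' Call genes up-regulated in the target condition
#'
#' A gene is detected when its maximum RPKM across samples reaches the
#' detection floor; undetected genes are not evaluable (`NA`, distinct
#' from `FALSE`). Under the default `"all_strict"` rule a detected gene
#' is up-regulated iff its RPKM in every target sample strictly exceeds
#' the reference sample; the `"mean"` rule compares the mean over target
#' samples instead.
#'
#' @param expr gene x sample RPKM matrix.
#' @param target_samples Column names of the target-condition samples.
#' @param reference_sample Column name of the reference sample.
#' @param floor Detection floor on max RPKM (default 0.01).
#' @param rule `"all_strict"` (default) or `"mean"`.
#' @return Named logical vector with `NA` for undetected genes.
#' @export
call_upregulated <- function(expr, target_samples, reference_sample,
                             floor = 0.01, rule = c("all_strict", "mean")) {
  rule <- match.arg(rule)
  expr <- as.matrix(expr)
  stopifnot(all(c(target_samples, reference_sample) %in% colnames(expr)))
  detected <- apply(expr, 1, max) >= floor
  up <- if (rule == "all_strict") {
    apply(expr[, target_samples, drop = FALSE] >
            expr[, reference_sample], 1, all)
  } else {
    rowMeans(expr[, target_samples, drop = FALSE]) > expr[, reference_sample]
  }
  up[!detected] <- NA
  up
}

#' qPCR relative quantification (delta-delta-Ct)
#'
#' Per replicate, `dCt = Ct_gene - Ct_reference` within the same
#' condition/replicate; `ddCt = dCt - mean(dCt over calibrator
#' replicates)`; fold change `2^(-ddCt)`. Condition-level folds are
#' computed from condition-mean dCt so the calibrator fold is exactly 1.
#' Each gene/condition is tested against the calibrator by a two-sided
#' independent-samples t test on the dCt replicates (pooled variance by
#' default, Welch optionally), with significance tiers (no
#' multiple-testing correction -- raw per-gene p values).
#'
#' @param ct Long-format `data.frame` with columns `gene`, `condition`,
#'   `replicate`, `ct`.
#' @param reference_gene Housekeeping reference (default `"18S"`); its Ct
#'   must be present for every condition/replicate.
#' @param calibrator Calibrator condition (default `"HESC"`).
#' @param var_equal Pooled-variance t test when `TRUE` (default), Welch
#'   otherwise.
#' @param tiers Decreasing significance tiers for the star annotation.
#' @return List with `delta_ct` (long table including `ddct` and `fold`),
#'   `fold` (gene x condition matrix, calibrator column = 1) and `tests`
#'   (gene x condition t statistics, p values and tier stars).
#' @export
qpcr_relative_expression <- function(ct, reference_gene = "18S",
                                     calibrator = "HESC",
                                     var_equal = TRUE,
                                     tiers = c(0.005, 0.001)) {
  need <- c("gene", "condition", "replicate", "ct")
  stopifnot(all(need %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("qpcr_relative_expression: Ct values must be finite and positive")
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0) stop("qpcr_relative_expression: reference gene absent")
  key <- function(d) paste(d$condition, d$replicate, sep = "\r")
  refct <- stats::setNames(ref$ct, key(ref))
  d <- ct[ct$gene != reference_gene, , drop = FALSE]
  if (!calibrator %in% d$condition)
    stop("qpcr_relative_expression: calibrator condition absent")
  miss <- setdiff(unique(key(d)), names(refct))
  if (length(miss))
    stop("qpcr_relative_expression: missing reference-gene Ct for ",
         paste(gsub("\r", "/", miss), collapse = ", "))
  d$dct <- d$ct - refct[key(d)]

  genes <- unique(d$gene)
  conds <- unique(d$condition)
  fold <- matrix(NA_real_, length(genes), length(conds),
                 dimnames = list(genes, conds))
  tests <- NULL
  d$ddct <- NA_real_
  for (g in genes) {
    gi <- d$gene == g
    cal <- d$dct[gi & d$condition == calibrator]
    if (length(cal) == 0)
      stop("qpcr_relative_expression: gene ", g, " has no calibrator replicates")
    d$ddct[gi] <- d$dct[gi] - mean(cal)
    for (cnd in conds) {
      x <- d$dct[gi & d$condition == cnd]
      fold[g, cnd] <- 2^(-(mean(x) - mean(cal)))
      if (cnd == calibrator) next
      if (length(x) >= 2 && length(cal) >= 2) {
        tt <- stats::t.test(x, cal, var.equal = var_equal)
        tests <- rbind(tests, data.frame(
          gene = g, condition = cnd, t = unname(tt$statistic),
          df = unname(tt$parameter), p_value = tt$p.value,
          stringsAsFactors = FALSE))
      }
    }
  }
  d$fold <- 2^(-d$ddct)
  if (!is.null(tests)) {
    tiers <- sort(tiers, decreasing = TRUE)
    tests$significance <- vapply(tests$p_value, function(p)
      strrep("*", 1 + sum(p < tiers)) , "")
    tests$significance[tests$p_value >= tiers[1]] <- ""
  }
  list(delta_ct = d, fold = fold, tests = tests)
}
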