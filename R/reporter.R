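#' Normalized dual-luciferase activity of one construct
#'
#' Per-well activity is firefly/renilla. Wells are nested in transfection
#' batches (a triplicate per transfection, transfections repeated); the
#' construct summary is the unweighted mean of batch means, with the SD
#' reported across all wells.
#'
#' @param wells `data.frame` with columns `batch`, `firefly`, `renilla`.
#' @return List with `mean_ratio` (summary), `sd_ratio`, `batch_means`,
#'   `ratios`, `n_batches`, `n_wells`, and `warnings` (audit trail; a
#'   single-batch construct is recorded, never silently dropped).
#' @export
normalized_activity <- function(wells) {
  stopifnot(all(c("batch", "firefly", "renilla") %in% names(wells)),
            nrow(wells) >= 1)
  if (any(wells$renilla <= 0))
    stop("normalized_activity: renilla must be positive")
  if (any(wells$firefly < 0))
    stop("normalized_activity: firefly must be non-negative")
  ratios <- wells$firefly / wells$renilla
  bm <- tapply(ratios, wells$batch, mean)
  warnings <- character()
  if (length(bm) < 2)
    warnings <- "fewer than 2 transfection batches"
  list(mean_ratio = mean(bm), sd_ratio = stats::sd(ratios),
       batch_means = as.numeric(bm), ratios = ratios,
       n_batches = length(bm), n_wells = nrow(wells),
       warnings = warnings)
}

#' Minimal-promoter enhancer call
#'
#' Fold activation of the candidate construct over the minP-only baseline;
#' the call is positive when the fold reaches the threshold (inclusive:
#' "5 fold or higher"). The threshold 5 corresponds to 2.32 on the log2
#' scale used for display.
#'
#' @param candidate_summary,baseline_summary Mean normalized activities
#'   (from [normalized_activity()]); the baseline must be positive.
#' @param fold_threshold Default 5, calibrated by the HS2 positive
#'   control.
#' @return List with `fold`, `log2_fold`, `enhancer`.
#' @export
call_minP_enhancer <- function(candidate_summary, baseline_summary,
                               fold_threshold = 5) {
  if (!is.finite(baseline_summary) || baseline_summary <= 0)
    stop("call_minP_enhancer: baseline activity must be positive")
  fold <- candidate_summary / baseline_summary
  list(fold = fold, log2_fold = log2(fold),
       enhancer = fold >= fold_threshold)
}

# Pooled one-way ANOVA for exactly two groups; F equals the squared
# pooled-variance t statistic. The zero-variance degenerate case is
# resolved explicitly: identical constant groups give p = 1 (no call).
anova_two_group <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  df2 <- nx + ny - 2
  ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  ssb <- nx * (mean(x) - mean(c(x, y)))^2 + ny * (mean(y) - mean(c(x, y)))^2
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = 1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = 1, df2 = df2, p = 0))
  }
  F <- (ssb / 1) / (ssw / df2)
  list(F = F, df1 = 1, df2 = df2, p = stats::pf(F, 1, df2, lower.tail = FALSE))
}

#' Gene-promoter enhancer call
#'
#' Compares candidate wells against the promoter-only baseline wells of
#' the same cell line by one-way ANOVA on normalized activities (two
#' groups, so F equals the squared pooled t statistic). Activities are
#' reported relative to the baseline mean set to 100%. The call is
#' positive only for a significant increase: `p < alpha` and candidate
#' mean above baseline mean (a significant decrease is not an enhancer).
#'
#' @param candidate_ratios,baseline_ratios Per-well normalized activities
#'   (firefly/renilla), at least 3 wells each.
#' @param alpha Significance level, default 0.01.
#' @return List with `fold_pct` (candidate mean as percent of baseline),
#'   `p_value`, `F`, `enhancer`.
#' @export
call_promoter_enhancer <- function(candidate_ratios, baseline_ratios,
                                   alpha = 0.01) {
  stopifnot(length(candidate_ratios) >= 3, length(baseline_ratios) >= 3)
  base_mean <- mean(baseline_ratios)
  if (base_mean <= 0) stop("call_promoter_enhancer: baseline mean must be positive")
  cand <- 100 * candidate_ratios / base_mean
  base <- 100 * baseline_ratios / base_mean
  a <- anova_two_group(cand, base)
  list(fold_pct = mean(cand), p_value = a$p, F = a$F,
       enhancer = a$p < alpha && mean(cand) > mean(base))
}

#' Cell-type-specific enhancer call
#'
#' A site is a target-cell-specific enhancer when it activates the gene
#' promoter in the target line but in none of the control lines.
#'
#' @param calls Named logical vector of promoter-enhancer calls by cell
#'   line.
#' @param target_line Target cell line (default `"K562"`).
#' @param control_lines Control lines (default `c("HeLa", "HEK293")`);
#'   every control must have been evaluated.
#' @return Logical.
#' @export
call_erythroid_specific <- function(calls, target_line = "K562",
                                    control_lines = c("HeLa", "HEK293")) {
  need <- c(target_line, control_lines)
  miss <- setdiff(need, names(calls))
  if (length(miss) || any(is.na(calls[need])))
    stop("call_erythroid_specific: missing evaluation for ",
         paste(c(miss, need[is.na(calls[need])]), collapse = ", "))
  unname(calls[target_line] && !any(calls[control_lines]))
}

#' Enhancer category from the two promoter routes
#'
#' Cross of the minP call and the gene-promoter call in the target line:
#' `non_enhancer`, `minP_only`, `promoter_only`, or `dual`. Vectorized.
#'
#' @param minP_enhancer,promoter_enhancer Logical vectors.
#' @return Character vector of categories (`NA` where either call is
#'   missing).
#' @export
categorize_site <- function(minP_enhancer, promoter_enhancer) {
  n <- max(length(minP_enhancer), length(promoter_enhancer))
  m <- rep_len(minP_enhancer, n); p <- rep_len(promoter_enhancer, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(m) & !is.na(p)
  out[ok & !m & !p] <- "non_enhancer"
  out[ok & m & !p] <- "minP_only"
  out[ok & !m & p] <- "promoter_only"
  out[ok & m & p] <- "dual"
  out
}

#' Score a dual-luciferase reporter plate
#'
#' Applies the full enhancer decision tree to a plate table. Within the
#' target line, each candidate insert on the minimal promoter is scored
#' against the minP-only baseline by fold threshold
#' ([call_minP_enhancer()]); each candidate on a gene promoter is scored
#' against the promoter-only baseline per cell line by ANOVA
#' ([call_promoter_enhancer()]); sites activating the promoter in the
#' target line but in no control line are called target-specific
#' ([call_erythroid_specific()]). Positive-control inserts (HS2) are
#' scored like candidates but reported separately and never gate other
#' calls.
#'
#' @param plate Plate `data.frame` (see [read_plate()]).
#' @param fold_threshold minP fold threshold (default 5).
#' @param alpha Promoter-call significance level (default 0.01).
#' @param target_line,control_lines Cell lines for the specificity call.
#' @param minp_promoter Name of the minimal promoter (default `"minP"`).
#' @param baseline_insert Insert value marking baselines (default
#'   `"none"`).
#' @param positive_control Insert value of the positive control (default
#'   `"HS2"`).
#' @return List with `calls` (per-site `data.frame`: minP fold + call,
#'   promoter fold/p/call per cell line, specificity, category),
#'   `positive_controls`, and `audit` (intermediate statistics and
#'   warnings).
#' @export
score_reporter_plate <- function(plate, fold_threshold = 5, alpha = 0.01,
                                 target_line = "K562",
                                 control_lines = c("HeLa", "HEK293"),
                                 minp_promoter = "minP",
                                 baseline_insert = "none",
                                 positive_control = "HS2") {
  if (any(plate$renilla <= 0)) stop("score_reporter_plate: renilla must be positive")
  plate$ratio <- plate$firefly / plate$renilla
  lines <- c(target_line, control_lines)
  audit <- list(parameters = list(fold_threshold = fold_threshold, alpha = alpha,
                                  target_line = target_line,
                                  control_lines = control_lines,
                                  multiple_testing_correction = "none"),
                warnings = character())
  note <- function(msg) audit$warnings <<- c(audit$warnings, msg)

  inserts <- setdiff(unique(plate$insert), baseline_insert)
  sites <- setdiff(inserts, positive_control)

  ## minP route (target line only)
  minp <- plate[plate$promoter == minp_promoter & plate$cell_line == target_line, ]
  minp_res <- list()
  if (nrow(minp)) {
    base <- minp[minp$insert == baseline_insert, ]
    if (nrow(base) == 0) stop("score_reporter_plate: minP batch lacks its insert-free baseline")
    bsum <- normalized_activity(base)
    if (length(bsum$warnings)) note(paste0(minp_promoter, "/", target_line,
                                           " baseline: ", bsum$warnings))
    for (ins in intersect(inserts, unique(minp$insert))) {
      csum <- normalized_activity(minp[minp$insert == ins, ])
      if (length(csum$warnings)) note(paste0(ins, " on ", minp_promoter, ": ", csum$warnings))
      minp_res[[ins]] <- c(call_minP_enhancer(csum$mean_ratio, bsum$mean_ratio,
                                              fold_threshold),
                           list(summary = csum))
    }
  }

  ## gene-promoter route, per promoter and cell line
  prom_res <- list()  # [[insert]][[cell_line]]
  for (pr in setdiff(unique(plate$promoter), minp_promoter)) {
    for (cl in intersect(lines, unique(plate$cell_line[plate$promoter == pr]))) {
      d <- plate[plate$promoter == pr & plate$cell_line == cl, ]
      base <- d[d$insert == baseline_insert, ]
      if (nrow(base) == 0)
        stop("score_reporter_plate: promoter ", pr, " in ", cl,
             " lacks its insert-free baseline")
      for (ins in intersect(inserts, unique(d$insert))) {
        r <- call_promoter_enhancer(d$ratio[d$insert == ins], base$ratio, alpha)
        prom_res[[ins]][[cl]] <- r
      }
    }
  }

  build_row <- function(ins) {
    m <- minp_res[[ins]]
    row <- data.frame(site_id = ins,
                      minP_fold = if (is.null(m)) NA_real_ else m$fold,
                      minP_log2_fold = if (is.null(m)) NA_real_ else m$log2_fold,
                      minP_enhancer = if (is.null(m)) NA else m$enhancer,
                      stringsAsFactors = FALSE)
    pr <- prom_res[[ins]]
    for (cl in lines) {
      r <- pr[[cl]]
      row[[paste0("promoter_fold_pct_", cl)]] <- if (is.null(r)) NA_real_ else r$fold_pct
      row[[paste0("promoter_p_", cl)]] <- if (is.null(r)) NA_real_ else r$p_value
      row[[paste0("promoter_enhancer_", cl)]] <- if (is.null(r)) NA else r$enhancer
    }
    pe <- stats::setNames(vapply(lines, function(cl)
      if (is.null(pr[[cl]])) NA else pr[[cl]]$enhancer, logical(1)), lines)
    row$erythroid_specific <- if (any(is.na(pe))) NA else
      call_erythroid_specific(pe, target_line, control_lines)
    row$category <- categorize_site(row$minP_enhancer,
                                    row[[paste0("promoter_enhancer_", target_line)]])
    row
  }

  calls <- do.call(rbind, lapply(sites, build_row))
  pcs <- if (positive_control %in% inserts &&
             (!is.null(minp_res[[positive_control]]) ||
              !is.null(prom_res[[positive_control]])))
    build_row(positive_control) else NULL
  if (!is.null(calls)) rownames(calls) <- NULL
  audit$minP <- minp_res
  audit$promoter <- prom_res
  list(calls = calls, positive_controls = pcs, audit = audit)
}
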