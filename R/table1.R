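#' Path to the packaged published-screen cross-tabulation fixture
#'
#' The packaged TSV transcribes the printed cross-tabulation of the 23
#' candidate sites of the erythroid KLF screen: per-site conservation,
#' FAIRE, histone marks (with `Y*` flagging erythroid-specific
#' modification), GATA-1/NF-E2 occupancy, and the reporter-assay enhancer
#' calls on minP (K562) and on the gene promoter in K562, HeLa and
#' HEK293.
#'
#' @return File path.
#' @export
table1_path <- function() {
  system.file("extdata", "table1_dhs.tsv", package = "dhscreen",
              mustWork = TRUE)
}

#' Read the published cross-tabulation fixture
#'
#' @param path Fixture path (default: the packaged copy).
#' @return `data.frame` with one row per site (`site_id = gene-dhs_id`),
#'   call columns as logicals and histone columns as the three-level
#'   factor used by [annotate_evidence()].
#' @export
read_table1 <- function(path = table1_path()) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("gene", "dhs_id", "cs", "faire", "h3k4me1", "h3k27ac",
            "gata1", "nfe2", "minp", "klfp_k562", "klfp_hela", "klfp_hek293")
  if (!all(need %in% names(d)))
    stop(path, ": fixture needs columns ", paste(need, collapse = ", "))
  yn <- function(x) x == "Y"
  histone <- function(x) c("-" = "absent", "Y" = "present",
                           "Y*" = "present_target_specific")[x]
  data.frame(
    site_id = paste0(d$gene, "-", d$dhs_id),
    gene = d$gene, dhs_id = d$dhs_id,
    conserved = yn(d$cs), faire = yn(d$faire),
    h3k4me1 = unname(histone(d$h3k4me1)),
    h3k27ac = unname(histone(d$h3k27ac)),
    gata1 = yn(d$gata1), nfe2 = yn(d$nfe2),
    minp = yn(d$minp), klfp_k562 = yn(d$klfp_k562),
    klfp_hela = yn(d$klfp_hela), klfp_hek293 = yn(d$klfp_hek293),
    stringsAsFactors = FALSE)
}

#' Replay the enhancer decision tree on pre-made calls
#'
#' "Call-replay" mode: the published table records boolean enhancer calls
#' rather than raw luminescence, so the decision tree
#' ([call_erythroid_specific()], [categorize_site()]) and the summary
#' arithmetic are applied directly to the call columns.
#'
#' @param tbl `data.frame` from [read_table1()].
#' @param target_line,control_lines Cell lines of the specificity rule.
#' @return List with `calls`, `evidence` (both keyed by `site_id`) and
#'   `summary` (a `screen_summary`).
#' @export
replay_table1 <- function(tbl, target_line = "K562",
                          control_lines = c("HeLa", "HEK293")) {
  line_col <- function(cl) paste0("klfp_", tolower(gsub("[^A-Za-z0-9]", "", cl)))
  lines <- c(target_line, control_lines)
  calls <- data.frame(site_id = tbl$site_id,
                      minP_enhancer = tbl$minp,
                      stringsAsFactors = FALSE)
  for (cl in lines)
    calls[[paste0("promoter_enhancer_", cl)]] <- tbl[[line_col(cl)]]
  calls$erythroid_specific <- vapply(seq_len(nrow(tbl)), function(i) {
    pe <- stats::setNames(vapply(lines, function(cl) tbl[[line_col(cl)]][i],
                                 logical(1)), lines)
    call_erythroid_specific(pe, target_line, control_lines)
  }, logical(1))
  calls$category <- categorize_site(
    calls$minP_enhancer, calls[[paste0("promoter_enhancer_", target_line)]])

  evidence <- tbl[, c("site_id", "conserved", "faire", "h3k4me1", "h3k27ac",
                      "gata1", "nfe2")]
  list(calls = calls, evidence = evidence,
       summary = summarize_screen(calls, evidence, target_line = target_line))
}

#' Write a copy of the packaged cross-tabulation fixture
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_table1_fixture <- function(path) {
  file.copy(table1_path(), path, overwrite = TRUE)
  invisible(path)
}
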