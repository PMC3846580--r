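#' Pipeline configuration
#'
#' Collects the screen's tunable parameters and input/output paths.
#' Parameter defaults are the published screen settings: locus domains of
#' 70 kb upstream / 20 kb downstream, minP fold threshold 5, promoter
#' ANOVA alpha 0.01, subdued-peak ratio 0.5 with at most two non-target
#' presences, k = 3 TF classes. The upstream peak-calling FDR (0.5%) is
#' an input property recorded for the run report only.
#'
#' @param inputs Named list of paths: any of `gene_models`, `peaks_dir`,
#'   `counts`, `ct`, `plate`, `tracks_dir`, `table1` (call-replay mode).
#' @param out_dir Output directory.
#' @param panel A [cell_type_panel()] or list with `target`/`non_target`.
#' @param upstream,downstream Locus-domain extents (bp).
#' @param subdued_ratio,max_nontarget_presence Specificity parameters.
#' @param fold_threshold,alpha Reporter-call parameters.
#' @param qpcr_tiers Significance tiers of the qPCR report.
#' @param k TF-matrix k-means classes.
#' @param seed Seed for the k-means restarts.
#' @param target_line,control_lines Reporter cell lines.
#' @param reference_sample Expression reference condition.
#' @param reference_gene qPCR housekeeping gene.
#' @param fdr_note Informational: upstream peak-call FDR.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), out_dir = tempfile("dhscreen_run"),
                            panel = erythroid_panel(),
                            upstream = 70000, downstream = 20000,
                            subdued_ratio = 0.5, max_nontarget_presence = 2,
                            fold_threshold = 5, alpha = 0.01,
                            qpcr_tiers = c(0.005, 0.001), k = 3, seed = 1,
                            target_line = "K562",
                            control_lines = c("HeLa", "HEK293"),
                            reference_sample = "HESC",
                            reference_gene = "18S",
                            fdr_note = 0.005) {
  if (!inherits(panel, "cell_type_panel"))
    panel <- cell_type_panel(panel$target, panel$non_target)
  stopifnot(fold_threshold > 0, alpha > 0, upstream >= 0, downstream >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' File keys mirror the arguments of [pipeline_config()]; unknown keys
#' are an error. YAML support requires the `yaml` package.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(path, ": unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$panel))
    raw$panel <- cell_type_panel(raw$panel$target, raw$panel$non_target)
  do.call(pipeline_config, raw)
}

stage_record <- function(report, stage, status, params = list(),
                         warnings = character(), outputs = character()) {
  digests <- if (length(outputs))
    as.list(tools::md5sum(outputs)) else list()
  report$stages[[stage]] <- list(status = status, parameters = params,
                                 warnings = warnings, outputs = outputs,
                                 digests = digests)
  report
}

#' Run the end-to-end screening pipeline
#'
#' Stages run in order expression -> specificity -> reporter -> evidence
#' -> summary; a stage whose inputs are absent is skipped and recorded in
#' the run report. When `inputs$table1` is set the pipeline runs in
#' call-replay mode: the decision tree and summaries are applied to the
#' pre-made boolean calls of the cross-tabulation fixture instead of raw
#' wells and peaks.
#'
#' @param config A [pipeline_config()] or path to a config file.
#' @return List with the per-stage results and `report` (a run-report
#'   list with parameters, warnings and output digests). Output tables
#'   are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list())
  res <- list()
  tsv <- function(d, name) {
    p <- file.path(cf$out_dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  ## call-replay mode
  if (!is.null(cf$inputs$table1)) {
    tbl <- read_table1(cf$inputs$table1)
    rep1 <- replay_table1(tbl, cf$target_line, cf$control_lines)
    outs <- c(tsv(rep1$calls, "calls.tsv"), tsv(rep1$evidence, "evidence.tsv"))
    sj <- file.path(cf$out_dir, "summary.json")
    write_screen_summary(rep1$summary, sj)
    report <- stage_record(report, "call_replay", "ran",
                           params = list(target_line = cf$target_line,
                                         control_lines = cf$control_lines),
                           outputs = c(outs, sj))
    res <- c(rep1, list(report = report))
    return(res)
  }

  ## expression stage
  if (!is.null(cf$inputs$counts)) {
    cm <- read_count_matrix(cf$inputs$counts)
    expr <- rpkm(cm$counts, cm$lengths, cm$totals)
    targets <- setdiff(colnames(expr), cf$reference_sample)
    up <- call_upregulated(expr, targets, cf$reference_sample)
    res$rpkm <- expr
    res$upregulated <- up
    outs <- c(tsv(data.frame(gene_id = rownames(expr), expr), "rpkm.tsv"),
              tsv(data.frame(gene_id = names(up), upregulated = up),
                  "upregulated.tsv"))
    qout <- character()
    if (!is.null(cf$inputs$ct)) {
      q <- qpcr_relative_expression(read_ct_table(cf$inputs$ct),
                                    reference_gene = cf$reference_gene,
                                    calibrator = cf$reference_sample,
                                    tiers = cf$qpcr_tiers)
      res$qpcr <- q
      qout <- c(tsv(data.frame(gene_id = rownames(q$fold), q$fold), "qpcr_fold.tsv"),
                tsv(q$tests, "qpcr_tests.tsv"))
    }
    report <- stage_record(report, "expression", "ran",
                           params = list(reference_sample = cf$reference_sample,
                                         detection_floor = 0.01),
                           outputs = c(outs, qout))
  } else report <- stage_record(report, "expression", "skipped (no counts input)")

  ## specificity stage
  if (!is.null(cf$inputs$gene_models) && !is.null(cf$inputs$peaks_dir)) {
    genes <- read_gene_models(cf$inputs$gene_models)
    cells <- panel_cells(cf$panel)
    peaks <- list()
    for (ct in cells) {
      f <- file.path(cf$inputs$peaks_dir, paste0(ct, ".bed"))
      if (file.exists(f) && file.size(f) > 0) peaks[[ct]] <- read_bed(f)
    }
    screens <- lapply(genes, function(g) {
      dom <- define_locus_domain(g, cf$upstream, cf$downstream)
      screen_locus(dom, peaks, cf$panel, cf$subdued_ratio,
                   cf$max_nontarget_presence)
    })
    parts <- Filter(Negate(is.null), lapply(names(screens), function(g)
      if (nrow(screens[[g]]$sites))
        cbind(gene_id = g, screens[[g]]$sites, stringsAsFactors = FALSE)
      else NULL))
    sites <- if (length(parts)) do.call(rbind, parts) else data.frame(
      gene_id = character(), site_id = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      label = character(), offending_cell_types = character())
    rownames(sites) <- NULL
    res$sites <- sites
    res$candidates <- sites[sites$label != "non_specific", , drop = FALSE]
    res$screens <- screens

    # positional annotation of every site against its locus gene
    res$positions <- if (nrow(sites)) do.call(rbind, lapply(
      seq_len(nrow(sites)), function(i) {
        ann <- annotate_position(
          genomic_interval(sites$chrom[i], sites$start[i], sites$end[i]),
          genes[[sites$gene_id[i]]], genes)
        data.frame(site_id = sites$site_id[i],
                   genic_context = ann$genic_context,
                   tss_relation = ann$tss_relation,
                   signed_tss_distance = ann$signed_tss_distance,
                   stringsAsFactors = FALSE)
      })) else NULL
    outs <- tsv(sites, "sites.tsv")
    cand_bed <- file.path(cf$out_dir, "candidates.bed")
    if (nrow(res$candidates)) {
      cb <- res$candidates
      cb$name <- cb$site_id; cb$score <- 0
      write_bed(cb, cand_bed)
    } else file.create(cand_bed)
    pos_out <- if (!is.null(res$positions)) tsv(res$positions, "positions.tsv")
    report <- stage_record(report, "specificity", "ran",
                           params = list(upstream = cf$upstream,
                                         downstream = cf$downstream,
                                         subdued_ratio = cf$subdued_ratio,
                                         max_nontarget_presence = cf$max_nontarget_presence,
                                         fdr_note = cf$fdr_note),
                           outputs = c(outs, cand_bed, pos_out))
  } else report <- stage_record(report, "specificity",
                                "skipped (no gene models / peaks input)")

  ## reporter stage
  if (!is.null(cf$inputs$plate)) {
    plate <- read_plate(cf$inputs$plate)
    sc <- score_reporter_plate(plate, cf$fold_threshold, cf$alpha,
                               cf$target_line, cf$control_lines)
    res$reporter <- sc
    outs <- tsv(sc$calls, "reporter_calls.tsv")
    aj <- file.path(cf$out_dir, "reporter_audit.json")
    jsonlite::write_json(
      list(parameters = sc$audit$parameters, warnings = sc$audit$warnings),
      aj, auto_unbox = TRUE, pretty = TRUE)
    report <- stage_record(report, "reporter", "ran",
                           params = sc$audit$parameters,
                           warnings = sc$audit$warnings,
                           outputs = c(outs, aj))
  } else report <- stage_record(report, "reporter", "skipped (no plate input)")

  ## evidence stage
  if (!is.null(cf$inputs$tracks_dir) && !is.null(res$candidates) &&
      nrow(res$candidates)) {
    tracks <- read_evidence_tracks(cf$inputs$tracks_dir)
    ev <- annotate_evidence(res$candidates, tracks, cf$target_line)
    res$evidence <- ev
    outs <- tsv(ev, "evidence.tsv")
    krec <- NULL
    if (!is.null(tracks$tf) && nrow(tracks$tf)) {
      m <- build_tf_matrix(res$candidates, tracks$tf, cf$target_line)
      if (nrow(m) >= cf$k && ncol(m) >= cf$k) {
        res$tf_matrix <- m
        res$tf_classes <- kmeans_classes(m, cf$k, seed = cf$seed)
        kout <- tsv(data.frame(site_id = names(res$tf_classes$row_classes),
                               class = res$tf_classes$row_classes),
                    "tf_classes.tsv")
        outs <- c(outs, kout)
      }
    }
    report <- stage_record(report, "evidence", "ran",
                           params = list(k = cf$k, seed = cf$seed,
                                         absent_tracks = attr(ev, "absent_tracks")),
                           outputs = outs)
  } else report <- stage_record(report, "evidence",
                                "skipped (no tracks input or no candidates)")

  ## summary stage
  if (!is.null(res$reporter) && !is.null(res$evidence)) {
    calls <- res$reporter$calls
    shared <- intersect(calls$site_id, res$evidence$site_id)
    summ <- summarize_screen(calls[calls$site_id %in% shared, , drop = FALSE],
                             res$evidence[res$evidence$site_id %in% shared, ,
                                          drop = FALSE],
                             positions = if (!is.null(res$positions))
                               res$positions[res$positions$site_id %in% shared, ,
                                             drop = FALSE],
                             target_line = cf$target_line)
    res$summary <- summ
    sj <- file.path(cf$out_dir, "summary.json")
    write_screen_summary(summ, sj)
    report <- stage_record(report, "summary", "ran", outputs = sj)
  } else report <- stage_record(report, "summary",
                                "skipped (needs reporter + evidence)")

  jsonlite::write_json(report, file.path(cf$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  res$report <- report
  res
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic screen), `classify-dhs`,
#' `score-reporter`, `annotate`, `summarize` (stage shortcuts via a
#' config file), and `run` (full pipeline). Invoke from a shell as
#' `Rscript -e 'dhscreen::dhscreen_cli()' <subcommand> ...` or via the
#' launcher installed under `inst/cli/dhscreen.R`.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Exit status, invisibly (0 on success); errors abort with a
#'   non-zero status under `Rscript`.
#' @export
dhscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: dhscreen <simulate|classify-dhs|score-reporter|annotate|summarize|run> [options]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  sub <- args[1]; rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "pipeline config file (YAML or JSON)"),
    optparse::make_option("--out", type = "character", default = "dhscreen_out",
                          help = "output directory [default %default]"),
    optparse::make_option("--seed", type = "integer", default = 1,
                          help = "simulation seed [default %default]"),
    optparse::make_option("--n-genes", type = "integer", default = 10,
                          dest = "n_genes", help = "simulated loci [default %default]"))
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = opt_list, usage = usage),
    args = rest)

  run_with_config <- function() {
    if (is.null(opts$config)) stop(sub, " needs --config")
    cfg <- read_pipeline_config(opts$config)
    cfg$out_dir <- opts$out
    run_pipeline(cfg)
  }
  switch(sub,
    simulate = {
      simulate_screen(sim_config(seed = opts$seed, n_genes = opts$n_genes),
                      out_dir = opts$out)
      message("simulated screen written to ", opts$out)
    },
    `classify-dhs` = , `score-reporter` = , annotate = , summarize = ,
    run = {
      out <- run_with_config()
      ran <- names(Filter(function(s) s$status == "ran", out$report$stages))
      message("stages run: ", paste(ran, collapse = ", "))
    },
    stop("unknown subcommand '", sub, "'\n", usage))
  invisible(0L)
}
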