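#' Simulation configuration
#'
#' Parameters of the synthetic screen generator. Defaults state the world
#' the screen design assumes: a panel of four target (erythroid) and
#' seven non-target cell types, locus domains from 70 kb upstream of the
#' TSS to 20 kb downstream of the poly(A) site, triplicate wells repeated
#' over two transfection batches with 10% multiplicative (log-normal)
#' well noise, Poisson read counts, normal Ct noise, and subdued
#' non-target peaks planted at a quarter of the weakest target peak
#' (safely inside the 0.5 classification ratio).
#'
#' Two RNG streams are used: planted *structure* (site layout, labels,
#' enhancer categories, up-regulated gene set, evidence booleans) is
#' drawn from the fixed `structure_seed`, while measurement *noise*
#' (signals, counts, Ct values, luminescence) is drawn from `seed`. A
#' given `seed` therefore fully determines all outputs, and different
#' seeds share identical planted structure counts.
#'
#' @param seed Integer seed for the noise stream.
#' @param n_genes Number of simulated gene loci.
#' @param target_cells,nontarget_cells Panel cell-type names.
#' @param upstream,downstream Locus-domain extents in bp.
#' @param sites_per_locus_lambda Sites per locus are `1 + Poisson(lambda)`.
#' @param specificity_mix Named fractions (sum 1) of planted labels.
#' @param signal_meanlog,signal_sdlog Log-normal base peak signal.
#' @param signal_noise_sdlog Per-cell multiplicative signal jitter (log-sd).
#' @param subdued_level Planted subdued non-target signal as a fraction of
#'   the weakest present target signal.
#' @param target_presence_prob Per-target-cell presence probability for
#'   specific/putative sites (at least one forced).
#' @param expression_samples,reference_sample Expression conditions.
#' @param frac_upregulated,expression_fold Planted up-regulation.
#' @param base_rpkm_meanlog,base_rpkm_sdlog Baseline expression level.
#' @param library_size Total mapped reads per sample.
#' @param qpcr_replicates,qpcr_ct_sd,reference_gene qPCR design.
#' @param category_mix Named fractions (sum 1) of planted enhancer
#'   categories for candidate sites.
#' @param prob_erythroid_specific Probability that a promoter-active
#'   candidate is planted target-specific.
#' @param minp_active_fold,promoter_active_fold,hs2_fold Planted folds.
#' @param well_cv Coefficient of variation of well noise.
#' @param batches,replicates Transfection batches and wells per batch.
#' @param target_line,control_lines Reporter cell lines.
#' @param evidence_probs Planting probabilities for evidence fields, one
#'   set for target-specific enhancers and one for the background.
#' @param tf_extra Additional TF names for the cluster-score matrix.
#' @param tf_bound_prob_enhancer,tf_bound_prob_other Per-TF binding
#'   probabilities by enhancer status.
#' @param chrom_length Simulated chromosome length.
#' @param structure_seed Fixed seed of the structure stream.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 10,
                       target_cells = c("ESER", "FLER", "PBER", "K562"),
                       nontarget_cells = c("HESC", "GM12878", "hTH2", "HeLa",
                                           "HepG2", "CACO2", "BJ"),
                       upstream = 70000, downstream = 20000,
                       sites_per_locus_lambda = 2,
                       specificity_mix = c(target_specific = 0.4,
                                           putative_target_specific = 0.2,
                                           non_specific = 0.4),
                       signal_meanlog = log(100), signal_sdlog = 0.4,
                       signal_noise_sdlog = 0.1,
                       subdued_level = 0.25,
                       target_presence_prob = 0.8,
                       expression_samples = c("HESC", "ESER", "FLER", "PBER"),
                       reference_sample = "HESC",
                       frac_upregulated = 0.5, expression_fold = 4,
                       base_rpkm_meanlog = log(5), base_rpkm_sdlog = 0.5,
                       library_size = 2e7,
                       qpcr_replicates = 3, qpcr_ct_sd = 0.2,
                       reference_gene = "18S",
                       category_mix = c(non_enhancer = 0.35, minP_only = 0.2,
                                        promoter_only = 0.2, dual = 0.25),
                       prob_erythroid_specific = 0.6,
                       minp_active_fold = 8, promoter_active_fold = 3,
                       hs2_fold = 5,
                       well_cv = 0.10, batches = 2, replicates = 3,
                       target_line = "K562",
                       control_lines = c("HeLa", "HEK293"),
                       evidence_probs = list(
                         specific = c(conserved = 0.5, faire = 0.6,
                                      h3k4me1 = 0.9, h3k27ac = 0.8,
                                      specific_mark = 0.7,
                                      gata1 = 0.5, nfe2 = 0.25),
                         background = c(conserved = 0.3, faire = 0.5,
                                        h3k4me1 = 0.7, h3k27ac = 0.6,
                                        specific_mark = 0.2,
                                        gata1 = 0.2, nfe2 = 0.1)),
                       tf_extra = c("TAL1", "GATA2", "JUND", "MAX", "CTCF",
                                    "SP1", "EP300"),
                       tf_bound_prob_enhancer = 0.7,
                       tf_bound_prob_other = 0.3,
                       chrom_length = 500000,
                       structure_seed = 104729) {
  cfg <- as.list(environment())
  if (abs(sum(specificity_mix) - 1) > 1e-8)
    stop("sim_config: specificity_mix fractions must sum to 1")
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop("sim_config: category_mix fractions must sum to 1")
  stopifnot(well_cv >= 0, n_genes >= 1, batches >= 1, replicates >= 1)
  structure(cfg, class = "sim_config")
}

# log-normal multiplier with unit mean and coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate dual-luciferase wells for one construct
#'
#' Well activity is `base * fold` times log-normal noise of unit mean and
#' the given coefficient of variation; renilla carries small independent
#' variation that cancels in the firefly/renilla ratio. Draws from the
#' current RNG state.
#'
#' @param fold Planted activation fold over the baseline.
#' @param base Baseline normalized activity.
#' @param cv Coefficient of variation of the well noise.
#' @param batches,replicates Plate design.
#' @return `data.frame` with `batch`, `replicate`, `firefly`, `renilla`.
#' @export
simulate_wells <- function(fold, base = 100, cv = 0.10,
                           batches = 2, replicates = 3) {
  n <- batches * replicates
  renilla <- stats::rlnorm(n, 0, 0.05)
  ratio <- base * fold * lnorm_noise(n, cv)
  data.frame(batch = rep(seq_len(batches), each = replicates),
             replicate = rep(seq_len(replicates), batches),
             firefly = ratio * renilla, renilla = renilla)
}

# non-overlapping site intervals inside [dom_start, dom_end): one site per
# equal-width slot, with a 1 kb inset so merged sites never touch
place_sites <- function(n, dom_start, dom_end, widths) {
  slot <- floor((dom_end - dom_start) / n)
  if (any(slot < widths + 3000))
    stop("simulate_screen: domain shorter than requested site spacing")
  starts <- vapply(seq_len(n), function(i) {
    lo <- dom_start + (i - 1) * slot + 1000
    hi <- dom_start + i * slot - widths[i] - 1000
    floor(stats::runif(1, lo, hi))
  }, numeric(1))
  data.frame(start = starts, end = starts + widths)
}

sample_mix <- function(n, mix) {
  # deterministic quota by rounded fractions, remainder to the largest
  counts <- floor(mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_ord <- order(mix * n - counts, decreasing = TRUE)
    counts[frac_ord[seq_len(rem)]] <- counts[frac_ord[seq_len(rem)]] + 1
  }
  sample(rep(names(mix), counts))
}

#' Simulate a complete enhancer screen with planted ground truth
#'
#' Generates every input the pipeline consumes -- gene models,
#' per-cell-type peak tables, a read-count matrix, a qPCR Ct table, a
#' dual-luciferase plate table and evidence tracks -- together with a
#' ground-truth ledger covering every generated entity. With all noise
#' parameters at zero the pipeline recovers the ledger exactly; under
#' default noise, recovery rates are the subject of the package's
#' property tests.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all tables are written
#'   in the same plain-text formats the pipeline readers consume.
#' @return List with `genes` (gene models), `peaks` (per cell type),
#'   `counts`/`lengths`/`totals`, `ct`, `plate`, `tracks`, `panel`,
#'   `domains`, `ledger` (`$genes`, `$sites`) and `config`.
#' @export
simulate_screen <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  panel <- cell_type_panel(cf$target_cells, cf$nontarget_cells)
  cells <- panel_cells(panel)

  ## ---- structure stream: everything "planted" ----
  st <- with_seed_(cf$structure_seed, {
    genes <- list(); domains <- list(); site_rows <- NULL
    for (g in seq_len(cf$n_genes)) {
      gid <- sprintf("GENE%03d", g)
      strand <- if (g %% 2 == 0) "-" else "+"
      glen <- 10000 + floor(stats::runif(1, 0, 20000))
      gstart <- 150000
      n_ex <- 2 + stats::rpois(1, 2)
      exw <- 150 + floor(stats::runif(n_ex, 0, 1200))
      if (sum(exw) > 0.6 * glen) exw <- pmax(150, floor(exw * 0.5 * glen / sum(exw)))
      u <- stats::runif(n_ex - 1)
      introns <- 1 + floor((glen - sum(exw) - n_ex) * u / sum(u))
      es <- gstart + cumsum(c(0, exw[-n_ex] + introns))
      ee <- es + exw
      ee[n_ex] <- gstart + glen  # last exon runs to the poly(A) site
      gm <- gene_model(gid, paste0("chr", g), strand, gstart, gstart + glen,
                       exon_starts = es, exon_ends = ee)
      genes[[gid]] <- gm
      domains[[gid]] <- define_locus_domain(gm, cf$upstream, cf$downstream,
                                            cf$chrom_length)
      dom <- domains[[gid]]$interval
      ns <- 1 + stats::rpois(1, cf$sites_per_locus_lambda)
      widths <- 200 + floor(stats::runif(ns, 0, 800))
      pos <- place_sites(ns, dom$start, dom$end, widths)
      pos <- pos[order(pos$start), , drop = FALSE]
      rank <- if (strand == "-") rev(seq_len(ns)) else seq_len(ns)
      site_rows <- rbind(site_rows, data.frame(
        gene_id = gid, site_id = paste0(gid, "-", as.character(utils::as.roman(rank))),
        chrom = dom$chrom, start = pos$start, end = pos$end, strand = strand,
        stringsAsFactors = FALSE))
    }
    site_rows$label <- sample_mix(nrow(site_rows), cf$specificity_mix)

    # planted presence pattern
    nt_count <- integer(nrow(site_rows))
    presence <- matrix(FALSE, nrow(site_rows), length(cells),
                       dimnames = list(site_rows$site_id, cells))
    for (i in seq_len(nrow(site_rows))) {
      tp <- stats::runif(length(cf$target_cells)) < cf$target_presence_prob
      if (!any(tp)) tp[sample.int(length(tp), 1)] <- TRUE
      lab <- site_rows$label[i]
      if (lab == "non_specific") {
        tp[] <- TRUE
        off <- sample(cf$nontarget_cells,
                      3 + sample.int(length(cf$nontarget_cells) - 3, 1) - 1)
      } else if (lab == "putative_target_specific") {
        off <- sample(cf$nontarget_cells, sample(1:2, 1))
      } else off <- character()
      presence[i, cf$target_cells] <- tp
      presence[i, off] <- TRUE
      nt_count[i] <- length(off)
    }

    # candidate sites: reporter categories and specificity
    cand <- site_rows$label != "non_specific"
    category <- rep(NA_character_, nrow(site_rows))
    category[cand] <- sample_mix(sum(cand), cf$category_mix)
    promoter_active <- !is.na(category) & category %in% c("promoter_only", "dual")
    ery <- rep(NA, nrow(site_rows))
    ery[cand] <- FALSE
    ery[promoter_active] <- stats::runif(sum(promoter_active)) <
      cf$prob_erythroid_specific
    leak_line <- rep(NA_character_, nrow(site_rows))
    leak_line[promoter_active & !ery] <-
      sample(cf$control_lines, sum(promoter_active & !ery), replace = TRUE)

    # planted evidence for candidates
    evf <- c("conserved", "faire", "h3k4me1", "h3k27ac", "gata1", "nfe2")
    evm <- matrix(NA, nrow(site_rows), length(evf) + 1,
                  dimnames = list(site_rows$site_id, c(evf, "specific_mark")))
    for (i in which(cand)) {
      p <- if (isTRUE(ery[i])) cf$evidence_probs$specific else
        cf$evidence_probs$background
      evm[i, evf] <- stats::runif(length(evf)) < p[evf]
      evm[i, "specific_mark"] <- (evm[i, "h3k4me1"] || evm[i, "h3k27ac"]) &&
        stats::runif(1) < p["specific_mark"]
    }

    # TF occupancy for the cluster-score matrix
    tfs <- unique(c("GATA1", "NFE2", cf$tf_extra))
    tfb <- matrix(FALSE, nrow(site_rows), length(tfs),
                  dimnames = list(site_rows$site_id, tfs))
    for (i in which(cand)) {
      pb <- if (category[i] %in% c("minP_only", "promoter_only", "dual"))
        cf$tf_bound_prob_enhancer else cf$tf_bound_prob_other
      tfb[i, cf$tf_extra] <- stats::runif(length(cf$tf_extra)) < pb
      tfb[i, "GATA1"] <- isTRUE(evm[i, "gata1"] == 1)
      tfb[i, "NFE2"] <- isTRUE(evm[i, "nfe2"] == 1)
    }

    up <- sample(names(genes), round(cf$frac_upregulated * cf$n_genes))
    list(genes = genes, domains = domains, sites = site_rows,
         presence = presence, nt_count = nt_count, category = category,
         ery = ery, leak_line = leak_line, evm = evm, tfb = tfb,
         upregulated = up)
  })

  ## ---- noise stream ----
  set.seed(cf$seed)
  sub_seeds <- sample.int(2^31 - 2, 5)
  sites <- st$sites
  n_sites <- nrow(sites)

  # 1. peak signals and per-cell-type peak tables
  peaks <- with_seed_(sub_seeds[1], {
    base <- stats::rlnorm(n_sites, cf$signal_meanlog, cf$signal_sdlog)
    signal <- matrix(0, n_sites, length(cells), dimnames = dimnames(st$presence))
    for (i in seq_len(n_sites)) {
      tcells <- cf$target_cells[st$presence[i, cf$target_cells]]
      signal[i, tcells] <- base[i] *
        lnorm_noise(length(tcells), sqrt(exp(cf$signal_noise_sdlog^2) - 1))
      ncells <- cf$nontarget_cells[st$presence[i, cf$nontarget_cells]]
      if (length(ncells)) {
        lev <- if (sites$label[i] == "putative_target_specific")
          cf$subdued_level * min(signal[i, tcells]) else base[i]
        signal[i, ncells] <- lev *
          lnorm_noise(length(ncells), sqrt(exp(cf$signal_noise_sdlog^2) - 1))
      }
    }
    pk <- lapply(stats::setNames(cells, cells), function(ct) {
      sel <- which(st$presence[, ct])
      if (!length(sel))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), name = character(),
                          score = numeric(), strand = character(),
                          stringsAsFactors = FALSE))
      data.frame(chrom = sites$chrom[sel], start = sites$start[sel],
                 end = sites$end[sel],
                 name = paste0(ct, "_pk", seq_along(sel)),
                 score = round(signal[sel, ct], 4), strand = "*",
                 stringsAsFactors = FALSE)
    })
    list(tables = pk, signal = signal)
  })

  # 2. read counts
  gene_ids <- names(st$genes)
  lengths <- vapply(st$genes, function(g) sum(g$exons$end - g$exons$start),
                    numeric(1))
  expr <- with_seed_(sub_seeds[2], {
    base_rpkm <- stats::rlnorm(length(gene_ids), cf$base_rpkm_meanlog,
                               cf$base_rpkm_sdlog)
    names(base_rpkm) <- gene_ids
    rp <- sapply(cf$expression_samples, function(s) {
      f <- ifelse(gene_ids %in% st$upregulated & s != cf$reference_sample,
                  cf$expression_fold, 1)
      base_rpkm * f
    })
    lam <- rp * (lengths / 1e3) * (cf$library_size / 1e6)
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam),
                     dimnames = dimnames(lam))
    counts
  })
  totals <- stats::setNames(rep(cf$library_size, length(cf$expression_samples)),
                            cf$expression_samples)

  # 3. qPCR Ct table
  ct_tab <- with_seed_(sub_seeds[3], {
    rows <- list()
    for (cnd in cf$expression_samples) for (r in seq_len(cf$qpcr_replicates))
      rows[[length(rows) + 1]] <- data.frame(
        gene = cf$reference_gene, condition = cnd, replicate = r,
        ct = 10 + stats::rnorm(1, 0, cf$qpcr_ct_sd / 2))
    base_dct <- 12 + stats::runif(length(gene_ids), -2, 2)
    names(base_dct) <- gene_ids
    for (g in gene_ids) for (cnd in cf$expression_samples) {
      f <- if (g %in% st$upregulated && cnd != cf$reference_sample)
        cf$expression_fold else 1
      for (r in seq_len(cf$qpcr_replicates))
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, condition = cnd, replicate = r,
          ct = 10 + base_dct[g] - log2(f) + stats::rnorm(1, 0, cf$qpcr_ct_sd))
    }
    out <- do.call(rbind, rows)
    # pair each gene well with its same-condition/replicate reference well
    ref <- out[out$gene == cf$reference_gene, ]
    key <- paste(out$condition, out$replicate)
    refct <- stats::setNames(ref$ct, paste(ref$condition, ref$replicate))
    out$ct <- ifelse(out$gene == cf$reference_gene, out$ct,
                     out$ct - 10 + refct[key])
    rownames(out) <- NULL
    out
  })

  # 4. reporter plate
  plate <- with_seed_(sub_seeds[4], {
    lines <- c(cf$target_line, cf$control_lines)
    rows <- list()
    add <- function(promoter, insert, line, fold, base) {
      w <- simulate_wells(fold, base, cf$well_cv, cf$batches, cf$replicates)
      w$construct_id <- paste(promoter, insert, sep = "+")
      w$promoter <- promoter; w$insert <- insert; w$cell_line <- line
      rows[[length(rows) + 1]] <<- w
    }
    cand_idx <- which(!is.na(st$category))
    # minP route in the target line
    add("minP", "none", cf$target_line, 1, 100)
    add("minP", "HS2", cf$target_line, cf$hs2_fold, 100)
    for (i in cand_idx) {
      f <- if (st$category[i] %in% c("minP_only", "dual")) cf$minp_active_fold else 1
      add("minP", sites$site_id[i], cf$target_line, f, 100)
    }
    # gene-promoter route in every line
    for (g in unique(sites$gene_id[cand_idx])) {
      pr <- paste0(g, "-P")
      for (ln in lines) {
        base <- 80
        add(pr, "none", ln, 1, base)
        add(pr, "HS2", ln, 2, base)
        for (i in cand_idx[sites$gene_id[cand_idx] == g]) {
          active <- (st$category[i] %in% c("promoter_only", "dual")) &&
            (ln == cf$target_line ||
               (!isTRUE(st$ery[i]) && identical(st$leak_line[i], ln)))
          add(pr, sites$site_id[i], ln,
              if (active) cf$promoter_active_fold else 1, base)
        }
      }
    }
    out <- do.call(rbind, rows)
    out[, c("construct_id", "promoter", "insert", "cell_line", "batch",
            "replicate", "firefly", "renilla")]
  })

  # 5. evidence tracks
  tracks <- with_seed_(sub_seeds[5], {
    cand_idx <- which(!is.na(st$category))
    el <- function(i, pad = -20) {
      s <- max(sites$start[i] - pad, 0)
      data.frame(chrom = sites$chrom[i], start = sites$start[i] + 20,
                 end = sites$end[i] - 20, strand = "*",
                 stringsAsFactors = FALSE)
    }
    tr <- list()
    pick <- function(field) cand_idx[isTRUE_v(st$evm[cand_idx, field] == 1)]
    mk <- function(idx, name) {
      if (!length(idx)) return(NULL)
      do.call(rbind, lapply(idx, function(i) {
        d <- el(i); d$name <- name; d$score <- 0
        d$cell_type <- "K562"; d
      }))
    }
    tr$conserved <- mk(pick("conserved"), "cons")
    tr$faire <- mk(pick("faire"), "faire")
    for (h in c("h3k4me1", "h3k27ac")) {
      idx <- pick(h)
      if (length(idx)) {
        d <- mk(idx, h)
        d$specific <- isTRUE_v(st$evm[idx, "specific_mark"] == 1)
        tr[[h]] <- d
      }
    }
    tfs <- colnames(st$tfb)
    tf_rows <- list()
    for (i in cand_idx) for (tf in tfs[st$tfb[i, ]]) {
      d <- el(i); d$name <- tf
      d$score <- floor(stats::runif(1, 200, 1001))
      d$cell_type <- "K562"
      tf_rows[[length(tf_rows) + 1]] <- d
    }
    tr$tf <- if (length(tf_rows)) do.call(rbind, tf_rows) else NULL
    tr[!vapply(tr, is.null, logical(1))]
  })

  ## ---- ledger ----
  ledger_sites <- cbind(sites, data.frame(
    planted_category = st$category,
    planted_erythroid_specific = st$ery,
    planted_conserved = st$evm[, "conserved"] == 1,
    planted_faire = st$evm[, "faire"] == 1,
    planted_h3k4me1 = st$evm[, "h3k4me1"] == 1,
    planted_h3k27ac = st$evm[, "h3k27ac"] == 1,
    planted_specific_mark = st$evm[, "specific_mark"] == 1,
    planted_gata1 = st$evm[, "gata1"] == 1,
    planted_nfe2 = st$evm[, "nfe2"] == 1,
    row.names = NULL))
  names(ledger_sites)[names(ledger_sites) == "label"] <- "planted_label"
  ledger_genes <- data.frame(
    gene_id = gene_ids, length = unname(lengths),
    planted_upregulated = gene_ids %in% st$upregulated,
    planted_fold = ifelse(gene_ids %in% st$upregulated, cf$expression_fold, 1),
    stringsAsFactors = FALSE)

  out <- list(genes = st$genes, domains = st$domains,
              peaks = peaks$tables, signal = peaks$signal,
              counts = expr, lengths = lengths, totals = totals,
              ct = ct_tab, plate = plate, tracks = tracks, panel = panel,
              ledger = list(genes = ledger_genes, sites = ledger_sites),
              config = cf)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

#' Write a simulated screen to disk in pipeline-readable formats
#' @param sim Result of [simulate_screen()].
#' @param out_dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE, recursive = TRUE)
  write_gene_models(sim$genes, file.path(out_dir, "gene_models.tsv"))
  for (ct in names(sim$peaks)) {
    p <- sim$peaks[[ct]]
    if (nrow(p) == 0) {
      file.create(file.path(out_dir, "peaks", paste0(ct, ".bed")))
    } else write_bed(p, file.path(out_dir, "peaks", paste0(ct, ".bed")))
  }
  write_count_matrix(sim$counts, sim$lengths, sim$totals,
                     file.path(out_dir, "counts.tsv"))
  utils::write.table(format(sim$ct, digits = 15, scientific = FALSE, trim = TRUE),
                     file.path(out_dir, "ct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(sim$plate, digits = 15, scientific = FALSE, trim = TRUE),
                     file.path(out_dir, "plate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_evidence_tracks(sim$tracks, file.path(out_dir, "tracks"))
  utils::write.table(sim$ledger$sites, file.path(out_dir, "ledger_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ledger$genes, file.path(out_dir, "ledger_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
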