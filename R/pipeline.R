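# End-to-end orchestration: simulate -> quantify -> differential ->
# correlate -> compartments -> enrichment, with a machine-readable run
# report and deterministic outputs under one seed.

#' Build (or load) a pipeline run configuration
#'
#' All printed thresholds of the analysis are defaults and can be
#' overridden: protein/transcript BH level 0.05, transcript fold-change
#' floor 1.0 (log2), low-transcript filter 2.0 RPKM, enrichment cutoffs
#' 0.01 (logistic) / 0.05 (Fisher) / 0.05 (set t), set-size floors 5 / 5 /
#' strictly more than 5.
#'
#' @param n_genes Synthetic study size (default 1000).
#' @param seed Run seed (default 1).
#' @param alpha_protein,alpha_transcript BH significance levels.
#' @param l2fc_min Transcript absolute-L2fc DE threshold.
#' @param rpkm_min Low-abundance transcript exclusion for the pooled model.
#' @param logistic_fdr,fisher_alpha,set_t_q Enrichment cutoffs.
#' @param min_set_size Minimum annotated members (logistic/Fisher; the set
#'   t test uses a strict `>` bound with the same value).
#' @param top_k Rows per direction in the top table (default 30).
#' @param stages Named logical vector toggling pipeline stages.
#' @param sim Optional list of extra arguments for [sim_config()].
#' @param path Optional YAML file to load; its keys override nothing given
#'   explicitly.
#' @return A `run_config` list.
#' @export
run_config <- function(n_genes = 1000L, seed = 1L,
                       alpha_protein = 0.05, alpha_transcript = 0.05,
                       l2fc_min = 1.0, rpkm_min = 2.0,
                       logistic_fdr = 0.01, fisher_alpha = 0.05,
                       set_t_q = 0.05, min_set_size = 5L, top_k = 30L,
                       stages = c(simulate = TRUE, quantify = TRUE,
                                  differential = TRUE, correlate = TRUE,
                                  compartments = TRUE, enrichment = TRUE),
                       sim = list(), path = NULL) {
  cfg <- list(n_genes = n_genes, seed = seed,
              alpha_protein = alpha_protein,
              alpha_transcript = alpha_transcript, l2fc_min = l2fc_min,
              rpkm_min = rpkm_min, logistic_fdr = logistic_fdr,
              fisher_alpha = fisher_alpha, set_t_q = set_t_q,
              min_set_size = min_set_size, top_k = top_k,
              stages = stages, sim = sim)
  if (!is.null(path)) {
    from_file <- yaml::read_yaml(path)
    for (k in names(from_file))
      if (k %in% names(cfg)) cfg[[k]] <- from_file[[k]]
  }
  stopifnot(cfg$alpha_protein > 0, cfg$alpha_protein < 1,
            cfg$alpha_transcript > 0, cfg$alpha_transcript < 1,
            cfg$rpkm_min >= 0, cfg$l2fc_min >= 0)
  class(cfg) <- "run_config"
  cfg
}

.stage_log <- function(report, stage, t0, ...) {
  counts <- list(...)
  message(sprintf("[%s] %.2fs %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(names(counts), unlist(counts), sep = "=",
                        collapse = " ")))
  report$stages[[stage]] <- counts
  report
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulates a paired study, quantifies proteins (filter, isotope
#' correction, emPAI/PAMUS), calls differential proteins (N-/C, P-/C) and
#' transcripts (per group and day), runs the three correlation analyses,
#' compartment summaries for both protein contrasts, and the three
#' enrichment tests on the N-/C protein fold changes. All outputs are
#' written as schema-versioned TSVs; reruns with the same config are
#' byte-identical.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory.
#' @return A `run_report` list with per-stage counts, echoed config and
#'   seed; also written to `report.yaml`.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version =
                   as.character(utils::packageVersion("pamuslink")),
                 seed = cfg$seed, config = cfg[setdiff(names(cfg), "stages")],
                 stages = list())
  on <- function(s) isTRUE(cfg$stages[[s]])

  # --- simulate -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sim_args <- utils::modifyList(list(n_genes = cfg$n_genes,
                                     seed = cfg$seed), cfg$sim)
  scfg <- do.call(sim_config, sim_args)
  study <- simulate_study(scfg, outdir = if (on("simulate")) outdir)
  report <- .stage_log(report, "simulate", t0,
                       genes = scfg$n_genes, psms = nrow(study$psms),
                       rna_samples = ncol(study$counts))

  # --- quantify -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  chan <- grep("^ch", names(study$psms), value = TRUE)
  psms <- filter_identifications(study$psms)
  corrected <- correct_isotope_impurities(as.matrix(psms[, chan]),
                                          scfg$isotope_impurity)
  psms[, chan] <- corrected
  quant <- pamus_quantify(psms, study$db$sequences,
                          design = study$truth$proteome_design)
  write_tsv(quant, file.path(outdir, "protein_quant.tsv"), "protein_quant")
  report <- .stage_log(report, "quantify", t0,
                       psms_kept = nrow(psms),
                       proteins_quantified = nrow(quant))

  # --- differential ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pdes <- study$truth$proteome_design
  de_N <- protein_de(quant, pdes, c("N-", "C"), alpha = cfg$alpha_protein,
                     seed = cfg$seed + 11L)
  de_P <- suppressWarnings(
    protein_de(quant, pdes, c("P-", "C"), alpha = cfg$alpha_protein,
               seed = cfg$seed + 12L))
  write_tsv(rbind(de_N, de_P), file.path(outdir, "de_proteins.tsv"),
            "de_proteins")
  rdes <- study$truth$rna_design
  tr_list <- list()
  for (d in unique(rdes$day)) for (g in c("N-", "P-")) {
    des_d <- rdes[rdes$day == d, ]
    tde <- transcript_de(study$counts[, des_d$sample, drop = FALSE], des_d,
                         c(g, "C"), alpha = cfg$alpha_transcript,
                         l2fc_min = cfg$l2fc_min,
                         seed = cfg$seed + 20L + d)
    tde$contrast <- sprintf("%s/C_day%d", g, d)
    tr_list[[sprintf("%s_d%d", g, d)]] <- tde
  }
  de_tr <- do.call(rbind, tr_list)
  rownames(de_tr) <- NULL
  write_tsv(de_tr, file.path(outdir, "de_transcripts.tsv"),
            "de_transcripts")
  top <- summarize_top_table(de_N, cfg$top_k)
  write_tsv(top, file.path(outdir, "top_proteins_N.tsv"), "top_table")
  report <- .stage_log(report, "differential", t0,
    proteins_tested = nrow(de_N),
    de_proteins_N = sum(de_N$significant),
    de_proteins_P = sum(de_P$significant),
    de_transcripts_N_day3 = sum(tr_list[["N-_d3"]]$significant),
    de_transcripts_P_day3 = sum(tr_list[["P-_d3"]]$significant))

  # --- correlate ------------------------------------------------------
  corr_rows <- list()
  if (on("correlate")) {
    t0 <- as.numeric(Sys.time())
    rpkm <- compute_rpkm(study$counts, study$lengths)
    ann <- study$db$annotations
    # transcript rows are gene ids; relabel with accessions to match quant
    rpkm_acc <- rpkm
    rownames(rpkm_acc) <- ann$accession[match(rownames(rpkm), ann$gene_id)]
    tr_N3 <- tr_list[["N-_d3"]]
    prot_l2fc <- stats::setNames(de_N$l2fc, de_N$feature)
    tr_l2fc <- stats::setNames(
      tr_N3$l2fc, ann$accession[match(tr_N3$feature, ann$gene_id)])
    ca <- l2fc_correlation(prot_l2fc, tr_l2fc)
    tr_P3 <- tr_list[["P-_d3"]]
    tr_l2fc_P <- stats::setNames(
      tr_P3$l2fc, ann$accession[match(tr_P3$feature, ann$gene_id)])
    ca_P <- l2fc_correlation(stats::setNames(de_P$l2fc, de_P$feature),
                             tr_l2fc_P)
    mm <- fit_pooled_mixed_model(quant, rpkm_acc, study$pairing,
                                 rpkm_min = cfg$rpkm_min)
    pg <- per_gene_regressions(quant, rpkm_acc, study$pairing,
                               de_table = de_N)
    census_all <- slope_sign_census(pg)
    census_sig <- if (any(pg$fits$significant))
      slope_sign_census(pg, only_significant = TRUE) else
      list(frac_positive = NA, frac_negative = NA, n = 0L)
    corr_report <- data.frame(
      method = c("l2fc_correlation", "l2fc_correlation",
                 "l2fc_correlation", "mixed_model", "mixed_model",
                 "mixed_model", "per_gene", "per_gene", "per_gene",
                 "per_gene", "per_gene"),
      statistic = c("r_squared_N", "r_squared_P", "n_pairs",
                    "fixed_slope", "pearson_r2", "n_pairs_pooled",
                    "median_r2_all", "median_r2_significant",
                    "frac_positive_slopes_sig", "n_models", "n_sig_models"),
      value = c(ca$r_squared, ca_P$r_squared, ca$n_pairs,
                mm$fixed_slope, mm$pearson_r2, mm$n_pairs,
                pg$median_r2_all, pg$median_r2_significant,
                census_sig$frac_positive, nrow(pg$fits), census_sig$n))
    write_tsv(corr_report, file.path(outdir, "correlation_report.tsv"),
              "correlation_report")
    write_tsv(pg$fits, file.path(outdir, "per_gene_fits.tsv"),
              "per_gene_fits")
    corr_rows <- corr_report
    report <- .stage_log(report, "correlate", t0,
                         pairs_l2fc = ca$n_pairs,
                         pairs_pooled = mm$n_pairs,
                         gene_models = nrow(pg$fits))
  }

  # --- compartments ---------------------------------------------------
  if (on("compartments")) {
    t0 <- as.numeric(Sys.time())
    ann <- study$db$annotations
    assign <- stats::setNames(
      assign_compartment(ann$subcellular_location), ann$accession)
    comp <- rbind(
      compartment_l2fc_distribution(de_N, assign, min_size =
                                      cfg$min_set_size),
      compartment_l2fc_distribution(de_P, assign, min_size =
                                      cfg$min_set_size))
    write_tsv(comp, file.path(outdir, "compartment_summary.tsv"),
              "compartment_summary")
    report <- .stage_log(report, "compartments", t0,
                         compartments = length(unique(comp$compartment)))
  }

  # --- enrichment -----------------------------------------------------
  if (on("enrichment")) {
    t0 <- as.numeric(Sys.time())
    ann <- study$db$annotations
    go_sets <- sets_from_annotations(ann, "go_terms")
    ko_sets <- sets_from_annotations(ann, "ko_terms")
    write_gmt(go_sets, file.path(outdir, "go_sets.gmt"))
    l2fc <- stats::setNames(de_N$l2fc, de_N$feature)
    labels <- stats::setNames(
      ifelse(!de_N$significant, "ns",
             ifelse(de_N$l2fc > 0, "up", "down")), de_N$feature)
    enr <- list()
    enr$logistic <- tryCatch(
      logistic_gsea(l2fc, go_sets, fdr_cutoff = cfg$logistic_fdr,
                    min_members = cfg$min_set_size),
      error = function(e) NULL)
    enr$fisher_up <- tryCatch(
      fisher_enrichment(labels, go_sets, "up", alpha = cfg$fisher_alpha,
                        min_members = cfg$min_set_size),
      error = function(e) NULL)
    enr$fisher_down <- tryCatch(
      fisher_enrichment(labels, go_sets, "down", alpha = cfg$fisher_alpha,
                        min_members = cfg$min_set_size),
      error = function(e) NULL)
    enr$set_t <- tryCatch(
      set_level_test(l2fc, ko_sets, min_members = cfg$min_set_size,
                     q_cutoff = cfg$set_t_q),
      error = function(e) NULL)
    enr <- enr[!vapply(enr, is.null, logical(1L))]
    common <- c("term", "method", "statistic", "p_raw", "q", "direction",
                "n_members", "significant")
    enr_all <- do.call(rbind, lapply(enr, function(e) e[, common]))
    rownames(enr_all) <- NULL
    write_tsv(enr_all, file.path(outdir, "enrichment.tsv"), "enrichment")
    report <- .stage_log(report, "enrichment", t0,
                         terms_tested = nrow(enr_all),
                         terms_significant = sum(enr_all$significant))
  }

  class(report) <- "run_report"
  yaml::write_yaml(.report_as_list(report), file.path(outdir, "report.yaml"))
  report
}

.report_as_list <- function(report) {
  r <- unclass(report)
  r$config <- lapply(r$config, function(v)
    if (is.list(v) || is.matrix(v)) NULL else unname(v))
  r$config <- r$config[!vapply(r$config, is.null, logical(1L))]
  r
}

#' Top-k up- and downregulated features
#'
#' Two blocks of at most `k` rows each, sorted by decreasing absolute log2
#' fold change within direction; ties break by ascending p-value, then
#' lexicographic feature id.
#'
#' @param de_table A `diff_expression` table.
#' @param k Rows per direction (default 30).
#' @return data.frame `direction`, `rank`, `feature`, `l2fc`, `p_raw`.
#' @export
summarize_top_table <- function(de_table, k = 30L) {
  stopifnot(nrow(de_table) > 0L)
  block <- function(df, direction) {
    df <- df[is.finite(df$l2fc), , drop = FALSE]
    df <- df[order(-abs(df$l2fc), df$p_raw, df$feature), , drop = FALSE]
    df <- utils::head(df, k)
    if (nrow(df) == 0L) return(NULL)
    data.frame(direction = direction, rank = seq_len(nrow(df)),
               feature = df$feature, l2fc = df$l2fc, p_raw = df$p_raw,
               row.names = NULL)
  }
  up <- block(de_table[de_table$l2fc > 0, , drop = FALSE], "up")
  down <- block(de_table[de_table$l2fc < 0, , drop = FALSE], "down")
  rbind(up, down)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pamuslink run (seed", x$seed, ")\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-12s %s\n", s,
                paste(names(x$stages[[s]]), unlist(x$stages[[s]]),
                      sep = "=", collapse = " ")))
  }
  invisible(x)
}
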