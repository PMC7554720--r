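# Three complementary transcript-protein association analyses:
# (a) fold-change correlation, (b) pooled linear mixed-effects model with
# per-culture random slopes, (c) per-gene regressions with slope-sign census.

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param counts Gene x sample count matrix.
#' @param lengths Gene lengths in bp (recycled across samples).
#' @param library_sizes Mapped reads per sample; defaults to column sums.
#' @return Matrix of RPKM values, same shape as `counts`.
#' @export
compute_rpkm <- function(counts, lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (length(lengths) != nrow(counts))
    stop("'lengths' must have one entry per gene")
  sweep(counts / (lengths / 1e3), 2L, library_sizes / 1e6, "/")
}

#' Correlation of transcript and protein log2 fold changes
#'
#' Ordinary least squares on gene-matched (protein L2fc, transcript L2fc)
#' pairs; features present in only one of the two vectors are dropped and
#' counted. The slope is for transcript L2fc regressed on protein L2fc
#' (R-squared is orientation-invariant).
#'
#' @param protein_l2fc,transcript_l2fc Named numeric vectors keyed by the
#'   shared gene/protein accession.
#' @return List with `r_squared`, `slope`, `n_pairs`, `n_unmatched`.
#' @export
l2fc_correlation <- function(protein_l2fc, transcript_l2fc) {
  stopifnot(!is.null(names(protein_l2fc)), !is.null(names(transcript_l2fc)))
  shared <- intersect(names(protein_l2fc), names(transcript_l2fc))
  x <- protein_l2fc[shared]
  y <- transcript_l2fc[shared]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 matched finite pairs")
  fit <- stats::lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       n_pairs = length(x),
       n_unmatched = length(protein_l2fc) + length(transcript_l2fc) -
         2L * length(shared) + sum(!ok))
}

# Long paired table of log-abundances for samples present in both assays.
# pairing: data.frame(sample_protein, sample_rna, replicate).
.paired_log_abundance <- function(molpct, rpkm, pairing, rpkm_min = 2.0) {
  genes <- intersect(rownames(molpct), rownames(rpkm))
  pairing <- pairing[pairing$sample_protein %in% colnames(molpct) &
                     pairing$sample_rna %in% colnames(rpkm), , drop = FALSE]
  if (nrow(pairing) == 0L) stop("no sample could be paired across assays")
  long <- do.call(rbind, lapply(seq_len(nrow(pairing)), function(i) {
    data.frame(gene = genes,
               replicate = pairing$replicate[i],
               sample = pairing$sample_protein[i],
               molpct = molpct[genes, pairing$sample_protein[i]],
               rpkm = rpkm[genes, pairing$sample_rna[i]],
               row.names = NULL)
  }))
  n0 <- nrow(long)
  long <- long[long$rpkm >= rpkm_min, , drop = FALSE]
  n_low_rpkm <- n0 - nrow(long)
  n1 <- nrow(long)
  long <- long[long$molpct > 0, , drop = FALSE]
  long$log_molpct <- log(long$molpct)
  long$log_rpkm <- log(long$rpkm)
  attr(long, "n_low_rpkm") <- n_low_rpkm
  attr(long, "n_zero_molpct") <- n1 - nrow(long)
  long
}

#' Pooled mixed-effects model of transcript on protein abundance
#'
#' Pools every gene/sample pair across all matched experimental units and
#' fits `log(RPKM) ~ log(Mol\%)` with random intercepts and random slopes
#' per replicate culture (`~ 1 + log(Mol\%) | replicate`), both axes on the
#' natural-log scale. Pairs with transcript abundance below `rpkm_min`
#' (default 2.0 RPKM) or zero Mol% are excluded. The pooled Pearson
#' R-squared on the same filtered pairs is also reported.
#'
#' @param quant `protein_quant` table or Mol% matrix (proteins x samples).
#' @param rpkm Gene x sample RPKM matrix (shared rownames with `quant`).
#' @param pairing data.frame with columns `sample_protein`, `sample_rna`,
#'   `replicate` matching samples to experimental units.
#' @param rpkm_min Low-abundance transcript exclusion threshold (default 2).
#' @param method `"REML"` (default) or `"ML"`.
#' @return A `mixed_model_fit` list: fixed intercept/slope, slope standard
#'   error and 95% CI, random-effect standard deviations, residual SD,
#'   pooled `pearson_r2`, `n_pairs`, `n_replicates`, exclusion counts, and
#'   the underlying `nlme::lme` fit.
#' @export
fit_pooled_mixed_model <- function(quant, rpkm, pairing, rpkm_min = 2.0,
                                   method = c("REML", "ML")) {
  method <- match.arg(method)
  molpct <- if (is.matrix(quant)) quant else molpct_matrix(quant)
  long <- .paired_log_abundance(molpct, rpkm, pairing, rpkm_min)
  n_rep <- length(unique(long$replicate))
  if (n_rep < 2L)
    stop("mixed model needs >= 2 replicates; use pooled OLS instead")
  ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 200, opt = "optim",
                           returnObject = TRUE)
  fit <- nlme::lme(log_rpkm ~ log_molpct, data = long,
                   random = ~ 1 + log_molpct | replicate,
                   method = method, control = ctrl)
  fx <- nlme::fixef(fit)
  tt <- summary(fit)$tTable
  se <- tt["log_molpct", "Std.Error"]
  vc <- nlme::VarCorr(fit)
  out <- list(
    fixed_intercept = unname(fx[1L]),
    fixed_slope = unname(fx[2L]),
    slope_se = unname(se),
    slope_ci = unname(fx[2L] + c(-1, 1) * stats::qnorm(0.975) * se),
    sd_random_intercept = as.numeric(vc["(Intercept)", "StdDev"]),
    sd_random_slope = as.numeric(vc["log_molpct", "StdDev"]),
    sd_residual = as.numeric(vc["Residual", "StdDev"]),
    pearson_r2 = stats::cor(long$log_molpct, long$log_rpkm)^2,
    n_pairs = nrow(long),
    n_replicates = n_rep,
    n_low_rpkm = attr(long, "n_low_rpkm"),
    n_zero_molpct = attr(long, "n_zero_molpct"),
    lme_fit = fit)
  class(out) <- "mixed_model_fit"
  out
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("Pooled mixed-effects model: log(RPKM) ~ log(Mol%),",
      "random ~1 + log(Mol%) | replicate\n")
  cat(sprintf("  fixed slope %.4f (95%% CI %.4f..%.4f), intercept %.4f\n",
              x$fixed_slope, x$slope_ci[1L], x$slope_ci[2L],
              x$fixed_intercept))
  cat(sprintf("  random SD: intercept %.4f, slope %.4f; residual %.4f\n",
              x$sd_random_intercept, x$sd_random_slope, x$sd_residual))
  cat(sprintf("  pooled Pearson R2 %.4f on %d pairs, %d replicates\n",
              x$pearson_r2, x$n_pairs, x$n_replicates))
  invisible(x)
}

#' Per-gene transcript-protein regressions
#'
#' Fits one ordinary least-squares model per gene, `log(RPKM) ~ log(Mol\%)`,
#' across the matched samples. Genes with fewer than `min_points` usable
#' points or with constant protein abundance are excluded with a reason
#' code. Summaries report the median R-squared over all fitted genes and
#' over the subset whose protein was significantly differentially expressed.
#'
#' @param quant `protein_quant` table or Mol% matrix.
#' @param rpkm Gene x sample RPKM matrix.
#' @param pairing Sample pairing as in [fit_pooled_mixed_model()].
#' @param de_table Optional `diff_expression` table supplying the
#'   significant-protein flag.
#' @param min_points Minimum matched points per gene (default 3).
#' @param rpkm_min Pair-level RPKM exclusion threshold (default 0: per-gene
#'   fits use all matched samples unless excluded by zeros).
#' @return A `gene_pair_fits` list: `fits` data.frame (gene, slope,
#'   intercept, r_squared, n_points, significant), `excluded` data.frame
#'   (gene, reason), `median_r2_all`, `median_r2_significant`.
#' @export
per_gene_regressions <- function(quant, rpkm, pairing, de_table = NULL,
                                 min_points = 3L, rpkm_min = 0) {
  molpct <- if (is.matrix(quant)) quant else molpct_matrix(quant)
  long <- .paired_log_abundance(molpct, rpkm, pairing, rpkm_min)
  sig <- if (is.null(de_table)) character(0L) else
    de_table$feature[de_table$significant]
  rows <- list(); excl <- list()
  for (d in split(long, long$gene)) {
    g <- d$gene[1L]
    if (nrow(d) < min_points) {
      excl[[g]] <- "too_few_points"; next
    }
    x <- d$log_molpct; y <- d$log_rpkm
    if (stats::sd(x) == 0) {
      excl[[g]] <- "constant_protein"; next
    }
    if (stats::sd(y) == 0) {
      excl[[g]] <- "constant_transcript"; next
    }
    slope <- stats::cov(x, y) / stats::var(x)   # closed-form simple OLS
    rows[[g]] <- data.frame(
      gene = g, slope = slope, intercept = mean(y) - slope * mean(x),
      r_squared = stats::cor(x, y)^2, n_points = nrow(d),
      significant = g %in% sig, row.names = NULL)
  }
  fits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), slope = numeric(),
               intercept = numeric(), r_squared = numeric(),
               n_points = integer(), significant = logical())
  rownames(fits) <- NULL
  excluded <- data.frame(gene = names(excl),
                         reason = unlist(excl, use.names = FALSE))
  out <- list(
    fits = fits, excluded = excluded,
    median_r2_all = if (nrow(fits)) stats::median(fits$r_squared) else NA_real_,
    median_r2_significant = if (any(fits$significant))
      stats::median(fits$r_squared[fits$significant]) else NA_real_)
  class(out) <- "gene_pair_fits"
  out
}

#' @export
print.gene_pair_fits <- function(x, ...) {
  cat(sprintf("Per-gene regressions: %d fitted, %d excluded\n",
              nrow(x$fits), nrow(x$excluded)))
  cat(sprintf("  median R2 (all) %.3f; median R2 (significant proteins) %.3f\n",
              x$median_r2_all, x$median_r2_significant))
  invisible(x)
}

#' Census of per-gene regression slope signs
#'
#' @param fits A `gene_pair_fits` object or its `fits` data.frame.
#' @param only_significant Restrict to genes whose protein was significantly
#'   differentially expressed (default FALSE).
#' @return List with `frac_positive`, `frac_negative`, `n` (genes with a
#'   defined nonzero slope).
#' @export
slope_sign_census <- function(fits, only_significant = FALSE) {
  f <- if (inherits(fits, "gene_pair_fits")) fits$fits else fits
  if (only_significant) f <- f[f$significant, , drop = FALSE]
  slopes <- f$slope[is.finite(f$slope) & f$slope != 0]
  if (length(slopes) == 0L) stop("no fits with a defined nonzero slope")
  list(frac_positive = mean(slopes > 0),
       frac_negative = mean(slopes < 0),
       n = length(slopes))
}
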