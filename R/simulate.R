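# Synthetic paired proteome/transcriptome study generator with recorded
# ground truth: protein FASTA, PSM table with 10-plex reporter intensities,
# negative-binomial transcript counts, annotations and design sheets.

.TMT_LABELS <- c("126", "127N", "127C", "128N", "128C",
                 "129N", "129C", "130N", "130C", "131")

# Approximate natural amino-acid frequencies; K+R ~ 11% keeps tryptic
# fragments short enough that most proteins yield several observable
# peptides.
.AA_FREQ <- c(
  A = 0.082, R = 0.055, N = 0.040, D = 0.054, C = 0.014, Q = 0.039,
  E = 0.062, G = 0.072, H = 0.022, I = 0.053, L = 0.096, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.054, W = 0.011,
  Y = 0.029, V = 0.069)

#' Default TMT 10-plex isotope impurity matrix
#'
#' Column j describes how label j's reporter signal distributes over the
#' observed channels: 95% in its own channel, 3% bleeding into the next
#' heavier channel and 2% into the next lighter one (edge channels lose the
#' out-of-range fraction), a simplified manufacturer-style purity profile.
#'
#' @param n Number of channels (default 10).
#' @return n x n mixing matrix.
#' @export
default_impurity_matrix <- function(n = 10L) {
  m <- diag(0.95, n)
  for (j in seq_len(n)) {
    if (j > 1L) m[j - 1L, j] <- 0.02
    if (j < n) m[j + 1L, j] <- 0.03
  }
  dimnames(m) <- list(.TMT_LABELS[seq_len(n)], .TMT_LABELS[seq_len(n)])
  m
}

#' Configuration for the synthetic paired-study generator
#'
#' Defaults emulate a turbidostat nutrient-deprivation design: 10 TMT
#' proteome channels (control 4, nitrogen-deprived 4, phosphorus-deprived
#' 2, sampled at day 3) against 12 transcriptome cultures sampled at days
#' 3 and 5 (4 replicates per group), a strong broad N- contrast and a weak
#' sparse P- contrast, a mixture of positively coupled, negatively coupled
#' and uncoupled genes, and a plastid-specific depression of protein
#' abundance under N deprivation.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_replicates Named integer vector of proteome channels per group,
#'   default `c("C" = 4, "N-" = 4, "P-" = 2)`.
#' @param n_rna_replicates Transcriptome replicates per group (default 4).
#' @param days Sampling days for the transcriptome (default `c(3, 5)`);
#'   the proteome is sampled at the first day.
#' @param frac_affected_N,frac_affected_P Fraction of genes with a true
#'   treatment effect in each contrast (defaults 0.45 and 0.03).
#' @param effect_sd_N,effect_sd_P Scale of true log2 effects (defaults 1.0
#'   and 0.5); affected genes draw `|delta| ~ effect_sd * U(0.5, 2)` with a
#'   random sign (60% down under deprivation).
#' @param day5_scale Day-5 effects are the day-3 effects scaled by this
#'   factor, same direction (default 1.6).
#' @param coupling_mix Named fractions `c(positive, negative, null)` of the
#'   transcript-to-protein coupling-sign mixture; must sum to 1.
#' @param coupling_noise_sd SD of the protein-level log2 noise around the
#'   coupled response (default 0.15).
#' @param pool_slope,pool_intercept,pool_resid_sd Cross-gene relation
#'   between baseline log2 mRNA and log2 protein abundance
#'   (`mrna = intercept + slope * protein + N(0, resid_sd)`), the quantity
#'   the pooled mixed model estimates.
#' @param bio_sd Per-sample biological log2 noise (default 0.25).
#' @param compartment_shift Named list per group of named compartment
#'   protein log2 shifts; default `list("N-" = c(plastid = -0.42))`.
#' @param reporter_noise_cv Coefficient of variation of multiplicative
#'   reporter-ion noise (default 0.1).
#' @param isotope_impurity Channel mixing matrix applied to the true
#'   reporter intensities (default [default_impurity_matrix()]).
#' @param frac_single_peptide Fraction of proteins observed with exactly
#'   one unique peptide, exercising the identification filter
#'   (default 0.10).
#' @param low_confidence_frac Fraction of proteins given sub-threshold
#'   identification confidence (default 0.02).
#' @param seq_length_range Protein length range in amino acids.
#' @param count_depth Total mapped reads per transcript sample
#'   (default 2e6).
#' @param dispersion Negative-binomial overdispersion of counts (0 gives
#'   Poisson counts; default 0.05).
#' @param missing_rate Fraction of protein/channel observations zeroed out
#'   (default 0: complete observation).
#' @param seed Integer seed fixing all downstream draws.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes,
                       n_replicates = c("C" = 4L, "N-" = 4L, "P-" = 2L),
                       n_rna_replicates = 4L,
                       days = c(3L, 5L),
                       frac_affected_N = 0.45,
                       frac_affected_P = 0.03,
                       effect_sd_N = 1.0,
                       effect_sd_P = 0.5,
                       day5_scale = 1.6,
                       coupling_mix = c(positive = 0.55, negative = 0.15,
                                        null = 0.30),
                       coupling_noise_sd = 0.15,
                       pool_slope = 0.8,
                       pool_intercept = 0.5,
                       pool_resid_sd = 1.0,
                       bio_sd = 0.25,
                       compartment_shift = list("N-" = c(plastid = -0.42)),
                       reporter_noise_cv = 0.1,
                       isotope_impurity = default_impurity_matrix(),
                       frac_single_peptide = 0.10,
                       low_confidence_frac = 0.02,
                       seq_length_range = c(120L, 600L),
                       count_depth = 2e6,
                       dispersion = 0.05,
                       missing_rate = 0,
                       seed = 1L) {
  if (n_genes < 1L) stop("'n_genes' must be >= 1")
  fracs <- c(frac_affected_N, frac_affected_P, frac_single_peptide,
             low_confidence_frac, missing_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(coupling_mix) - 1) > 1e-8)
    stop("'coupling_mix' must sum to 1")
  if (any(coupling_mix < 0)) stop("'coupling_mix' fractions must be >= 0")
  isotope_impurity <- as.matrix(isotope_impurity)
  if (nrow(isotope_impurity) != ncol(isotope_impurity))
    stop("impurity matrix must be square")
  if (any(isotope_impurity < 0))
    stop("impurity matrix entries must be nonnegative")
  if (count_depth <= 0) stop("'count_depth' must be positive")
  if (seed >= 2^31 - 100) stop("'seed' too large")
  cfg <- list(n_genes = as.integer(n_genes), n_replicates = n_replicates,
              n_rna_replicates = as.integer(n_rna_replicates), days = days,
              frac_affected_N = frac_affected_N,
              frac_affected_P = frac_affected_P,
              effect_sd_N = effect_sd_N, effect_sd_P = effect_sd_P,
              day5_scale = day5_scale, coupling_mix = coupling_mix,
              coupling_noise_sd = coupling_noise_sd,
              pool_slope = pool_slope, pool_intercept = pool_intercept,
              pool_resid_sd = pool_resid_sd, bio_sd = bio_sd,
              compartment_shift = compartment_shift,
              reporter_noise_cv = reporter_noise_cv,
              isotope_impurity = isotope_impurity,
              frac_single_peptide = frac_single_peptide,
              low_confidence_frac = low_confidence_frac,
              seq_length_range = seq_length_range,
              count_depth = count_depth, dispersion = dispersion,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.COMPARTMENTS <- c(plastid = 0.25, mitochondrion = 0.12,
                   `endoplasmic reticulum` = 0.08, membrane = 0.15,
                   cytoplasm = 0.20, nucleus = 0.10, unannotated = 0.10)

.LOCATION_STRING <- c(
  plastid = "Plastid, chloroplast stroma",
  mitochondrion = "Mitochondrion matrix",
  `endoplasmic reticulum` = "Endoplasmic reticulum membrane",
  membrane = "Cell membrane; Single-pass membrane protein",
  cytoplasm = "Cytoplasm, cytosol",
  nucleus = "Nucleus",
  unannotated = "")

#' Generate the gene-level ground truth and latent per-sample abundances
#'
#' Draws, per gene: baseline log2 abundances (protein baseline, and mRNA
#' baseline linearly tied to it with the configured pooled slope), the
#' transcript-to-protein coupling coefficient kappa (sign from
#' `coupling_mix`, magnitude near 1), true treatment effects per contrast
#' and day (protein response = kappa x mRNA response, plus any compartment
#' shift), compartment membership, and the latent log2 abundance matrices
#' for every transcript sample and proteome channel.
#'
#' @param cfg A [sim_config()].
#' @return A `ground_truth` list: `genes` data.frame, `mrna_log2` and
#'   `protein_log2` latent matrices, `rna_design`, `proteome_design`.
#' @export
generate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("SYNG%05d", seq_len(n))
  accession <- sprintf("SYNP%05d", seq_len(n))

  protein_base <- stats::rnorm(n, mean = 1.0, sd = 1.0)
  mrna_base <- cfg$pool_intercept + cfg$pool_slope * protein_base +
    stats::rnorm(n, sd = cfg$pool_resid_sd)

  sign_mix <- sample(c(1, -1, 0), n, replace = TRUE,
                     prob = cfg$coupling_mix[c("positive", "negative",
                                              "null")])
  kappa <- sign_mix * stats::runif(n, 0.6, 1.4)

  compartment <- sample(names(.COMPARTMENTS), n, replace = TRUE,
                        prob = .COMPARTMENTS)

  draw_effects <- function(frac, sd) {
    affected <- stats::runif(n) < frac
    s <- ifelse(stats::runif(n) < 0.6, -1, 1)   # deprivation mostly down
    delta <- ifelse(affected, s * sd * stats::runif(n, 0.5, 2), 0)
    list(affected = affected, delta = delta)
  }
  eff_N <- draw_effects(cfg$frac_affected_N, cfg$effect_sd_N)
  eff_P <- draw_effects(cfg$frac_affected_P, cfg$effect_sd_P)

  shift_for <- function(group) {
    sh <- cfg$compartment_shift[[group]]
    out <- numeric(n)
    if (!is.null(sh)) {
      idx <- compartment %in% names(sh)
      out[idx] <- sh[compartment[idx]]
    }
    out
  }

  genes <- data.frame(
    gene_id = gene_id, accession = accession, compartment = compartment,
    length_aa = sample(cfg$seq_length_range[1L]:cfg$seq_length_range[2L],
                       n, replace = TRUE),
    mrna_base_log2 = mrna_base, protein_base_log2 = protein_base,
    kappa = kappa, slope_sign = sign(kappa),
    affected_N = eff_N$affected, affected_P = eff_P$affected,
    delta_N_day3 = eff_N$delta, delta_N_day5 = eff_N$delta * cfg$day5_scale,
    delta_P_day3 = eff_P$delta, delta_P_day5 = eff_P$delta * cfg$day5_scale,
    shift_N = shift_for("N-"), shift_P = shift_for("P-"))
  genes$length_bp <- genes$length_aa * 3L +
    sample(100:600, n, replace = TRUE)       # UTRs etc.

  groups <- names(cfg$n_replicates)
  rna_design <- expand.grid(replicate = seq_len(cfg$n_rna_replicates),
                            group = groups, day = cfg$days,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  rna_design$sample <- sprintf("%s%d_d%d", sub("-", "", rna_design$group),
                               rna_design$replicate, rna_design$day)
  rna_design <- rna_design[, c("sample", "group", "day", "replicate")]

  proteome_design <- do.call(rbind, lapply(groups, function(g)
    data.frame(group = g, replicate = seq_len(cfg$n_replicates[[g]]))))
  proteome_design$day <- cfg$days[1L]
  proteome_design$sample <- sprintf("%s%d_prot",
                                    sub("-", "", proteome_design$group),
                                    proteome_design$replicate)
  proteome_design$tmt_label <- .TMT_LABELS[seq_len(nrow(proteome_design))]
  proteome_design <- proteome_design[, c("sample", "group", "day",
                                         "replicate", "tmt_label")]

  delta_of <- function(group, day) {
    col <- switch(group, "C" = NULL,
                  "N-" = paste0("delta_N_day", day),
                  "P-" = paste0("delta_P_day", day))
    if (is.null(col)) numeric(n) else genes[[col]]
  }
  shift_of <- function(group)
    switch(group, "C" = numeric(n), "N-" = genes$shift_N,
           "P-" = genes$shift_P)

  mrna_log2 <- matrix(unlist(lapply(seq_len(nrow(rna_design)), function(i) {
    with(rna_design[i, ],
         genes$mrna_base_log2 + delta_of(group, day) +
           stats::rnorm(n, sd = cfg$bio_sd))
  })), nrow = n, dimnames = list(gene_id, rna_design$sample))

  protein_log2 <- matrix(
    unlist(lapply(seq_len(nrow(proteome_design)), function(i) {
      with(proteome_design[i, ],
           genes$protein_base_log2 + genes$kappa * delta_of(group, day) +
             shift_of(group) + stats::rnorm(n, sd = cfg$coupling_noise_sd))
    })), nrow = n, dimnames = list(accession, proteome_design$sample))

  out <- list(config = cfg, genes = genes, mrna_log2 = mrna_log2,
              protein_log2 = protein_log2, rna_design = rna_design,
              proteome_design = proteome_design)
  class(out) <- "ground_truth"
  out
}

#' Generate the synthetic protein database and annotation table
#'
#' One random protein sequence per gene over the 20 canonical amino acids
#' (natural-like composition, so tryptic digestion yields several
#' observable peptides for nearly every protein), plus an annotation table
#' with GO terms, KO terms and a UniProt-style subcellular-location string
#' per accession.
#'
#' @param cfg A [sim_config()].
#' @param truth Optional [generate_ground_truth()] result (regenerated from
#'   `cfg` when missing, so the same seed gives the same database).
#' @return List with `sequences` (named character vector) and
#'   `annotations` data.frame (`accession`, `gene_id`, `go_terms`,
#'   `ko_terms`, `subcellular_location`).
#' @export
generate_protein_db <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- generate_ground_truth(cfg)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  genes <- truth$genes
  sequences <- vapply(genes$length_aa, function(len)
    paste(sample(names(.AA_FREQ), len, replace = TRUE, prob = .AA_FREQ),
          collapse = ""), character(1L))
  names(sequences) <- genes$accession

  n_go <- max(10L, n %/% 8L)
  go_pool <- sprintf("GO:%07d", sample.int(9999999L, n_go))
  n_ko <- max(5L, n %/% 25L)
  ko_pool <- sprintf("KO:%05d", sample.int(99999L, n_ko))
  go_terms <- vapply(seq_len(n), function(i)
    paste(sample(go_pool, min(n_go, stats::rpois(1L, 2))), collapse = ";"),
    character(1L))
  ko_terms <- vapply(seq_len(n), function(i)
    paste(sample(ko_pool, stats::rbinom(1L, 2L, 0.35)), collapse = ";"),
    character(1L))

  annotations <- data.frame(
    accession = genes$accession, gene_id = genes$gene_id,
    go_terms = go_terms, ko_terms = ko_terms,
    subcellular_location = unname(.LOCATION_STRING[genes$compartment]))
  list(sequences = sequences, annotations = annotations)
}

#' Simulate the peptide-spectrum-match table with reporter intensities
#'
#' Each protein contributes a random subset of its observable tryptic
#' peptides (a configured fraction yields exactly one unique peptide, so
#' the identification filter is exercised; detection probability rises with
#' protein abundance, giving emPAI its abundance signal). Every PSM carries
#' 10 reporter intensities: true per-channel abundance x a fixed lognormal
#' peptide response factor x multiplicative noise, then mixed by the
#' isotope impurity matrix.
#'
#' @param cfg A [sim_config()].
#' @param truth A [generate_ground_truth()] result.
#' @param db A [generate_protein_db()] result.
#' @return PSM data.frame: `spectrum_id`, `peptide`, `accession`,
#'   `peptide_prob`, `protein_prob`, `decoy` and one `ch<label>` intensity
#'   column per TMT channel.
#' @export
simulate_psm_table <- function(cfg, truth, db) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  impurity <- cfg$isotope_impurity
  if (nrow(impurity) != nrow(truth$proteome_design))
    stop("impurity matrix dimension does not match the number of channels")
  set.seed(cfg$seed + 2L)
  n <- cfg$n_genes
  genes <- truth$genes
  abundance <- 2^truth$protein_log2      # accession x channel, linear scale
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(abundance)) < cfg$missing_rate,
                   nrow = nrow(abundance))
    abundance[drop] <- 0
  }
  sdlog <- sqrt(log(1 + cfg$reporter_noise_cv^2))
  abundance_rank <- rank(genes$protein_base_log2) / n
  detect_p <- 0.15 + 0.55 * abundance_rank    # more abundant => more peptides

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- genes$accession[i]
    obs_peps <- digest_protein(db$sequences[[acc]], 0L)
    m <- peptide_mass(obs_peps)
    obs_peps <- obs_peps[m >= 500 & m <= 5000]
    if (length(obs_peps) == 0L) next
    if (stats::runif(1L) < cfg$frac_single_peptide) {
      k <- 1L
    } else {
      k <- min(length(obs_peps),
               2L + stats::rbinom(1L, max(0L, length(obs_peps) - 2L),
                                  detect_p[i]))
    }
    peps <- sample(obs_peps, k)
    resp <- stats::rlnorm(k, meanlog = 0, sdlog = 0.5)  # fixed per peptide
    n_psm <- 1L + stats::rpois(k, 0.5)
    pep_idx <- rep(seq_len(k), n_psm)
    true_int <- 1e3 * outer(resp[pep_idx], abundance[acc, ])
    noise <- matrix(stats::rlnorm(length(true_int), -sdlog^2 / 2, sdlog),
                    nrow = nrow(true_int))
    raw <- t(impurity %*% t(true_int * noise))
    colnames(raw) <- paste0("ch", .TMT_LABELS[seq_len(ncol(raw))])
    rows[[i]] <- data.frame(peptide = peps[pep_idx], accession = acc,
                            raw, check.names = FALSE)
  }
  psms <- do.call(rbind, rows)
  psms <- data.frame(spectrum_id = sprintf("scan%06d", seq_len(nrow(psms))),
                     psms, check.names = FALSE, row.names = NULL)
  low_conf_acc <- genes$accession[stats::runif(n) < cfg$low_confidence_frac]
  psms$peptide_prob <- 1.0
  psms$protein_prob <- ifelse(psms$accession %in% low_conf_acc, 0.5, 1.0)
  psms$decoy <- FALSE
  psms
}

#' Simulate the gene-level transcript count matrix
#'
#' Counts are negative-binomial with mean proportional to the latent
#' expression times gene length, scaled to the configured sequencing depth
#' per sample; `dispersion = 0` gives the Poisson limit.
#'
#' @param cfg A [sim_config()].
#' @param truth A [generate_ground_truth()] result.
#' @return List with `counts` (gene x sample integer matrix) and `lengths`
#'   (named bp vector).
#' @export
simulate_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  if (cfg$count_depth <= 0) stop("'count_depth' must be positive")
  set.seed(cfg$seed + 3L)
  w <- 2^truth$mrna_log2 * truth$genes$length_bp
  mu <- sweep(w, 2L, colSums(w), "/") * cfg$count_depth
  counts <- if (cfg$dispersion <= 0) {
    matrix(stats::rpois(length(mu), as.vector(mu)), nrow = nrow(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                          size = 1 / cfg$dispersion), nrow = nrow(mu))
  }
  dimnames(counts) <- dimnames(truth$mrna_log2)
  lengths <- stats::setNames(truth$genes$length_bp, truth$genes$gene_id)
  list(counts = counts, lengths = lengths)
}

#' Generate a complete synthetic paired study
#'
#' Runs [generate_ground_truth()], [generate_protein_db()],
#' [simulate_psm_table()] and [simulate_counts()] under one seed and
#' optionally writes every output (FASTA, PSM/count/annotation/design TSVs
#' and the serialized truth) to a directory.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional output directory (created if needed).
#' @return A `sim_study` list: `truth`, `db`, `psms`, `counts`, `lengths`,
#'   `pairing` (protein-to-RNA sample matching by experimental unit).
#' @export
simulate_study <- function(cfg, outdir = NULL) {
  truth <- generate_ground_truth(cfg)
  db <- generate_protein_db(cfg, truth)
  psms <- simulate_psm_table(cfg, truth, db)
  cnt <- simulate_counts(cfg, truth)
  pairing <- match_samples(truth$proteome_design, truth$rna_design,
                           day = cfg$days[1L])
  study <- list(truth = truth, db = db, psms = psms, counts = cnt$counts,
                lengths = cnt$lengths, pairing = pairing)
  class(study) <- "sim_study"
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

#' Match proteome samples to transcriptome samples by experimental unit
#'
#' Pairs are formed for (group, replicate) combinations present in both
#' assays at the given day; unpaired samples (e.g. transcriptome replicates
#' beyond the available TMT labels) are left out.
#'
#' @param proteome_design,rna_design Design sheets with `sample`, `group`,
#'   `day`, `replicate` columns.
#' @param day Which transcriptome day to pair against (default 3).
#' @return data.frame `sample_protein`, `sample_rna`, `replicate` (the
#'   shared experimental-unit label).
#' @export
match_samples <- function(proteome_design, rna_design, day = 3L) {
  rna <- rna_design[rna_design$day == day, , drop = FALSE]
  key_p <- paste(proteome_design$group, proteome_design$replicate)
  key_r <- paste(rna$group, rna$replicate)
  idx <- match(key_p, key_r)
  ok <- !is.na(idx)
  data.frame(sample_protein = proteome_design$sample[ok],
             sample_rna = rna$sample[idx[ok]],
             replicate = key_p[ok])
}

#' Write a synthetic study to disk
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param outdir Output directory.
#' @return The directory, invisibly. Files: `proteins.fasta`, `psms.tsv`,
#'   `counts.tsv`, `gene_lengths.tsv`, `annotations.tsv`,
#'   `design_proteome.tsv`, `design_rna.tsv`, `truth_genes.tsv`.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(study$db$sequences)
  Biostrings::writeXStringSet(aa, file.path(outdir, "proteins.fasta"))
  write_tsv(study$psms, file.path(outdir, "psms.tsv"), "psms")
  .write_matrix_tsv(study$counts, file.path(outdir, "counts.tsv"),
                    "counts", id_col = "gene_id")
  write_tsv(data.frame(gene_id = names(study$lengths),
                       length_bp = unname(study$lengths)),
            file.path(outdir, "gene_lengths.tsv"), "gene_lengths")
  write_tsv(study$db$annotations, file.path(outdir, "annotations.tsv"),
            "annotations")
  write_tsv(study$truth$proteome_design,
            file.path(outdir, "design_proteome.tsv"), "design_proteome")
  write_tsv(study$truth$rna_design, file.path(outdir, "design_rna.tsv"),
            "design_rna")
  write_tsv(study$truth$genes, file.path(outdir, "truth_genes.tsv"),
            "truth_genes")
  invisible(outdir)
}

#' Simulate paired log-abundance data with per-replicate random slopes
#'
#' A direct generator for the pooled mixed-model geometry: every replicate
#' culture draws its own intercept and slope around the population values,
#' then gene-level points are scattered around that line. Used to verify
#' that [fit_pooled_mixed_model()] recovers the configured slope.
#'
#' @param n_genes Genes per replicate.
#' @param n_replicates Number of replicate cultures.
#' @param slope,intercept Population fixed effects.
#' @param slope_sd,intercept_sd Between-replicate SDs of the random
#'   effects.
#' @param noise_sd Residual SD.
#' @param x_mean,x_sd Distribution of the protein-axis values.
#' @param seed Integer seed.
#' @return data.frame `gene`, `replicate`, `log_molpct`, `log_rpkm` plus
#'   matrices in attributes for the module interfaces: `molpct`, `rpkm`,
#'   `pairing`.
#' @export
simulate_paired_abundance <- function(n_genes = 300L, n_replicates = 10L,
                                      slope = 0.8, intercept = 0.5,
                                      slope_sd = 0.1, intercept_sd = 0.2,
                                      noise_sd = 0.5, x_mean = 0.5,
                                      x_sd = 1.5, seed = 1L) {
  set.seed(seed)
  reps <- sprintf("rep%02d", seq_len(n_replicates))
  b <- slope + stats::rnorm(n_replicates, sd = slope_sd)
  a <- intercept + stats::rnorm(n_replicates, sd = intercept_sd)
  long <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    x <- stats::rnorm(n_genes, x_mean, x_sd)
    y <- a[r] + b[r] * x + stats::rnorm(n_genes, sd = noise_sd)
    data.frame(gene = sprintf("SYNG%05d", seq_len(n_genes)),
               replicate = reps[r], log_molpct = x, log_rpkm = y)
  }))
  molpct <- matrix(exp(long$log_molpct), ncol = n_replicates,
                   dimnames = list(unique(long$gene),
                                   paste0(reps, "_prot")))
  rpkm <- matrix(exp(long$log_rpkm), ncol = n_replicates,
                 dimnames = list(unique(long$gene), paste0(reps, "_rna")))
  attr(long, "molpct") <- molpct
  attr(long, "rpkm") <- rpkm
  attr(long, "pairing") <- data.frame(sample_protein = colnames(molpct),
                                      sample_rna = colnames(rpkm),
                                      replicate = reps)
  long
}
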