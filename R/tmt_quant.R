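# emPAI/PAMUS protein quantification from TMT reporter-ion evidence.

# Monoisotopic residue masses (Da) for the 20 canonical amino acids.
# A peptide's monoisotopic mass is the sum of its residue masses plus one
# water (18.010565 Da).
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.WATER_MASS <- 18.010565

#' Canonical amino-acid alphabet used throughout the package
#' @return Character vector of the 20 one-letter residue codes.
#' @export
amino_acids <- function() names(.RESIDUE_MASS)

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single character string")
  if (nchar(sequence) == 0L)
    stop("protein sequence is empty")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(residues), names(.RESIDUE_MASS))
  if (length(bad))
    stop("non-canonical residue(s) in sequence: ", paste(bad, collapse = ", "))
  residues
}

#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves after lysine (K) or arginine (R) unless the following residue is
#' proline (P). With `missed_cleavages = m`, every concatenation of up to
#' `m + 1` adjacent fully-tryptic fragments is returned; duplicate sequences
#' are collapsed.
#'
#' @param sequence Protein sequence (single string over the 20 canonical
#'   amino acids).
#' @param missed_cleavages Maximum number of internal cleavage sites left
#'   uncut (default 0, i.e. fully tryptic).
#' @return Character vector of distinct peptide sequences.
#' @examples
#' digest_protein("MKRAAAKPDER")
#' @export
digest_protein <- function(sequence, missed_cleavages = 0L) {
  residues <- .check_sequence(sequence)
  if (missed_cleavages < 0L) stop("'missed_cleavages' must be >= 0")
  n <- length(residues)
  # cleavage after position i: residue i is K/R and i+1 is not P
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & residues[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  frags <- substring(sequence, starts, ends)
  k <- length(frags)
  out <- character(0L)
  for (span in 0:min(missed_cleavages, k - 1L)) {
    i <- seq_len(k - span)
    out <- c(out, substring(sequence, starts[i], ends[i + span]))
  }
  unique(out)
}

#' Monoisotopic peptide mass
#'
#' @param peptides Character vector of peptide sequences.
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
peptide_mass <- function(peptides) {
  vapply(peptides, function(p) {
    residues <- .check_sequence(p)
    sum(.RESIDUE_MASS[residues]) + .WATER_MASS
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Count peptides observable within a mass window
#'
#' The emPAI denominator: the number of distinct peptides whose monoisotopic
#' mass falls inside the instrument's effective scan range.
#'
#' @param peptides Character vector of peptides (duplicates collapsed).
#' @param mass_window Numeric length-2 vector, `c(min_Da, max_Da)`.
#' @return Integer count.
#' @export
count_observable_peptides <- function(peptides, mass_window = c(500, 5000)) {
  if (length(peptides) == 0L) return(0L)
  stopifnot(length(mass_window) == 2L, mass_window[1L] <= mass_window[2L])
  peptides <- unique(peptides)
  m <- peptide_mass(peptides)
  sum(m >= mass_window[1L] & m <= mass_window[2L])
}

#' Protein abundance index (PAI) and its exponential modification (emPAI)
#'
#' PAI is the ratio of observed to observable peptides for a protein;
#' emPAI = 10^PAI - 1 is approximately proportional to the protein's molar
#' amount in the mixture.
#'
#' @param n_observed Count(s) of distinct identified peptides.
#' @param n_observable Count(s) of in-silico observable peptides (>= 1).
#' @return A data.frame with columns `pai` and `empai`.
#' @examples
#' compute_empai(3, 12)   # PAI 0.25, emPAI 10^0.25 - 1
#' @export
compute_empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1L))
    stop("protein has no observable peptides (n_observable = 0)")
  if (any(n_observed < 0L)) stop("'n_observed' must be >= 0")
  pai <- n_observed / n_observable
  data.frame(pai = pai, empai = 10^pai - 1)
}

#' Correct reporter-ion intensities for TMT isotope impurities
#'
#' Each TMT label carries minor isotopic variants that bleed signal into
#' neighbouring reporter channels. Given the label-purity matrix (column j =
#' how label j's signal distributes over observed channels), the true
#' channel intensities are recovered by solving
#' `impurity %*% corrected = raw` for every PSM. Negative solutions
#' (possible in the presence of noise) are clamped to zero with a warning.
#'
#' @param raw Numeric matrix, PSMs x channels, of raw reporter intensities.
#' @param impurity Square channels x channels mixing matrix.
#' @return Corrected matrix of the same shape.
#' @export
correct_isotope_impurities <- function(raw, impurity) {
  raw <- as.matrix(raw)
  impurity <- as.matrix(impurity)
  if (nrow(impurity) != ncol(impurity))
    stop("impurity matrix must be square")
  if (ncol(raw) != ncol(impurity))
    stop("number of reporter channels (", ncol(raw),
         ") does not match impurity matrix dimension (", ncol(impurity), ")")
  if (any(impurity < 0)) stop("impurity matrix entries must be nonnegative")
  corrected <- tryCatch(
    t(solve(impurity, t(raw))),
    error = function(e) stop("impurity matrix is singular: ",
                             conditionMessage(e), call. = FALSE)
  )
  n_neg <- sum(corrected < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative corrected intensit",
            if (n_neg == 1L) "y" else "ies", " clamped to 0")
    corrected[corrected < 0] <- 0
  }
  dimnames(corrected) <- dimnames(raw)
  corrected
}

#' Filter peptide-spectrum matches on FDR and unique-peptide criteria
#'
#' Mirrors the usual identification filter for multiplexed experiments:
#' PSMs must reach peptide-level confidence `1 - peptide_fdr`, proteins must
#' reach confidence `1 - protein_fdr`, and each surviving protein must carry
#' at least `min_unique_peptides` distinct peptide sequences.
#'
#' @param psms PSM data.frame with at least `peptide`, `accession` and
#'   (optionally) `peptide_prob`, `protein_prob`, `decoy` columns. Missing
#'   confidence columns are treated as fully confident targets.
#' @param protein_fdr,peptide_fdr Maximum tolerated false discovery rates
#'   (defaults 0.03 each).
#' @param min_unique_peptides Minimum distinct peptides per protein
#'   (default 2).
#' @return The filtered PSM table; attribute `"attrition"` records row and
#'   protein counts removed at each step.
#' @export
filter_identifications <- function(psms, protein_fdr = 0.03,
                                   peptide_fdr = 0.03,
                                   min_unique_peptides = 2L) {
  stopifnot(is.data.frame(psms),
            all(c("peptide", "accession") %in% names(psms)))
  n0 <- nrow(psms)
  if (!is.null(psms$decoy))
    psms <- psms[!psms$decoy, , drop = FALSE]
  if (!is.null(psms$peptide_prob))
    psms <- psms[psms$peptide_prob >= 1 - peptide_fdr, , drop = FALSE]
  n_after_pep <- nrow(psms)
  if (!is.null(psms$protein_prob)) {
    prot_prob <- tapply(psms$protein_prob, psms$accession, max)
    keep <- names(prot_prob)[prot_prob >= 1 - protein_fdr]
    psms <- psms[psms$accession %in% keep, , drop = FALSE]
  }
  n_prot_before <- length(unique(psms$accession))
  uniq <- tapply(psms$peptide, psms$accession,
                 function(p) length(unique(p)))
  keep <- names(uniq)[uniq >= min_unique_peptides]
  psms <- psms[psms$accession %in% keep, , drop = FALSE]
  attr(psms, "attrition") <- c(
    psms_in = n0, psms_low_confidence = n0 - n_after_pep,
    proteins_before_unique_filter = n_prot_before,
    proteins_out = length(keep))
  psms
}

# Resolve shared peptides: a PSM whose accession field lists several
# proteins (';'-separated) is assigned to the accession with the most unique
# peptides in the table; ties break lexicographically.
.resolve_shared_peptides <- function(psms) {
  shared <- grepl(";", psms$accession, fixed = TRUE)
  if (!any(shared)) return(psms)
  uniq_count <- tapply(psms$peptide[!shared], psms$accession[!shared],
                       function(p) length(unique(p)))
  psms$accession[shared] <- vapply(
    strsplit(psms$accession[shared], ";", fixed = TRUE),
    function(accs) {
      accs <- sort(trimws(accs))
      counts <- uniq_count[accs]
      counts[is.na(counts)] <- 0
      accs[which.max(counts)]  # which.max keeps the first (lexicographic) tie
    }, character(1L))
  psms
}

#' emPAI/PAMUS quantification of a filtered PSM table
#'
#' For every protein: the emPAI is computed from the count of distinct
#' observed peptides and the in-silico count of observable tryptic peptides;
#' the emPAI is then partitioned across reporter channels in proportion to
#' the protein's summed channel intensities (PAMUS); finally each channel is
#' normalised so that the molar shares of all proteins sum to 100 (Mol%).
#'
#' @param psms Filtered PSM data.frame with `peptide`, `accession` and ten
#'   (or `n`) intensity columns named in `channels`.
#' @param db Protein database: named character vector or
#'   `Biostrings::AAStringSet` of sequences, names = accessions.
#' @param design Optional sample sheet with columns `sample` and `tmt_label`;
#'   when given, Mol% columns are named `molpct_<sample>` in label order,
#'   otherwise `molpct_<channel>`.
#' @param channels Names of the intensity columns in `psms`; defaults to all
#'   columns starting with `"ch"`.
#' @param mass_window Observable-peptide monoisotopic mass window in Da.
#' @param missed_cleavages Missed cleavages allowed in the observable-peptide
#'   model (default 0).
#' @param aggregate How PSM intensities are combined per protein: `"sum"`
#'   (default) or `"mean"`.
#' @return A `protein_quant` data.frame with columns `accession`,
#'   `n_observed`, `n_observable`, `pai`, `empai`, one emPAI-share column and
#'   one Mol% column per channel.
#' @export
pamus_quantify <- function(psms, db, design = NULL, channels = NULL,
                           mass_window = c(500, 5000),
                           missed_cleavages = 0L,
                           aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (methods::is(db, "AAStringSet")) db <- as.character(db)
  stopifnot(is.data.frame(psms), !is.null(names(db)))
  if (is.null(channels))
    channels <- grep("^ch", names(psms), value = TRUE)
  if (length(channels) == 0L) stop("no reporter intensity columns found")
  psms <- .resolve_shared_peptides(psms)
  missing_acc <- setdiff(unique(psms$accession), names(db))
  if (length(missing_acc))
    stop("PSM accession(s) absent from protein database: ",
         paste(utils::head(missing_acc, 5L), collapse = ", "))

  accs <- sort(unique(psms$accession))
  n_obs <- vapply(accs, function(a)
    length(unique(psms$peptide[psms$accession == a])), integer(1L))
  n_obsable <- vapply(accs, function(a) {
    count_observable_peptides(
      digest_protein(db[[a]], missed_cleavages), mass_window)
  }, integer(1L))
  if (any(n_obsable == 0L)) {
    warning(sum(n_obsable == 0L),
            " protein(s) with no observable peptides dropped")
    keep <- n_obsable > 0L
    accs <- accs[keep]; n_obs <- n_obs[keep]; n_obsable <- n_obsable[keep]
  }
  e <- compute_empai(pmin(n_obs, n_obsable), n_obsable)

  intens <- as.matrix(psms[, channels, drop = FALSE])
  agg_fun <- if (aggregate == "sum") function(x) colSums(x) else
    function(x) colMeans(x)
  prot_int <- t(vapply(accs, function(a)
    agg_fun(intens[psms$accession == a, , drop = FALSE]),
    numeric(length(channels))))

  tot <- rowSums(prot_int)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sum(zero), " protein(s) with all-zero intensities dropped")
    accs <- accs[!zero]; e <- e[!zero, ]; n_obs <- n_obs[!zero]
    n_obsable <- n_obsable[!zero]
    prot_int <- prot_int[!zero, , drop = FALSE]; tot <- tot[!zero]
  }
  share <- e$empai * prot_int / tot          # channel shares sum to emPAI
  molpct <- 100 * sweep(share, 2L, colSums(share), "/")

  sample_names <- channels
  if (!is.null(design)) {
    stopifnot(all(c("sample", "tmt_label") %in% names(design)))
    lab <- sub("^ch", "", channels)
    idx <- match(lab, design$tmt_label)
    if (!anyNA(idx)) sample_names <- design$sample[idx]
  }
  colnames(share) <- paste0("share_", sample_names)
  colnames(molpct) <- paste0("molpct_", sample_names)
  out <- data.frame(accession = accs, n_observed = n_obs,
                    n_observable = n_obsable, pai = e$pai, empai = e$empai,
                    share, molpct, row.names = NULL,
                    check.names = FALSE)
  class(out) <- c("protein_quant", "data.frame")
  attr(out, "samples") <- as.character(sample_names)
  out
}

#' Extract the Mol% matrix from a protein quantification table
#'
#' @param quant A `protein_quant` table from [pamus_quantify()].
#' @return Numeric matrix, proteins x samples, rownames = accessions.
#' @export
molpct_matrix <- function(quant) {
  cols <- grep("^molpct_", names(quant), value = TRUE)
  m <- as.matrix(quant[, cols, drop = FALSE])
  rownames(m) <- quant$accession
  colnames(m) <- sub("^molpct_", "", cols)
  m
}
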