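# Permutation-based differential expression with Benjamini-Hochberg control.

#' Log2 fold change between two groups
#'
#' @param treatment_values,control_values Positive abundance values.
#' @return `log2(mean(treatment) / mean(control))`.
#' @export
log2_fold_change <- function(treatment_values, control_values) {
  if (length(treatment_values) == 0L || length(control_values) == 0L)
    stop("both groups must be non-empty")
  mt <- mean(treatment_values)
  mc <- mean(control_values)
  if (mc <= 0 || mt <= 0)
    stop("group means must be positive for a log2 fold change")
  log2(mt / mc)
}

# All distinct assignments of n_a out of n samples to group A, as a
# samples x assignments weight matrix W with +1/n_a for group-A members and
# -1/n_b otherwise, so that |x %*% W| is the permuted mean-difference
# statistic for every assignment at once.
.perm_weight_matrix <- function(n, n_a, n_perm, seed = NULL) {
  n_b <- n - n_a
  n_exact <- choose(n, n_a)
  if (n_exact <= 10000) {
    sel <- utils::combn(n, n_a)
    exact <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    sel <- replicate(n_perm, sample.int(n, n_a))
    exact <- FALSE
  }
  w <- matrix(-1 / n_b, nrow = n, ncol = ncol(sel))
  w[cbind(as.vector(sel), rep(seq_len(ncol(sel)), each = n_a))] <- 1 / n_a
  list(w = w, exact = exact)
}

# Row-wise permutation p-values for a matrix of log2 abundances.
# idx_a/idx_b index columns of x. Statistic: |difference of group means|.
# pool = TRUE compares each feature's observed statistic against the null
# statistics pooled over ALL features, which refines the attainable p-value
# resolution from 1/(#assignments) to 1/(#features x #assignments); small
# designs (e.g. 4 vs 4, 70 assignments) otherwise floor every p-value at
# 3/71 and no feature could survive FDR control.
.perm_test_rows <- function(x, idx_a, idx_b, n_perm = 10000, seed = NULL,
                            pool = FALSE) {
  x <- x[, c(idx_a, idx_b), drop = FALSE]
  n_a <- length(idx_a)
  n <- ncol(x)
  pw <- .perm_weight_matrix(n, n_a, n_perm, seed)
  obs <- abs(x %*% c(rep(1 / n_a, n_a), rep(-1 / (n - n_a), n - n_a)))
  stats <- abs(x %*% pw$w)
  tol <- 1e-12 * (1 + abs(obs))
  if (pool) {
    null_sorted <- sort(as.vector(stats))
    # #{null >= obs} = total - #{null < obs - tol}
    below <- findInterval(as.vector(obs - tol), null_sorted)
    hits <- length(null_sorted) - below
    return((1 + hits) / (1 + length(null_sorted)))
  }
  hits <- rowSums(stats >= matrix(obs - tol, nrow(x), ncol(stats)))
  as.vector((1 + hits) / (1 + ncol(stats)))
}

#' Two-sample permutation test on log2 abundances
#'
#' The statistic is the absolute difference of group means. When the number
#' of distinct group-label assignments is at most 10,000 the permutation
#' distribution is enumerated exactly (e.g. C(8,4) = 70 for a 4-vs-4
#' design); otherwise `n_perm` assignments are sampled with the given seed.
#' The p-value uses the add-one estimator
#' `p = (1 + #\{permuted >= observed\}) / (1 + #permutations)`, which keeps
#' p strictly positive.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each) of log2
#'   abundances.
#' @param n_perm Number of sampled permutations when exact enumeration is
#'   infeasible (default 10000).
#' @param seed Optional integer seed for the sampled branch.
#' @return The permutation p-value.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 10000, seed = NULL) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  x <- matrix(c(group_a, group_b), nrow = 1L)
  .perm_test_rows(x, seq_along(group_a),
                  length(group_a) + seq_along(group_b), n_perm, seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Raw-p significance cutoff implied by a BH rejection at a target FDR
#'
#' Expresses the Benjamini-Hochberg rejection boundary on the raw p-value
#' scale: the largest order statistic `p(i)` satisfying
#' `p(i) <= (i/m) * fdr_target`. This is the "corrected threshold" a
#' volcano plot draws on its raw-p axis. Returns 0 when nothing is
#' rejected.
#'
#' @param p_values Raw p-values.
#' @param fdr_target Target FDR in (0, 1).
#' @return The raw-p cutoff (a value of `p_values`, or 0).
#' @export
corrected_raw_threshold <- function(p_values, fdr_target) {
  stopifnot(fdr_target > 0, fdr_target < 1)
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- ps <= seq_len(m) / m * fdr_target
  if (!any(ok)) return(0)
  ps[max(which(ok))]
}

.check_contrast_power <- function(n_t, n_c, contrast) {
  n_assign <- choose(n_t + n_c, n_t)
  min_p <- 1 / (1 + min(n_assign, 10000))
  # with |mean diff| the complement assignment ties the observed one, so the
  # attainable floor under exact enumeration is (1 + 2)/(1 + n_assign)
  if (n_assign <= 10000) min_p <- 3 / (1 + n_assign)
  if (min_p > 0.05)
    warning(sprintf(
      "contrast %s (%d vs %d): minimum attainable permutation p = %.3f; the contrast is under-powered",
      contrast, n_t, n_c, min_p))
  invisible(min_p)
}

#' Differential protein expression by permutation test on Mol% abundances
#'
#' For each protein the log2 fold change is the log2 ratio of mean Mol%
#' (treatment over control) and the p-value comes from a permutation test on
#' the per-sample log2 Mol% values, BH-adjusted across proteins.
#' Proteins with a non-positive Mol% in any sample of the contrast are
#' excluded (counted in the `"n_excluded"` attribute) because their log2
#' abundance is undefined.
#'
#' @param quant A `protein_quant` table (or a proteins x samples Mol%
#'   matrix).
#' @param design Sample sheet with columns `sample` and `group`.
#' @param contrast Length-2 character vector `c(treatment, control)`,
#'   e.g. `c("N-", "C")`.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param n_perm,seed Passed to the permutation test.
#' @param null `"pooled"` (default) compares each protein's statistic to
#'   the permutation statistics pooled across all proteins, giving a
#'   p-value resolution of about `1/(n_proteins * n_assignments)`;
#'   `"per_feature"` uses each protein's own permutation distribution
#'   only, whose resolution at small designs (4 vs 4: minimum p = 3/71)
#'   is too coarse for any feature to survive FDR control.
#' @return A `diff_expression` data.frame: `feature`, `contrast`, `l2fc`,
#'   `p_raw`, `p_adj`, `significant`. Attributes: `raw_p_cutoff` (the BH
#'   boundary on the raw-p scale) and `n_excluded`.
#' @export
protein_de <- function(quant, design, contrast = c("N-", "C"),
                       alpha = 0.05, n_perm = 10000, seed = NULL,
                       null = c("pooled", "per_feature")) {
  null <- match.arg(null)
  m <- if (is.matrix(quant)) quant else molpct_matrix(quant)
  stopifnot(all(c("sample", "group") %in% names(design)),
            length(contrast) == 2L)
  s_t <- design$sample[design$group == contrast[1L]]
  s_c <- design$sample[design$group == contrast[2L]]
  s_t <- intersect(s_t, colnames(m)); s_c <- intersect(s_c, colnames(m))
  if (length(s_t) < 2L || length(s_c) < 2L)
    stop("each group needs at least 2 quantified samples")
  .check_contrast_power(length(s_t), length(s_c), paste(contrast, collapse = "/"))
  sub <- m[, c(s_t, s_c), drop = FALSE]
  ok <- rowSums(sub <= 0) == 0L
  sub <- sub[ok, , drop = FALSE]
  l2fc <- log2(rowMeans(sub[, s_t, drop = FALSE]) /
               rowMeans(sub[, s_c, drop = FALSE]))
  p <- .perm_test_rows(log2(sub), seq_along(s_t),
                       length(s_t) + seq_along(s_c), n_perm, seed,
                       pool = null == "pooled")
  p_adj <- bh_adjust(p)
  out <- data.frame(feature = rownames(sub),
                    contrast = paste(contrast, collapse = "/"),
                    l2fc = as.vector(l2fc), p_raw = p, p_adj = p_adj,
                    significant = p_adj < alpha, row.names = NULL)
  class(out) <- c("diff_expression", "data.frame")
  attr(out, "raw_p_cutoff") <- corrected_raw_threshold(p, alpha)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across genes of the ratio of its count to the
#' gene's geometric mean over samples; genes containing a zero are excluded
#' from factor estimation.
#'
#' @param counts Gene x sample count matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts <= 0) == 0L
  if (!any(all_pos))
    stop("no gene has all-positive counts; cannot estimate size factors")
  lg <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lg)                      # log geometric mean
  apply(exp(lg - ref), 2L, stats::median)
}

#' Differential transcript expression (normalised-count permutation test)
#'
#' Counts are normalised by median-of-ratios size factors; the log2 fold
#' change is the ratio of normalised group means; the per-gene p-value comes
#' from a permutation test on log2 of the normalised counts (plus one to
#' tolerate zeros), BH-adjusted. A gene is called differentially expressed
#' when `p_adj < alpha` and `|l2fc| > l2fc_min`.
#'
#' @param counts Gene x sample integer matrix.
#' @param design Sample sheet with columns `sample` and `group` (rows in any
#'   order; matched to `colnames(counts)`).
#' @param contrast Length-2 `c(treatment, control)`.
#' @param alpha BH significance level (default 0.05).
#' @param l2fc_min Absolute log2-fold-change threshold (default 1.0, i.e.
#'   fold change > 2).
#' @param n_perm,seed Permutation settings.
#' @param null Null-distribution mode, see [protein_de()] (default
#'   `"pooled"`).
#' @return A `diff_expression` data.frame as in [protein_de()], with the DE
#'   call combining the p and fold-change criteria.
#' @export
transcript_de <- function(counts, design, contrast, alpha = 0.05,
                          l2fc_min = 1.0, n_perm = 10000, seed = NULL,
                          null = c("pooled", "per_feature")) {
  null <- match.arg(null)
  counts <- as.matrix(counts)
  stopifnot(all(c("sample", "group") %in% names(design)))
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  s_t <- intersect(design$sample[design$group == contrast[1L]],
                   colnames(counts))
  s_c <- intersect(design$sample[design$group == contrast[2L]],
                   colnames(counts))
  if (length(s_t) < 2L || length(s_c) < 2L)
    stop("each group needs at least 2 replicates")
  mean_t <- rowMeans(norm[, s_t, drop = FALSE])
  mean_c <- rowMeans(norm[, s_c, drop = FALSE])
  l2fc <- log2(mean_t / mean_c)            # +-Inf when a group mean is 0
  x <- log2(norm[, c(s_t, s_c), drop = FALSE] + 1)
  p <- .perm_test_rows(x, seq_along(s_t),
                       length(s_t) + seq_along(s_c), n_perm, seed,
                       pool = null == "pooled")
  p_adj <- bh_adjust(p)
  out <- data.frame(feature = rownames(counts),
                    contrast = paste(contrast, collapse = "/"),
                    l2fc = as.vector(l2fc), p_raw = p, p_adj = p_adj,
                    significant = p_adj < alpha & abs(l2fc) > l2fc_min,
                    row.names = NULL)
  class(out) <- c("diff_expression", "data.frame")
  attr(out, "raw_p_cutoff") <- corrected_raw_threshold(p, alpha)
  attr(out, "size_factors") <- sf
  out
}
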