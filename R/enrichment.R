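# Gene-set statistics: logistic log-odds-ratio model on L2fc, classic
# one-sided Fisher enrichment, and a GAGE-style set-level t test.

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `term<TAB>description<TAB>member1<TAB>member2...`.
#' @return Named list of character vectors; names are term ids, the
#'   `"description"` attribute keeps the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1L), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1L), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of member character vectors.
#' @param path Output path.
#' @param descriptions Optional vector for the second GMT column.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(term, desc, members)
    paste(c(term, desc, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
}

#' Build gene sets from an annotation table column
#'
#' @param annotations data.frame with an `accession` column and a
#'   `;`-separated term column.
#' @param column Which column holds the terms (default `"go_terms"`).
#' @return Named list of member accessions per term.
#' @export
sets_from_annotations <- function(annotations, column = "go_terms") {
  stopifnot(column %in% names(annotations))
  terms <- strsplit(annotations[[column]], ";", fixed = TRUE)
  terms <- lapply(terms, function(t) trimws(t[nzchar(trimws(t))]))
  long <- data.frame(
    accession = rep(annotations$accession, lengths(terms)),
    term = unlist(terms, use.names = FALSE))
  lapply(split(long$accession, long$term), unique)
}

# Intersect sets with the quantified universe, drop sets below/at the size
# bound. strict = TRUE keeps sets with MORE than min_members members.
.prepare_sets <- function(sets, universe, min_members, strict = FALSE) {
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  keep <- if (strict) lengths(sets) > min_members else
    lengths(sets) >= min_members
  sets[keep]
}

#' Logistic-model gene-set enrichment (log-odds-ratio statistic)
#'
#' For each term, fits a logistic regression of set membership (0/1 over
#' the quantified universe) on the per-feature log2 fold change. The fitted
#' slope is the log-odds ratio (LOR): LOR > 0 means the set is
#' over-represented among upregulated features, LOR < 0 among downregulated
#' ones. p-values are Wald tests on the slope, BH-adjusted across terms.
#' Complete separation is caught: the term is reported with an
#' infinite-LOR flag and a likelihood-ratio p-value instead of crashing.
#'
#' @param l2fc Named numeric vector of log2 fold changes (the universe).
#' @param sets Named list of member-feature vectors.
#' @param fdr_cutoff Significance threshold on the BH q-value
#'   (default 0.01).
#' @param min_members Sets with fewer members after intersecting with the
#'   universe are dropped (default 5).
#' @return An `enrichment` data.frame: `term`, `method`, `statistic` (LOR),
#'   `p_raw`, `q`, `direction`, `n_members`, `infinite_lor`, `significant`.
#' @export
logistic_gsea <- function(l2fc, sets, fdr_cutoff = 0.01, min_members = 5L) {
  stopifnot(!is.null(names(l2fc)))
  l2fc <- l2fc[is.finite(l2fc)]
  universe <- names(l2fc)
  sets <- .prepare_sets(sets, universe, min_members)
  if (length(sets) == 0L) stop("no set has enough quantified members")
  res <- lapply(names(sets), function(term) {
    y <- as.integer(universe %in% sets[[term]])
    fit <- suppressWarnings(stats::glm(y ~ l2fc, family = stats::binomial()))
    co <- summary(fit)$coefficients
    lor <- co["l2fc", "Estimate"]
    se <- co["l2fc", "Std. Error"]
    separated <- !fit$converged || abs(lor) > 15 || se > 100
    if (separated) {
      # Wald inference collapses under separation; bound p by the
      # likelihood-ratio test against the intercept-only model.
      null_dev <- fit$null.deviance
      p <- stats::pchisq(null_dev - fit$deviance, df = 1L,
                         lower.tail = FALSE)
      lor <- sign(lor) * Inf
    } else {
      p <- co["l2fc", "Pr(>|z|)"]
    }
    data.frame(term = term, method = "logistic", statistic = lor,
               p_raw = p, n_members = sum(y), infinite_lor = separated)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p_raw)
  out$direction <- ifelse(out$statistic > 0, "up", "down")
  out$significant <- out$q < fdr_cutoff
  out <- out[, c("term", "method", "statistic", "p_raw", "q", "direction",
                 "n_members", "infinite_lor", "significant")]
  class(out) <- c("enrichment", "data.frame")
  out
}

#' Classic one-sided Fisher enrichment of a DE direction
#'
#' Tests each term's 2x2 table (in set vs not) x (in direction vs not) with
#' the one-sided hypergeometric tail for over-representation, the
#' hierarchy-free "classic" variant. Sets with fewer than `min_members`
#' annotated members in the universe are pruned before testing.
#'
#' @param de_labels Named character vector over the universe with values
#'   `"up"`, `"down"` or `"ns"`.
#' @param sets Named list of member-feature vectors.
#' @param direction `"up"` or `"down"`: which DE class to test.
#' @param alpha Significance threshold on the BH q-value (default 0.05).
#' @param min_members Pruning bound (default 5).
#' @return An `enrichment` data.frame with the odds ratio as statistic.
#' @export
fisher_enrichment <- function(de_labels, sets, direction = c("up", "down"),
                              alpha = 0.05, min_members = 5L) {
  direction <- match.arg(direction)
  stopifnot(!is.null(names(de_labels)))
  universe <- names(de_labels)
  n_universe <- length(universe)
  in_dir <- names(de_labels)[de_labels == direction]
  m <- length(in_dir)
  sets <- .prepare_sets(sets, universe, min_members)
  if (length(sets) == 0L) stop("no set has enough annotated members")
  res <- lapply(names(sets), function(term) {
    members <- sets[[term]]
    k <- length(members)
    q <- length(intersect(members, in_dir))
    # P(X >= q), X ~ Hypergeometric(m in-direction, N - m others, k drawn)
    p <- stats::phyper(q - 1L, m, n_universe - m, k, lower.tail = FALSE)
    or <- (q * (n_universe - m - k + q)) / ((k - q) * (m - q))
    data.frame(term = term, method = "fisher",
               statistic = or, p_raw = p, n_members = k, n_overlap = q)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p_raw)
  out$direction <- direction
  out$significant <- out$q < alpha
  out <- out[, c("term", "method", "statistic", "p_raw", "q", "direction",
                 "n_members", "n_overlap", "significant")]
  class(out) <- c("enrichment", "data.frame")
  out
}

#' Set-level t test on log2 fold changes (GAGE-style)
#'
#' Compares each set's member L2fc values against the non-member background
#' with a two-sample unequal-variance (Welch) t test. In unidirectional
#' mode each set is reported twice, with one-sided p-values for coordinated
#' up- and downregulation; in bidirectional mode a single two-sided test on
#' the absolute fold changes detects perturbation regardless of sign. Only
#' sets with strictly more than `min_members` annotated members are tested.
#'
#' @param l2fc Named numeric vector of per-feature log2 fold changes.
#' @param sets Named list of member vectors.
#' @param min_members Strict lower size bound (default 5: sets need > 5
#'   members).
#' @param q_cutoff Significance threshold on the BH q-value (default 0.05).
#' @param mode `"unidirectional"` (default) or `"bidirectional"`.
#' @return An `enrichment` data.frame with the Welch t statistic.
#' @export
set_level_test <- function(l2fc, sets, min_members = 5L, q_cutoff = 0.05,
                           mode = c("unidirectional", "bidirectional")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(l2fc)))
  l2fc <- l2fc[is.finite(l2fc)]
  universe <- names(l2fc)
  sets <- .prepare_sets(sets, universe, min_members, strict = TRUE)
  if (length(sets) == 0L)
    stop("no set has more than ", min_members, " quantified members")
  vals <- if (mode == "bidirectional") abs(l2fc) else l2fc
  welch <- function(a, b) {
    res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                    error = function(e) NULL)  # zero variance etc.
    if (is.null(res)) list(t = 0, p_two = 1, degenerate = TRUE) else
      list(t = unname(res$statistic), p_two = res$p.value,
           degenerate = FALSE)
  }
  res <- lapply(names(sets), function(term) {
    inset <- universe %in% sets[[term]]
    w <- welch(vals[inset], vals[!inset])
    if (mode == "bidirectional") {
      data.frame(term = term, method = "set_t", statistic = w$t,
                 p_raw = w$p_two, direction = "both",
                 n_members = sum(inset))
    } else {
      p_up <- if (w$degenerate) 1 else
        if (w$t >= 0) w$p_two / 2 else 1 - w$p_two / 2
      p_down <- if (w$degenerate) 1 else 1 - p_up
      data.frame(term = rep(term, 2L), method = "set_t",
                 statistic = w$t, p_raw = c(p_up, p_down),
                 direction = c("up", "down"), n_members = sum(inset))
    }
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  for (d in unique(out$direction))
    out$q[out$direction == d] <- bh_adjust(out$p_raw[out$direction == d])
  out$significant <- out$q < q_cutoff
  out <- out[, c("term", "method", "statistic", "p_raw", "q", "direction",
                 "n_members", "significant")]
  rownames(out) <- NULL
  class(out) <- c("enrichment", "data.frame")
  out
}
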