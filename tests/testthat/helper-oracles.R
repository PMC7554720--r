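# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's implementation paths.

# Tryptic digestion by naive left-to-right scan: walk the sequence,
# end a fragment after every K/R not followed by P.
oracle_digest <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  frags <- character(0)
  cur <- ""
  for (i in seq_along(chars)) {
    cur <- paste0(cur, chars[i])
    nxt <- if (i < length(chars)) chars[i + 1] else ""
    if (chars[i] %in% c("K", "R") && nxt != "P" && i < length(chars)) {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  unique(c(frags, cur))
}

# Monoisotopic mass by direct table lookup (independent constant source:
# typed out per-residue in the test that uses it).
oracle_mass <- function(peptide, table) {
  sum(table[strsplit(peptide, "")[[1]]]) + 18.010565
}

# BH step-up by hand: p(i) * m / i from the sorted tail, cumulative min.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-sample permutation p-value by exhaustive enumeration with
# per-assignment loops (no matrix algebra).
oracle_perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  sel <- utils::combn(n, na)
  obs <- abs(mean(a) - mean(b))
  hits <- 0
  for (j in seq_len(ncol(sel))) {
    ga <- pool[sel[, j]]
    gb <- pool[-sel[, j]]
    if (abs(mean(ga) - mean(gb)) >= obs - 1e-12) hits <- hits + 1
  }
  (1 + hits) / (1 + ncol(sel))
}

# One-sided hypergeometric tail by direct summation of binomial
# coefficients: P(X >= q) with m successes, N total, k drawn.
oracle_hyper_p <- function(q, m, N, k) {
  js <- q:min(k, m)
  sum(choose(m, js) * choose(N - m, k - js)) / choose(N, k)
}

# Maximum-likelihood logistic slope by coarse-to-fine grid search over
# (intercept, slope) maximizing the Bernoulli log-likelihood.
oracle_logistic_slope <- function(y, x) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log(1 + exp(eta)))
  }
  b0s <- seq(-5, 5, length.out = 41)
  b1s <- seq(-5, 5, length.out = 41)
  best <- c(0, 0)
  best_ll <- -Inf
  for (pass in 1:4) {
    for (b0 in b0s) for (b1 in b1s) {
      v <- ll(b0, b1)
      if (v > best_ll) { best_ll <- v; best <- c(b0, b1) }
    }
    span0 <- diff(range(b0s)) / 8
    span1 <- diff(range(b1s)) / 8
    b0s <- seq(best[1] - span0, best[1] + span0, length.out = 41)
    b1s <- seq(best[2] - span1, best[2] + span1, length.out = 41)
  }
  best[2]
}

# Small PSM table builder for quantification tests: one row per
# peptide/protein with explicit channel intensities.
make_psms <- function(accession, peptide, intensities) {
  colnames(intensities) <- paste0("ch", seq_len(ncol(intensities)))
  data.frame(spectrum_id = sprintf("s%03d", seq_along(accession)),
             peptide = peptide, accession = accession,
             intensities, check.names = FALSE)
}

# Synthetic protein sequence with a controlled fully tryptic digest:
# n distinct peptide blocks of `len` residues, each ending in K; for
# len >= 6 every block's monoisotopic mass falls inside [500, 5000] Da.
make_sequence <- function(n_peptides, len = 8) {
  # no K/R (cleavage sites) and no P (blocks cleavage when it follows K/R)
  safe <- c("A", "G", "V", "S", "T", "L", "F", "E", "D", "N",
            "Q", "H", "I", "M", "W", "Y", "C")
  blocks <- vapply(seq_len(n_peptides), function(i) {
    a <- safe[(i - 1) %% 17 + 1]
    b <- safe[((i - 1) %/% 17) %% 17 + 1]
    paste0(a, b, strrep("A", len - 3), "K")
  }, character(1))
  stopifnot(!anyDuplicated(blocks))
  paste(blocks, collapse = "")
}
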