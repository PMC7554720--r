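test_that("RPKM follows its definition", {
  counts <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(compute_rpkm(counts, 1000, 1e6)[1, 1], 10)
  counts0 <- matrix(0, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(compute_rpkm(counts0, 1000, 1e6)[1, 1], 0)
  # doubling library size halves every RPKM
  set.seed(2)
  cm <- matrix(rpois(40, 100), 20, 2)
  lens <- rpois(20, 1500) + 200
  r1 <- compute_rpkm(cm, lens, c(1e6, 1e6))
  r2 <- compute_rpkm(cm, lens, c(2e6, 2e6))
  expect_equal(r1 / 2, r2)
  expect_error(compute_rpkm(cm, rep(0, 20), c(1, 1)), "positive")
})

test_that("fold-change correlation handles perfect and null coupling", {
  set.seed(4)
  x <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  same <- suppressWarnings(l2fc_correlation(x, x))
  expect_equal(same$r_squared, 1)
  expect_equal(same$slope, 1)
  neg <- suppressWarnings(l2fc_correlation(x, -x))
  expect_equal(neg$r_squared, 1)
  expect_equal(neg$slope, -1)
  # independent standard normals: R^2 near zero
  a <- setNames(rnorm(2000), sprintf("g%04d", 1:2000))
  b <- setNames(rnorm(2000), sprintf("g%04d", 1:2000))
  expect_lt(l2fc_correlation(a, b)$r_squared, 0.01)
  # unmatched features are dropped and counted (30 shared of 60 + 70)
  part <- suppressWarnings(l2fc_correlation(x[1:60], x[31:100]))
  expect_equal(part$n_pairs, 30)
  expect_equal(part$n_unmatched, 70)
})

test_that("the pooled mixed model recovers a degenerate common line", {
  set.seed(8)
  long <- simulate_paired_abundance(
    n_genes = 150, n_replicates = 4, slope = 0.5, intercept = 2,
    slope_sd = 0, intercept_sd = 0, noise_sd = 1e-6, seed = 8)
  fit <- fit_pooled_mixed_model(attr(long, "molpct"), attr(long, "rpkm"),
                                attr(long, "pairing"), rpkm_min = 0)
  expect_equal(fit$fixed_slope, 0.5, tolerance = 1e-3)
  expect_equal(fit$fixed_intercept, 2, tolerance = 1e-3)
  expect_lt(fit$sd_random_slope, 0.01)
  expect_gt(fit$pearson_r2, 0.999)
})

test_that("low-abundance transcripts are excluded from the pooled fit", {
  set.seed(9)
  long <- simulate_paired_abundance(n_genes = 50, n_replicates = 3,
                                    seed = 9)
  rpkm <- attr(long, "rpkm")
  rpkm["SYNG00001", ] <- 1.5            # below the 2.0 RPKM default
  fit <- fit_pooled_mixed_model(attr(long, "molpct"), rpkm,
                                attr(long, "pairing"))
  expect_equal(fit$n_pairs, sum(rpkm >= 2))
  expect_gt(fit$n_low_rpkm, 0)
  # monotonicity: raising rpkm_min never increases n_pairs
  fits <- lapply(c(0, 1, 2, 3), function(t)
    fit_pooled_mixed_model(attr(long, "molpct"), rpkm,
                           attr(long, "pairing"), rpkm_min = t)$n_pairs)
  expect_true(all(diff(unlist(fits)) <= 0))
})

test_that("a single replicate is rejected with advice", {
  long <- simulate_paired_abundance(n_genes = 30, n_replicates = 1,
                                    seed = 3)
  expect_error(
    fit_pooled_mixed_model(attr(long, "molpct"), attr(long, "rpkm"),
                           attr(long, "pairing"), rpkm_min = 0),
    "pooled OLS")
})

test_that("per-gene regressions fit, exclude, and summarise correctly", {
  set.seed(14)
  n_rep <- 10
  genes <- sprintf("g%02d", 1:12)
  # genes g01-g10: y = 2x + noise; g11 collinear; g12 constant protein
  molpct <- matrix(exp(rnorm(12 * n_rep)), 12,
                   dimnames = list(genes, paste0("s", 1:n_rep)))
  molpct["g12", ] <- 5
  rpkm <- exp(2 * log(molpct) + matrix(rnorm(12 * n_rep, sd = 0.1), 12))
  rpkm["g11", ] <- exp(0.5 + 3 * log(molpct["g11", ]))
  rownames(rpkm) <- genes
  colnames(rpkm) <- paste0("r", 1:n_rep)
  pairing <- data.frame(sample_protein = paste0("s", 1:n_rep),
                        sample_rna = paste0("r", 1:n_rep),
                        replicate = paste0("u", 1:n_rep))
  pg <- per_gene_regressions(molpct, rpkm, pairing, rpkm_min = 0)
  f11 <- pg$fits[pg$fits$gene == "g11", ]
  expect_equal(f11$r_squared, 1)
  expect_equal(f11$slope, 3)
  expect_equal(f11$intercept, 0.5, tolerance = 1e-9)
  expect_true("g12" %in% pg$excluded$gene)
  expect_equal(pg$excluded$reason[pg$excluded$gene == "g12"],
               "constant_protein")
  expect_true(all(pg$fits$slope > 0))
})

test_that("per-gene R2 is invariant to affine rescaling of either axis", {
  set.seed(15)
  molpct <- matrix(exp(rnorm(50)), 5,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  rpkm <- exp(matrix(rnorm(50), 5))
  dimnames(rpkm) <- list(paste0("g", 1:5), paste0("r", 1:10))
  pairing <- data.frame(sample_protein = paste0("s", 1:10),
                        sample_rna = paste0("r", 1:10),
                        replicate = paste0("u", 1:10))
  pg1 <- per_gene_regressions(molpct, rpkm, pairing, rpkm_min = 0)
  # multiplicative rescaling on the natural scale = affine on log scale
  pg2 <- per_gene_regressions(molpct^2 * 3, rpkm * 10, pairing,
                              rpkm_min = 0)
  expect_equal(pg1$fits$r_squared, pg2$fits$r_squared, tolerance = 1e-9)
})

test_that("pooled R2 is invariant to replicate relabeling", {
  set.seed(16)
  long <- simulate_paired_abundance(n_genes = 80, n_replicates = 5,
                                    seed = 16)
  pairing <- attr(long, "pairing")
  f1 <- fit_pooled_mixed_model(attr(long, "molpct"), attr(long, "rpkm"),
                               pairing, rpkm_min = 0)
  pairing2 <- pairing
  pairing2$replicate <- rev(pairing2$replicate)
  f2 <- fit_pooled_mixed_model(attr(long, "molpct"), attr(long, "rpkm"),
                               pairing2, rpkm_min = 0)
  expect_equal(f1$pearson_r2, f2$pearson_r2, tolerance = 1e-12)
})

test_that("slope-sign census counts positive and negative fits", {
  fits <- data.frame(gene = c("a", "b", "c"), slope = c(1, 2, -3),
                     significant = c(TRUE, FALSE, TRUE))
  cs <- slope_sign_census(fits)
  expect_equal(cs$frac_positive, 2 / 3)
  expect_equal(cs$frac_negative, 1 / 3)
  expect_equal(cs$n, 3)
  allpos <- slope_sign_census(data.frame(gene = "a", slope = 2,
                                         significant = TRUE))
  expect_equal(allpos$frac_positive, 1)
  sig <- slope_sign_census(fits, only_significant = TRUE)
  expect_equal(sig$frac_positive, 0.5)
  expect_equal(sig$frac_positive + sig$frac_negative, 1)
})

test_that("the three methods agree on a fully coupled noiseless study", {
  set.seed(17)
  n_rep <- 8
  genes <- sprintf("g%03d", 1:40)
  molpct <- matrix(exp(rnorm(40 * n_rep)), 40,
                   dimnames = list(genes, paste0("s", 1:n_rep)))
  # near-exact positive coupling (exactly zero residuals would make the
  # mixed model's covariance singular)
  rpkm <- exp(1 + 1 * log(molpct) +
                matrix(rnorm(40 * n_rep, sd = 1e-6), 40)) * 10
  dimnames(rpkm) <- list(genes, paste0("r", 1:n_rep))
  pairing <- data.frame(sample_protein = paste0("s", 1:n_rep),
                        sample_rna = paste0("r", 1:n_rep),
                        replicate = rep(c("u1", "u2"), each = n_rep / 2))
  # (a) identical fold changes
  l2 <- setNames(rnorm(40), genes)
  expect_equal(suppressWarnings(l2fc_correlation(l2, l2))$r_squared, 1)
  # (b) pooled model: R2 -> 1
  fit <- fit_pooled_mixed_model(molpct, rpkm, pairing, rpkm_min = 0)
  expect_gt(fit$pearson_r2, 0.999)
  expect_equal(fit$fixed_slope, 1, tolerance = 1e-3)
  # (c) every per-gene fit perfect with positive slope
  pg <- per_gene_regressions(molpct, rpkm, pairing, rpkm_min = 0)
  expect_true(all(pg$fits$r_squared > 0.999))
  cs <- slope_sign_census(pg)
  expect_equal(cs$frac_positive, 1)
})

test_that("coupled DE genes raise the significant-subset median R2", {
  set.seed(18)
  n_rep <- 10
  n <- 60
  genes <- sprintf("g%03d", 1:n)
  coupled <- 1:30
  molpct <- matrix(exp(rnorm(n * n_rep)), n,
                   dimnames = list(genes, paste0("s", 1:n_rep)))
  noise_sd <- c(rep(0.1, 30), rep(3, 30))    # uncoupled genes: noise only
  logr <- log(molpct) * c(rep(1, 30), rep(0, 30)) +
    matrix(rnorm(n * n_rep, sd = noise_sd), n)
  rpkm <- exp(logr) * 100
  dimnames(rpkm) <- list(genes, paste0("r", 1:n_rep))
  pairing <- data.frame(sample_protein = paste0("s", 1:n_rep),
                        sample_rna = paste0("r", 1:n_rep),
                        replicate = paste0("u", 1:n_rep))
  de <- data.frame(feature = genes,
                   significant = seq_len(n) %in% coupled)
  pg <- per_gene_regressions(molpct, rpkm, pairing, de_table = de,
                             rpkm_min = 0)
  expect_gt(pg$median_r2_significant, pg$median_r2_all)
})
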