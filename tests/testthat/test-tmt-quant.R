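test_that("tryptic digestion follows the KR-not-before-P rule", {
  expect_equal(digest_protein("AAAK"), "AAAK")
  expect_setequal(digest_protein("MKRAAAKPDER"), c("MK", "R", "AAAKPDER"))
  expect_error(digest_protein("AAKBB"), "non-canonical")
  expect_error(digest_protein(""), "empty")
})

test_that("digestion matches the exhaustive-scan oracle on random sequences", {
  set.seed(42)
  aa <- amino_acids()
  for (i in 1:25) {
    seq <- paste(sample(aa, sample(20:120, 1), replace = TRUE),
                 collapse = "")
    expect_setequal(digest_protein(seq), oracle_digest(seq))
  }
})

test_that("missed cleavages return concatenations of adjacent fragments", {
  # fully tryptic fragments of MKRAAAKPDER: MK, R, AAAKPDER
  expect_setequal(
    digest_protein("MKRAAAKPDER", missed_cleavages = 1L),
    c("MK", "R", "AAAKPDER", "MKR", "RAAAKPDER"))
  expect_setequal(
    digest_protein("MKRAAAKPDER", missed_cleavages = 2L),
    c("MK", "R", "AAAKPDER", "MKR", "RAAAKPDER", "MKRAAAKPDER"))
  # more allowed missed cleavages than sites: full set, no error
  expect_setequal(digest_protein("AAAK", missed_cleavages = 5L), "AAAK")
})

test_that("peptide masses come from the residue-mass table plus water", {
  # independent table typed here, values from the standard monoisotopic set
  tab <- c(A = 71.03711, G = 57.02146, K = 128.09496)
  expect_equal(peptide_mass("AAAK"), oracle_mass("AAAK", tab),
               tolerance = 1e-9)
  # 3 x 71.03711 + 128.09496 + 18.010565
  expect_equal(peptide_mass("AAAK"), 359.21686, tolerance = 1e-5)
})

test_that("observable peptides are counted within the mass window", {
  expect_equal(count_observable_peptides("AAAK", c(0, Inf)), 1L)
  expect_equal(count_observable_peptides(character(0)), 0L)
  # mass("AAAK") ~ 359.24 inside; "G" ~ 75.03 and "AAAKAAAK" ~ 700.47 outside
  expect_equal(
    count_observable_peptides(c("G", "AAAK", "AAAKAAAK"), c(350, 700)), 1L)
  # duplicates collapse
  expect_equal(count_observable_peptides(c("AAAK", "AAAK"), c(0, Inf)), 1L)
})

test_that("emPAI is the exponentially modified observed/observable ratio", {
  expect_equal(compute_empai(0, 10), data.frame(pai = 0, empai = 0))
  expect_equal(compute_empai(10, 10), data.frame(pai = 1, empai = 9))
  e <- compute_empai(3, 12)
  expect_equal(e$pai, 0.25)
  expect_equal(e$empai, 10^0.25 - 1, tolerance = 1e-12)
  expect_equal(round(e$empai, 5), 0.77828)
  expect_error(compute_empai(3, 0), "observable")
  # monotone nondecreasing in n_observed at fixed n_observable
  em <- compute_empai(0:12, 12)$empai
  expect_true(all(diff(em) > 0))
})

test_that("isotope impurity correction inverts the mixing exactly", {
  raw <- matrix(runif(30, 10, 100), nrow = 3)
  expect_equal(correct_isotope_impurities(raw, diag(10)), raw)

  m2 <- matrix(c(0.95, 0.05, 0.03, 0.97), nrow = 2)  # column-major
  truth <- matrix(c(40, 7), nrow = 1)
  mixed <- t(m2 %*% t(truth))
  expect_equal(correct_isotope_impurities(mixed, m2), truth,
               tolerance = 1e-10)

  # closed-form 2x2 inverse oracle for raw = (100, 0)
  det2 <- 0.95 * 0.97 - 0.03 * 0.05
  inv2 <- matrix(c(0.97, -0.05, -0.03, 0.95), nrow = 2) / det2
  raw2 <- matrix(c(100, 0), nrow = 1)
  expected <- t(inv2 %*% t(raw2))
  got <- suppressWarnings(correct_isotope_impurities(raw2, m2))
  expected[expected < 0] <- 0
  expect_equal(got, expected, tolerance = 1e-10)
  expect_warning(correct_isotope_impurities(raw2, m2), "clamped")

  expect_error(correct_isotope_impurities(raw2, matrix(1, 2, 3)), "square")
  expect_error(correct_isotope_impurities(raw2, matrix(1, 2, 2)),
               "singular")
})

test_that("identification filter enforces FDR and unique-peptide rules", {
  # 5 proteins with unique-peptide counts (1, 2, 2, 3, 1) -> 3 survive
  psms <- data.frame(
    peptide = c("AAAK", "CCCK", "DDDK", "EEEK", "FFFK", "GGGK", "HHHK",
                "IIIK", "LLLK"),
    accession = c("p1", "p2", "p2", "p3", "p3", "p4", "p4", "p4", "p5"))
  out <- filter_identifications(psms)
  expect_setequal(unique(out$accession), c("p2", "p3", "p4"))

  # all proteins >= 2 unique peptides at confidence 1.0 -> unchanged
  psms2 <- data.frame(peptide = c("AAAK", "CCCK", "DDDK", "EEEK"),
                      accession = c("p1", "p1", "p2", "p2"),
                      peptide_prob = 1, protein_prob = 1, decoy = FALSE)
  expect_equal(nrow(filter_identifications(psms2)), 4L)

  # low protein confidence removes the protein under the 3% FDR default
  psms2$protein_prob[psms2$accession == "p2"] <- 0.5
  expect_setequal(unique(filter_identifications(psms2)$accession), "p1")
})

test_that("PAMUS partitions emPAI by channel intensity and normalises to Mol%", {
  db <- c(p1 = make_sequence(10), p2 = make_sequence(10))
  peps <- digest_protein(db[["p1"]])

  # single protein: Mol% = 100 in every channel
  psms1 <- make_psms(c("p1", "p1"), peps[1:2],
                     matrix(c(5, 1, 2, 8, 3, 3), nrow = 2))
  q1 <- pamus_quantify(psms1, db, channels = paste0("ch", 1:3))
  expect_equal(unname(molpct_matrix(q1)[1, ]), c(100, 100, 100))

  # proportional split: one observed of 9 observable peptides, so
  # emPAI = 10^(1/9) - 1; channel shares follow intensity shares .5/.3/.2
  db9 <- c(px = make_sequence(9))
  psms9 <- make_psms("px", digest_protein(db9[["px"]])[1],
                     matrix(c(0.5, 0.3, 0.2), nrow = 1))
  q9 <- pamus_quantify(psms9, db9, channels = paste0("ch", 1:3))
  e <- 10^(1 / 9) - 1
  share_cols <- grep("^share_", names(q9))
  expect_equal(unname(unlist(q9[1, share_cols])), e * c(0.5, 0.3, 0.2),
               tolerance = 1e-12)

  # two proteins, equal emPAI and equal intensity vectors -> 50/50 Mol%
  psms2 <- make_psms(c("p1", "p1", "p2", "p2"),
                     peps[c(1, 2, 3, 4)],
                     matrix(rep(c(4, 2, 1), each = 4), nrow = 4))
  q2 <- pamus_quantify(psms2, db, channels = paste0("ch", 1:3))
  expect_equal(unname(molpct_matrix(q2)),
               matrix(50, 2, 3), ignore_attr = TRUE)
})

test_that("Mol% sums to 100 per channel on arbitrary PSM tables", {
  set.seed(11)
  db <- setNames(vapply(1:20, function(i) make_sequence(12),
                        character(1)), paste0("p", 1:20))
  pep_pool <- digest_protein(db[[1]])
  psms <- make_psms(
    sample(names(db), 200, replace = TRUE),
    sample(pep_pool, 200, replace = TRUE),
    matrix(rlnorm(200 * 10), nrow = 200))
  # reassign peptides so each row's peptide belongs to its protein
  psms$peptide <- vapply(psms$accession, function(a)
    sample(digest_protein(db[[a]]), 1), character(1))
  q <- pamus_quantify(psms, db)
  sums <- colSums(molpct_matrix(q))
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("quantification is invariant to PSM row order", {
  set.seed(12)
  db <- setNames(vapply(1:5, function(i) make_sequence(8),
                        character(1)), paste0("p", 1:5))
  psms <- make_psms(rep(names(db), each = 4),
                    unlist(lapply(names(db), function(a)
                      sample(digest_protein(db[[a]]), 4))),
                    matrix(rlnorm(20 * 10), nrow = 20))
  q1 <- pamus_quantify(psms, db)
  q2 <- pamus_quantify(psms[sample(nrow(psms)), ], db)
  expect_equal(q1, q2, ignore_attr = TRUE)
})

test_that("shared peptides go to the accession with the most unique peptides", {
  db <- c(pa = make_sequence(8), pb = make_sequence(8))
  peps <- digest_protein(db[["pa"]])
  psms <- make_psms(c("pa", "pa", "pa", "pb", "pa;pb"),
                    peps[1:5], matrix(1, 5, 3))
  q <- pamus_quantify(psms, db, channels = paste0("ch", 1:3))
  expect_equal(q$n_observed[q$accession == "pa"], 4L)
  expect_equal(q$n_observed[q$accession == "pb"], 1L)
})

test_that("all-zero-intensity proteins are dropped with a warning", {
  db <- c(p1 = make_sequence(8), p2 = make_sequence(8))
  psms <- make_psms(c("p1", "p1", "p2", "p2"),
                    digest_protein(db[[1]])[1:4],
                    rbind(matrix(1, 2, 3), matrix(0, 2, 3)))
  expect_warning(q <- pamus_quantify(psms, db, channels = paste0("ch", 1:3)),
                 "all-zero")
  expect_equal(q$accession, "p1")
})
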