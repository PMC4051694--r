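test_that("tryptic digestion matches brute-force enumeration", {
  expect_setequal(
    digest("MKTAYIAKQR", max_missed = 0)$peptide,
    c("MK", "TAYIAK", "QR")
  )
  expect_setequal(
    digest("MKTAYIAKQR", max_missed = 1)$peptide,
    c("MK", "TAYIAK", "QR", "MKTAYIAK", "TAYIAKQR")
  )
  expect_equal(digest("AAAA", max_missed = 1)$peptide, "AAAA")
  # proline suppresses cleavage
  expect_equal(digest("AKPA", max_missed = 0)$peptide, "AKPA")

  set.seed(42)
  for (i in 1:10) {
    s <- random_protein(sample(20:60, 1))
    for (mm in 0:2) {
      expect_setequal(digest(s, mm)$peptide, digest_oracle(s, mm))
    }
  }
})

test_that("digestion rejects unknown residues by name", {
  expect_error(digest("AKXZR"), "X")
  expect_error(peptide_mass("ABC"), "B")
})

test_that("peptide masses agree with an external monoisotopic oracle", {
  # frozen from pyteomics.mass.calculate_mass (monoisotopic)
  expect_equal(peptide_mass("AAK"), 288.17976, tolerance = 1e-6)
  expect_equal(peptide_mass("MKTAYIAKQR"), 1208.66996, tolerance = 1e-6)
  expect_equal(peptide_mass("PEPTIDEK"), 927.45493, tolerance = 1e-6)
})

test_that("PSM filter applies the score gates and ion-progression rule", {
  psms <- data.frame(
    score = c(60, 30, 25, 50, 50.0001, 26),
    consecutive_ions = c(0, 3, 9, 4, 0, 4),
    decoy = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  out <- filter_psms(psms)
  expect_equal(out$score, c(60, 50, 50.0001, 26))
  expect_true(any(out$decoy)) # decoy flag preserved

  # idempotent and order-independent
  expect_identical(filter_psms(out), out)
  shuffled <- psms[c(4, 2, 6, 1, 3, 5), ]
  expect_setequal(filter_psms(shuffled)$score, out$score)
})

test_that("decoy FDR follows the chosen estimator", {
  expect_equal(decoy_fdr(data.frame(decoy = rep(FALSE, 100))), 0)
  one_in_99 <- data.frame(decoy = c(rep(FALSE, 99), TRUE))
  expect_equal(decoy_fdr(one_in_99), 100 / 99)
  expect_equal(decoy_fdr(one_in_99, "two_times"), 100 * 2 / 100)
  expect_error(decoy_fdr(data.frame(decoy = TRUE)), "no target")

  # symmetric null: equal-sized target and decoy populations -> FDR ~ 100%
  set.seed(1)
  n <- 4000
  null_psms <- data.frame(decoy = runif(n) < 0.5)
  expect_lt(abs(decoy_fdr(null_psms) - 100), 3 * 100 / sqrt(n / 4))
})

test_that("protein inference groups indistinguishable proteins", {
  proteome <- c(
    P1 = "MKTAYIAKQR", P2 = "MKTAYIAKQR", P3 = "AAAAKTTTTR"
  )
  one <- data.frame(peptide = "TAYIAK", protein_id = "P1", decoy = FALSE)
  g <- infer_proteins(one, proteome)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_observed, 1L)
  expect_true(g$single_peptide)

  # identical peptide sets merge into a single group
  shared <- data.frame(
    peptide = c("TAYIAK", "TAYIAK"),
    protein_id = c("P1", "P2"), decoy = FALSE
  )
  g2 <- infer_proteins(shared, proteome)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$protein_id, "P1;P2")

  expect_error(
    infer_proteins(
      data.frame(peptide = "AAAAK", protein_id = "NOPE", decoy = FALSE),
      proteome
    ),
    "NOPE"
  )
})

test_that("inference on random fixtures equals a brute-force grouping oracle", {
  set.seed(7)
  for (trial in 1:5) {
    n_prot <- 20
    proteome <- setNames(
      vapply(rep(60, n_prot), random_protein, character(1)),
      sprintf("P%02d", seq_len(n_prot))
    )
    # sample observed peptides, with deliberate sharing via duplicate ids
    pool <- do.call(rbind, lapply(names(proteome), function(id) {
      d <- digest(proteome[[id]], 0)
      data.frame(peptide = d$peptide, protein_id = id)
    }))
    obs <- pool[sample(nrow(pool), 30, replace = TRUE), ]
    obs$decoy <- FALSE
    g <- infer_proteins(obs, proteome)

    # oracle: group proteins by identical observed-peptide incidence columns
    prots <- unique(obs$protein_id)
    peps <- unique(obs$peptide)
    inc <- sapply(prots, function(p) {
      peps %in% obs$peptide[obs$protein_id == p]
    })
    if (length(peps) == 1L) inc <- matrix(inc, nrow = 1L)
    n_groups_oracle <- length(unique(apply(inc, 2, paste, collapse = "")))
    expect_equal(nrow(g), n_groups_oracle)
  }
})

test_that("emPAI follows its defining formula and monotonicity", {
  expect_equal(empai(0, 5), 0)
  expect_equal(empai(6, 6), 9)
  expect_equal(empai(3, 6), 10^0.5 - 1)
  expect_error(empai(1, 0), "N_observable")
  vals <- empai(0:8, 8)
  expect_true(all(diff(vals) > 0))
})

test_that("method aggregation reproduces exact Venn arithmetic", {
  r <- aggregate_methods(list(A = "p1"), theoretical_size = 10)
  expect_equal(r$union_size, 1L)
  expect_equal(r$coverage, 0.1)

  set.seed(3)
  for (trial in 1:5) {
    inv <- lapply(setNames(1:4, c("A", "B", "C", "D")), function(i) {
      sample(sprintf("id%02d", 1:50), sample(5:50, 1))
    })
    rep_ <- aggregate_methods(inv)
    oracle <- venn_oracle(inv)
    got <- setNames(rep_$venn$count, rep_$venn$region)
    expect_true(all(got[names(oracle)] == as.integer(oracle)))
    # regions not in the oracle are empty; counts sum to the union
    expect_equal(sum(rep_$venn$count), rep_$union_size)
    expect_true(all(rep_$venn$count >= 0))
  }
})

test_that("emPAI ranking matches an independent sort oracle", {
  set.seed(9)
  groups <- data.frame(
    protein_id = sprintf("P%02d", 1:30),
    empai = round(runif(30, 0, 5), 2)
  )
  top <- top_n_by_empai(groups, 10)
  oracle <- groups[order(-groups$empai, groups$protein_id), ][1:10, ]
  expect_equal(top$protein_id, oracle$protein_id)
  # n larger than the list returns everything
  expect_equal(nrow(top_n_by_empai(groups, 100)), 30L)

  # two fractions sharing exactly 5 of their top-20
  a <- data.frame(
    protein_id = sprintf("A%02d", 1:40),
    empai = seq(40, 1)
  )
  b <- a
  b$protein_id[1:20] <- c(a$protein_id[1:5], sprintf("B%02d", 1:15))
  expect_equal(top_n_shared(a, b, 20), 5L)
})

test_that("decoy FDR recovers the configured rate on synthetic data", {
  cfg <- sim_config(
    n_proteins = 500, decoy_psm_rate = 0.03, seed = 29,
    method_detection_probs = c(A = 0.6, B = 0.6)
  )
  truth <- generate_proteome(cfg)
  psms <- simulate_psm_tables(truth, cfg)
  n <- nrow(psms)
  expect_gt(n, 1e4)
  f <- decoy_fdr(psms) # 100 * D / T over all generated PSMs
  implied_fraction <- f / (100 + f) # back to D / (D + T)
  ci <- 1.96 * sqrt(0.03 * 0.97 / n)
  expect_lt(abs(implied_fraction - 0.03), ci + 1e-12)
})
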