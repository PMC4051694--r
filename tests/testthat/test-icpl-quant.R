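test_that("pair matching accepts co-eluting traces and rejects the rest", {
  g <- gaussian_trace(7)
  perfect <- match_pair(g$rt, g$intensity, g$rt, 2 * g$intensity)
  expect_true(perfect$accepted)
  expect_equal(perfect$correlation, 1.0)

  skew <- 100 * dnorm(g$rt, 1.2, 1.2) # off-centre peak: reversal decorrelates
  reversed <- match_pair(g$rt, skew, g$rt, rev(skew))
  expect_false(reversed$accepted)
  expect_equal(reversed$reason, "low_correlation")
  expect_lt(reversed$correlation, 0.8)

  flat <- match_pair(g$rt, rep(5, 7), g$rt, g$intensity)
  expect_false(flat$accepted)
  expect_equal(flat$reason, "zero_variance")

  narrow <- match_pair(0:1, c(1, 2), 0:1, c(2, 4))
  expect_false(narrow$accepted)
  expect_equal(narrow$reason, "insufficient_overlap")
})

test_that("integration window honours max width and apex threshold", {
  g <- gaussian_trace(21, width = 2)
  pair <- match_pair(g$rt, g$intensity, g$rt, g$intensity, max_width = 7)
  expect_true(pair$accepted)
  expect_lte(length(pair$rt), 7L)
  apex <- max(pair$intensity_light + pair$intensity_heavy)
  expect_true(all(pair$intensity_light + pair$intensity_heavy >= 0.2 * apex))
  # window is centred: apex scan inside the window
  expect_true(g$rt[which.max(g$intensity)] %in% pair$rt)
})

test_that("Simpson integration is exact for cubics and accurate on peaks", {
  x5 <- seq(0, 2, length.out = 5)
  expect_equal(integrate_simpson(x5, rep(0, 5)), 0)
  expect_equal(integrate_simpson(x5, x5^2), 8 / 3)
  x9 <- seq(0, 1, length.out = 9)
  expect_equal(integrate_simpson(x9, x9^3 - 2 * x9^2 + 3), 1 / 4 - 2 / 3 + 3)
  expect_error(integrate_simpson(c(0, 1), c(1, 1)), "3 points")

  # Gaussian peak vs 1e4-point trapezoid oracle, within 0.1%
  g <- gaussian_trace(21, area = 50, width = 2)
  simp <- integrate_simpson(g$rt, g$intensity)
  fine <- seq(min(g$rt), max(g$rt), length.out = 1e4)
  fy <- 50 * dnorm(fine, g$rt[11], 2)
  trap <- sum(diff(fine) * (head(fy, -1) + tail(fy, -1)) / 2)
  expect_lt(abs(simp - trap) / trap, 0.001)

  # odd interval count falls back to trapezoid on the last slice
  x4 <- c(0, 1, 2, 3)
  expect_equal(integrate_simpson(x4, rep(2, 4)), 6)

  # linear in intensity (scale equivariance of areas)
  expect_equal(
    integrate_simpson(g$rt, 3 * g$intensity),
    3 * simp
  )
})

test_that("peptide ratios apply the strict ion-score gate", {
  g <- gaussian_trace(7)
  pair <- match_pair(g$rt, g$intensity, g$rt, 3 * g$intensity)
  equal_pair <- match_pair(g$rt, g$intensity, g$rt, g$intensity)

  expect_equal(peptide_ratio(equal_pair, ion_score = 50)$ratio, 1.0)
  expect_equal(peptide_ratio(pair, ion_score = 45)$ratio, 3.0)
  r30 <- peptide_ratio(pair, ion_score = 30)
  expect_false(r30$accepted)
  expect_equal(r30$reason, "low_ion_score")

  zero <- pair
  zero$area_light <- 0
  expect_equal(peptide_ratio(zero, 50)$reason, "zero_light_area")
})

test_that("median normalization forces the run median to one", {
  expect_equal(median_normalize(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(median_normalize(c(1, 2, 4)), c(0.5, 1, 2))
  set.seed(5)
  for (i in 1:10) {
    x <- rlnorm(2 * sample(3:20, 1) + 1) # odd n: median exactly 1
    expect_equal(median(median_normalize(x)), 1)
  }
  # data-frame form normalizes per run
  df <- data.frame(ratio = c(2, 4, 8, 10, 20, 40), replicate = rep(1:2, each = 3))
  norm <- median_normalize(df, run = "replicate")
  expect_equal(norm$ratio_normalized, c(0.5, 1, 2, 0.5, 1, 2))
})

test_that("protein rollup implements the log-space significance test", {
  r <- rollup_protein(c(2, 0.5))
  expect_equal(r$ratio, 1.0)
  expect_equal(r$log_mean, 0)
  expect_false(r$significant)
  expect_error(rollup_protein(numeric(0)), "at least one")

  # single-peptide protein: no spread, never significant
  r1 <- rollup_protein(1.9)
  expect_equal(r1$n, 1L)
  expect_false(r1$significant)
  expect_true(is.na(r1$sdgeo))

  # brute-force oracle: recompute every term of |x| > t*s/sqrt(N) in log10
  set.seed(12)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    ratios <- rlnorm(n, meanlog = rnorm(1, 0, 0.3), sdlog = 0.25)
    got <- rollup_protein(ratios)
    lx <- log10(ratios)
    verdict <- abs(mean(lx)) > qt(0.975, n - 1) * sd(lx) / sqrt(n)
    expect_equal(got$significant, verdict) # log-base invariance included
    expect_equal(got$ratio, exp(mean(log(ratios))))
    expect_gte(got$sdgeo, 1)
  }
})

test_that("published summary statistics reproduce their significance calls", {
  expect_true(significant_vs_unity(0.52, 1.04, 2))
  expect_false(significant_vs_unity(0.55, 1.13, 2))
  expect_true(is.na(significant_vs_unity(1.14, NA, 10)))
  # explicit arithmetic: |ln 0.52| = 0.6539 vs 12.706 * ln 1.04 / sqrt(2)
  expect_gt(abs(log(0.52)), qt(0.975, 1) * log(1.04) / sqrt(2))
  expect_lt(abs(log(0.55)), qt(0.975, 1) * log(1.13) / sqrt(2))
})

test_that("replicate combination is a geometric mean in linear space", {
  rec <- data.frame(
    protein_id = c("P1", "P1", "P2", "P2", "P3"),
    replicate = c(1L, 2L, 1L, 2L, 1L),
    ratio = c(1.13, 1.30, 2.0, 0.5, 3.0),
    n = c(3L, 3L, 2L, 2L, 2L),
    significant = TRUE
  )
  out <- combine_replicates(rec)
  p1 <- out$summaries[out$summaries$protein_id == "P1", ]
  expect_equal(p1$combined_ratio, exp((log(1.13) + log(1.30)) / 2))
  expect_equal(round(p1$combined_ratio, 4), 1.212)
  p2 <- out$summaries[out$summaries$protein_id == "P2", ]
  expect_equal(p2$combined_ratio, 1.0)
  expect_equal(out$excluded$protein_id, "P3")
  expect_equal(out$excluded$reason, "missing_replicate")

  # identical replicates: combined ratio r, geometric SD exactly 1
  same <- data.frame(
    protein_id = "Q", replicate = 1:2, ratio = 1.7,
    n = 2L, significant = FALSE
  )
  s <- combine_replicates(same)$summaries
  expect_equal(s$combined_ratio, 1.7)
  expect_equal(s$combined_sdgeo, 1)

  # betweenness: combined ratio lies between the replicate ratios
  expect_true(p1$combined_ratio >= 1.13 && p1$combined_ratio <= 1.30)
})

test_that("differential filter enforces thresholds, significance and coverage", {
  mk <- function(id, r1, r2, sig1, sig2, n1 = 3L, n2 = 3L) {
    data.frame(
      protein_id = id, replicate = 1:2, ratio = c(r1, r2),
      n = c(n1, n2), significant = c(sig1, sig2)
    )
  }
  rec <- rbind(
    mk("inside_band", 1.10, 1.12, TRUE, TRUE), # threshold fail
    mk("down_rep1", 0.70, 0.90, TRUE, FALSE), # retained via rep1
    mk("up_not_sig", 1.50, 1.60, FALSE, FALSE), # significance fail
    mk("one_pep", 0.50, 0.55, TRUE, TRUE, n2 = 1L) # coverage fail
  )
  out <- differential_filter(rec)
  expect_equal(out$protein_id, "down_rep1")
  expect_equal(out$direction, "down")

  # strict-average variant keys on the combined ratio instead
  strict <- differential_filter(rec, rule = "strict_average")
  expect_equal(strict$protein_id, "down_rep1")
  borderline <- mk("avg_inside", 0.70, 1.05, TRUE, FALSE)
  expect_equal(nrow(differential_filter(borderline, rule = "strict_average")), 0L)
  expect_equal(differential_filter(borderline)$protein_id, "avg_inside")
})

test_that("type-I error of the significance test matches its nominal level", {
  set.seed(101)
  n_prot <- 2000
  flags <- vapply(seq_len(n_prot), function(i) {
    rollup_protein(exp(rnorm(4, 0, 0.3)))$significant
  }, logical(1))
  rate <- mean(flags)
  expect_lt(abs(rate - 0.05), 1.5e-2) # exact test; 3 binomial SDs ~ 1.5%
})

test_that("rollup recovers a simulated two-fold change", {
  set.seed(202)
  est <- vapply(seq_len(300), function(i) {
    rollup_protein(exp(rnorm(8, log(2), 0.2)))$ratio
  }, numeric(1))
  expect_gt(median(est), 1.9)
  expect_lt(median(est), 2.1)
})

test_that("quantification is scale equivariant and normalization removes it", {
  cfg <- sim_config(n_proteins = 12, seed = 55)
  truth <- generate_proteome(cfg)
  x <- simulate_xic_pairs(truth, cfg, replicate = 1, keep_all = TRUE)
  q1 <- quantify_xic_pairs(x)
  x2 <- x
  x2$traces$intensity_heavy <- x2$traces$intensity_heavy * 3
  q2 <- quantify_xic_pairs(x2)
  common <- intersect(q1$ratios$peptide, q2$ratios$peptide)
  m1 <- q1$ratios$ratio[match(common, q1$ratios$peptide)]
  m2 <- q2$ratios$ratio[match(common, q2$ratios$peptide)]
  expect_equal(m2, 3 * m1, tolerance = 1e-9)
  expect_equal(
    median_normalize(m2),
    median_normalize(m1),
    tolerance = 1e-9
  )
})

test_that("quantified ratios reproduce the simulated areas end to end", {
  cfg <- sim_config(n_proteins = 10, seed = 77)
  truth <- generate_proteome(cfg)
  x <- simulate_xic_pairs(truth, cfg, replicate = 1, keep_all = TRUE)
  q <- quantify_xic_pairs(x)
  expect_gt(nrow(q$ratios), 0)
  sim <- x$pairs$sim_area_ratio[match(q$ratios$peptide, x$pairs$peptide)]
  # identical Gaussian shapes: windowed Simpson areas keep the exact ratio
  expect_equal(q$ratios$ratio, sim, tolerance = 1e-9)
  # rejections only for the ion-score gate on this clean fixture
  expect_true(all(q$rejected$reason == "low_ion_score"))
})
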