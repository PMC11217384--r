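ct_fix <- function(r, s) list(r = as.integer(r), s = as.integer(s))

test_that("identical case/control genotype distributions give zero statistics", {
  t0 <- ct_fix(c(10, 30, 10), c(10, 30, 10))
  expect_equal(trend_test(t0)$statistic, 0, tolerance = 1e-12)
  expect_equal(trend_test(t0)$p, 1, tolerance = 1e-12)
  expect_equal(model_test(t0, "allelic")$statistic, 0, tolerance = 1e-12)
  expect_equal(genotypic_test(t0)$statistic, 0, tolerance = 1e-12)
  expect_equal(genotypic_test(t0)$p, 1, tolerance = 1e-12)
})

test_that("the trend statistic equals the direct score-test formula", {
  t1 <- ct_fix(c(10, 30, 10), c(30, 15, 5))
  expect_equal(trend_test(t1)$statistic,
               oracle_trend_chisq(t1$r, t1$s), tolerance = 1e-10)
  expect_equal(trend_test(t1)$df, 1L)
  set.seed(99)
  for (i in 1:30) {
    r <- rpois(3, c(10, 8, 3)); s <- rpois(3, c(12, 6, 2))
    if (sum(r) == 0 || sum(s) == 0 || sum((r + s) > 0) < 2) next
    expect_equal(trend_test(ct_fix(r, s))$statistic,
                 oracle_trend_chisq(r, s), tolerance = 1e-10)
  }
})

test_that("the trend p-value approximates its permutation distribution", {
  set.seed(2024)
  dos <- c(rbinom(50, 2, 0.35), rbinom(50, 2, 0.2))
  lab <- rep(c("case", "control"), each = 50)
  obs <- trend_test(ct_fix(tabulate(dos[lab == "case"] + 1L, 3L),
                           tabulate(dos[lab == "control"] + 1L, 3L)))
  nperm <- 10000L
  stat_perm <- replicate(nperm, {
    sh <- sample(lab)
    r <- tabulate(dos[sh == "case"] + 1L, 3L)
    s <- tabulate(dos[sh == "control"] + 1L, 3L)
    oracle_trend_chisq(r, s)
  })
  # the permutation distribution is discrete with a sizeable atom at the
  # observed statistic; the asymptotic p approximates its mid-p (half the
  # atom counted), the standard continuity-corrected comparison
  atom <- mean(abs(stat_perm - obs$statistic) < 1e-9)
  p_mid <- mean(stat_perm > obs$statistic + 1e-9) + 0.5 * atom
  mc_se <- sqrt(max(p_mid, 1e-4) * (1 - max(p_mid, 1e-4)) / nperm)
  expect_lt(abs(obs$p - p_mid), max(4 * mc_se, 0.01))
})

test_that("the 2x2 model tables follow the model definitions", {
  # dominant on (42,4,0) vs (51,0,0): the published 4/46 vs 0/51 comparison
  t2 <- ct_fix(c(42, 4, 0), c(51, 0, 0))
  dom <- model_test(t2, "dominant")
  expect_equal(dom$statistic,
               oracle_pearson_chisq(rbind(c(42, 4), c(51, 0))),
               tolerance = 1e-10)
  # allelic with equal allele frequencies is exactly null
  t3 <- ct_fix(c(16, 8, 1), c(16, 8, 1))
  expect_equal(model_test(t3, "allelic")$statistic, 0, tolerance = 1e-12)
})

test_that("all 2x2 and 2x3 statistics match the direct O/E formula on random fixtures", {
  set.seed(7)
  checked <- 0L
  while (checked < 30L) {
    r <- rpois(3, c(15, 10, 4)); s <- rpois(3, c(18, 8, 3))
    t <- ct_fix(r, s)
    al <- rbind(c(2 * r[1] + r[2], r[2] + 2 * r[3]),
                c(2 * s[1] + s[2], s[2] + 2 * s[3]))
    dm <- rbind(c(r[1], r[2] + r[3]), c(s[1], s[2] + s[3]))
    rc <- rbind(c(r[1] + r[2], r[3]), c(s[1] + s[2], s[3]))
    if (any(c(rowSums(al), colSums(al), rowSums(dm), colSums(dm),
              rowSums(rc), colSums(rc)) == 0)) next
    expect_equal(model_test(t, "allelic")$statistic,
                 oracle_pearson_chisq(al), tolerance = 1e-10)
    expect_equal(model_test(t, "dominant")$statistic,
                 oracle_pearson_chisq(dm), tolerance = 1e-10)
    expect_equal(model_test(t, "recessive")$statistic,
                 oracle_pearson_chisq(rc), tolerance = 1e-10)
    occ <- (r + s) > 0
    expect_equal(genotypic_test(t)$statistic,
                 oracle_pearson_chisq(rbind(r[occ], s[occ])),
                 tolerance = 1e-10)
    checked <- checked + 1L
  }
})

test_that("statistics are invariant to allele relabeling with dosage reflection", {
  set.seed(8)
  for (i in 1:10) {
    r <- rpois(3, c(12, 9, 4)) + 1L; s <- rpois(3, c(12, 9, 4)) + 1L
    t <- ct_fix(r, s); t_rev <- ct_fix(rev(r), rev(s))
    expect_equal(trend_test(t)$statistic, trend_test(t_rev)$statistic,
                 tolerance = 1e-10)
    expect_equal(model_test(t, "allelic")$statistic,
                 model_test(t_rev, "allelic")$statistic, tolerance = 1e-10)
    expect_equal(genotypic_test(t)$statistic,
                 genotypic_test(t_rev)$statistic, tolerance = 1e-10)
    # dominant on reflected dosages equals recessive on the original
    expect_equal(model_test(t_rev, "dominant")$statistic,
                 model_test(t, "recessive")$statistic, tolerance = 1e-10)
  }
})

test_that("degenerate tables yield an undefined-test signal, not a number", {
  mono <- ct_fix(c(20, 0, 0), c(25, 0, 0))
  expect_true(is.na(trend_test(mono)$p))
  expect_true(is.na(genotypic_test(mono)$p))
  expect_true(is.na(model_test(mono, "dominant")$p))
  expect_match(trend_test(mono)$note, "single occupied")
  no_ctrl <- ct_fix(c(10, 5, 1), c(0, 0, 0))
  expect_true(is.na(trend_test(no_ctrl)$p))
})

test_that("the genotypic df drops with empty genotype columns", {
  t23 <- ct_fix(c(10, 8, 2), c(12, 6, 1))
  expect_equal(genotypic_test(t23)$df, 2L)
  t22 <- ct_fix(c(10, 8, 0), c(12, 6, 0))
  expect_equal(genotypic_test(t22)$df, 1L)
})

test_that("sva_scan runs five models per QC-passing variant in the requested strata", {
  co <- simulate_cohort(null_spec(21L, n_genes = 10L,
                                  maf_spectrum = list(list(weight = 1,
                                                           type = "uniform",
                                                           min = 0.1,
                                                           max = 0.4))))
  qc <- site_qc(co$genotypes, co$phenotypes)
  res <- sva_scan(co$genotypes, co$phenotypes, qc, strata = "common")
  expect_equal(sort(unique(res$model)), sort(sva_models))
  n_tested <- length(unique(res$vid))
  expect_equal(nrow(res), 5L * n_tested)
  expect_true(all(res$stratum == "common"))
  expect_true(all(res$vid %in% qc$vid[qc$qc_pass & qc$stratum == "common"]))
  expect_true(all(res$statistic >= 0, na.rm = TRUE))
  expect_true(all(res$df[res$model != "genotypic"] == 1L, na.rm = TRUE))
})

test_that("under an additive risk model the trend test beats the dominant model", {
  # planted common variant, allelic odds ratio 3 at control MAF 0.2, 50 vs 50
  reps <- 500L
  hits <- c(trend = 0L, dominant = 0L)
  set.seed(321)
  for (i in seq_len(reps)) {
    p0 <- 0.2
    o <- 3 * p0 / (1 - p0); p1 <- o / (1 + o)
    r <- tabulate(rbinom(50, 2, p1) + 1L, 3L)
    s <- tabulate(rbinom(50, 2, p0) + 1L, 3L)
    tt <- trend_test(ct_fix(r, s))$p
    dd <- model_test(ct_fix(r, s), "dominant")$p
    if (!is.na(tt) && tt < 0.05) hits["trend"] <- hits["trend"] + 1L
    if (!is.na(dd) && dd < 0.05) hits["dominant"] <- hits["dominant"] + 1L
  }
  expect_gt(hits[["trend"]], hits[["dominant"]])
})
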