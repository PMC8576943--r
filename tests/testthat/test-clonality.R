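test_that("the CCF formula reproduces hand-computed cases", {
  ## pure diploid heterozygous: vaf 0.5 -> ccf 1
  r <- computeCcf(50, 100, purity = 1)
  expect_equal(r$vaf, 0.5)
  expect_equal(r$multiplicity, 1)
  expect_equal(r$ccf, 1.0)
  ## purity 0.8: vaf 0.3 -> m = round(0.3*2/0.8) = 1, ccf = 0.3*2/0.8 = 0.75
  r2 <- computeCcf(30, 100, purity = 0.8)
  expect_equal(r2$multiplicity, 1)
  expect_equal(r2$ccf, 0.75)
  ## zero depth is not assessable, no error
  expect_equal(computeCcf(0, 0, purity = 1)$status, "not_assessable")
})

test_that("confidence bounds match the exact binomial oracle", {
  cases <- rbind(c(30, 100, 0.8, 2), c(90, 100, 0.9, 2), c(5, 50, 1, 2),
                 c(0, 80, 0.7, 2), c(80, 80, 1, 2), c(40, 200, 0.6, 3))
  for (i in seq_len(nrow(cases))) {
    alt <- cases[i, 1]; dp <- cases[i, 2]
    rho <- cases[i, 3]; cnt <- cases[i, 4]
    r <- computeCcf(alt, dp, purity = rho, cn_tumor = cnt)
    ci <- stats::binom.test(alt, dp)$conf.int
    scale <- (rho * cnt + (1 - rho) * 2) / (rho * r$multiplicity)
    clamp <- function(x) pmin(pmax(x, 0), 1.5)
    expect_equal(r$ci_low, clamp(ci[1] * scale), tolerance = 1e-9)
    expect_equal(r$ci_high, clamp(ci[2] * scale), tolerance = 1e-9)
    expect_equal(r$status,
                 if (clamp(ci[2] * scale) < 0.95) "subclonal" else "clonal")
    expect_true(r$ci_low <= r$ccf && r$ccf <= r$ci_high)
  }
})

test_that("CCF is monotone in alt reads and scale-invariant in depth", {
  ## monotone within a fixed-multiplicity regime (m = 1 throughout here;
  ## at an m transition the point estimate legitimately re-scales)
  cc <- computeCcf(seq(0, 50, by = 5), 100, purity = 0.8)
  expect_true(all(cc$multiplicity == 1))
  expect_true(all(diff(cc$ccf) >= 0))
  a <- computeCcf(30, 100, purity = 0.8)
  b <- computeCcf(300, 1000, purity = 0.8)
  expect_equal(a$ccf, b$ccf)
  expect_lt(b$ci_high - b$ci_low, a$ci_high - a$ci_low)
})

test_that("per-patient pooling sums reads and classifies on pooled CCF", {
  vt <- filteredTable(depth = cbind(s1 = 100L, s2 = 100L),
                      alt = cbind(s1 = 30L, s2 = 0L), purity = 1)
  pp <- perPatientClonality(vt)
  expect_equal(pp$vaf, 0.15)
  expect_equal(pp$ccf, 0.30)
  expect_equal(pp$status, "subclonal")
  ## symmetric 50/100 in both samples: pooled ccf 1, clonal
  vt2 <- filteredTable(depth = cbind(s1 = 100L, s2 = 100L),
                       alt = cbind(s1 = 50L, s2 = 50L), purity = 1)
  pp2 <- perPatientClonality(vt2)
  expect_equal(pp2$ccf, 1.0)
  expect_equal(pp2$status, "clonal")
  ## single-sample patient: pooled equals per-sample
  vt3 <- filteredTable(depth = cbind(s1 = 100L), alt = cbind(s1 = 50L),
                       purity = 0.9)
  ps3 <- perSampleClonality(vt3)
  pp3 <- perPatientClonality(vt3)
  expect_equal(pp3$ccf, ps3$ccf)
  expect_equal(pp3$ci_high, ps3$ci_high)
})

test_that("clonal illusion flags sample-clonal but patient-subclonal variants", {
  ## v1 clonal in s1, absent in s2; v2 truncal everywhere
  vt <- filteredTable(depth = matrix(200L, 2, 2),
                      alt = rbind(c(100L, 0L), c(100L, 100L)), purity = 1)
  ps <- perSampleClonality(vt)
  pp <- perPatientClonality(vt)
  rep <- clonalIllusionReport(ps, pp)
  expect_equal(rep$variant_id, rownames(vt)[1])
  expect_equal(rep$samples_clonal, "s1")
  ## empty inputs give an empty report
  e <- clonalIllusionReport(ps[0, ], pp[0, ])
  expect_equal(nrow(e), 0L)
  expect_error(clonalIllusionReport(ps[ps$variant_id == rownames(vt)[1], ],
                                    pp), "different variant sets")
})

test_that("truncal variants are not demoted by pooling at high depth", {
  cfg <- simConfig(n_regions = 5, n_clonal = 40, depth_mean = 200,
                   purity = 0.9, mu_eff = 5, seed = 51)
  vt <- recoverVariants(applyFilters(simulateTumor(cfg)))
  truth <- metadata(vt)$truth
  pp <- perPatientClonality(vt)
  tc <- truth$truly_clonal[match(pp$variant_id, truth$variant_id)]
  sens <- mean(pp$status[tc] == "clonal")
  expect_gte(sens, 0.9)
})

test_that("the apparent-clonal curve matches exhaustive subset counting", {
  ## truncal set of 3 shared by all, disjoint private sets of sizes 2,1,3
  pres <- rbind(matrix(TRUE, 3, 3),
                cbind(matrix(c(TRUE, TRUE), 2), FALSE, FALSE),
                cbind(FALSE, TRUE, FALSE),
                cbind(matrix(FALSE, 3, 2), TRUE))
  curve <- apparentClonalCurve(pres)
  expect_equal(curve[1], 3 + mean(c(2, 1, 3)))
  expect_equal(curve[2], 3)
  expect_equal(curve[3], 3)
  ## identical samples: constant curve
  expect_equal(apparentClonalCurve(matrix(TRUE, 5, 4)), rep(5, 4))
  ## non-increasing on random fixtures
  set.seed(52)
  for (i in 1:10) {
    p <- matrix(runif(60) < 0.5, 12, 5)
    expect_true(all(diff(apparentClonalCurve(p)) <= 1e-9))
  }
  expect_error(apparentClonalCurve(matrix(TRUE, 3, 1)), "2 samples")
})

test_that("balance-factor fitting inverts exact geometric curves", {
  fit <- fitBalanceFactor(100 + 50 * 0.5^(0:4))
  expect_equal(fit@g, 0.5, tolerance = 1e-6)
  expect_equal(fit@c_inf, 100, tolerance = 1e-6)
  ## constant curve: boundary g, c_inf = C(1)
  fit2 <- fitBalanceFactor(rep(80, 5))
  expect_lt(fit2@g, 1e-5)
  expect_equal(fit2@c_inf, 80)
  expect_error(fitBalanceFactor(c(3, 2)), "3 points")
})

test_that("balance factor is recovered from Bernoulli-mixing tumors", {
  ## C(n) = T + V g^n in expectation when each non-truncal variant enters
  ## each sample independently with probability g
  set.seed(53)
  errs <- replicate(20, {
    g_true <- 0.5
    pres <- rbind(matrix(TRUE, 50, 6),
                  matrix(runif(200 * 6) < g_true, 200, 6))
    fit <- fitBalanceFactor(apparentClonalCurve(pres))
    abs(balanceG(fit) - g_true)
  })
  expect_lte(median(errs), 0.1)
})

test_that("the c_inf estimate tracks the true truncal count on simulations", {
  set.seed(54)
  devs <- vapply(1:7, function(i) {
    cfg <- simConfig(n_regions = 5, n_clonal = 40, depth_mean = 200,
                     purity = 0.9, mu_eff = 0, seed = 530 + i)
    vt <- recoverVariants(applyFilters(simulateTumor(cfg)))
    fit <- fitBalanceFactor(apparentClonalCurve(vt))
    abs(fit@c_inf - 40) / 40
  }, numeric(1))
  expect_lte(median(devs), 0.15)
})

test_that("samples-needed follows the closed form and is monotone", {
  expect_equal(samplesNeeded(0.2, 0.98)$n, 3L)    # ln 0.02 / ln 0.2 = 2.43
  expect_equal(samplesNeeded(0.56, 0.90)$n, 4L)
  expect_equal(samplesNeeded(1e-9, 0.9)$n, 1L)    # g -> 0+: one sample
  expect_error(samplesNeeded(1, 0.9))
  expect_error(samplesNeeded(0.5, 1))
  ## P_correct strictly increasing in n; n needed non-decreasing in g and p
  expect_true(all(diff(pCorrect(0.56, 1:10)) > 0))
  ns_g <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                 function(g) samplesNeeded(g, 0.9)$n, integer(1))
  expect_true(all(diff(ns_g) >= 0))
  ns_p <- vapply(c(0.5, 0.8, 0.9, 0.99),
                 function(p) samplesNeeded(0.5, p)$n, integer(1))
  expect_true(all(diff(ns_p) >= 0))
})
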