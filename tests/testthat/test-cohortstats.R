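test_that("exact paired Wilcoxon reproduces hand-enumerated cases", {
  # three positive differences: extreme W among 2^3 sign patterns
  expect_equal(pairedWilcoxon(c(1, 2, 3), c(2, 3, 5))$p, 0.25)
  # balanced antisymmetric pattern at n = 4: W at the null midpoint
  expect_equal(pairedWilcoxon(c(0, 0, 0, 0), c(1, -1, 2, -2))$p, 1.0)
  expect_error(pairedWilcoxon(1:4, 1:4), "degenerate pairs")
})

test_that("zero differences are discarded and counted", {
  r <- pairedWilcoxon(c(1, 2, 3, 4), c(1, 3, 4, 6))
  expect_equal(r$n, 3)
  expect_match(r$note, "1 zero difference")
})

test_that("exact Wilcoxon agrees with the enumeration oracle and wilcox.test", {
  set.seed(1)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    pre <- round(rnorm(n, 10, 3), 1)
    post <- pre + round(rnorm(n, 0.5, 1.5), 1)
    if (sum(post != pre) < 3) next
    p_pkg <- pairedWilcoxon(pre, post)$p
    expect_equal(p_pkg, oracleWilcoxonP(pre, post), tolerance = 1e-12)
    d <- post - pre
    if (all(d != 0) && !any(duplicated(abs(d)))) {
      expect_equal(p_pkg,
                   stats::wilcox.test(post, pre, paired = TRUE,
                                      exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("exact Mann-Whitney reproduces hand-enumerated cases", {
  # complete separation at nA = nB = 4: p = 2 / choose(8, 4)
  expect_equal(mannWhitneyU(1:4, 5:8)$p, 2 / 70, tolerance = 1e-12)
  # identical multisets: midpoint, p = 1
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with the pair-counting oracle", {
  set.seed(2)
  for (i in 1:60) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- round(rnorm(na, 0, 2), 1)
    b <- round(rnorm(nb, 0.5, 2), 1)
    p_pkg <- mannWhitneyU(a, b)$p
    expect_equal(p_pkg, oracleMannWhitneyP(a, b), tolerance = 1e-12)
    if (!any(duplicated(c(a, b)))) {
      expect_equal(p_pkg,
                   stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("tau-b matches the pair-enumeration oracle, with and without ties", {
  expect_equal(kendallTauB(1:5, c(2, 4, 6, 8, 10))$estimate, 1)
  expect_equal(kendallTauB(1:5, 5:1)$estimate, -1)
  expect_equal(kendallTauB(c(1, 2, 2, 3), c(1, 2, 3, 3))$estimate,
               oracleTauB(c(1, 2, 2, 3), c(1, 2, 3, 3)),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) {
      r <- kendallTauB(x, y)
      expect_true(is.na(r$estimate))
      expect_match(r$note, "undefined")
    } else {
      expect_equal(kendallTauB(x, y)$estimate, oracleTauB(x, y),
                   tolerance = 1e-12)
      expect_equal(kendallTauB(x, y)$estimate,
                   stats::cor(x, y, method = "kendall"),
                   tolerance = 1e-12)
    }
  }
})

test_that("Pearson r is exact on collinear data and matches the formula", {
  expect_equal(pearsonR(1:3, c(2, 4, 6))$estimate, 1)
  set.seed(4)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  r <- pearsonR(x, y)$estimate
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, brute, tolerance = 1e-12)
  # invariance under positive affine maps
  expect_equal(pearsonR(3 * x + 2, 0.1 * y - 7)$estimate, r,
               tolerance = 1e-12)
  expect_error(pearsonR(rep(1, 5), 1:5), "constant")
})

test_that("subgroup delta tests compare post-pre changes between labels", {
  ch <- defaultCohort()$cohort
  g <- ch@patients$af
  if (length(unique(g)) == 2) {
    r <- subgroupDeltaTest(ch, "ef", "af")
    d <- ch@post[, "ef"] - ch@pre[, "ef"]
    expect_equal(r$p, mannWhitneyU(d[!g], d[g])$p, tolerance = 1e-12)
  }
  expect_error(subgroupDeltaTest(ch, "nonesuch", "af"), "unknown index")
})

test_that("cohort tables carry every clinical row with mean, SD and markers", {
  ch <- defaultCohort()$cohort
  tb <- buildCohortTables(ch)
  need <- c("hr", "ef", "sv", "svi", "sw", "co", "ci",
            "edv", "esv", "edp", "esp", "prsw", "dpdt_max", "dpdt_min",
            "tau_half", "ees", "sci", "ea", "zva", "eed", "vac_ea_ees")
  expect_true(all(need %in% tb$summary$index))
  # marker appears iff the paired p is below 0.05
  expect_identical(tb$summary$sig,
                   is.finite(tb$summary$p) & tb$summary$p < 0.05)
})

test_that("a single-patient cohort reports NA spread and runs no tests", {
  ch <- defaultCohort()$cohort
  one <- new("CohortTable", patients = ch@patients[1, , drop = FALSE],
             pre = ch@pre[1, , drop = FALSE],
             post = ch@post[1, , drop = FALSE])
  tb <- buildCohortTables(one)
  expect_true(all(is.na(tb$summary$pre_sd)))
  expect_true(all(is.na(tb$summary$p)))
  expect_length(tb$deltas, 0)
})
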