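# Independent oracles: direct summation over the Poisson support for the
# one-sample test, full enumeration of the conditional binomial for the
# two-sample test.

brute_poisson_two_tailed <- function(x, lam, kmax = 1000) {
  dens <- dpois(0:kmax, lam)
  sum(dens[dens <= dpois(x, lam) * (1 + 1e-7)])
}

brute_binom_two_tailed <- function(x1, n, pr) {
  dens <- dbinom(0:n, n, pr)
  sum(dens[dens <= dbinom(x1, n, pr) * (1 + 1e-7)])
}

test_that("one-sample exact test reproduces the published primary-set result", {
  res <- poisson_exact_test(9, 1.20)
  expect_equal(signif(res$p, 1), 5e-6)
  expect_equal(res$rate_ratio, 7.5)
  # with the unrounded expectation the printed rate ratio and CI follow
  res2 <- poisson_exact_test(9, 1.203)
  expect_equal(signif(res2$p, 2), 5.0e-6)
  expect_equal(round(res2$rate_ratio, 2), 7.48)
  expect_equal(round(res2$ci_low, 2), 3.42)
  expect_equal(round(res2$ci_high, 1), 14.2)
})

test_that("one-sample exact test reproduces the comparator-set result", {
  res <- poisson_exact_test(8, 9.86)
  expect_equal(round(res$rate_ratio, 2), 0.81)
  expect_equal(round(res$p, 2), 0.75)
  expect_equal(round(res$ci_low, 2), 0.35)
  expect_equal(round(res$ci_high, 2), 1.60)
})

test_that("one-sample exact test matches brute-force enumeration", {
  for (lam in c(0.5, 1, 2, 5)) {
    for (x in 0:12) {
      expect_equal(poisson_exact_test(x, lam)$p,
                   brute_poisson_two_tailed(x, lam), tolerance = 1e-10,
                   info = sprintf("x=%d lam=%g", x, lam))
      expect_equal(poisson_exact_test(x, lam, alternative = "greater")$p,
                   sum(dpois(x:1000, lam)), tolerance = 1e-10)
    }
  }
  expect_equal(poisson_exact_test(0, 3, alternative = "greater")$p, 1)
})

test_that("one-sample exact test agrees with the stats reference", {
  for (lam in c(0.7, 1.2, 9.86)) {
    for (x in c(0, 1, 3, 9, 15)) {
      ref <- poisson.test(x, T = lam)
      got <- poisson_exact_test(x, lam)
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
      expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
                   tolerance = 1e-10)
    }
  }
})

test_that("doubled-tail rule is available as the configured alternative", {
  p_lower <- ppois(2, 6); p_upper <- ppois(1, 6, lower.tail = FALSE)
  expect_equal(poisson_exact_test(2, 6, two_sided_rule = "doubled")$p,
               min(1, 2 * min(p_lower, p_upper)))
})

test_that("exact test rejects invalid inputs", {
  expect_error(poisson_exact_test(2.5, 1), "integer")
  expect_error(poisson_exact_test(2, 0), "positive")
  expect_error(poisson_exact_test(-1, 1), "integer")
})

test_that("two-sample test matches enumeration on the small grid", {
  for (x1 in 0:6) for (x2 in 0:6) {
    if (x1 + x2 == 0) next
    lam1 <- 2.5; lam2 <- 7.5
    got <- two_sample_poisson_test(x1, lam1, x2, lam2)
    expect_equal(got$p,
                 brute_binom_two_tailed(x1, x1 + x2, lam1 / (lam1 + lam2)),
                 tolerance = 1e-10, info = sprintf("x1=%d x2=%d", x1, x2))
  }
})

test_that("two-sample test agrees with the stats reference", {
  cases <- list(c(20, 3.41, 166, 138.4), c(5, 2.5, 10, 5), c(0, 1, 4, 2),
                c(9, 1.2, 8, 9.86))
  for (cs in cases) {
    ref <- poisson.test(c(cs[1], cs[3]), T = c(cs[2], cs[4]))
    got <- two_sample_poisson_test(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$rate_ratio, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("two-sample rate ratio reconstructs the in-set vs background contrast", {
  # equal per-unit rates give rate ratio 1 by symmetry
  expect_equal(two_sample_poisson_test(5, 2.5, 10, 5)$rate_ratio, 1)
  # 20/3.41 in-set vs a background consistent with the published 4.89
  res <- two_sample_poisson_test(20, 3.41, 166, 138.4)
  expect_equal(round(res$rate_ratio, 2), 4.89)
})

test_that("two-sample test is invariant to common rescaling of expectations", {
  base <- two_sample_poisson_test(7, 1.3, 19, 22.8)
  for (c_scale in c(1e-3, 0.5, 17, 1e4)) {
    s <- two_sample_poisson_test(7, 1.3 * c_scale, 19, 22.8 * c_scale)
    expect_equal(s$p, base$p, tolerance = 1e-12)
    expect_equal(s$rate_ratio, base$rate_ratio)
    expect_equal(c(s$ci_low, s$ci_high), c(base$ci_low, base$ci_high))
  }
})

test_that("two-sample degenerate inputs are flagged, not fatal", {
  res <- two_sample_poisson_test(0, 1, 0, 1)
  expect_equal(res$p, 1)
  expect_true(is.na(res$rate_ratio))
  expect_match(res$flag, "zero")
  res2 <- two_sample_poisson_test(3, 1, 0, 1)
  expect_true(is.infinite(res2$rate_ratio))
})
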