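# Exact Poisson enrichment tests. The two-tailed P value uses the
# point-probability rule: sum of all outcome probabilities not exceeding
# that of the observed count, with a relative tie tolerance of 1 + 1e-7
# (the de facto behaviour of the standard exact Poisson test). The
# doubled-tail rule min(1, 2 * min(tails)) is available as an alternative.

enrichment_result <- function(observed, expected, rate_ratio, ci_low, ci_high,
                              p, sidedness, test_name, flag = NULL) {
  structure(list(observed = observed, expected = expected,
                 rate_ratio = rate_ratio, ci_low = ci_low, ci_high = ci_high,
                 p = p, sidedness = sidedness, test_name = test_name,
                 flag = flag),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$test_name, x$sidedness))
  cat(sprintf("  observed %s, expected %.4g\n",
              paste(x$observed, collapse = " vs "), x$expected))
  cat(sprintf("  rate ratio %.3g (95%% CI %.3g, %.3g), P = %.3g\n",
              x$rate_ratio, x$ci_low, x$ci_high, x$p))
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

# two-tailed point-probability sum for X ~ Poisson(lam); direct summation
# over a support window that carries all mass above double precision.
poisson_two_tailed_point <- function(x, lam, rel_tol = 1e-7) {
  kmax <- max(x, ceiling(lam + 20 * sqrt(lam) + 100))
  dens <- stats::dpois(0:kmax, lam)
  sum(dens[dens <= dens[x + 1L] * (1 + rel_tol)])
}

#' One-sample exact Poisson test
#'
#' Tests an observed de novo count against its null expectation
#' (`Poisson(lam)`). Reports the rate ratio `x / lam` with an exact 95%
#' confidence interval from the chi-square quantiles of the count
#' (`[qchisq(a/2, 2x)/2, qchisq(1-a/2, 2x+2)/2] / lam`, lower bound 0 when
#' x = 0).
#'
#' @param x observed count (non-negative integer).
#' @param lam expected count under the null (> 0).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param two_sided_rule "point_prob" (default) or "doubled".
#' @param conf_level confidence level for the rate-ratio interval.
#' @return an `enrichment_result`.
#' @export
poisson_exact_test <- function(x, lam,
                               alternative = c("two.sided", "greater", "less"),
                               two_sided_rule = c("point_prob", "doubled"),
                               conf_level = 0.95) {
  alternative <- match.arg(alternative)
  two_sided_rule <- match.arg(two_sided_rule)
  if (!is_whole(x) || x < 0) stop("x must be a non-negative integer")
  if (!is.finite(lam) || lam <= 0) stop("lam must be positive")
  p_lower <- stats::ppois(x, lam)
  p_upper <- stats::ppois(x - 1, lam, lower.tail = FALSE)
  p <- switch(alternative,
              greater = p_upper,
              less = p_lower,
              two.sided = switch(two_sided_rule,
                                 point_prob = poisson_two_tailed_point(x, lam),
                                 doubled = min(1, 2 * min(p_lower, p_upper))))
  p <- min(1, p)
  a <- 1 - conf_level
  ci_low <- if (x == 0) 0 else stats::qchisq(a / 2, 2 * x) / 2 / lam
  ci_high <- stats::qchisq(1 - a / 2, 2 * x + 2) / 2 / lam
  if (alternative == "greater") ci_high <- Inf
  if (alternative == "less") ci_low <- 0
  if (alternative != "two.sided") {
    # one-sided 95% bound on the open side
    if (alternative == "greater")
      ci_low <- if (x == 0) 0 else stats::qchisq(a, 2 * x) / 2 / lam
    else ci_high <- stats::qchisq(1 - a, 2 * x + 2) / 2 / lam
  }
  enrichment_result(x, lam, x / lam, ci_low, ci_high, p,
                    alternative, "poisson_exact")
}

# exact conditional binomial P value with the point-probability rule
binom_two_tailed_point <- function(x, n, pr, rel_tol = 1e-7) {
  dens <- stats::dbinom(0:n, n, pr)
  sum(dens[dens <= dens[x + 1L] * (1 + rel_tol)])
}

#' Two-sample exact Poisson rate-ratio test
#'
#' Compares the enrichment of one count over its expectation with that of
#' a second count over its own expectation (e.g. in-set vs out-of-set de
#' novo rates, controlling for a shifted cohort-wide background). Exact
#' inference conditions on the total: under the null of equal rate ratios,
#' `X1 | X1 + X2 ~ Binomial(x1 + x2, lam1 / (lam1 + lam2))`. The reported
#' rate ratio `(x1/lam1)/(x2/lam2)` and its Clopper-Pearson-derived CI are
#' invariant to rescaling both expectations by a common factor.
#'
#' @param x1,lam1 observed and expected count in the first (focal) set.
#' @param x2,lam2 observed and expected count in the second (reference) set.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param two_sided_rule "point_prob" (default) or "doubled".
#' @param conf_level confidence level.
#' @return an `enrichment_result`; `observed` holds `c(x1, x2)`.
#' @export
two_sample_poisson_test <- function(x1, lam1, x2, lam2,
                                    alternative = c("two.sided", "greater", "less"),
                                    two_sided_rule = c("point_prob", "doubled"),
                                    conf_level = 0.95) {
  alternative <- match.arg(alternative)
  two_sided_rule <- match.arg(two_sided_rule)
  if (!is_whole(x1) || !is_whole(x2) || x1 < 0 || x2 < 0)
    stop("counts must be non-negative integers")
  if (!is.finite(lam1) || lam1 <= 0 || !is.finite(lam2) || lam2 <= 0)
    stop("expectations must be positive")
  n <- x1 + x2
  if (n == 0)
    return(enrichment_result(c(x1 = 0, x2 = 0), lam1 / lam2, NA_real_,
                             NA_real_, NA_real_, 1, alternative,
                             "two_sample_poisson",
                             flag = "both counts zero; rate ratio undefined"))
  pr <- lam1 / (lam1 + lam2)
  p_lower <- stats::pbinom(x1, n, pr)
  p_upper <- stats::pbinom(x1 - 1, n, pr, lower.tail = FALSE)
  p <- switch(alternative,
              greater = p_upper,
              less = p_lower,
              two.sided = switch(two_sided_rule,
                                 point_prob = binom_two_tailed_point(x1, n, pr),
                                 doubled = min(1, 2 * min(p_lower, p_upper))))
  p <- min(1, p)
  a <- 1 - conf_level
  # Clopper-Pearson interval on the conditional proportion, mapped to the
  # rate-ratio scale via rr = p/(1-p) * lam2/lam1
  p_low <- if (x1 == 0) 0 else stats::qbeta(a / 2, x1, x2 + 1)
  p_high <- if (x1 == n) 1 else stats::qbeta(1 - a / 2, x1 + 1, x2)
  to_rr <- function(pp) if (pp >= 1) Inf else (pp / (1 - pp)) * (lam2 / lam1)
  rr <- if (x2 == 0) Inf else (x1 / lam1) / (x2 / lam2)
  flag <- if (x2 == 0) "reference count zero; rate ratio infinite" else NULL
  enrichment_result(c(x1 = x1, x2 = x2), lam1 / lam2, rr,
                    to_rr(p_low), to_rr(p_high), p, alternative,
                    "two_sample_poisson", flag = flag)
}
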