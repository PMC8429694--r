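# Genome-wide pleiotropy regression: per-gene de novo counts in one
# disorder regressed on gene-level association statistics from another,
# with the null expectation as a log offset:
#   N_variants_g ~ -log(P_ptv_g) + -log(P_mis_g) + offset(log(lambda_g)).
# A positive coefficient on a -log(P) term means genes more strongly
# associated in the second disorder accumulate proportionally more de
# novo variants in the first than their mutation rate predicts.

regression_fit <- function(terms, model, n_units, extra = list()) {
  structure(c(list(terms = terms, model = model, n_units = n_units), extra),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s regression on %d units\n", x$model, x$n_units))
  print(format(x$terms, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Genome-wide offset-Poisson pleiotropy regression
#'
#' @param gene_df per-gene data frame with columns `observed` (de novo
#'   count), `expected` (null expectation, > 0), `p_ndd_ptv`, `p_ndd_mis`
#'   and any covariate columns. Genes with a missing P value in either
#'   predictor are dropped (with a message), mirroring restriction to
#'   genes where both statistics were reported.
#' @param covariates character vector of extra covariate column names
#'   (e.g. `brain_expr`, `oe_ptv`, `oe_mis`), appended to the linear
#'   predictor; rows missing a covariate are dropped.
#' @param log_base base of the -log(P) transform (default natural log).
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return a `regression_fit` with one row per term (`name`, `beta`, `se`,
#'   `p`); the underlying `glm` object is attached as `$fit`.
#' @export
genomewide_pleiotropy_regression <- function(gene_df, covariates = character(),
                                             log_base = exp(1),
                                             epsilon = 1e-10, maxit = 100) {
  needed <- c("observed", "expected", "p_ndd_ptv", "p_ndd_mis", covariates)
  miss <- setdiff(needed, names(gene_df))
  if (length(miss)) stop("gene_df lacks column(s): ", paste(miss, collapse = ", "))
  keep <- !is.na(gene_df$p_ndd_ptv) & !is.na(gene_df$p_ndd_mis)
  for (cv in covariates) keep <- keep & !is.na(gene_df[[cv]])
  if (any(!keep))
    message("dropping ", sum(!keep), " gene(s) with missing predictor values")
  d <- gene_df[keep, , drop = FALSE]
  if (any(d$expected <= 0)) stop("expected counts must be positive for all fitted genes")
  d$nlp_ptv <- -log(d$p_ndd_ptv, base = log_base)
  d$nlp_mis <- -log(d$p_ndd_mis, base = log_base)
  rhs <- paste(c("nlp_ptv", "nlp_mis", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("observed ~", rhs, "+ offset(log(expected))"))
  fit <- stats::glm(fml, family = stats::poisson(), data = d,
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (!fit$converged)
    stop("offset-Poisson IRLS did not converge in ", maxit,
         " iterations (deviance ", format(fit$deviance), ")")
  sm <- summary(fit)$coefficients
  terms <- data.frame(name = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  regression_fit(terms, "poisson_offset", nrow(d), extra = list(fit = fit))
}
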