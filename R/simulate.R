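# Cohort simulators over a synthetic world. De novo events are generated
# site-allele by site-allele as Poisson counts with mean
#   opportunity(chrom) x mu x gamma,
# where gamma is the injected enrichment factor (1 everywhere under the
# null). Per-site rates are << 1, so the Poisson approximation to
# per-trio Bernoulli transmission is exact for practical purposes, and
# recurrence (the same allele arising in two probands) is allowed.

#' Specify injected enrichment factors
#'
#' @param gene_entries list of entries `list(genes =, class =, gamma =)`;
#'   `class` is one of "PTV", "missense", "synonymous" or "all"; `gamma`
#'   is a scalar or a vector named by gene (per-gene factors).
#' @param allele_entries list of entries `list(keys =, gamma =)` keyed by
#'   variant identity (see [variant_key()]).
#' @return object of class `enrichment_spec`; `gamma = 1` everywhere when
#'   both lists are empty (the null).
#' @export
enrichment_spec <- function(gene_entries = list(), allele_entries = list()) {
  for (e in gene_entries)
    stopifnot(!is.null(e$genes), !is.null(e$gamma),
              e$class %in% c("PTV", "missense", "synonymous", "all"),
              all(e$gamma >= 0))
  for (e in allele_entries)
    stopifnot(!is.null(e$keys), !is.null(e$gamma), all(e$gamma >= 0))
  structure(list(gene_entries = gene_entries, allele_entries = allele_entries),
            class = "enrichment_spec")
}

# per-site-allele gamma vector for a world
site_gamma <- function(world, spec) {
  gamma <- rep(1, nrow(world$sites))
  if (is.null(spec)) return(gamma)
  stopifnot(inherits(spec, "enrichment_spec"))
  for (e in spec$gene_entries) {
    hit <- world$sites$gene %in% e$genes
    if (e$class != "all") hit <- hit & world$sites$class == e$class
    g <- e$gamma
    if (!is.null(names(g))) {
      fac <- unname(g[world$sites$gene[hit]])
      fac[is.na(fac)] <- 1
      gamma[hit] <- gamma[hit] * fac
    } else gamma[hit] <- gamma[hit] * g
  }
  if (length(spec$allele_entries)) {
    keys <- variant_key(world$sites)
    for (e in spec$allele_entries) {
      hit <- keys %in% e$keys
      gamma[hit] <- gamma[hit] * e$gamma
    }
  }
  gamma
}

#' Simulate de novo variants for a trio cohort
#'
#' @param world a [make_world()] object.
#' @param cohort a [cohort_spec()].
#' @param spec optional [enrichment_spec()] (NULL = null model).
#' @param seed integer seed.
#' @param cohort_tag label written to the `cohort` column.
#' @return variant data frame (one row per de novo event; recurrent
#'   alleles appear once per event).
#' @export
simulate_trios <- function(world, cohort, spec = NULL, seed = 1,
                           cohort_tag = "sim") {
  stopifnot(inherits(world, "synthetic_world"))
  lam <- diploid_opportunity(world$sites$chrom, cohort) * world$sites$mu *
    site_gamma(world, spec)
  set.seed(seed)
  n <- stats::rpois(length(lam), lam)
  hit <- which(n > 0L)
  rows <- rep(hit, n[hit])
  out <- world$sites[rows, c("chrom", "pos", "ref", "alt", "gene",
                             "consequence", "mpc", "context"), drop = FALSE]
  rownames(out) <- NULL
  out$cohort <- rep(cohort_tag, nrow(out))
  out$is_snv <- rep(TRUE, nrow(out))
  out
}

#' Simulate the two NDD cohort variant lists and their unique union
#'
#' @param world a [make_world()] object.
#' @param n_dd_trios,n_asd_trios trio counts for the two cohorts.
#' @param spec optional [enrichment_spec()].
#' @param seed integer seed.
#' @param male_frac_dd,male_frac_asd proband male fractions.
#' @return list with `dd`, `asd` (event lists) and `unique_union`
#'   (deduplicated concatenation).
#' @export
make_ndd_variant_lists <- function(world, n_dd_trios = 31058,
                                   n_asd_trios = 6430, spec = NULL, seed = 1,
                                   male_frac_dd = 0.5, male_frac_asd = 0.8) {
  split_cohort <- function(n, male_frac) {
    m <- round(n * male_frac)
    cohort_spec(n, m, n - m)
  }
  dd <- simulate_trios(world, split_cohort(n_dd_trios, male_frac_dd),
                       spec, seed = seed, cohort_tag = "DD")
  asd <- simulate_trios(world, split_cohort(n_asd_trios, male_frac_asd),
                        spec, seed = seed + 1L, cohort_tag = "ASD")
  list(dd = dd, asd = asd,
       unique_union = deduplicate_variants(rbind(dd, asd)))
}

#' Simulate a case-control burden cohort with covariates
#'
#' Carrier status of primary-set variants is assigned from a logistic
#' model in which case status shifts the log-odds by `log(or_primary)` on
#' top of covariate effects, so the true covariate-adjusted burden odds
#' ratio equals `or_primary`. Covariates: 10 ancestry principal
#' components (standard normal), exome-wide synonymous burden (Poisson),
#' a two-level sequencing platform and sex.
#'
#' @param world a [make_world()] object (carried for provenance).
#' @param n_cases,n_controls arm sizes.
#' @param or_primary true burden odds ratio for the primary variant set.
#' @param seed integer seed.
#' @param base_rate control-arm carrier probability of a primary-set
#'   variant at covariate baseline.
#' @param comparator_rate mean per-subject comparator-set variant count.
#' @param or_comparator true odds/rate ratio for the comparator burden.
#' @return per-subject data frame: `phenotype` (1 = case),
#'   `primary_burden`, `comparator_burden`, `syn_burden`, `platform`,
#'   `sex`, `PC1`..`PC10`.
#' @export
simulate_case_control <- function(world, n_cases = 4070, n_controls = 5712,
                                  or_primary = 1.9, seed = 1,
                                  base_rate = 0.0023,
                                  comparator_rate = 0.095,
                                  or_comparator = 1) {
  stopifnot(or_primary > 0, or_comparator > 0)
  set.seed(seed)
  n <- n_cases + n_controls
  pheno <- c(rep(1L, n_cases), rep(0L, n_controls))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  platform <- sample(c("A", "B"), n, TRUE)
  sex <- sample(c("M", "F"), n, TRUE)
  syn <- stats::rpois(n, 7)
  eta_cov <- 0.05 * pcs[, 1] + 0.1 * (platform == "B") +
    0.05 * (sex == "M") + 0.02 * (syn - 7)
  eta <- stats::qlogis(base_rate) + log(or_primary) * pheno + eta_cov
  primary <- stats::rbinom(n, 1L, stats::plogis(eta))
  comparator <- stats::rpois(n, comparator_rate *
                               exp(log(or_comparator) * pheno + 0.1 * eta_cov))
  data.frame(phenotype = pheno, primary_burden = primary,
             comparator_burden = comparator, syn_burden = syn,
             platform = platform, sex = sex, pcs,
             stringsAsFactors = FALSE)
}

#' Expected constrained-background de novo count
#'
#' The cohort-wide null expectation of "constrained" de novo events: PTVs
#' in LoF-intolerant genes plus missense alleles with MPC at or above the
#' threshold, integrated exactly over the world's site inventory. Used as
#' the reference arm when asking whether enrichment of specific risk
#' alleles exceeds the cohort's general constrained de novo rate.
#'
#' @param world a [make_world()] object.
#' @param cohort a [cohort_spec()].
#' @param mpc_threshold,pli_threshold stratum thresholds.
#' @return an `expected_count` object.
#' @export
expected_constrained_background <- function(world, cohort,
                                            mpc_threshold = 2,
                                            pli_threshold = 0.9) {
  pli <- world$genes$pli[match(world$sites$gene, world$genes$gene)]
  keep <- (world$sites$class == "PTV" & pli >= pli_threshold) |
    (world$sites$class == "missense" & !is.na(world$sites$mpc) &
       world$sites$mpc >= mpc_threshold)
  s <- world$sites[keep, , drop = FALSE]
  opp <- diploid_opportunity(s$chrom, cohort)
  on_x <- s$chrom == "X"
  expected_count_obj(sum(s$mu[!on_x] * opp[!on_x]),
                     sum(s$mu[on_x] * opp[on_x]), nrow(s), "site-alleles")
}
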