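# The null model: expected de novo counts for allele sets and gene sets
# given a trio cohort's size and proband sex composition. Expected counts
# are Poisson means lambda = sum over units of (transmissible haplotypes x
# per-haploid rate), additive over disjoint unit sets.

#' Define a trio cohort
#'
#' @param n_trios number of proband-parent trios.
#' @param n_male,n_female proband sex split; must sum to `n_trios`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_trios, n_male, n_female) {
  stopifnot(is_whole(n_trios), n_trios > 0,
            is_whole(n_male), n_male >= 0,
            is_whole(n_female), n_female >= 0)
  if (n_male + n_female != n_trios)
    stop("n_male + n_female must equal n_trios")
  structure(list(n_trios = as.integer(n_trios), n_male = as.integer(n_male),
                 n_female = as.integer(n_female)), class = "cohort_spec")
}

#' Transmissible haplotype count per chromosome
#'
#' The number of parental haplotypes on which a de novo event could arise
#' and be transmitted to a proband: 2 per trio on autosomes; on X, one
#' transmissible meiosis for male probands (maternal X) and two for
#' females, i.e. `n_male + 2 * n_female`. Set `x_as_autosome = TRUE` to
#' treat X like an autosome (2 per trio).
#'
#' @param chrom character vector of chromosome labels ("1".."22", "X").
#' @param cohort a [cohort_spec()].
#' @param x_as_autosome ignore the proband sex split on X.
#' @return numeric vector of haplotype counts.
#' @export
diploid_opportunity <- function(chrom, cohort, x_as_autosome = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  bad <- !chrom %in% .CHROMS
  if (any(bad))
    stop("no de novo opportunity defined for chromosome(s): ",
         paste(unique(chrom[bad]), collapse = ", "))
  n_x <- if (x_as_autosome) 2 * cohort$n_trios else
    cohort$n_male + 2 * cohort$n_female
  ifelse(chrom == "X", n_x, 2 * cohort$n_trios)
}

expected_count_obj <- function(lam_auto, lam_x, n_items, unit = "alleles") {
  structure(list(lam = lam_auto + lam_x, lam_autosome = lam_auto,
                 lam_x = lam_x, n_items = n_items, unit = unit),
            class = "expected_count")
}

#' @export
print.expected_count <- function(x, ...) {
  cat(sprintf("Expected de novo count: lambda = %.6g over %d %s (autosome %.6g, X %.6g)\n",
              x$lam, x$n_items, x$unit, x$lam_autosome, x$lam_x))
  invisible(x)
}

#' Expected de novo count for a set of alleles
#'
#' Sums, over a deduplicated SNV allele set, the per-allele trinucleotide
#' mutation rate times the cohort's transmissible haplotype count for the
#' allele's chromosome. The result is the Poisson mean of the number of
#' de novo events at those alleles in the cohort under the null.
#'
#' @param variants deduplicated SNV data frame with contexts.
#' @param rates validated rate table.
#' @param cohort a [cohort_spec()].
#' @param x_as_autosome passed to [diploid_opportunity()].
#' @return an `expected_count` object.
#' @export
expected_allele_set_count <- function(variants, rates, cohort,
                                      x_as_autosome = FALSE) {
  if (nrow(variants) == 0) return(expected_count_obj(0, 0, 0L))
  if (anyDuplicated(variant_key(variants)))
    stop("allele set must be deduplicated before computing expectations")
  mu <- allele_rate(variants, rates)
  opp <- diploid_opportunity(variants$chrom, cohort, x_as_autosome)
  on_x <- variants$chrom == "X"
  expected_count_obj(sum(mu[!on_x] * opp[!on_x]), sum(mu[on_x] * opp[on_x]),
                     nrow(variants))
}

#' Expected de novo count for a gene set and mutation class
#'
#' Sums coverage-adjusted per-gene class mutation rates times the
#' transmissible haplotype count. Genes are treated as autosomal unless
#' the gene table carries a `chrom` column marking X-linked genes.
#'
#' @param genes character vector of gene ids (the set), or NULL with
#'   `complement = TRUE` semantics handled by the caller.
#' @param class one of "PTV", "missense", "synonymous".
#' @param gene_table validated gene table.
#' @param cohort a [cohort_spec()].
#' @param x_as_autosome passed to [diploid_opportunity()].
#' @return an `expected_count` object.
#' @export
expected_gene_set_count <- function(genes, class, gene_table, cohort,
                                    x_as_autosome = FALSE) {
  mu_col <- switch(class, PTV = "mu_ptv", missense = "mu_mis",
                   synonymous = "mu_syn",
                   stop("unknown mutation class: ", class))
  idx <- match(genes, gene_table$gene)
  if (anyNA(idx))
    stop("gene(s) absent from gene table: ",
         paste(genes[is.na(idx)], collapse = ", "))
  if (length(idx) == 0) return(expected_count_obj(0, 0, 0L, "genes"))
  g <- gene_table[idx, , drop = FALSE]
  chrom <- if ("chrom" %in% names(g)) g$chrom else rep("1", nrow(g))
  opp <- diploid_opportunity(chrom, cohort, x_as_autosome)
  contrib <- g[[mu_col]] * g$coverage_factor * opp
  on_x <- chrom == "X"
  expected_count_obj(sum(contrib[!on_x]), sum(contrib[on_x]),
                     length(idx), "genes")
}
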