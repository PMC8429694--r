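# Shared fixtures, all built in code.

# a minimal valid variant data frame
toy_variants <- function() {
  validate_variants(data.frame(
    chrom = c("1", "2", "X", "3", "3"),
    pos = c(100L, 200L, 300L, 400L, 400L),
    ref = c("G", "C", "T", "C", "C"),
    alt = c("A", "T", "C", "T", "T"),
    gene = c("KMT2D", "SCN2A", "GRIA3", "SLC6A1", "SLC6A1"),
    consequence = c("stop_gain", "missense", "missense", "missense",
                    "missense"),
    mpc = c(NA, 2.16, 3.54, 2.52, 2.52),
    context = c("AGT", "ACG", "TTA", "CCG", "CCG"),
    cohort = "toy", stringsAsFactors = FALSE))
}

toy_gene_table <- function() {
  validate_gene_table(data.frame(
    gene = c("KMT2D", "SCN2A", "GRIA3", "SLC6A1", "KLHL20", "RUNX3"),
    pli = c(1.00, 1.00, 1.00, 1.00, 0.0094, 0.84),
    mu_ptv = rep(2e-6, 6), mu_mis = rep(1e-5, 6), mu_syn = rep(5e-6, 6),
    stringsAsFactors = FALSE))
}

# a rate table where every canonical entry has a distinct, known rate
uniform_rate_table <- function(mu = 1e-8) {
  entries <- dnmpleio:::all_canonical_entries()
  entries$mu <- mu
  validate_rate_table(entries)
}

small_world <- function(seed = 42, n_genes = 300, sites_per_gene = 20) {
  make_world(n_genes = n_genes, sites_per_gene = sites_per_gene, seed = seed,
             n_risk = c(ptv_specific = 25, missense_specific = 20,
                        ptv_and_missense = 10))
}

sz_trio_cohort <- function() cohort_spec(3444, 2121, 1323)
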