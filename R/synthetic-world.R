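# Seeded synthetic-data generator. A "world" is the generative ground
# truth the pipeline is tested against: genes with context-resolved
# mutable sites and trinucleotide rates, a pLI/MPC landscape, gene-level
# NDD association P values with a spiked tail of risk genes, and named
# risk-gene sets mirroring the PTV-specific / missense-specific / both
# strata. Trio cohorts and case-control cohorts are simulated from the
# same rates the expectation engine integrates, so the simulator and the
# null model are inverse views of one model by construction.
#
# Sites are aggregated mutational-opportunity bins rather than single
# base pairs: a modest number of sites per gene combined with a
# `rate_scale` multiplier on the trinucleotide table reproduces realistic
# per-gene class rates (~1e-6 for PTVs) without a multi-million-row site
# inventory.

#' Generate a synthetic trinucleotide mutation-rate table
#'
#' Log-normal rates centred near 1.5e-8 per generation per haploid genome,
#' with a 10x boost for C>T transitions at CpG-like contexts, capped below
#' the 1e-4 sanity bound.
#'
#' @param seed integer seed.
#' @param rate_scale multiplier applied to every rate (aggregated-bin
#'   scaling; see package vignette).
#' @return validated canonical rate table (96 rows).
#' @export
make_rate_table <- function(seed = 1, rate_scale = 1) {
  entries <- all_canonical_entries()
  set.seed(seed)
  mu <- stats::rlnorm(nrow(entries), meanlog = log(1.5e-8), sdlog = 0.7)
  cpg <- substr(entries$context, 2, 2) == "C" &
    substr(entries$context, 3, 3) == "G" & entries$alt == "T"
  mu[cpg] <- mu[cpg] * 10
  entries$mu <- pmin(mu * rate_scale, 9.9e-5)
  validate_rate_table(entries)
}

#' Generate a synthetic gene/site world
#'
#' @param n_genes number of genes.
#' @param sites_per_gene mutable-site bins per gene; each bin carries 3
#'   alternate alleles with class annotations.
#' @param fraction_x_linked fraction of genes placed on X.
#' @param seed integer seed; identical seeds give identical worlds.
#' @param rates optional rate table (default [make_rate_table()] at
#'   `rate_scale`).
#' @param rate_scale passed to [make_rate_table()].
#' @param frac_lof_intolerant fraction of genes with pLI >= 0.9.
#' @param frac_mpc_high fraction of missense alleles with MPC >= 2.
#' @param n_risk named integer vector: sizes of the `ptv_specific`,
#'   `missense_specific` and `ptv_and_missense` risk-gene sets (the
#'   spiked NDD-significant tail).
#' @param frac_missing_pmis fraction of non-risk genes lacking a
#'   missense P value.
#' @param class_probs per-allele class probabilities (missense,
#'   synonymous, stop_gain, splice_donor, splice_acceptor).
#' @return object of class `synthetic_world` with elements `genes`
#'   (gene table), `sites` (one row per site-allele), `rates`,
#'   `risk_gene_sets`, `seed`.
#' @export
make_world <- function(n_genes = 2500, sites_per_gene = 40,
                       fraction_x_linked = 0.04, seed = 1,
                       rates = NULL, rate_scale = 25,
                       frac_lof_intolerant = 0.15, frac_mpc_high = 0.10,
                       n_risk = c(ptv_specific = 127, missense_specific = 103,
                                  ptv_and_missense = 53),
                       frac_missing_pmis = 0.33,
                       class_probs = c(missense = 0.68, synonymous = 0.25,
                                       stop_gain = 0.045, splice_donor = 0.0125,
                                       splice_acceptor = 0.0125)) {
  stopifnot(n_genes >= 1, sites_per_gene >= 1)
  if (sum(n_risk) > n_genes / 2)
    stop("risk-set sizes exceed half the gene count; enlarge n_genes")
  rates <- rates %||% make_rate_table(seed, rate_scale)
  set.seed(seed)
  gene <- sprintf("G%05d", seq_len(n_genes))
  on_x <- stats::runif(n_genes) < fraction_x_linked
  chrom <- ifelse(on_x, "X", sample(.AUTOSOMES, n_genes, replace = TRUE))
  pli <- ifelse(stats::runif(n_genes) < frac_lof_intolerant,
                stats::runif(n_genes, 0.9, 1), stats::runif(n_genes, 0, 0.9))

  n_sites <- n_genes * sites_per_gene
  ctx <- paste0(sample(.BASES, n_sites, TRUE), sample(.BASES, n_sites, TRUE),
                sample(.BASES, n_sites, TRUE))
  ref <- substr(ctx, 2, 2)
  site_gene_idx <- rep(seq_len(n_genes), each = sites_per_gene)
  pos <- site_gene_idx * 100000L + rep(seq_len(sites_per_gene), n_genes) * 5L
  # expand to one row per alternate allele
  idx3 <- rep(seq_len(n_sites), each = 3L)
  alt_offset <- rep(1:3, n_sites)
  alts_by_ref <- t(vapply(.BASES, function(b) setdiff(.BASES, b), character(3)))
  alt <- alts_by_ref[cbind(match(ref[idx3], .BASES), alt_offset)]
  n_rows <- length(idx3)
  consequence <- sample(names(class_probs), n_rows, TRUE, prob = class_probs)
  mpc <- rep(NA_real_, n_rows)
  is_mis <- consequence == "missense"
  hi <- is_mis & stats::runif(n_rows) < frac_mpc_high
  mpc[hi] <- stats::runif(sum(hi), 2, 4)
  mpc[is_mis & !hi] <- stats::runif(sum(is_mis & !hi), 0, 2)
  sites <- data.frame(
    gene = gene[site_gene_idx[idx3]], chrom = chrom[site_gene_idx[idx3]],
    pos = pos[idx3], ref = ref[idx3], alt = alt, context = ctx[idx3],
    consequence = consequence, mpc = mpc, stringsAsFactors = FALSE)
  sites$is_snv <- TRUE
  sites$mu <- allele_rate(sites, rates)
  sites$class <- classify_variant(sites$consequence)

  mu_by <- function(cls) {
    v <- rowsum(ifelse(sites$class == cls, sites$mu, 0), sites$gene)
    v[match(gene, rownames(v)), 1]
  }
  # disjoint spiked risk-gene sets
  pool <- sample(gene)
  sizes <- n_risk[c("ptv_specific", "missense_specific", "ptv_and_missense")]
  ends <- cumsum(sizes)
  risk <- list(ptv_specific = pool[seq_len(sizes[1])],
               missense_specific = pool[(ends[1] + 1):ends[2]],
               ptv_and_missense = pool[(ends[2] + 1):ends[3]])
  spike_p <- function(n) 10^-stats::runif(n, 5.7, 12)
  p_ptv <- stats::runif(n_genes)
  p_mis <- stats::runif(n_genes)
  ptv_sig <- gene %in% c(risk$ptv_specific, risk$ptv_and_missense)
  mis_sig <- gene %in% c(risk$missense_specific, risk$ptv_and_missense)
  p_ptv[ptv_sig] <- spike_p(sum(ptv_sig))
  p_mis[mis_sig] <- spike_p(sum(mis_sig))
  p_mis[!mis_sig & stats::runif(n_genes) < frac_missing_pmis] <- NA

  genes <- data.frame(
    gene = gene, chrom = chrom, pli = round(pli, 4),
    oe_ptv = round(pmax(0.02, (1 - 0.9 * pli) * stats::runif(n_genes, 0.5, 1.5)), 4),
    oe_mis = round(stats::runif(n_genes, 0.3, 1.3), 4),
    mu_ptv = mu_by("PTV"), mu_mis = mu_by("missense"), mu_syn = mu_by("synonymous"),
    coverage_factor = 1, p_ndd_ptv = p_ptv, p_ndd_mis = p_mis,
    brain_expr = round(stats::rlnorm(n_genes, 2, 1), 3),
    stringsAsFactors = FALSE)

  structure(list(genes = validate_gene_table(genes), sites = sites,
                 rates = rates, risk_gene_sets = risk, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d genes, %d site-alleles (%.1f%% X-linked genes), seed %d\n",
              nrow(x$genes), nrow(x$sites),
              100 * mean(x$genes$chrom == "X"), x$seed))
  cat("risk-gene sets:",
      paste(sprintf("%s (%d)", names(x$risk_gene_sets),
                    lengths(x$risk_gene_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Check world self-consistency
#'
#' Verifies that every per-gene class mutation rate equals the sum of its
#' site-allele rates — the invariant that makes the simulator and the
#' expectation engine two views of the same model.
#'
#' @param world a `synthetic_world`.
#' @param tol relative tolerance.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_world <- function(world, tol = 1e-12) {
  for (cls in c("PTV", "missense", "synonymous")) {
    col <- switch(cls, PTV = "mu_ptv", missense = "mu_mis",
                  synonymous = "mu_syn")
    v <- rowsum(ifelse(world$sites$class == cls, world$sites$mu, 0),
                world$sites$gene)
    got <- v[match(world$genes$gene, rownames(v)), 1]
    want <- world$genes[[col]]
    if (any(abs(got - want) > tol * pmax(1e-300, abs(want))))
      stop("per-gene ", col, " does not equal its site-level sum")
  }
  invisible(TRUE)
}
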