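# Variant and gene data model: class annotation, pathogenicity strata,
# deduplication and cross-cohort allele matching.

#' Build variant identity keys
#'
#' The matching identity of a variant is the tuple (chrom, pos, ref, alt);
#' two records from different cohorts denote the same allele iff their keys
#' are equal (all positions on one declared genome build per run).
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Collapse consequence annotations to mutation classes
#'
#' Protein-truncating variants (PTVs) are stop-gain, frameshift and
#' canonical splice donor/acceptor variants; missense and synonymous map to
#' themselves. Splice-region (non-canonical) consequences are not accepted.
#'
#' @param consequence character vector of consequence terms.
#' @return character vector over `c("PTV", "missense", "synonymous")`.
#' @export
classify_variant <- function(consequence) {
  bad <- setdiff(unique(consequence), .CONSEQUENCES)
  if (length(bad))
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "))
  out <- rep("PTV", length(consequence))
  out[consequence == "missense"] <- "missense"
  out[consequence == "synonymous"] <- "synonymous"
  out
}

#' Assign variants to the primary or comparator pathogenicity stratum
#'
#' The primary stratum holds alleles with properties predictive of
#' neurodevelopmental-disorder pathogenicity: PTVs in loss-of-function
#' intolerant genes (pLI >= `pli_threshold`) and missense variants with
#' MPC >= `mpc_threshold`. Everything else (PTVs in tolerant genes,
#' low-MPC missense, all synonymous) is the comparator stratum. Missing
#' MPC is treated as below threshold and missing pLI as 0, so incomplete
#' annotation can only demote a record to the comparator set.
#'
#' @param variants variant data frame (columns `gene`, `consequence`,
#'   `mpc`).
#' @param gene_table gene data frame with columns `gene` and `pli`.
#' @param mpc_threshold MPC cut-off for damaging missense (default 2).
#' @param pli_threshold pLI cut-off for LoF-intolerant genes (default 0.9).
#' @return character vector over `c("primary", "comparator")`.
#' @export
assign_ndd_stratum <- function(variants, gene_table,
                               mpc_threshold = 2, pli_threshold = 0.9) {
  cls <- classify_variant(variants$consequence)
  pli <- gene_table$pli[match(variants$gene, gene_table$gene)]
  n_missing_pli <- sum(is.na(pli))
  if (n_missing_pli > 0)
    message(n_missing_pli, " record(s) in genes without a pLI value; treated as pLI = 0")
  pli[is.na(pli)] <- 0
  mpc <- variants$mpc %||% rep(NA_real_, nrow(variants))
  mpc[is.na(mpc)] <- -Inf
  primary <- (cls == "PTV" & pli >= pli_threshold) |
    (cls == "missense" & mpc >= mpc_threshold)
  ifelse(primary, "primary", "comparator")
}

#' Deduplicate variant records by allele identity
#'
#' Collapses records sharing a (chrom, pos, ref, alt) key to one
#' representative (recurrent de novo events across probands are real and
#' expected). Annotation conflicts between duplicates are resolved
#' first-seen-wins with a warning naming the keys.
#'
#' @param variants variant data frame.
#' @return data frame with one row per unique key, first-seen order.
#' @export
deduplicate_variants <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  key <- variant_key(variants)
  dup <- duplicated(key)
  if (any(dup)) {
    ann_cols <- intersect(c("gene", "consequence", "mpc", "context"),
                          names(variants))
    ann <- do.call(paste, c(variants[ann_cols], sep = "\r"))
    first_ann <- ann[match(key, key)]
    conflict <- unique(key[ann != first_ann & !is.na(ann) & !is.na(first_ann)])
    if (length(conflict))
      warning("conflicting annotations among duplicates of: ",
              paste(conflict, collapse = ", "), "; first-seen kept")
  }
  variants[!dup, , drop = FALSE]
}

#' Count query variants whose allele appears in a target key set
#'
#' @param query deduplicated variant data frame.
#' @param target_keys character vector of variant keys (deduplicated).
#' @return list with `count` and the matched rows of `query` (`matched`).
#' @export
overlap_variants <- function(query, target_keys) {
  hit <- variant_key(query) %in% target_keys
  list(count = sum(hit), matched = query[hit, , drop = FALSE])
}

#' Partition significant genes into class-specific strata
#'
#' Genes exome-wide significant (P < `p_threshold`) for PTV enrichment
#' only, missense enrichment only, or independently for both. The three
#' strata are pairwise disjoint by construction.
#'
#' @param gene_table gene data frame with `p_ndd_ptv`, `p_ndd_mis`
#'   (NA allowed).
#' @param p_threshold exome-wide significance level (default 2.5e-6,
#'   0.05 over ~20,000 genes).
#' @return named list of gene-id character vectors: `ptv_specific`,
#'   `missense_specific`, `ptv_and_missense`.
#' @export
build_gene_strata <- function(gene_table, p_threshold = 2.5e-6) {
  sig_ptv <- !is.na(gene_table$p_ndd_ptv) & gene_table$p_ndd_ptv < p_threshold
  sig_mis <- !is.na(gene_table$p_ndd_mis) & gene_table$p_ndd_mis < p_threshold
  list(
    ptv_specific = gene_table$gene[sig_ptv & !sig_mis],
    missense_specific = gene_table$gene[sig_mis & !sig_ptv],
    ptv_and_missense = gene_table$gene[sig_ptv & sig_mis]
  )
}

#' Remove alleles common in a population reference database
#'
#' Restricts a case-control variant list to ultra-rare alleles by dropping
#' records whose reference-database allele count exceeds `threshold`.
#' Missing counts mean the allele is absent from the database and are kept.
#'
#' @param variants data frame with an `ac_gnomad` column.
#' @param threshold maximum allele count retained (default 5).
#' @return the filtered data frame.
#' @export
gnomad_ac_filter <- function(variants, threshold = 5) {
  ac <- variants$ac_gnomad
  ac[is.na(ac)] <- 0L
  if (any(ac < 0 | !is_whole(ac)))
    stop("ac_gnomad must be non-negative integers or missing")
  variants[ac <= threshold, , drop = FALSE]
}
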