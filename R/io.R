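# Readers and writers for the package's TSV dialects. Missing values are
# written as "." throughout.

read_tsv_dot <- function(path, col_classes) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    na.strings = c(".", "NA", ""),
                    colClasses = col_classes,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

write_tsv_dot <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a de novo variant table
#'
#' Expects a TSV with header `chrom pos ref alt gene consequence mpc
#' context cohort` and `.` for missing fields. Records on Y or MT are
#' dropped with a message (mutation-rate and opportunity models cover
#' autosomes and X only); invariants (ref != alt, MPC only on missense,
#' context only on SNVs, context centred on ref) are enforced.
#'
#' @param path file path.
#' @param drop_y_mt drop Y/MT records (default) instead of erroring.
#' @return validated variant data frame with an `is_snv` column added.
#' @export
read_variant_table <- function(path, drop_y_mt = TRUE) {
  v <- read_tsv_dot(path, col_classes = c(
    chrom = "character", pos = "integer", ref = "character",
    alt = "character", gene = "character", consequence = "character",
    mpc = "numeric", context = "character", cohort = "character"))
  validate_variants(v, drop_y_mt = drop_y_mt)
}

#' Validate an in-memory variant table
#'
#' @param v variant data frame (see [read_variant_table()] for columns).
#' @param drop_y_mt drop Y/MT records with a message instead of erroring.
#' @return the validated data frame with `is_snv` populated.
#' @export
validate_variants <- function(v, drop_y_mt = TRUE) {
  needed <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(needed, names(v))
  if (length(miss)) stop("variant table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"mpc" %in% names(v)) v$mpc <- NA_real_
  if (!"context" %in% names(v)) v$context <- NA_character_
  if (!"cohort" %in% names(v)) v$cohort <- NA_character_
  on_y_mt <- v$chrom %in% c("Y", "MT", "M", "chrY", "chrM")
  if (any(on_y_mt)) {
    if (!drop_y_mt) stop(sum(on_y_mt), " record(s) on Y/MT")
    message("dropping ", sum(on_y_mt), " record(s) on Y/MT")
    v <- v[!on_y_mt, , drop = FALSE]
  }
  bad_chrom <- !v$chrom %in% .CHROMS
  if (any(bad_chrom))
    stop("unrecognised chromosome label(s): ",
         paste(unique(v$chrom[bad_chrom]), collapse = ", "))
  if (any(v$ref == v$alt)) stop("ref == alt in ", sum(v$ref == v$alt), " record(s)")
  classify_variant(v$consequence)  # validates the vocabulary
  v$is_snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  stray_mpc <- !is.na(v$mpc) & v$consequence != "missense"
  if (any(stray_mpc)) {
    message("dropping MPC on ", sum(stray_mpc), " non-missense record(s)")
    v$mpc[stray_mpc] <- NA_real_
  }
  if (any(!is.na(v$mpc) & v$mpc < 0)) stop("negative MPC score(s)")
  has_ctx <- !is.na(v$context)
  if (any(has_ctx & !v$is_snv))
    stop("trinucleotide context present on non-SNV record(s)")
  bad_ctx <- has_ctx & (nchar(v$context) != 3L |
                          substr(v$context, 2L, 2L) != v$ref)
  if (any(bad_ctx))
    stop("context not centred on ref for: ",
         paste(utils::head(variant_key(v[bad_ctx, ]), 5), collapse = ", "))
  v
}

#' Read a per-gene annotation table
#'
#' TSV with header `gene pli oe_ptv oe_mis mu_ptv mu_mis mu_syn
#' coverage_factor p_ndd_ptv p_ndd_mis brain_expr` (an optional `chrom`
#' column marks X-linked genes for sex-aware opportunity). Mutation rates
#' are per-gene per-generation haploid probabilities; missing
#' coverage_factor defaults to 1.
#'
#' @param path file path.
#' @return validated gene data frame.
#' @export
read_gene_table <- function(path) {
  g <- read_tsv_dot(path, col_classes = NA)
  validate_gene_table(g)
}

#' Validate an in-memory gene table
#' @param g gene data frame.
#' @return the validated data frame.
#' @export
validate_gene_table <- function(g) {
  needed <- c("gene", "pli", "mu_ptv", "mu_mis", "mu_syn")
  miss <- setdiff(needed, names(g))
  if (length(miss)) stop("gene table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(g$gene)) stop("duplicate gene ids in gene table")
  for (col in c("mu_ptv", "mu_mis", "mu_syn")) {
    x <- g[[col]]
    if (any(!is.finite(x) | x < 0)) stop(col, " must be finite and >= 0")
  }
  if (any(!is.na(g$pli) & (g$pli < 0 | g$pli > 1)))
    stop("pli outside [0, 1]")
  if (!"coverage_factor" %in% names(g)) g$coverage_factor <- 1
  g$coverage_factor[is.na(g$coverage_factor)] <- 1
  if (any(g$coverage_factor <= 0 | g$coverage_factor > 1))
    stop("coverage_factor outside (0, 1]")
  for (col in c("p_ndd_ptv", "p_ndd_mis")) {
    if (!col %in% names(g)) g[[col]] <- NA_real_
    x <- g[[col]]
    if (any(!is.na(x) & (x <= 0 | x > 1))) stop(col, " outside (0, 1]")
  }
  if (!"brain_expr" %in% names(g)) g$brain_expr <- NA_real_
  g
}

#' Read a gene-set file (one gene symbol per line)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Write a variant table in the package TSV dialect
#' @param variants variant data frame.
#' @param path destination.
#' @return the path, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "mpc", "context", "cohort")
  for (col in setdiff(cols, names(variants))) variants[[col]] <- NA
  write_tsv_dot(variants[cols], path)
}

#' Write a gene table in the package TSV dialect
#' @param gene_table gene data frame.
#' @param path destination.
#' @return the path, invisibly.
#' @export
write_gene_table <- function(gene_table, path) {
  cols <- c("gene", "pli", "oe_ptv", "oe_mis", "mu_ptv", "mu_mis", "mu_syn",
            "coverage_factor", "p_ndd_ptv", "p_ndd_mis", "brain_expr")
  if ("chrom" %in% names(gene_table)) cols <- c(cols, "chrom")
  for (col in setdiff(cols, names(gene_table))) gene_table[[col]] <- NA
  write_tsv_dot(gene_table[cols], path)
}
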