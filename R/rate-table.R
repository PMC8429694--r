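# Trinucleotide mutation-rate table: 64 reference contexts x 3 alternate
# bases, strand-collapsed to 96 canonical (context, alt) entries. The
# canonical representative of a pair is the lexicographically smaller of
# the context and its reverse complement (no 3-mer is its own reverse
# complement, so the choice is unambiguous); the alt base is complemented
# whenever the context is flipped.

#' Canonicalise trinucleotide context/alt pairs
#'
#' @param context character vector of 3-mers over ACGT.
#' @param alt character vector of single alternate bases.
#' @return data frame with canonical `context` and `alt` columns.
#' @export
canonical_context <- function(context, alt) {
  if (any(nchar(context) != 3L)) stop("contexts must be 3-mers")
  rc <- revcomp3(context)
  flip <- rc < context
  data.frame(context = ifelse(flip, rc, context),
             alt = ifelse(flip, revcomp1(alt), alt),
             stringsAsFactors = FALSE)
}

all_canonical_entries <- function() {
  grid <- expand.grid(five = .BASES, mid = .BASES, three = .BASES,
                      alt = .BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$alt != grid$mid, ]
  ctx <- paste0(grid$five, grid$mid, grid$three)
  can <- canonical_context(ctx, grid$alt)
  unique(can[order(can$context, can$alt), ])
}

#' Validate a rate table
#'
#' Checks the strand-collapsed table is complete (all 96 canonical
#' context/alt entries) and that every rate is a sane per-generation
#' per-haploid-genome probability (0 <= mu < 1e-4).
#'
#' @param rates data frame with columns `context`, `alt`, `mu`.
#' @return the table, canonicalised and ordered.
#' @export
validate_rate_table <- function(rates) {
  stopifnot(all(c("context", "alt", "mu") %in% names(rates)))
  can <- canonical_context(rates$context, rates$alt)
  rates$context <- can$context
  rates$alt <- can$alt
  key <- paste(rates$context, rates$alt)
  if (anyDuplicated(key)) {
    # strand-duplicated input rows must agree
    mu_first <- rates$mu[match(key, key)]
    if (any(abs(rates$mu - mu_first) > 1e-15 * pmax(1, abs(mu_first))))
      stop("conflicting rates for strand-equivalent entries")
    rates <- rates[!duplicated(key), ]
    key <- key[!duplicated(key)]
  }
  want <- all_canonical_entries()
  missing <- setdiff(paste(want$context, want$alt), key)
  if (length(missing))
    stop("rate table incomplete; missing ", length(missing),
         " canonical entries, e.g. ", missing[1])
  if (any(!is.finite(rates$mu) | rates$mu < 0 | rates$mu >= 1e-4))
    stop("rates must satisfy 0 <= mu < 1e-4")
  rates[order(rates$context, rates$alt), c("context", "alt", "mu")]
}

#' Read a trinucleotide rate table (TSV `context alt mu`)
#' @param path file path.
#' @return validated canonical rate table (96 rows).
#' @export
read_rate_table <- function(path) {
  r <- read_tsv_dot(path, col_classes = c(context = "character",
                                          alt = "character", mu = "numeric"))
  validate_rate_table(r)
}

#' Write a rate table
#' @param rates validated rate table.
#' @param path destination.
#' @return the path, invisibly.
#' @export
write_rate_table <- function(rates, path) write_tsv_dot(rates, path)

# fast lookup environment: key "context alt" -> mu
rate_lookup <- function(rates) {
  stats::setNames(rates$mu, paste(rates$context, rates$alt))
}

#' Per-allele mutation rate from trinucleotide context
#'
#' Looks up each SNV's per-generation per-haploid-genome mutation rate by
#' its (strand-canonicalised) reference trinucleotide context and
#' alternate base.
#'
#' @param variants SNV data frame with `ref`, `alt`, `context` populated.
#' @param rates validated rate table.
#' @return numeric vector of rates, one per variant.
#' @export
allele_rate <- function(variants, rates) {
  if (nrow(variants) == 0) return(numeric(0))
  if (any(!variants$is_snv %||% (nchar(variants$ref) == 1 & nchar(variants$alt) == 1)))
    stop("allele_rate is defined for SNVs only (indel rates are not modelled)")
  if (any(is.na(variants$context)))
    stop("missing trinucleotide context for: ",
         paste(utils::head(variant_key(variants[is.na(variants$context), ]), 5),
               collapse = ", "))
  bad <- substr(variants$context, 2L, 2L) != variants$ref
  if (any(bad))
    stop("context not centred on ref for: ",
         paste(utils::head(variant_key(variants[bad, ]), 5), collapse = ", "))
  can <- canonical_context(variants$context, variants$alt)
  mu <- rate_lookup(rates)[paste(can$context, can$alt)]
  if (any(is.na(mu)))
    stop("no rate-table entry for: ",
         paste(utils::head(paste(can$context, can$alt)[is.na(mu)], 5),
               collapse = ", "))
  unname(mu)
}
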