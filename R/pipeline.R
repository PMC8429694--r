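# End-to-end orchestration of the three analyses: genic pleiotropy
# (gene-set and genome-wide), allelic pleiotropy, and case-control burden
# replication. A config is a plain list (or YAML file) naming inputs
# either as in-memory objects (`variants`, `gene_table`, `rates`,
# `ndd_variants`, `case_control`) or as file paths (`variants_file`,
# `gene_table_file`, `rate_table_file`, `ndd_variants_file`,
# `case_control_file`), plus the trio cohort and thresholds. All inputs
# are resolved and validated before any computation starts.

default_config <- function() {
  list(mpc_threshold = 2, pli_threshold = 0.9, p_threshold = 2.5e-6,
       gnomad_ac = 5, two_sided_rule = "point_prob", log_base = exp(1),
       x_as_autosome = FALSE, mpc_rate_fraction = 0.07, seed = 1)
}

#' Read and validate an analysis config
#'
#' @param path YAML file; file-path entries are checked for existence
#'   relative to the YAML's directory (fail-fast, before any computation).
#' @return config list with defaults filled in.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), cfg)
  file_keys <- grep("_file$", names(cfg), value = TRUE)
  for (k in file_keys) {
    cfg[[k]] <- file.path(dirname(path), cfg[[k]])
    if (!file.exists(cfg[[k]]))
      stop("config references missing file for ", k, ": ", cfg[[k]])
  }
  cfg
}

resolve_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  # pre-flight: every referenced file must exist before anything is parsed
  for (k in grep("_file$", names(cfg), value = TRUE))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("missing input file for ", k, ": ", cfg[[k]])
  get_tbl <- function(obj, file, reader) {
    if (!is.null(cfg[[obj]])) return(cfg[[obj]])
    if (!is.null(cfg[[file]])) return(reader(cfg[[file]]))
    NULL
  }
  cfg$variants <- get_tbl("variants", "variants_file", read_variant_table)
  if (!is.null(cfg$variants)) cfg$variants <- validate_variants(cfg$variants)
  cfg$gene_table <- get_tbl("gene_table", "gene_table_file", read_gene_table)
  if (!is.null(cfg$gene_table)) cfg$gene_table <- validate_gene_table(cfg$gene_table)
  cfg$rates <- get_tbl("rates", "rate_table_file", read_rate_table)
  if (!is.null(cfg$rates)) cfg$rates <- validate_rate_table(cfg$rates)
  cfg$ndd_variants <- get_tbl("ndd_variants", "ndd_variants_file",
                              read_variant_table)
  if (!is.null(cfg$ndd_variants))
    cfg$ndd_variants <- validate_variants(cfg$ndd_variants)
  cfg$case_control <- get_tbl("case_control", "case_control_file",
                              function(p) read_tsv_dot(p, NA))
  if (!is.null(cfg$cohort) && !inherits(cfg$cohort, "cohort_spec"))
    cfg$cohort <- cohort_spec(cfg$cohort$n_trios, cfg$cohort$n_male,
                              cfg$cohort$n_female)
  cfg
}

res_row <- function(set, n_items, class, res) {
  data.frame(set = set, n_items = n_items, class = class,
             observed = sum(res$observed), expected = res$expected,
             p = res$p, rate_ratio = res$rate_ratio,
             ci_low = res$ci_low, ci_high = res$ci_high,
             flag = res$flag %||% NA_character_,
             stringsAsFactors = FALSE)
}

empty_row <- function(set, n_items, class, flag) {
  data.frame(set = set, n_items = n_items, class = class, observed = 0L,
             expected = NA_real_, p = NA_real_, rate_ratio = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, flag = flag,
             stringsAsFactors = FALSE)
}

count_events <- function(variants, genes, class, mpc_threshold = NULL) {
  cls <- classify_variant(variants$consequence)
  hit <- cls == class & variants$gene %in% genes
  if (!is.null(mpc_threshold) && class == "missense")
    hit <- hit & !is.na(variants$mpc) & variants$mpc >= mpc_threshold
  sum(hit)
}

#' Run the genic pleiotropy analysis
#'
#' For each NDD gene-set stratum and each mutation class (PTV; missense at
#' or above the MPC threshold), compares in-set vs out-of-set de novo
#' enrichment with the two-sample exact Poisson rate-ratio test, adds the
#' between-class congruence test per stratum, and fits the genome-wide
#' offset-Poisson regression of per-gene counts on the -log gene-level NDD
#' P values, with and without brain-expression/constraint covariates.
#'
#' @param config config list (see package vignette) supplying `variants`
#'   (the trio de novo events), `gene_table`, `cohort` and thresholds.
#' @return object of class `genic_report`: `$table`, `$congruence`,
#'   `$regressions`.
#' @export
run_genic <- function(config) {
  cfg <- resolve_config(config)
  if (is.null(cfg$variants) || is.null(cfg$gene_table) || is.null(cfg$cohort))
    stop("run_genic needs variants, gene_table and cohort")
  v <- cfg$variants
  g <- cfg$gene_table
  strata <- build_gene_strata(g, cfg$p_threshold)
  all_genes <- g$gene
  rows <- list(); congr <- list()
  for (sname in names(strata)) {
    gs <- strata[[sname]]
    out_genes <- setdiff(all_genes, gs)
    if (length(gs) == 0) {
      rows[[length(rows) + 1L]] <- empty_row(sname, 0L, "PTV", "empty stratum")
      rows[[length(rows) + 1L]] <- empty_row(sname, 0L, "missense", "empty stratum")
      next
    }
    cells <- list()
    for (cls in c("PTV", "missense")) {
      x_in <- count_events(v, gs, cls, cfg$mpc_threshold)
      x_out <- count_events(v, out_genes, cls, cfg$mpc_threshold)
      lam_in <- expected_gene_set_count(gs, cls, g, cfg$cohort,
                                        cfg$x_as_autosome)$lam
      lam_out <- expected_gene_set_count(out_genes, cls, g, cfg$cohort,
                                         cfg$x_as_autosome)$lam
      res <- two_sample_poisson_test(x_in, lam_in, x_out, lam_out,
                                     two_sided_rule = cfg$two_sided_rule)
      row <- res_row(sname, length(gs), cls, res)
      row$observed <- x_in
      row$expected <- lam_in
      rows[[length(rows) + 1L]] <- row
      cells[[cls]] <- c(x_in = x_in, lam_in = lam_in,
                        x_out = x_out, lam_out = lam_out)
    }
    congr[[sname]] <- class_congruence_test(
      cells$PTV["x_in"], cells$PTV["lam_in"],
      cells$PTV["x_out"], cells$PTV["lam_out"],
      cells$missense["x_in"], cells$missense["lam_in"],
      cells$missense["x_out"], cells$missense["lam_out"])
  }
  # genome-wide regressions: per-gene observed counts by class
  per_gene <- function(cls) {
    cv <- classify_variant(v$consequence)
    tab <- table(factor(v$gene[cv == cls], levels = all_genes))
    exp_g <- g[[switch(cls, PTV = "mu_ptv", missense = "mu_mis")]] *
      g$coverage_factor *
      diploid_opportunity(if ("chrom" %in% names(g)) g$chrom else
        rep("1", nrow(g)), cfg$cohort, cfg$x_as_autosome)
    data.frame(gene = all_genes, observed = as.integer(tab),
               expected = exp_g, p_ndd_ptv = g$p_ndd_ptv,
               p_ndd_mis = g$p_ndd_mis, brain_expr = g$brain_expr,
               oe_ptv = g$oe_ptv, oe_mis = g$oe_mis,
               stringsAsFactors = FALSE)
  }
  regs <- list()
  for (cls in c("PTV", "missense")) {
    d <- per_gene(cls)
    d <- d[d$expected > 0, , drop = FALSE]
    key <- tolower(substr(cls, 1, 3))
    regs[[key]] <- genomewide_pleiotropy_regression(d, log_base = cfg$log_base)
    covs <- c("brain_expr", "oe_ptv", "oe_mis")
    covs <- covs[vapply(covs, function(cc) any(!is.na(d[[cc]])), logical(1))]
    if (length(covs))
      regs[[paste0(key, "_covariates")]] <-
        genomewide_pleiotropy_regression(d, covariates = covs,
                                         log_base = cfg$log_base)
  }
  structure(list(table = do.call(rbind, rows), congruence = congr,
                 regressions = regs, config_seed = cfg$seed),
            class = "genic_report")
}

#' Run the allelic pleiotropy analysis
#'
#' Deduplicates the NDD variant union (SNVs only), partitions it into the
#' primary and comparator pathogenicity strata, and tests the observed
#' overlap of trio de novo variants against each stratum's trinucleotide-
#' rate expectation with the two-tailed exact Poisson test. Also reports
#' per-class sub-rows of the primary set and the secondary two-sample
#' contrast of primary-set enrichment against the cohort-wide constrained
#' de novo background.
#'
#' @param config config list supplying `variants` (query trio events),
#'   `ndd_variants` (the NDD union or concatenated lists), `gene_table`,
#'   `rates`, `cohort`; optionally `constrained_lam` (precomputed
#'   background expectation, e.g. from
#'   [expected_constrained_background()]) else a gene-table approximation
#'   with `mpc_rate_fraction` is used.
#' @return object of class `allelic_report`: `$table`, `$matched`
#'   (overlapping records), `$background`.
#' @export
run_allelic <- function(config) {
  cfg <- resolve_config(config)
  for (k in c("variants", "ndd_variants", "gene_table", "rates", "cohort"))
    if (is.null(cfg[[k]])) stop("run_allelic needs ", k)
  sz <- deduplicate_variants(cfg$variants[cfg$variants$is_snv, , drop = FALSE])
  ndd <- deduplicate_variants(
    cfg$ndd_variants[cfg$ndd_variants$is_snv, , drop = FALSE])
  stratum <- assign_ndd_stratum(ndd, cfg$gene_table,
                                cfg$mpc_threshold, cfg$pli_threshold)
  stopifnot(all(stratum %in% c("primary", "comparator")))
  subsets <- list(
    primary = ndd[stratum == "primary", , drop = FALSE],
    comparator = ndd[stratum == "comparator", , drop = FALSE])
  prim <- subsets$primary
  prim_cls <- classify_variant(prim$consequence)
  subsets$primary_ptv <- prim[prim_cls == "PTV", , drop = FALSE]
  subsets$primary_missense <- prim[prim_cls == "missense", , drop = FALSE]
  rows <- list(); matched <- list(); lam_by <- c(); obs_by <- c()
  for (sname in names(subsets)) {
    s <- subsets[[sname]]
    ec <- expected_allele_set_count(s, cfg$rates, cfg$cohort,
                                    cfg$x_as_autosome)
    ov <- overlap_variants(sz, variant_key(s))
    lam_by[sname] <- ec$lam; obs_by[sname] <- ov$count
    matched[[sname]] <- ov$matched
    if (ec$lam <= 0) {
      if (nrow(s) > 0)
        stop("degenerate rate table: zero expectation for non-empty set ", sname)
      rows[[length(rows) + 1L]] <- empty_row(sname, 0L, "all", "empty set")
      next
    }
    res <- poisson_exact_test(ov$count, ec$lam,
                              two_sided_rule = cfg$two_sided_rule)
    rows[[length(rows) + 1L]] <- res_row(sname, nrow(s), "all", res)
  }
  # partition identity: primary + comparator must recover the full union
  stopifnot(nrow(subsets$primary) + nrow(subsets$comparator) == nrow(ndd))
  total_overlap <- overlap_variants(sz, variant_key(ndd))$count
  stopifnot(obs_by["primary"] + obs_by["comparator"] == total_overlap)
  # secondary contrast: primary-set enrichment vs the cohort-wide
  # constrained de novo background (primary alleles excluded from the
  # background arm)
  background <- NULL
  if (!is.null(cfg$constrained_lam)) {
    lam_bg <- cfg$constrained_lam
  } else {
    lam_ptv <- expected_gene_set_count(
      cfg$gene_table$gene[cfg$gene_table$pli >= cfg$pli_threshold &
                            !is.na(cfg$gene_table$pli)],
      "PTV", cfg$gene_table, cfg$cohort, cfg$x_as_autosome)$lam
    lam_mis <- cfg$mpc_rate_fraction *
      expected_gene_set_count(cfg$gene_table$gene, "missense",
                              cfg$gene_table, cfg$cohort,
                              cfg$x_as_autosome)$lam
    lam_bg <- lam_ptv + lam_mis
  }
  sz_constrained <- assign_ndd_stratum(sz, cfg$gene_table,
                                       cfg$mpc_threshold,
                                       cfg$pli_threshold) == "primary"
  in_primary <- variant_key(sz) %in% variant_key(subsets$primary)
  x_bg <- sum(sz_constrained & !in_primary)
  lam_bg_excl <- lam_bg - lam_by["primary"]
  if (lam_bg_excl > 0) {
    bg_res <- two_sample_poisson_test(obs_by[["primary"]],
                                      lam_by[["primary"]],
                                      x_bg, lam_bg_excl,
                                      two_sided_rule = cfg$two_sided_rule)
    background <- res_row("primary_vs_constrained_background",
                          nrow(subsets$primary), "all", bg_res)
    background$observed <- obs_by[["primary"]]
    background$expected <- lam_by[["primary"]]
  }
  structure(list(table = do.call(rbind, rows), matched = matched,
                 background = background, config_seed = cfg$seed),
            class = "allelic_report")
}

#' Run the case-control burden replication
#'
#' Firth penalised-likelihood logistic burden tests (one-tailed for excess
#' in cases) for the primary- and comparator-set burdens, adjusted for the
#' first 10 principal components, exome-wide synonymous burden, platform
#' and sex.
#'
#' @param config config list supplying `case_control` (per-subject burden
#'   table; see [simulate_case_control()] for the column contract) and
#'   optionally `covariates` (default PCs + synonymous burden + platform
#'   + sex).
#' @return object of class `case_control_report`: `$table` and `$fits`.
#' @export
run_case_control <- function(config) {
  cfg <- resolve_config(config)
  if (is.null(cfg$case_control)) stop("run_case_control needs case_control")
  cc <- cfg$case_control
  covariates <- cfg$covariates %||%
    c(paste0("PC", 1:10), "syn_burden", "platform", "sex")
  miss <- setdiff(c("phenotype", covariates), names(cc))
  if (length(miss)) stop("case-control table lacks column(s): ",
                         paste(miss, collapse = ", "))
  rows <- list(); fits <- list()
  for (set in c("primary", "comparator")) {
    col <- paste0(set, "_burden")
    if (!col %in% names(cc)) next
    fit <- firth_burden_test(cc, phenotype = "phenotype", burden = col,
                             covariates = covariates)
    fits[[set]] <- fit
    case <- cc$phenotype == 1
    rows[[length(rows) + 1L]] <- data.frame(
      set = set,
      case_rate = mean(cc[[col]][case]),
      control_rate = mean(cc[[col]][!case]),
      n_case_variants = sum(cc[[col]][case]),
      n_control_variants = sum(cc[[col]][!case]),
      p_one_tailed = fit$p_one_tailed, odds_ratio = fit$or,
      ci_low = fit$ci_low, ci_high = fit$ci_high,
      flag = if (sum(cc[[col]]) == 0) "no carriers in either arm" else
        NA_character_,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 config_seed = cfg$seed), class = "case_control_report")
}

#' @export
print.genic_report <- function(x, ...) {
  cat("Genic pleiotropy report\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
print.allelic_report <- function(x, ...) {
  cat("Allelic pleiotropy report\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  if (!is.null(x$background)) {
    cat("secondary contrast:\n")
    print(format(x$background, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.case_control_report <- function(x, ...) {
  cat("Case-control burden report\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write a report's table as TSV plus a full-precision JSON sidecar
#'
#' P values and ratios are printed at 2 significant figures in the TSV
#' (display convention); the JSON sidecar carries full precision and the
#' seed used.
#'
#' @param report a `genic_report`, `allelic_report` or
#'   `case_control_report`.
#' @param path output TSV path (the sidecar gets extension `.json`).
#' @return the TSV path, invisibly.
#' @export
write_report <- function(report, path) {
  tab <- report$table
  disp <- tab
  num <- vapply(disp, is.numeric, logical(1)) &
    !names(disp) %in% c("observed", "n_items")
  disp[num] <- lapply(disp[num], function(x) signif(x, 2))
  write_tsv_dot(disp, path)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(table = tab, seed = report$config_seed),
                       side, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}
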