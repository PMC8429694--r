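test_that("consequence terms collapse to the three mutation classes", {
  expect_equal(classify_variant(c("stop_gain", "frameshift", "splice_donor",
                                  "splice_acceptor")),
               rep("PTV", 4))
  expect_equal(classify_variant("missense"), "missense")
  expect_equal(classify_variant("synonymous"), "synonymous")
  expect_error(classify_variant("splice_region"), "splice_region")
})

test_that("stratum assignment follows the pLI/MPC rules and their boundaries", {
  g <- toy_gene_table()
  mk <- function(gene, consequence, mpc = NA_real_)
    data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G", gene = gene,
               consequence = consequence, mpc = mpc, stringsAsFactors = FALSE)
  # PTV in a pLI = 1 gene is primary; in a tolerant gene it is comparator
  expect_equal(assign_ndd_stratum(mk("KMT2D", "stop_gain"), g), "primary")
  expect_equal(assign_ndd_stratum(mk("KLHL20", "stop_gain"), g), "comparator")
  # MPC boundary: >= 2 is primary, 1.99 is not; missing MPC degrades
  expect_equal(assign_ndd_stratum(mk("SCN2A", "missense", 2.16), g), "primary")
  expect_equal(assign_ndd_stratum(mk("SCN2A", "missense", 2.00), g), "primary")
  expect_equal(assign_ndd_stratum(mk("SCN2A", "missense", 1.99), g), "comparator")
  expect_equal(assign_ndd_stratum(mk("SCN2A", "missense", NA), g), "comparator")
  # missense MPC >= 2 is primary regardless of gene pLI (KLHL20 pLI 0.0094)
  expect_equal(assign_ndd_stratum(mk("KLHL20", "missense", 2.22), g), "primary")
  expect_equal(assign_ndd_stratum(mk("KMT2D", "synonymous"), g), "comparator")
  # unknown gene: pLI treated as 0, logged
  expect_message(out <- assign_ndd_stratum(mk("NOPE", "stop_gain"), g),
                 "pLI")
  expect_equal(out, "comparator")
  # pLI boundary at the threshold itself
  expect_equal(assign_ndd_stratum(mk("RUNX3", "stop_gain"), g,
                                  pli_threshold = 0.84), "primary")
})

test_that("stratum assignment is total and monotone in MPC and pLI", {
  set.seed(11)
  n <- 200
  g <- data.frame(gene = paste0("g", 1:20),
                  pli = runif(20), mu_ptv = 1e-6, mu_mis = 1e-6,
                  mu_syn = 1e-6, stringsAsFactors = FALSE)
  g <- validate_gene_table(g)
  v <- data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
                  gene = sample(g$gene, n, TRUE),
                  consequence = sample(c("stop_gain", "missense", "synonymous"),
                                       n, TRUE),
                  mpc = runif(n, 0, 4), stringsAsFactors = FALSE)
  v$mpc[v$consequence != "missense"] <- NA
  s <- assign_ndd_stratum(v, g)
  expect_true(all(s %in% c("primary", "comparator")))
  # raising MPC never demotes
  v2 <- v; v2$mpc <- v2$mpc + 1
  s2 <- assign_ndd_stratum(v2, g)
  expect_true(all(!(s == "primary" & s2 == "comparator")))
  # raising pLI never demotes
  g2 <- g; g2$pli <- pmin(1, g2$pli + 0.5)
  s3 <- assign_ndd_stratum(v, g2)
  expect_true(all(!(s == "primary" & s3 == "comparator")))
})

test_that("deduplication keeps one record per allele key and is idempotent", {
  v <- toy_variants()  # rows 4 and 5 share a key
  d <- deduplicate_variants(v)
  expect_equal(nrow(d), 4)
  expect_identical(deduplicate_variants(d), d)
  expect_equal(nrow(deduplicate_variants(v[0, ])), 0)
  # conflicting annotations warn and keep first-seen
  v2 <- v; v2$consequence[5] <- "synonymous"; v2$mpc[5] <- NA
  expect_warning(d2 <- deduplicate_variants(v2), "conflicting")
  expect_equal(d2$consequence[d2$pos == 400], "missense")
})

test_that("overlap counting equals brute-force set intersection", {
  v <- deduplicate_variants(toy_variants())
  expect_equal(overlap_variants(v, variant_key(v))$count, nrow(v))
  expect_equal(overlap_variants(v, character(0))$count, 0)
  # planted overlap in random key sets
  set.seed(7)
  mk_keys <- function(n, offset)
    data.frame(chrom = sample(as.character(1:22), n, TRUE),
               pos = sample(1e6, n) + offset, ref = "A", alt = "G",
               gene = "g", consequence = "missense",
               stringsAsFactors = FALSE)
  q <- mk_keys(100, 0)
  t <- mk_keys(1000, 2e6)
  shared <- q[1:7, ]
  t[1:7, c("chrom", "pos")] <- shared[, c("chrom", "pos")]
  q <- deduplicate_variants(q); t <- deduplicate_variants(t)
  got <- overlap_variants(q, variant_key(t))
  brute <- length(intersect(variant_key(q), variant_key(t)))
  expect_equal(got$count, brute)
  expect_equal(got$count, 7)
  expect_equal(nrow(got$matched), 7)
})

test_that("gene strata partition the significant genes disjointly", {
  g <- validate_gene_table(data.frame(
    gene = paste0("g", 1:6),
    pli = 0.5, mu_ptv = 1e-6, mu_mis = 1e-6, mu_syn = 1e-6,
    p_ndd_ptv = c(1e-7, 1e-8, 0.3, 2.5e-6, NA, 0.9),
    p_ndd_mis = c(0.3, 1e-8, 1e-9, 1e-7, 1e-7, NA),
    stringsAsFactors = FALSE))
  s <- build_gene_strata(g)
  # hand enumeration: g1 ptv-only; g2 both; g3 mis-only; g4 mis-only
  # (2.5e-6 is not < 2.5e-6); g5 mis-only (NA ptv); g6 neither
  expect_setequal(s$ptv_specific, "g1")
  expect_setequal(s$ptv_and_missense, "g2")
  expect_setequal(s$missense_specific, c("g3", "g4", "g5"))
  expect_length(intersect(s$ptv_specific, s$missense_specific), 0)
  expect_length(intersect(s$ptv_specific, s$ptv_and_missense), 0)
  expect_length(intersect(s$missense_specific, s$ptv_and_missense), 0)
})

test_that("reference-database allele-count filter keeps ultra-rare alleles", {
  v <- data.frame(chrom = "1", pos = 1:10, ref = "A", alt = "G",
                  gene = "g", consequence = "missense",
                  ac_gnomad = c(0L, 1L, 5L, 6L, 100L, NA, 2L, 7L, 5L, 3L),
                  stringsAsFactors = FALSE)
  kept <- gnomad_ac_filter(v)
  expect_equal(nrow(kept), 7)  # hand count: three records above 5 removed
  expect_true(all(kept$ac_gnomad <= 5, na.rm = TRUE))
  expect_true(any(is.na(kept$ac_gnomad)))  # missing = absent, kept
  # at threshold 0 only the ac = 0 record and the absent-from-database
  # record survive
  expect_equal(nrow(gnomad_ac_filter(v, threshold = 0)), 2)
})

test_that("variant ingest enforces the record invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  v <- toy_variants()
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_equal(back$pos, v$pos)
  expect_equal(back$mpc, v$mpc)
  # Y/MT records are rejected at ingest
  v2 <- rbind(v, v[1, ]); v2$chrom[6] <- "Y"
  write_variant_table(v2, path)
  expect_message(back2 <- read_variant_table(path), "Y/MT")
  expect_equal(nrow(back2), nrow(v))
  # context must be centred on ref
  v3 <- v; v3$context[2] <- "AAG"
  expect_error(validate_variants(v3), "centred")
  v4 <- v; v4$alt[1] <- v4$ref[1]
  expect_error(validate_variants(v4), "ref == alt")
})
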