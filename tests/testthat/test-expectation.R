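test_that("context canonicalisation collapses strand pairs", {
  # ACG < CGT = revcomp(ACG); the pair (CGT, A) maps to (ACG, T)
  can <- canonical_context(c("ACG", "CGT"), c("T", "A"))
  expect_equal(can$context, c("ACG", "ACG"))
  expect_equal(can$alt, c("T", "T"))
  # exactly 96 canonical entries exist
  entries <- dnmpleio:::all_canonical_entries()
  expect_equal(nrow(entries), 96)
  expect_true(all(entries$context <= dnmpleio:::revcomp3(entries$context)))
})

test_that("allele rates are strand-symmetric lookups", {
  r <- uniform_rate_table(1e-8)
  r$mu[r$context == "ACG" & r$alt == "T"] <- 3e-8
  v <- validate_variants(data.frame(
    chrom = "1", pos = c(1L, 2L), ref = c("C", "G"), alt = c("T", "A"),
    gene = "g", consequence = "missense", mpc = NA_real_,
    context = c("ACG", "CGT"), stringsAsFactors = FALSE))
  # (CGT, A) is the reverse complement of (ACG, T): same rate
  expect_equal(allele_rate(v, r), c(3e-8, 3e-8))
  # indels carry no context and are rejected
  ind <- data.frame(chrom = "1", pos = 1L, ref = "CT", alt = "C", gene = "g",
                    consequence = "frameshift", is_snv = FALSE,
                    context = NA_character_, stringsAsFactors = FALSE)
  expect_error(allele_rate(ind, r), "SNV")
  # context/ref mismatch names the record
  v2 <- v; v2$context[1] <- "AAG"
  expect_error(allele_rate(v2, r), "1:1:C:T")
})

test_that("rate table loader validates completeness and sanity bounds", {
  r <- uniform_rate_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(r, path)
  expect_equal(read_rate_table(path), r, ignore_attr = TRUE)
  expect_error(validate_rate_table(r[-1, ]), "incomplete")
  r2 <- r; r2$mu[1] <- 2e-4
  expect_error(validate_rate_table(r2), "1e-4")
})

test_that("transmissible haplotype counts respect the proband sex split", {
  co <- sz_trio_cohort()
  expect_equal(diploid_opportunity("7", co), 6888)        # 2N
  expect_equal(diploid_opportunity("X", co), 4767)        # 2121 + 2*1323
  all_male <- cohort_spec(50, 50, 0)
  expect_equal(diploid_opportunity("X", all_male), 50)
  expect_equal(diploid_opportunity("X", co, x_as_autosome = TRUE), 6888)
  expect_error(diploid_opportunity("Y", co), "Y")
})

test_that("allele-set expectations are hand-checkable sums of 2N mu", {
  r <- uniform_rate_table(1e-8)
  co <- cohort_spec(50, 25, 25)
  v <- validate_variants(data.frame(
    chrom = "1", pos = c(1L, 2L), ref = "A", alt = "G", gene = "g",
    consequence = "synonymous", mpc = NA_real_,
    context = c("AAA", "CAC"), stringsAsFactors = FALSE))
  ec <- expected_allele_set_count(v, r, co)
  expect_equal(ec$lam, 2 * 1e-8 * 100)  # 2 alleles x mu x 2N
  expect_equal(expected_allele_set_count(v[0, ], r, co)$lam, 0)
  expect_error(expected_allele_set_count(rbind(v, v), r, co), "dedup")
})

test_that("gene-set expectations apply coverage and the 2N multiplier", {
  co <- sz_trio_cohort()
  g <- validate_gene_table(data.frame(
    gene = c("a", "b"), pli = 0.5, mu_ptv = c(5e-6, 5e-6),
    mu_mis = 1e-5, mu_syn = 1e-6,
    coverage_factor = c(1, 0.5), stringsAsFactors = FALSE))
  expect_equal(expected_gene_set_count("a", "PTV", g, co)$lam,
               2 * 3444 * 5e-6)  # 0.0344...
  # halving coverage halves the expectation
  expect_equal(expected_gene_set_count("b", "PTV", g, co)$lam,
               expected_gene_set_count("a", "PTV", g, co)$lam / 2)
  expect_equal(expected_gene_set_count(character(0), "PTV", g, co)$lam, 0)
  expect_error(expected_gene_set_count("zz", "PTV", g, co), "zz")
  # X-linked genes use the sex-aware opportunity when chrom is present
  g$chrom <- c("1", "X")
  expect_equal(expected_gene_set_count("b", "PTV", g, co)$lam,
               4767 * 5e-6 * 0.5)
})

test_that("expectations are additive and linear in cohort size", {
  w <- small_world(seed = 5)
  co <- cohort_spec(1000, 500, 500)
  v <- deduplicate_variants(w$sites[sample.int(nrow(w$sites), 400), ])
  a <- v[1:150, ]; b <- v[151:nrow(v), ]
  expect_equal(expected_allele_set_count(v, w$rates, co)$lam,
               expected_allele_set_count(a, w$rates, co)$lam +
                 expected_allele_set_count(b, w$rates, co)$lam)
  co2 <- cohort_spec(2000, 1000, 1000)
  auto <- v[v$chrom != "X", ]
  expect_equal(expected_allele_set_count(auto, w$rates, co2)$lam,
               2 * expected_allele_set_count(auto, w$rates, co)$lam)
  # reverse-complementing every context/alt leaves lam unchanged
  v_rc <- v
  v_rc$context <- dnmpleio:::revcomp3(v$context)
  v_rc$ref <- substr(v_rc$context, 2, 2)
  v_rc$alt <- dnmpleio:::revcomp1(v$alt)
  expect_equal(expected_allele_set_count(v_rc, w$rates, co)$lam,
               expected_allele_set_count(v, w$rates, co)$lam)
})
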