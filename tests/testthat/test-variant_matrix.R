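write_test_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=Y,length=5063000>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3"
)

test_that("read_vcf ingests haploid biallelic records", {
  skip_if_not_installed("VariantAnnotation")
  path <- write_test_vcf(c(
    vcf_header,
    "Y\t100\tv1\tA\tG\t.\t.\t.\tGT\t0\t1\t1",
    "Y\t200\tv2\tC\tT\t.\t.\t.\tGT\t1\t0\t1"
  ))
  am <- read_vcf(path)
  expect_equal(am$samples, c("S1", "S2", "S3"))
  expect_equal(dim(am$calls), c(3L, 2L))
  expect_false(anyNA(am$calls))
  expect_equal(unname(am$calls[, "v1"]), c("A", "G", "G"))
  expect_equal(am$variants$pos, c(100L, 200L))
})

test_that("diploid heterozygous calls become missing with a warning", {
  skip_if_not_installed("VariantAnnotation")
  path <- write_test_vcf(c(
    vcf_header,
    "Y\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/1\t1/1\t0/0"
  ))
  expect_warning(am <- read_vcf(path), "heterozygous")
  expect_true(is.na(am$calls["S1", "v1"]))
  expect_equal(am$calls["S2", "v1"], "G")
  expect_equal(am$calls["S3", "v1"], "A")
})

test_that("multiallelic records split into biallelic records", {
  skip_if_not_installed("VariantAnnotation")
  path <- write_test_vcf(c(
    vcf_header,
    "Y\t100\tv1\tA\tC,T\t.\t.\t.\tGT\t0\t1\t2",
    "Y\t200\tv2\tG\tA\t.\t.\t.\tGT\t1\t.\t0"
  ))
  am <- read_vcf(path)
  # hand-split oracle: v1.1 = A->C (S3 carries T, missing for this record),
  # v1.2 = A->T (S2 carries C, missing), v2 untouched
  expect_equal(am$variants$id, c("v1.1", "v1.2", "v2"))
  expect_equal(am$variants$alt, c("C", "T", "A"))
  expect_equal(unname(am$calls[, "v1.1"]), c("A", "C", NA))
  expect_equal(unname(am$calls[, "v1.2"]), c("A", NA, "T"))
  expect_equal(unname(am$calls[, "v2"]), c("A", NA, "G"))
})

test_that("read_vcf rejects junk and missing files", {
  skip_if_not_installed("VariantAnnotation")
  expect_error(read_vcf(tempfile()), "no such file")
  bad <- write_test_vcf(c("not a vcf at all"))
  expect_error(read_vcf(bad), "malformed|scan|header")
})

test_that("polarize orients states by the outgroup allele", {
  # 4 variants; outgroup pattern: ref, alt, missing, ref
  calls <- rbind(
    S1 = c("A", "C", "G", "T"),
    S2 = c("G", "T", "A", "T"),
    OUT = c("A", "T", NA, "T")
  )
  colnames(calls) <- paste0("v", 1:4)
  am <- structure(list(
    samples = rownames(calls),
    variants = variant_table(colnames(calls), pos = 1:4,
                             ref = c("A", "C", "G", "T"),
                             alt = c("G", "T", "A", "A")),
    calls = calls), class = "allele_matrix")
  pm <- polarize(am, "OUT")
  expect_equal(pm$samples, c("S1", "S2"))
  # v1: outgroup=ref -> derived=G: S1 ancestral, S2 derived
  expect_equal(unname(pm$states[, "v1"]), c(0L, 1L))
  # v2: outgroup=alt T -> C is derived: S1 derived, S2 ancestral
  expect_equal(pm$variants$ancestral[2], "alt")
  expect_equal(unname(pm$states[, "v2"]), c(1L, 0L))
  # v3: outgroup missing -> unpolarized, all NA, flagged
  expect_equal(pm$variants$ancestral[3], "unknown")
  expect_true(all(is.na(pm$states[, "v3"])))
  expect_equal(attr(pm, "unpolarized"), "v3")
  # v4: T->A, outgroup T=ref
  expect_equal(unname(pm$states[, "v4"]), c(0L, 0L))
  expect_error(polarize(am, "NOPE"), "not found")
})

test_that("polarize is idempotent given the same outgroup", {
  set.seed(1)
  st <- matrix(sample(c(0L, 1L, NA), 40, TRUE, c(.45, .45, .1)), 5, 8,
               dimnames = list(paste0("S", 1:5), paste0("v", 1:8)))
  st["S5", ] <- 0L   # outgroup carries the reference = ancestral everywhere
  pm <- make_pm(st)
  p1 <- polarize(pm, "S5")
  # re-polarizing with an all-ancestral outgroup must not change states
  p1b <- p1
  p1b$states <- rbind(p1$states, S5 = rep(0L, 8))
  p1b$samples <- c(p1$samples, "S5")
  p2 <- polarize(polarized_matrix(p1b$states, variants = p1$variants), "S5")
  expect_identical(p2$states, p1$states)
})

test_that("filter_stringent applies rules in order and reconciles", {
  set.seed(7)
  n <- 10; p <- 20
  st <- matrix(sample(c(0L, 1L), n * p, TRUE), n, p,
               dimnames = list(paste0("S", 1:n), sprintf("v%02d", 1:p)))
  v <- variant_table(colnames(st), pos = 1:p, ancestral = "ref")
  # engineered failures: v01 unpolarized, v02 high site missingness,
  # v03 flagged non-biallelic
  v$ancestral[1] <- "unknown"
  st[1:6, 2] <- NA
  v$biallelic <- TRUE; v$biallelic[3] <- FALSE
  pm <- make_pm(st, variants = v)
  res <- filter_stringent(pm, filter_config(max_site_missing = 0.2))
  expect_equal(res$report$retained_variants, 17L)
  expect_equal(unname(res$report$removed_variants["unpolarized"]), 1L)
  expect_equal(unname(res$report$removed_variants["site_missing"]), 1L)
  expect_equal(unname(res$report$removed_variants["non_biallelic"]), 1L)
  expect_equal(sum(res$report$removed_variants) + res$report$retained_variants,
               res$report$input_variants)
  # all-pass case: output identical to input
  pm2 <- make_pm(st[, 4:10], variants = v[4:10, ])
  res2 <- filter_stringent(pm2)
  expect_identical(res2$matrix$states, pm2$states)
  expect_true(all(res2$report$removed_variants == 0L))
  # threshold validation
  expect_error(filter_config(max_site_missing = 1.5), "\\[0, 1\\]")
})

test_that("filter never increases missingness of retained cells", {
  set.seed(11)
  st <- matrix(sample(c(0L, 1L, NA), 200, TRUE, c(.4, .4, .2)), 10, 20)
  pm <- make_pm(st)
  res <- filter_stringent(pm, filter_config(max_site_missing = 0.5,
                                            max_sample_missing = 0.6))
  kept_s <- res$matrix$samples
  kept_v <- res$matrix$variants$id
  expect_identical(res$matrix$states,
                   pm$states[kept_s, kept_v, drop = FALSE])
})

test_that("haplotype strings concatenate states and count distinct HTs", {
  st <- rbind(S1 = c(0L, 1L, 1L), S2 = c(0L, 1L, 1L), S3 = c(1L, 0L, 0L))
  colnames(st) <- paste0("v", 1:3)
  pm <- make_pm(st)
  hs <- haplotype_strings(pm)
  expect_equal(hs$n_distinct, 2L)
  expect_equal(unname(hs$haplotypes["S1"]), "011")
  # STR as terminal splitter: identical SNPs, repeat 12 vs 13 -> 2 HTs
  pm2 <- make_pm(st[1:2, ], str_alleles = c(S1 = 12L, S2 = 13L))
  expect_equal(haplotype_strings(pm2)$n_distinct, 2L)
  # require_complete drops samples with NA
  st3 <- st; st3["S2", 2] <- NA
  hs3 <- haplotype_strings(make_pm(st3), impute_policy = "require_complete")
  expect_equal(sort(names(hs3$haplotypes)), c("S1", "S3"))
})

test_that("distinct-HT count is invariant to row/column permutation", {
  set.seed(3)
  st <- matrix(sample(c(0L, 1L, NA), 120, TRUE, c(.45, .45, .1)), 12, 10,
               dimnames = list(paste0("S", 1:12), paste0("v", 1:10)))
  pm <- make_pm(st)
  n0 <- haplotype_strings(pm)$n_distinct
  sp <- sample(12); vp <- sample(10)
  pm2 <- make_pm(st[sp, vp])
  expect_equal(haplotype_strings(pm2)$n_distinct, n0)
})

test_that("matrix TSV round-trips states and order", {
  set.seed(5)
  st <- matrix(sample(c(0L, 1L, NA), 60, TRUE), 6, 10,
               dimnames = list(paste0("S", 1:6), sprintf("eS%04d", 1:10)))
  pm <- make_pm(st)
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(pm, path)
  back <- read_matrix_tsv(path)
  expect_identical(back$states, pm$states)
  expect_identical(back$samples, pm$samples)
  expect_identical(back$variants$id, pm$variants$id)
})
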