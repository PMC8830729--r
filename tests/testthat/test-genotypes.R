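test_that("VCF parsing handles missing calls and multiallelic records", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    "chr1\t100\tsnp1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnp2\tA\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1/1",
    "chr1\t300\tsnp3\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t2/2",
    "chr1\t400\tsnp4\tA\tT\t.\tPASS\t.\tGT\t1/0\t0/0\t./."),
    path)
  expect_warning(g <- read_vcf(path), "multiallelic")
  expect_equal(dim(g), c(3L, 3L))
  expect_equal(unname(g$g[, "snp1"]), c(0L, 1L, 2L))
  expect_true(is.na(g$g["s1", "snp2"]))
  expect_equal(unname(g$g[, "snp4"]), c(1L, 0L, NA))
  expect_equal(g$ids, c("s1", "s2", "s3"))
})

test_that("HWE exact test equals the enumeration oracle", {
  # worked case n = 2: configurations 0 and 2 hets with probs 1/3 and 2/3
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  # equilibrium-looking counts give p near 1
  expect_gt(hwe_exact_test(25, 50, 25), 0.9)
  # a total heterozygote deficit is essentially impossible
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  # all configurations up to n = 10 against the oracle
  for (n in 1:10)
    for (het in 0:n)
      for (hom_alt in 0:(n - het)) {
        hom_ref <- n - het - hom_alt
        expect_equal(hwe_exact_test(hom_ref, het, hom_alt),
                     hwe_enum_oracle(hom_ref, het, hom_alt),
                     tolerance = 1e-12,
                     info = sprintf("(%d,%d,%d)", hom_ref, het, hom_alt))
      }
})

test_that("locus filters apply boundary semantics in order with exact attribution", {
  # planted matrix, 20 individuals x 7 loci:
  #  locus 1 fine; locus 2 call rate 85% (<90) -> call_rate;
  #  locus 3 MAF 0.05 exactly -> maf (strict >);
  #  locus 4 MAF 0.2 fine; locus 5 all het -> hwe;
  #  locus 6 monomorphic (MAF 0) -> maf; locus 7 fine
  set.seed(1)
  n <- 20
  g <- cbind(
    rbinom(n, 2, 0.4),
    c(rep(NA, 3), rbinom(n - 3, 2, 0.4)),
    c(rep(1, 2), rep(0, n - 2)),          # MAF = 2/40 = 0.05
    c(rep(1, 8), rep(0, 12)),             # MAF = 0.2
    rep(1, n),                            # all heterozygous
    rep(0, n),
    rbinom(n, 2, 0.5))
  g[1, 1] <- 1  # ensure polymorphic
  res <- apply_locus_filters(genotype_matrix(g), hwe_p = 0.001)
  rep_ <- res$report
  expect_equal(rep_$n_removed[rep_$rule == "call_rate"], 1)
  expect_equal(rep_$n_removed[rep_$rule == "maf"], 2)
  expect_equal(rep_$n_removed[rep_$rule == "hwe"], 1)
  expect_equal(ncol(res$geno$g), 3)
  # chain is idempotent
  res2 <- apply_locus_filters(res$geno, hwe_p = 0.001)
  expect_equal(res2$geno$g, res$geno$g)
  expect_equal(sum(res2$report$n_removed), 0)
})

test_that("individual missingness filter retains the 85% boundary", {
  g <- matrix(0L, 4, 20)
  g[1, 1:18] <- NA          # 90% missing -> removed
  g[2, 1:17] <- NA          # 85% exactly -> retained
  g[3, 1] <- 1L
  res <- apply_individual_filters(genotype_matrix(g))
  expect_equal(res$report$n_removed, 1)
  expect_equal(nrow(res$geno$g), 3)
})

test_that("LD pruning removes correlated loci deterministically", {
  set.seed(2)
  base <- rbinom(60, 2, 0.5)
  # locus 2 duplicates locus 1 -> one of the pair goes
  g <- cbind(base, base, rbinom(60, 2, 0.4), rbinom(60, 2, 0.3))
  keep <- ld_prune(genotype_matrix(g))
  expect_length(keep, 3)
  expect_true(!(1 %in% keep) || !(2 %in% keep))
  # three perfectly correlated loci in one window -> one retained
  g3 <- cbind(base, base, base, rbinom(60, 2, 0.4))
  keep3 <- ld_prune(genotype_matrix(g3))
  expect_length(intersect(keep3, 1:3), 1)
  # independent loci are retained
  set.seed(3)
  gi <- sapply(1:40, function(i) rbinom(500, 2, runif(1, 0.2, 0.8)))
  keepi <- ld_prune(genotype_matrix(gi))
  expect_length(keepi, 40)
  # deterministic
  expect_identical(keep, ld_prune(genotype_matrix(g)))
})
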