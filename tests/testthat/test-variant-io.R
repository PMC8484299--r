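test_that("read_vcf keeps biallelic SNPs and drops indels/multiallelics", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  samples <- c("a1", "a2")
  groups <- c(a1 = "CO", a2 = "VO")
  write_vcf_fixture(tmp, samples, c(
    vcf_rec(100, "A", "G", 60, c("0/0:10", "1/1:12")),
    vcf_rec(200, "A", "AT", 60, c("0/0:10", "0/1:12")),      # indel
    vcf_rec(300, "C", "T", 60, c("0/1:9", "0/0:11"))))
  panel <- suppressMessages(read_vcf(tmp, groups))
  expect_equal(n_sites(panel), 2)
  expect_equal(panel$sites$pos, c(100L, 300L))
  expect_equal(unname(attr(panel, "read_summary")[c("indel", "multiallelic")]),
               c(1, 0))
  expect_equal(panel$geno[1, ], c(a1 = 0L, a2 = 2L))
  expect_equal(panel$dp[2, ], c(a1 = 9L, a2 = 11L))
  expect_equal(panel$sites$mq, c(60, 60))

  # multiallelic records are counted separately
  write_vcf_fixture(tmp, samples, c(
    vcf_rec(100, "A", "G,T", 60, c("0/0:10", "1/2:12")),
    vcf_rec(300, "C", "T", 60, c("0/1:9", "0/0:11"))))
  panel <- suppressMessages(read_vcf(tmp, groups))
  expect_equal(n_sites(panel), 1)
  expect_equal(unname(attr(panel, "read_summary")["multiallelic"]), 1)
})

test_that("read_vcf refuses samples absent from the group table", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(tmp, c("a1", "mystery"), c(
    vcf_rec(100, "A", "G", 60, c("0/0:10", "1/1:12"))))
  expect_error(suppressMessages(read_vcf(tmp, c(a1 = "CO"))), "mystery")
})

test_that("VCF round-trip preserves sites and genotypes", {
  panel <- toy_panel(rbind(c(0, 1, 2, NA), c(2, 2, 0, 1), c(0, 0, 0, 1)),
                     pos = c(50L, 400L, 9000L),
                     dp = matrix(10L, 3, 4))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(panel, tmp)
  back <- suppressMessages(read_vcf(tmp, panel$groups))
  expect_identical(back$sites[c("chrom", "pos", "ref", "alt")],
                   panel$sites[c("chrom", "pos", "ref", "alt")])
  expect_identical(back$geno, panel$geno)
  expect_identical(back$dp, panel$dp)
  expect_equal(back$sites$mq, panel$sites$mq)
})

test_that("genotype depth filter masks outside [min_dp, max_dp] inclusive", {
  panel <- toy_panel(rbind(c(0L, 1L, 2L, 1L)),
                     dp = rbind(c(2L, 3L, 50L, 51L)))
  f <- suppressMessages(filter_genotypes(panel))
  expect_equal(as.vector(f$geno), c(NA, 1L, 2L, NA))
  expect_equal(sum(!is.na(f$geno)), 2)
  # panels without depth pass through untouched
  nodp <- toy_panel(rbind(c(0L, 1L, 2L, 1L)))
  expect_identical(suppressMessages(filter_genotypes(nodp))$geno, nodp$geno)
})

test_that("site filter applies mq, maf, miss rules with first-fail attribution", {
  # 12 samples; one low-mq site, one monomorphic, one maf 1/24 < 0.05,
  # one with 2/12 missing, one clean
  g_clean <- c(rep(0L, 6), rep(1L, 3), rep(2L, 3))
  g_mono <- rep(0L, 12)
  g_rare <- c(1L, rep(0L, 11))
  g_miss <- c(NA, NA, rep(1L, 10))
  geno <- rbind(g_clean, g_rare, g_mono, g_miss, g_clean)
  panel <- toy_panel(geno, mq = c(15, 60, 60, 60, 60))
  f <- suppressMessages(filter_sites(panel))
  tally <- attr(f, "filter_tally")
  expect_equal(tally$removed[tally$rule == "mq"], 1)
  expect_equal(tally$removed[tally$rule == "maf"], 2)
  expect_equal(tally$removed[tally$rule == "miss"], 1)
  expect_equal(n_sites(f), 1)
  # tallies account for every removed site
  expect_equal(n_sites(panel), n_sites(f) + sum(tally$removed))
})

test_that("maf boundary 0.05 is kept and computed over called alleles", {
  # 10 samples, one het among 10 -> af = 1/20 = 0.05 exactly: kept
  g <- rbind(c(1L, rep(0L, 9)))
  expect_equal(n_sites(suppressMessages(filter_sites(toy_panel(g)))), 1)
  # same count but 2 of 12 samples missing: af = 1/20 over called, but
  # missingness 2/12 > 0.1 removes it
  g2 <- rbind(c(1L, rep(0L, 9), NA, NA))
  f2 <- suppressMessages(filter_sites(toy_panel(g2)))
  expect_equal(n_sites(f2), 0)
  expect_equal(attr(f2, "filter_tally")$removed, c(0, 0, 1))
})

test_that("filtering is idempotent", {
  set.seed(11)
  geno <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                        prob = c(.4, .2, .3, .1)), 20, 10)
  dp <- matrix(rpois(200, 14), 20, 10)
  panel <- toy_panel(geno, dp = dp, mq = sample(c(15, 60), 20, TRUE))
  once <- suppressMessages(filter_sites(filter_genotypes(panel)))
  twice <- suppressMessages(filter_sites(filter_genotypes(once)))
  expect_identical(once$geno, twice$geno)
  expect_identical(once$sites, twice$sites)
  expect_equal(sum(attr(twice, "filter_tally")$removed), 0)
})

test_that("read_gff3 loads gene models and rejects malformed coordinates", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t100\t500\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\tx\texon\t100\t300\t.\t+\t.\tID=m1.e1;Parent=m1",
               "chr1\tx\tCDS\t150\t300\t.\t+\t.\tID=m1.c1;Parent=m1",
               "chr2\tx\tgene\t1000\t2000\t.\t-\t.\tID=g2"), tmp)
  gm <- read_gff3(tmp)
  expect_equal(nrow(gm$genes), 2)
  expect_equal(gm$genes$gene_id, c("g1", "g2"))
  expect_equal(unname(gm$features$gene_id), c("g1", "g1"))
  expect_setequal(gm$features$type, c("exon", "CDS"))
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t500\t100\t.\t+\t.\tID=g1"), tmp)
  expect_error(read_gff3(tmp), "line 2")
})

test_that("simulator toy GFF3 has the tiled gene count and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  n <- write_toy_gff3(tmp, L = 100000)
  expect_equal(n, 10)  # 3-kb genes every 10 kb on 100 kb
  gm <- read_gff3(tmp)
  expect_equal(nrow(gm$genes), 10)
  expect_true(all(gm$genes$end - gm$genes$start + 1 == 3000))
  expect_setequal(unique(gm$features$type),
                  c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
})

test_that("simulator VCF site count matches the truth file", {
  params <- sim_params(seed = 31, N = 40, t = 10, m = 300, L = 50000)
  out <- withr::local_tempdir()
  sw <- suppressMessages(sample_and_write(params, file.path(out, "sim")))
  panel <- suppressMessages(read_vcf(sw$files$vcf, sw$files$groups))
  truth <- read.delim(sw$files$truth)
  expect_equal(n_sites(panel), sw$truth$n_segregating)
  expect_equal(nrow(truth), sw$truth$n_segregating)
  expect_identical(panel$geno, sw$panel$geno)
})
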