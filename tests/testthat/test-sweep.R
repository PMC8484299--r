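# a synthetic scan table with known moments, used by several blocks
make_scan <- function(fst, pi_a, pi_b, n_snps = 50, chrom = "chr1") {
  n <- length(fst)
  tab <- data.frame(chrom = chrom, start = seq(0, by = 10000, length.out = n),
                    end = seq(20000, by = 10000, length.out = n),
                    n_snps = n_snps, pi_a = pi_a, pi_b = pi_b, fst = fst)
  tab$eligible <- !is.na(tab$fst) & tab$pi_a > 0 & tab$pi_b > 0 &
    tab$n_snps >= 10
  attr(tab, "ref_group") <- "CO"
  attr(tab, "alt_group") <- "VO"
  class(tab) <- c("scan_table", "data.frame")
  tab
}

test_that("zscore_fst standardizes to mean 0 / sd 1 and rejects degeneracy", {
  expect_equal(zscore_fst(c(0.1, 0.2, 0.3)), c(-1, 0, 1))
  set.seed(2)
  z <- zscore_fst(runif(200))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_error(zscore_fst(rep(0.5, 10)), "zero standard deviation")
  # NA windows are carried through, not dropped
  z2 <- zscore_fst(c(0.1, NA, 0.3))
  expect_true(is.na(z2[2]))
})

test_that("log2_pi_ratio flags zero-diversity windows ineligible", {
  expect_equal(log2_pi_ratio(0.002, 0.0005), 2)
  expect_equal(log2_pi_ratio(1e-4, 1e-4), 0)
  expect_true(is.na(log2_pi_ratio(1e-4, 0)))
  expect_true(is.na(log2_pi_ratio(0, 1e-4)))
})

test_that("joint outliers require both tails and bound the flagged fraction", {
  set.seed(42)
  n <- 100
  scan <- make_scan(fst = runif(n), pi_a = runif(n, 1e-4, 1e-3),
                    pi_b = runif(n, 1e-4, 1e-3))
  out <- joint_outliers(scan, q = 0.05)
  # exchangeable statistics: at most ceiling(q n) windows can clear one tail
  expect_lte(sum(out$direction == "VO"), 5)
  expect_lte(sum(out$direction == "CO"), 5)
  # Z column is standardized over eligible windows
  expect_equal(mean(out$zfst[out$eligible]), 0, tolerance = 1e-9)
  expect_equal(sd(out$zfst[out$eligible]), 1, tolerance = 1e-9)
  # a window with extreme Fst but median ratio is not flagged
  scan2 <- make_scan(fst = c(5, runif(n)), pi_a = rep(5e-4, n + 1),
                     pi_b = rep(5e-4, n + 1))
  scan2$pi_a[-1] <- runif(n, 1e-4, 1e-3)  # spread the others
  out2 <- joint_outliers(scan2, q = 0.05)
  expect_equal(out2$direction[1], "none")
  expect_error(joint_outliers(make_scan(runif(10), runif(10), runif(10))),
               "eligible")
})

test_that("engineered outlier windows are flagged in the right direction", {
  set.seed(7)
  n <- 200
  fst <- rnorm(n, 0.2, 0.02)
  pi_a <- rep(5e-4, n) * exp(rnorm(n, 0, 0.05))
  pi_b <- rep(5e-4, n) * exp(rnorm(n, 0, 0.05))
  # window 10: VO-selected (high fst, depressed pi_b); window 50: CO-selected
  fst[c(10, 50)] <- 0.6
  pi_b[10] <- 5e-5
  pi_a[50] <- 5e-5
  out <- joint_outliers(make_scan(fst, pi_a, pi_b), q = 0.05)
  expect_equal(out$direction[10], "VO")
  expect_equal(out$direction[50], "CO")
})

test_that("merge_regions unions abutting same-direction windows only", {
  w <- data.frame(chrom = "chr1",
                  start = c(0, 10000, 30000, 40000),
                  end = c(20000, 30000, 50000, 60000),
                  direction = c("VO", "VO", "VO", "CO"),
                  zfst = c(2, 3, 2.5, 4))
  r <- merge_regions(w)
  expect_equal(nrow(r), 2)
  vo <- r[r$direction == "VO", ]
  expect_equal(c(vo$start, vo$end), c(0, 50000))
  expect_equal(vo$n_windows, 3L)
  expect_equal(c(vo$z_min, vo$z_max), c(2, 3))

  # disjoint windows stay separate
  w2 <- data.frame(chrom = "chr1", start = c(0, 30000), end = c(20000, 50000),
                   direction = "VO", zfst = 1)
  expect_equal(nrow(merge_regions(w2)), 2)

  # overlapping but opposite directions never merge
  w3 <- data.frame(chrom = "chr1", start = c(0, 10000), end = c(20000, 30000),
                   direction = c("VO", "CO"), zfst = 1)
  expect_equal(nrow(merge_regions(w3)), 2)
})

test_that("merge_regions is idempotent and order-invariant", {
  set.seed(9)
  w <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                  start = sample(seq(0, 2e5, 1e4), 30, TRUE))
  w$end <- w$start + 20000
  w$direction <- sample(c("VO", "CO"), 30, TRUE)
  w$zfst <- rnorm(30)
  r1 <- merge_regions(w)
  r2 <- merge_regions(w[sample(nrow(w)), ])
  expect_equal(r1, r2)
  again <- merge_regions(transform(r1, zfst = z_min))
  expect_equal(again[c("chrom", "start", "end", "direction")],
               r1[c("chrom", "start", "end", "direction")])
})

test_that("genes_in_regions uses >= 1 bp overlap of the gene span", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(tmp, L = 100000)  # genes at 1-3000, 10001-13000, ...
  gm <- read_gff3(tmp)
  regions <- data.frame(chrom = "chr1", start = 0, end = 30000,
                        direction = "VO")
  hit <- genes_in_regions(regions, gm)
  expect_equal(sort(hit$gene_id), c("gene0001", "gene0002", "gene0003"))
  # half-open boundary: region ending at 30000 includes a gene starting
  # at 30001? no
  expect_false("gene0004" %in% hit$gene_id)
  r2 <- data.frame(chrom = "chr1", start = 12999, end = 13100,
                   direction = "CO")
  expect_equal(genes_in_regions(r2, gm)$gene_id, "gene0002")  # 1-bp overlap
})

test_that("diagnostic markers require strict opposite fixation", {
  g <- rbind(c(0L, 0L, 0L, 2L, 2L, 2L),   # marker (A ref, B alt)
             c(2L, 2L, 2L, 0L, 0L, 0L),   # marker (A alt, B ref)
             c(0L, 1L, 0L, 2L, 2L, 2L),   # het in A -> not strict
             c(0L, 0L, 0L, 2L, 2L, NA),   # 1/3 missing in B > 0.1
             c(0L, 0L, 0L, 0L, 0L, 2L))   # not fixed in B
  panel <- toy_panel(g, groups = rep(c("CO", "VO"), each = 3))
  mk <- diagnostic_markers(panel)
  expect_equal(mk$pos, c(100L, 200L))
  expect_equal(mk$allele_a, c("A", "G"))
  expect_equal(mk$allele_b, c("G", "A"))
  # relaxed mode admits the near-fixed site
  mk2 <- diagnostic_markers(panel, strict = FALSE, min_freq_diff = 0.8)
  expect_true(300L %in% mk2$pos)
  # missingness ceiling can be lifted explicitly
  mk3 <- diagnostic_markers(panel, max_miss = 0.5)
  expect_true(400L %in% mk3$pos)
})

test_that("an engineered fixed difference is recovered exactly from simulation", {
  params <- sim_params(seed = 19, N = 60, t = 0, m = 2000, L = 2e5,
                       n_fixed_diff = 1)
  sim <- suppressMessages(simulate_panel(params))
  mk <- diagnostic_markers(sim$panel)
  expect_equal(nrow(mk), 1)
  expect_equal(mk$pos, sim$truth$engineered_pos)
})
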