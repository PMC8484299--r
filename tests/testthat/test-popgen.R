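test_that("make_windows enumerates sliding windows with truncation", {
  w <- make_windows(c(chr1 = 100000))
  full <- w[w$end - w$start == 20000, ]
  expect_equal(nrow(full), 9)
  expect_equal(full$start, seq(0, 80000, by = 10000))
  expect_equal(w$end[nrow(w)], 100000)

  w2 <- make_windows(c(chr1 = 15000))
  expect_equal(w2$start, c(0, 10000))
  expect_equal(w2$end, c(15000, 15000))

  w3 <- make_windows(c(chr1 = 20000))
  expect_equal(nrow(w3), 2)  # [0,20k) full + truncated [10k,20k)
  expect_equal(w3$start, c(0, 10000))

  expect_error(make_windows(c(chr1 = 1e5), window_size = 5000, step = 6000))
  expect_error(make_windows(c(1e5)), "named")
})

test_that("site_pi matches pairwise enumeration", {
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(2, 4), 2 / 3)   # 4 of 6 haplotype pairs differ
  expect_equal(site_pi(1, 2), 1)
  expect_true(is.na(site_pi(0, 1)))
})

test_that("windowed_pi equals the all-pairs brute-force oracle", {
  for (seed in 1:5) {
    panel <- random_hom_panel(n_samples = sample(4:10, 1),
                              n_sites = sample(20:100, 1), seed = seed)
    w <- make_windows(c(chr1 = 50000), 20000, 10000)
    for (g in c("CO", "VO")) {
      expect_equal(windowed_pi(panel, g, w), oracle_windowed_pi(panel, g, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("windowed_pi divides by the actual span of truncated windows", {
  panel <- toy_panel(rbind(c(0L, 2L, 0L, 2L)), pos = 5000L,
                     groups = rep("CO", 4))
  w <- make_windows(c(chr1 = 10000))
  # n = 8 alleles, j = 4: site pi = 2*4*4/(8*7) = 4/7 over a 10-kb span
  expect_equal(windowed_pi(panel, "CO", w), (4 / 7) / 10000)
  expect_equal(nrow(w), 1)
})

test_that("WC Fst components match hand-computed cases", {
  fixed <- wc_fst_site(n = c(4, 4), p = c(1, 0), h = c(0, 0))
  expect_equal(unname(fixed), c(0.5, 0, 0))
  expect_equal(fixed[["a"]] / sum(fixed), 1)

  hets <- wc_fst_site(n = c(2, 2), p = c(0.5, 0.5), h = c(1, 1))
  expect_equal(unname(hets), c(0, -0.25, 0.5))
  expect_equal(hets[["a"]] / sum(hets), 0)

  expect_error(wc_fst_site(c(1, 5), c(0.5, 0.5), c(0, 0)), "diploids")
})

test_that("WC components agree with the literal 1984 transcription", {
  set.seed(21)
  for (i in 1:1000) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    # genotype counts -> (p, h) guaranteed feasible
    g1 <- as.vector(stats::rmultinom(1, n1, runif(3)))
    g2 <- as.vector(stats::rmultinom(1, n2, runif(3)))
    p1 <- (g1[2] + 2 * g1[3]) / (2 * n1); h1 <- g1[2] / n1
    p2 <- (g2[2] + 2 * g2[3]) / (2 * n2); h2 <- g2[2] / n2
    got <- wc_fst_site(c(n1, n2), c(p1, p2), c(h1, h2))
    want <- oracle_wc84(n1, p1, h1, n2, p2, h2)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("windowed Fst is ratio-of-sums and keeps negative values", {
  # one fixed-difference site alone in a window -> Fst = 1
  panel <- toy_panel(rbind(c(0L, 2L, 0L, 2L, 0L, 2L)),
                     groups = c("CO", "VO", "CO", "VO", "CO", "VO"),
                     pos = 100L)
  w <- make_windows(c(chr1 = 10000))
  expect_equal(windowed_fst(panel, w), 1)

  # all-monomorphic window -> undefined
  mono <- toy_panel(rbind(rep(0L, 6), rep(2L, 6)), pos = c(10L, 20L))
  expect_true(is.na(windowed_fst(mono, w)))
})

test_that("windowed Fst of a label-duplicated panel is non-positive", {
  # identical genotype distribution in both groups: expected Fst <= 0
  set.seed(5)
  g <- matrix(rbinom(50 * 8, 2, 0.4), 50, 8)
  panel <- toy_panel(cbind(g, g), groups = rep(c("CO", "VO"), each = 8),
                     pos = sort(sample.int(40000, 50)))
  w <- make_windows(c(chr1 = 40000))
  fst <- windowed_fst(panel, w)
  expect_true(all(fst[!is.na(fst)] <= 1e-12))
})

test_that("tajimas_d reproduces the 1989 evaluation over a parameter grid", {
  set.seed(3)
  for (n in seq(4, 60, by = 7)) {
    for (S in c(1, 2, 5, 17, 50, 100)) {
      pi_hat <- runif(1, 0, S)
      got <- tajimas_d(S, pi_hat, n)$D
      expect_equal(got, oracle_tajima_d(S, pi_hat, n), tolerance = 1e-9)
    }
  }
  # worked small case: n = 4, S = 1, pi = 2/3
  expect_equal(tajimas_d(1, 2 / 3, 4)$D, 1.633, tolerance = 1e-3)
  expect_true(is.na(tajimas_d(0, 0, 10)$D))
  expect_true(is.na(tajimas_d(3, 1, 3)$D))
  # pi constructed to equal S/a1 exactly -> D = 0
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(5, 5 / a1, 10)$D, 0)
})

test_that("tajima_windows counts segregating sites within the group", {
  # 3 sites: segregating in CO, fixed-diff (mono within groups), mono
  panel <- toy_panel(rbind(c(0L, 1L, 0L, 0L),
                           c(0L, 0L, 2L, 2L),
                           c(2L, 2L, 2L, 2L)),
                     groups = c("CO", "CO", "VO", "VO"),
                     pos = c(100L, 200L, 300L))
  w <- make_windows(c(chr1 = 10000))
  taj_co <- tajima_windows(panel, "CO", w)
  expect_equal(taj_co$S, 1L)
  expect_equal(taj_co$n, 4)
  taj_vo <- tajima_windows(panel, "VO", w)
  expect_equal(taj_vo$S, 0L)
  expect_true(is.na(taj_vo$D))
})
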