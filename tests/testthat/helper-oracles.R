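# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive, literal transcription of the
# underlying definition, kept separate from the package's vectorized code
# paths.

# all-pairs haplotype enumeration of windowed per-bp diversity; panels must
# be het-free (dosages 0/2) so the two haplotypes of a sample are known
oracle_windowed_pi <- function(panel, group, windows) {
  samp <- samples_in_group(panel, group)
  G <- panel$geno[, samp, drop = FALSE]
  stopifnot(all(G %in% c(0L, 2L)))
  H <- cbind(G / 2L, G / 2L)  # two identical haplotypes per sample
  out <- numeric(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    inw <- panel$sites$chrom == windows$chrom[w] &
      panel$sites$pos > windows$start[w] & panel$sites$pos <= windows$end[w]
    tot <- 0
    for (s in which(inw)) {
      h <- H[s, ]
      diffs <- 0; pairs <- 0
      for (i in seq_along(h)) for (j in seq_along(h)) if (i < j) {
        pairs <- pairs + 1
        if (h[i] != h[j]) diffs <- diffs + 1
      }
      tot <- tot + diffs / pairs
    }
    out[w] <- tot / (windows$end[w] - windows$start[w])
  }
  out
}

# Weir & Cockerham (1984), two populations, transcribed term by term for
# r alleles = 2 populations of diploids
oracle_wc84 <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  C2 <- ((n1 - n_bar)^2 + (n2 - n_bar)^2) / ((r - 1) * n_bar^2)  # squared CV
  n_c <- n_bar * (1 - C2 / r)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# Tajima (1989): literal stepwise evaluation of D from S, pi-hat and n
oracle_tajima_d <- function(S, pi_hat, n) {
  if (S == 0 || n < 4) return(NA_real_)
  a1 <- 0; for (i in 1:(n - 1)) a1 <- a1 + 1 / i
  a2 <- 0; for (i in 1:(n - 1)) a2 <- a2 + 1 / i^2
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# random het-free panel on one chromosome (for exact pi comparisons)
random_hom_panel <- function(n_samples, n_sites, span = 50000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n_samples))
  groups <- stats::setNames(rep(c("CO", "VO"), length.out = n_samples), samples)
  pos <- sort(sample.int(span, n_sites))
  geno <- matrix(sample(c(0L, 2L), n_sites * n_samples, replace = TRUE),
                 n_sites, n_samples)
  genotype_panel(geno, data.frame(chrom = "chr1", pos = pos,
                                  ref = "A", alt = "G", mq = 60),
                 samples, groups)
}

# small fully-specified panel from a dosage matrix (rows = sites)
toy_panel <- function(geno, pos = NULL, groups = NULL, dp = NULL,
                      mq = 60, chrom = "chr1") {
  geno <- as.matrix(geno)
  ns <- ncol(geno)
  samples <- sprintf("s%02d", seq_len(ns))
  if (is.null(groups)) groups <- rep(c("CO", "VO"), length.out = ns)
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 100L
  genotype_panel(geno, data.frame(chrom = chrom, pos = pos, ref = "A",
                                  alt = "G", mq = mq),
                 samples, stats::setNames(groups, samples), dp = dp)
}

# write a VCF text fixture; records is a character vector of body lines
write_vcf_fixture <- function(path, samples, records,
                              format = "GT:DP") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_rec <- function(pos, ref, alt, mq, genos, chrom = "chr1",
                    format = "GT:DP") {
  paste(c(chrom, pos, ".", ref, alt, ".", ".",
          if (is.na(mq)) "." else paste0("MQ=", mq), format, genos),
        collapse = "\t")
}
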