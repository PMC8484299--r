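#' Sliding windows over chromosomes
#'
#' Windows are 0-based half-open \code{[start, end)} internally. Starts run
#' at multiples of \code{step}; the last window on each chromosome is
#' truncated at the chromosome end, and windows whose start would be at or
#' beyond the end are not emitted.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp)
#' @param window_size window size in bp (default 20000)
#' @param step step in bp (default 10000); must satisfy
#'   \code{0 < step <= window_size}
#' @return data.frame with columns chrom, start, end
#' @export
make_windows <- function(chrom_lengths, window_size = 20000, step = 10000) {
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (step <= 0 || window_size <= 0 || step > window_size)
    stop("need 0 < step <= window_size")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# site -> window membership (windows overlap when step < size)
.window_hits <- function(sites, windows) {
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L, windows$end))
  s <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  h <- GenomicRanges::findOverlaps(s, w)
  data.frame(site = S4Vectors::queryHits(h), window = S4Vectors::subjectHits(h))
}

.sum_by_window <- function(values, hits, n_windows) {
  out <- numeric(n_windows)
  if (nrow(hits)) {
    agg <- rowsum(values[hits$site], group = hits$window)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Per-site nucleotide diversity
#'
#' Unbiased mean pairwise difference at one biallelic site:
#' \code{2 j (n - j) / (n (n - 1))} for \code{j} alternate alleles among
#' \code{n} called alleles. Vectorized.
#'
#' @param j alternate-allele count(s)
#' @param n called-allele count(s); sites with \code{n < 2} return \code{NA}
#' @return numeric vector of per-site diversity
#' @export
site_pi <- function(j, n) {
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

#' Windowed nucleotide diversity for one group
#'
#' Sums per-site diversity over the sites falling in each window and divides
#' by the window span in bp (truncated windows divide by their actual span),
#' the usual per-bp windowed pi convention. Windows without SNPs get 0.
#'
#' @param panel a \code{genotype_panel}
#' @param group group label
#' @param windows data.frame from \code{\link{make_windows}}
#' @return numeric vector, one theta-pi per window (per bp)
#' @export
windowed_pi <- function(panel, group, windows) {
  st <- .group_site_stats(panel, group)
  n <- 2 * st$n_called
  pi_site <- site_pi(st$j, n)
  skipped <- sum(is.na(pi_site))
  if (skipped) .ps_msg("windowed_pi: %d site(s) with <2 called alleles skipped", skipped)
  pi_site[is.na(pi_site)] <- 0
  hits <- .window_hits(panel$sites, windows)
  .sum_by_window(pi_site, hits, nrow(windows)) / (windows$end - windows$start)
}

# Weir & Cockerham (1984) two-population variance components, vectorized
# over sites. n1/n2 = called diploids, p = alt-allele frequency, h =
# observed heterozygote frequency among called diploids.
.wc_components <- function(n1, p1, h1, n2, p2, h2) {
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham Fst variance components at one site
#'
#' Computes the among-population (a), among-individual (b) and
#' within-individual (c) components of Weir & Cockerham (1984) for two
#' populations of diploids; the site estimate is \code{a / (a + b + c)}.
#'
#' @param n length-2 vector of called diploid counts per population (both
#'   must be >= 2)
#' @param p length-2 vector of alternate-allele frequencies
#' @param h length-2 vector of observed heterozygote frequencies
#' @return named numeric vector \code{c(a, b, c)}
#' @export
wc_fst_site <- function(n, p, h) {
  stopifnot(length(n) == 2, length(p) == 2, length(h) == 2)
  if (any(n < 2)) stop("wc_fst_site needs >= 2 called diploids in each population")
  comp <- .wc_components(n[1], p[1], h[1], n[2], p[2], h[2])
  c(a = comp$a, b = comp$b, c = comp$c)
}

#' Windowed Weir-Cockerham Fst between the two panel groups
#'
#' Ratio-of-sums weighting: per window,
#' \code{Fst = sum(a) / sum(a + b + c)} over the sites with >= 2 called
#' diploids in both groups. Windows whose denominator is zero (or that carry
#' no usable site) are \code{NA}. Negative estimates are reported, not
#' clamped.
#'
#' @param panel a \code{genotype_panel} with exactly two groups
#' @param windows data.frame from \code{\link{make_windows}}
#' @return numeric vector of per-window Fst (possibly NA and/or negative)
#' @export
windowed_fst <- function(panel, windows) {
  gs <- group_names(panel)
  if (length(gs) != 2) stop("windowed_fst needs exactly two groups, got: ",
                            paste(gs, collapse = ", "))
  A <- .group_site_stats(panel, gs[1])
  B <- .group_site_stats(panel, gs[2])
  ok <- A$n_called >= 2 & B$n_called >= 2
  comp <- .wc_components(A$n_called, A$j / (2 * A$n_called), A$n_het / A$n_called,
                         B$n_called, B$j / (2 * B$n_called), B$n_het / B$n_called)
  a <- ifelse(ok, comp$a, 0)
  abc <- ifelse(ok, comp$a + comp$b + comp$c, 0)
  a[!is.finite(a)] <- 0
  abc[!is.finite(abc)] <- 0
  hits <- .window_hits(panel$sites, windows)
  num <- .sum_by_window(a, hits, nrow(windows))
  den <- .sum_by_window(abc, hits, nrow(windows))
  ifelse(den > 0, num / den, NA_real_)
}

# Tajima (1989) constants for a sample of n alleles
.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-diversity estimator and
#' Watterson's estimator \code{S / a1}, using the Tajima (1989) variance
#' constants. \code{D} is undefined (NA) when \code{S = 0} or \code{n < 4}.
#'
#' @param S number of segregating sites
#' @param pi_sum sum over sites of per-site mean pairwise differences
#' @param n number of sampled alleles used for the constants
#' @return list with elements \code{S}, \code{pi_sum}, \code{n},
#'   \code{theta_w} and \code{D}
#' @export
tajimas_d <- function(S, pi_sum, n) {
  if (n < 4 || S == 0)
    return(list(S = S, pi_sum = pi_sum, n = n, theta_w = NA_real_, D = NA_real_))
  k <- .tajima_constants(n)
  theta_w <- S / k$a1
  D <- (pi_sum - theta_w) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(S = S, pi_sum = pi_sum, n = n, theta_w = theta_w, D = D)
}

#' Windowed Tajima's D for one group
#'
#' Per window, \code{S} counts the sites segregating within the group and
#' \code{pi_sum} accumulates per-site diversity over called alleles; the
#' constants use the nominal allele count \code{n = 2 * group size} (an
#' approximation justified by the 10 percent missingness ceiling of the
#' site filter).
#'
#' @param panel a \code{genotype_panel}
#' @param group group label
#' @param windows data.frame from \code{\link{make_windows}}
#' @return data.frame: chrom, start, end, S, pi_sum, n, D
#' @export
tajima_windows <- function(panel, group, windows) {
  st <- .group_site_stats(panel, group)
  n_alleles <- 2 * st$n_called
  seg <- st$j > 0 & st$j < n_alleles & n_alleles >= 2
  pi_site <- site_pi(st$j, n_alleles)
  pi_site[is.na(pi_site)] <- 0
  hits <- .window_hits(panel$sites, windows)
  S <- .sum_by_window(as.numeric(seg), hits, nrow(windows))
  P <- .sum_by_window(pi_site * seg, hits, nrow(windows))
  n_nom <- 2 * length(samples_in_group(panel, group))
  D <- vapply(seq_len(nrow(windows)),
              function(i) tajimas_d(S[i], P[i], n_nom)$D, numeric(1))
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             S = as.integer(S), pi_sum = P, n = n_nom, D = D,
             stringsAsFactors = FALSE)
}
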