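#' Genotype-based LD r-squared for one SNP pair
#'
#' Squared Pearson correlation of unphased genotype dosages over
#' pairwise-complete samples (the Rogers-Huff composite measure). Symmetric
#' in its arguments and invariant to flipping ref/alt polarity of either
#' site. Returns \code{NA} when fewer than two complete pairs remain or a
#' vector has zero variance.
#'
#' @param dosage_x,dosage_y numeric dosage vectors (0/1/2, NA allowed)
#' @return r-squared in \code{[0, 1]}, or NA
#' @export
ld_r2 <- function(dosage_x, dosage_y) {
  ok <- !is.na(dosage_x) & !is.na(dosage_y)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosage_x[ok]; y <- dosage_y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD decay curve for one group
#'
#' Computes r-squared for every intra-chromosome SNP pair separated by at
#' most \code{max_dist} bp (after applying a per-group MAF floor), bins the
#' pairs by physical distance and averages r-squared per bin. The
#' half-decay distance is the midpoint of the first bin whose mean
#' r-squared drops to half the maximum bin mean.
#'
#' @param panel a \code{genotype_panel}
#' @param group group label
#' @param max_dist maximum pair distance in bp (default 5e6, i.e. the
#'   5000-kb pairing window)
#' @param bin_width distance bin width in bp (default 10000)
#' @param min_maf per-group MAF floor for eligible sites (default 0.05)
#' @return object of class \code{ld_decay_curve}: list with \code{curve}
#'   (data.frame bin_mid, mean_r2, n_pairs) and \code{half_decay} (bp, NA
#'   when the curve never falls to half its maximum)
#' @export
ld_decay <- function(panel, group, max_dist = 5e6, bin_width = 10000,
                     min_maf = 0.05) {
  st <- .group_site_stats(panel, group)
  n_al <- 2 * st$n_called
  af <- ifelse(n_al > 0, st$j / n_al, NA_real_)
  maf <- pmin(af, 1 - af)
  keep <- which(!is.na(maf) & maf >= min_maf)
  samp <- samples_in_group(panel, group)

  n_bins <- as.integer(ceiling(max_dist / bin_width))
  sums <- numeric(n_bins)
  cnts <- numeric(n_bins)

  for (ch in unique(panel$sites$chrom[keep])) {
    idx <- keep[panel$sites$chrom[keep] == ch]
    if (length(idx) < 2) next
    pos <- panel$sites$pos[idx]
    ord <- order(pos)
    idx <- idx[ord]; pos <- pos[ord]
    X <- t(panel$geno[idx, samp, drop = FALSE])  # samples x sites
    m <- length(idx)
    bs <- 512L
    for (b0 in seq(1L, m - 1L, by = bs)) {
      b1 <- min(b0 + bs - 1L, m - 1L)
      hi <- findInterval(pos[b1] + max_dist, pos)
      part <- (b0 + 1L):hi
      R <- suppressWarnings(
        stats::cor(X[, b0:b1, drop = FALSE], X[, part, drop = FALSE],
                   use = "pairwise.complete.obs"))
      d <- outer(pos[b0:b1], pos[part], function(a, b) b - a)
      ok <- d > 0 & d <= max_dist & is.finite(R)
      if (!any(ok)) next
      bin <- ceiling(d[ok] / bin_width)
      r2 <- R[ok]^2
      agg <- rowsum(cbind(r2, 1), group = bin)
      bi <- as.integer(rownames(agg))
      sums[bi] <- sums[bi] + agg[, 1]
      cnts[bi] <- cnts[bi] + agg[, 2]
    }
  }

  used <- which(cnts > 0)
  if (!length(used)) {
    .ps_msg("ld_decay: no eligible SNP pairs for group %s", group)
    curve <- data.frame(bin_mid = numeric(0), mean_r2 = numeric(0),
                        n_pairs = numeric(0))
    return(structure(list(curve = curve, half_decay = NA_real_),
                     class = "ld_decay_curve"))
  }
  curve <- data.frame(bin_mid = (used - 0.5) * bin_width,
                      mean_r2 = sums[used] / cnts[used],
                      n_pairs = cnts[used])
  half <- max(curve$mean_r2) / 2
  below <- which(curve$mean_r2 <= half)
  structure(list(curve = curve,
                 half_decay = if (length(below)) curve$bin_mid[min(below)] else NA_real_),
            class = "ld_decay_curve")
}

#' @exportS3Method base::print
print.ld_decay_curve <- function(x, ...) {
  cat(sprintf("ld_decay_curve: %d bins, %g pairs, half-decay %s bp\n",
              nrow(x$curve), sum(x$curve$n_pairs),
              format(x$half_decay)))
  invisible(x)
}
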