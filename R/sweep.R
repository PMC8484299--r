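#' Z-transform window Fst values
#'
#' \code{Z_i = (Fst_i - mean) / sd} using the sample standard deviation over
#' the non-missing values; NA entries (undefined windows) stay NA and are
#' excluded from the moments.
#'
#' @param fst numeric vector of per-window Fst (NA allowed)
#' @return numeric vector of Z scores, same length
#' @export
zscore_fst <- function(fst) {
  v <- fst[!is.na(fst)]
  if (length(v) < 2) stop("zscore_fst needs >= 2 defined windows")
  s <- stats::sd(v)
  if (s == 0) stop("zscore_fst: zero standard deviation (degenerate scan)")
  (fst - mean(v)) / s
}

#' log2 diversity ratio of a window
#'
#' \code{log2(pi_A / pi_B)} with group A the reference (CO-like) group.
#' Windows where either diversity is zero or missing return NA (ineligible)
#' rather than +/-Inf.
#'
#' @param pi_a,pi_b per-window diversities of the reference and contrast
#'   group
#' @return numeric vector of log2 ratios
#' @export
log2_pi_ratio <- function(pi_a, pi_b) {
  ifelse(!is.na(pi_a) & !is.na(pi_b) & pi_a > 0 & pi_b > 0,
         log2(pi_a / pi_b), NA_real_)
}

#' Build the per-window scan table
#'
#' Computes, over a sliding-window tiling, the per-group diversities, the
#' ratio-of-sums Weir-Cockerham Fst and the SNP count of every window,
#' plus an eligibility flag (defined Fst, both diversities positive, at
#' least \code{min_snps} SNPs).
#'
#' @param panel a filtered two-group \code{genotype_panel}
#' @param ref_group label of the reference group A (pi-ratio numerator);
#'   defaults to the alphabetically first group
#' @param window_size,step window specification in bp (defaults 20000 and
#'   10000)
#' @param chrom_lengths optional named lengths; defaults to the maximum SNP
#'   position per chromosome
#' @param min_snps minimum SNPs for eligibility (default 10)
#' @return data.frame of class \code{scan_table}: chrom, start, end,
#'   n_snps, pi_a, pi_b, fst, eligible; attributes \code{ref_group} and
#'   \code{alt_group}
#' @export
sweep_scan_table <- function(panel, ref_group = NULL, window_size = 20000,
                             step = 10000, chrom_lengths = NULL,
                             min_snps = 10) {
  gs <- group_names(panel)
  if (length(gs) != 2) stop("sweep scan needs exactly two groups")
  if (is.null(ref_group)) ref_group <- gs[1]
  if (!ref_group %in% gs) stop("ref_group '", ref_group, "' not in panel")
  alt_group <- setdiff(gs, ref_group)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(panel$sites$pos, panel$sites$chrom, max)
  windows <- make_windows(chrom_lengths, window_size, step)
  hits <- .window_hits(panel$sites, windows)
  n_snps <- .sum_by_window(rep(1, n_sites(panel)), hits, nrow(windows))
  tab <- data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    n_snps = as.integer(n_snps),
    pi_a = windowed_pi(panel, ref_group, windows),
    pi_b = windowed_pi(panel, alt_group, windows),
    fst = windowed_fst(panel, windows),
    stringsAsFactors = FALSE)
  tab$eligible <- !is.na(tab$fst) & tab$pi_a > 0 & tab$pi_b > 0 &
    tab$n_snps >= min_snps
  attr(tab, "ref_group") <- ref_group
  attr(tab, "alt_group") <- alt_group
  class(tab) <- c("scan_table", "data.frame")
  tab
}

#' Flag joint Fst x diversity-ratio outlier windows
#'
#' Implements the joint empirical top-5 percent rule: over eligible windows,
#' Z(Fst) is computed and the log2 diversity ratio log2(pi_A/pi_B) formed;
#' a window is flagged selected in group B when both Z(Fst) and the ratio
#' reach their upper \code{1 - q} quantile, and selected in group A when
#' Z(Fst) reaches the upper quantile while the ratio falls at or below its
#' lower \code{q} quantile. Quantiles are type-7 empirical order statistics
#' over eligible windows; ties at a threshold are included.
#'
#' @param scan a \code{scan_table} from \code{\link{sweep_scan_table}}
#' @param q tail fraction (default 0.05)
#' @param min_snps re-applied eligibility floor (default 10)
#' @return the scan table with added columns \code{zfst},
#'   \code{log2_ratio} and \code{direction} (\code{"none"} or a group
#'   label)
#' @export
joint_outliers <- function(scan, q = 0.05, min_snps = 10) {
  ref <- attr(scan, "ref_group"); alt <- attr(scan, "alt_group")
  if (is.null(ref) || is.null(alt)) stop("scan lacks group attributes")
  scan$log2_ratio <- log2_pi_ratio(scan$pi_a, scan$pi_b)
  elig <- scan$eligible & scan$n_snps >= min_snps & !is.na(scan$log2_ratio)
  if (sum(elig) < 20)
    stop("joint_outliers: only ", sum(elig),
         " eligible windows; quantile thresholds are meaningless")
  scan$eligible <- elig
  scan$zfst <- NA_real_
  scan$zfst[elig] <- zscore_fst(scan$fst[elig])
  z_hi <- stats::quantile(scan$zfst[elig], 1 - q, type = 7, names = FALSE)
  r_hi <- stats::quantile(scan$log2_ratio[elig], 1 - q, type = 7, names = FALSE)
  r_lo <- stats::quantile(scan$log2_ratio[elig], q, type = 7, names = FALSE)
  dir <- rep("none", nrow(scan))
  dir[elig & scan$zfst >= z_hi & scan$log2_ratio >= r_hi] <- alt
  dir[elig & scan$zfst >= z_hi & scan$log2_ratio <= r_lo] <- ref
  scan$direction <- dir
  attr(scan, "thresholds") <- c(z_hi = z_hi, ratio_hi = r_hi, ratio_lo = r_lo)
  scan
}

#' Merge outlier windows into sweep regions
#'
#' Overlapping or abutting same-direction windows on one chromosome merge
#' into a single region (span = union); opposite directions never merge.
#' The result is independent of input row order.
#'
#' @param scan a scan table carrying a \code{direction} column (from
#'   \code{\link{joint_outliers}}), or any data.frame with chrom, start,
#'   end, direction (and optionally zfst)
#' @return data.frame: chrom, start, end, direction, n_windows, z_min,
#'   z_max
#' @export
merge_regions <- function(scan) {
  w <- scan[scan$direction != "none", , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), n_windows = integer(),
                      z_min = numeric(), z_max = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(w)) return(empty)
  if (is.null(w$zfst)) w$zfst <- NA_real_
  w <- w[order(w$chrom, w$direction, w$start, w$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(w))) {
    r <- w[i, ]
    if (!is.null(cur) && cur$chrom == r$chrom && cur$direction == r$direction &&
        r$start <= cur$end) {
      cur$end <- max(cur$end, r$end)
      cur$n_windows <- cur$n_windows + 1L
      cur$z_min <- min(cur$z_min, r$zfst, na.rm = TRUE)
      cur$z_max <- max(cur$z_max, r$zfst, na.rm = TRUE)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                        direction = r$direction, n_windows = 1L,
                        z_min = r$zfst, z_max = r$zfst,
                        stringsAsFactors = FALSE)
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genes overlapping sweep regions
#'
#' A gene is reported for a region when its gene span (not CDS only)
#' overlaps the region by at least 1 bp. Regions are 0-based half-open,
#' gene models 1-based inclusive.
#'
#' @param regions data.frame from \code{\link{merge_regions}}
#' @param models a \code{gene_models} object from \code{\link{read_gff3}}
#' @return data.frame: region_id (row index into \code{regions}), chrom,
#'   start, end, direction, gene_id
#' @export
genes_in_regions <- function(regions, models) {
  empty <- data.frame(region_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      direction = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(models$genes)) return(empty)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  gg <- GenomicRanges::GRanges(models$genes$chrom,
                               IRanges::IRanges(models$genes$start,
                                                models$genes$end))
  h <- GenomicRanges::findOverlaps(rg, gg)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  data.frame(region_id = qi,
             chrom = regions$chrom[qi], start = regions$start[qi],
             end = regions$end[qi], direction = regions$direction[qi],
             gene_id = models$genes$gene_id[si],
             stringsAsFactors = FALSE)
}

#' Group-diagnostic SNP markers
#'
#' Strict mode: a site qualifies when every called genotype in one group is
#' homozygous for one allele, every called genotype in the other group is
#' homozygous for the opposite allele, and per-group missingness is at most
#' \code{max_miss}. Relaxed mode replaces fixation by an absolute
#' allele-frequency difference of at least \code{min_freq_diff}.
#'
#' @param panel a two-group \code{genotype_panel}
#' @param max_miss per-group missing-fraction ceiling (default 0.1)
#' @param strict logical (default TRUE)
#' @param min_freq_diff relaxed-mode frequency-difference floor (default
#'   0.8)
#' @return data.frame: chrom, pos, ref, alt, allele_a, allele_b,
#'   call_rate_a, call_rate_b, freq_diff (one row per marker; groups a/b in
#'   sorted label order)
#' @export
diagnostic_markers <- function(panel, max_miss = 0.1, strict = TRUE,
                               min_freq_diff = 0.8) {
  gs <- group_names(panel)
  if (length(gs) != 2) stop("diagnostic_markers needs exactly two groups")
  sa <- samples_in_group(panel, gs[1]); sb <- samples_in_group(panel, gs[2])
  ga <- panel$geno[, sa, drop = FALSE]; gb <- panel$geno[, sb, drop = FALSE]
  ca <- rowSums(!is.na(ga)); cb <- rowSums(!is.na(gb))
  miss_ok <- (length(sa) - ca) / length(sa) <= max_miss &
    (length(sb) - cb) / length(sb) <= max_miss & ca > 0 & cb > 0
  ja <- rowSums(ga, na.rm = TRUE); jb <- rowSums(gb, na.rm = TRUE)
  if (strict) {
    a_ref <- ja == 0; a_alt <- ja == 2 * ca
    b_ref <- jb == 0; b_alt <- jb == 2 * cb
    hit <- miss_ok & ((a_ref & b_alt) | (a_alt & b_ref))
  } else {
    fa <- ja / (2 * ca); fb <- jb / (2 * cb)
    hit <- miss_ok & abs(fa - fb) >= min_freq_diff
  }
  idx <- which(hit)
  fa <- ja[idx] / (2 * ca[idx]); fb <- jb[idx] / (2 * cb[idx])
  pick <- function(f, ref, alt) ifelse(f >= 0.5, alt, ref)
  data.frame(chrom = panel$sites$chrom[idx], pos = panel$sites$pos[idx],
             ref = panel$sites$ref[idx], alt = panel$sites$alt[idx],
             allele_a = pick(fa, panel$sites$ref[idx], panel$sites$alt[idx]),
             allele_b = pick(fb, panel$sites$ref[idx], panel$sites$alt[idx]),
             call_rate_a = ca[idx] / length(sa),
             call_rate_b = cb[idx] / length(sb),
             freq_diff = abs(fa - fb),
             stringsAsFactors = FALSE)
}
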