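#' Construct a genotype panel
#'
#' The central in-memory container of the package: a biallelic diploid SNP
#' panel holding a sites-by-samples dosage matrix (counts of the alternate
#' allele, \code{0/1/2}, \code{NA} = uncalled), per-site metadata and a
#' two-group sample assignment.
#'
#' @param geno integer matrix, sites in rows and samples in columns; entries
#'   in \code{0:2} or \code{NA}.
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (single nucleotides) and optionally \code{mq}
#'   (RMS mapping quality; \code{NA} if the source VCF carries none).
#' @param samples character vector of sample IDs, one per column of
#'   \code{geno}.
#' @param groups named character vector mapping every sample to one group
#'   label (e.g. \code{c(s1 = "CO", s2 = "VO")}).
#' @param dp optional integer matrix of per-genotype read depths, same
#'   dimensions as \code{geno}.
#'
#' @return An object of class \code{genotype_panel}: a list with elements
#'   \code{geno}, \code{dp}, \code{sites}, \code{samples}, \code{groups}.
#'   Sites are stored sorted by (chrom, pos); duplicate (chrom, pos) pairs
#'   are an error.
#' @export
genotype_panel <- function(geno, sites, samples, groups, dp = NULL) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(sites)))
    stop("`sites` must have columns chrom and pos")
  if (!"mq" %in% names(sites)) sites$mq <- NA_real_
  if (!"ref" %in% names(sites)) sites$ref <- NA_character_
  if (!"alt" %in% names(sites)) sites$alt <- NA_character_
  if (nrow(sites) != nrow(geno))
    stop("nrow(sites) != nrow(geno)")
  if (length(samples) != ncol(geno))
    stop("length(samples) != ncol(geno)")
  colnames(geno) <- samples
  bad <- setdiff(samples, names(groups))
  if (length(bad))
    stop("sample(s) missing from group assignment: ", paste(bad, collapse = ", "))
  groups <- as.character(groups[samples])
  names(groups) <- samples
  if (anyNA(groups)) stop("NA group label")
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    storage.mode(dp) <- "integer"
    if (!all(dim(dp) == dim(geno))) stop("dp dimensions differ from geno")
    colnames(dp) <- samples
  }
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
  }
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate (chrom, pos) in sites")
  rownames(sites) <- NULL
  bad_g <- geno[!is.na(geno) & (geno < 0L | geno > 2L)]
  if (length(bad_g)) stop("dosages must be in 0:2 or NA")
  structure(
    list(geno = geno, dp = dp, sites = sites,
         samples = as.character(samples), groups = groups),
    class = "genotype_panel"
  )
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("genotype_panel: %d sites x %d samples (%s)\n",
              nrow(x$geno), length(x$samples),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  chroms: %s; missing genotype rate: %.3f\n",
              paste(unique(x$sites$chrom), collapse = ","),
              mean(is.na(x$geno))))
  invisible(x)
}

#' Number of sites / samples in a panel
#' @param panel a \code{genotype_panel}
#' @return integer scalar
#' @export
n_sites <- function(panel) nrow(panel$geno)

#' @rdname n_sites
#' @export
n_samples <- function(panel) length(panel$samples)

#' Group labels of a panel
#' @param panel a \code{genotype_panel}
#' @return character vector of distinct group labels, sorted
#' @export
group_names <- function(panel) sort(unique(panel$groups))

#' Sample IDs belonging to one group
#' @param panel a \code{genotype_panel}
#' @param group group label
#' @return character vector of sample IDs
#' @export
samples_in_group <- function(panel, group) {
  out <- names(panel$groups)[panel$groups == group]
  if (!length(out)) stop("no samples in group '", group, "'")
  out
}

#' Subset a panel to a set of sites
#' @param panel a \code{genotype_panel}
#' @param idx logical or integer site index
#' @return a \code{genotype_panel}
#' @export
subset_sites <- function(panel, idx) {
  genotype_panel(panel$geno[idx, , drop = FALSE],
                 panel$sites[idx, , drop = FALSE],
                 panel$samples, panel$groups,
                 dp = if (!is.null(panel$dp)) panel$dp[idx, , drop = FALSE])
}

# Per-site allele bookkeeping within one group: called diploids, alt-allele
# count and het count (the sufficient statistics of every estimator here).
.group_site_stats <- function(panel, group) {
  g <- panel$geno[, samples_in_group(panel, group), drop = FALSE]
  list(n_called = rowSums(!is.na(g)),
       j = rowSums(g, na.rm = TRUE),
       n_het = rowSums(g == 1L, na.rm = TRUE))
}

# internal logging: stderr message with a package prefix
.ps_msg <- function(fmt, ...) message(sprintf(paste0("[popsweep] ", fmt), ...))
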