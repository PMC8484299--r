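#' Read a sample-to-group assignment table
#'
#' Two-column TSV (sample, group); a header line \code{sample<TAB>group} is
#' allowed and skipped.
#'
#' @param path path to the TSV
#' @return named character vector mapping sample ID to group label
#' @export
read_group_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("group table must have two columns: sample, group")
  if (identical(tolower(as.character(tab[1, 1:2])), c("sample", "group")))
    tab <- tab[-1, , drop = FALSE]
  grp <- as.character(tab[[2]])
  names(grp) <- as.character(tab[[1]])
  if (anyDuplicated(names(grp))) stop("duplicate sample in group table")
  grp
}

#' Read a multi-sample VCF into a genotype panel
#'
#' Keeps biallelic SNP records only; indels and multiallelic records are
#' dropped and counted. Per-genotype dosages come from \code{FORMAT/GT},
#' depths from \code{FORMAT/DP} (if present), RMS mapping quality from
#' \code{INFO/MQ} (if present).
#'
#' @param path VCF 4.x file (plain or gzipped)
#' @param group_table path to a group TSV, or a named character vector
#'   sample -> group. Every VCF sample must be assigned.
#' @return a \code{genotype_panel}; attribute \code{"read_summary"} carries
#'   the record tally (input, kept, indel, multiallelic, duplicate).
#' @export
read_vcf <- function(path, group_table) {
  groups <- if (is.character(group_table) && length(group_table) == 1 &&
                is.null(names(group_table)) && file.exists(group_table))
    read_group_table(group_table) else group_table
  if (is.null(names(groups))) stop("group_table must be a file path or a named vector")

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0) stop("no records in VCF: ", path)

  nuc <- c("A", "C", "G", "T")
  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & ref %in% nuc & alt %in% nuc
  indel <- !multi & !snp
  keep <- which(snp)
  if (!length(keep)) stop("no biallelic SNP records usable in VCF: ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(gt)
  missing_s <- setdiff(vcf_samples, names(groups))
  if (length(missing_s))
    stop("VCF sample(s) absent from group table: ", paste(missing_s, collapse = ", "))

  gt <- gt[keep, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  dos <- matrix(as.integer(dos), nrow = length(keep),
                dimnames = list(NULL, vcf_samples))

  dp <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    dp <- dp[keep, , drop = FALSE]
    rownames(dp) <- NULL
  }

  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "MQ")))
  if (all(is.na(mq))) mq <- rep(NA_real_, n_in)
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = ref[keep], alt = alt[keep],
                      mq = mq[keep], stringsAsFactors = FALSE)

  dup <- duplicated(paste(sites$chrom, sites$pos))
  if (any(dup)) {
    .ps_msg("dropping %d duplicate (chrom,pos) record(s)", sum(dup))
    sites <- sites[!dup, , drop = FALSE]
    dos <- dos[!dup, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[!dup, , drop = FALSE]
  }

  panel <- genotype_panel(dos, sites, vcf_samples, groups, dp = dp)
  summ <- c(input = n_in, kept = nrow(panel$sites),
            indel = sum(indel), multiallelic = sum(multi),
            duplicate = sum(dup))
  .ps_msg("read_vcf: %d records -> %d biallelic SNPs (%d indel, %d multiallelic dropped)",
          summ["input"], summ["kept"], summ["indel"], summ["multiallelic"])
  attr(panel, "read_summary") <- summ
  panel
}

#' Write a genotype panel as VCF 4.2
#'
#' Emits GT (and DP when the panel carries depths) plus \code{INFO/MQ} when
#' mapping qualities are present.
#'
#' @param panel a \code{genotype_panel}
#' @param path output path (plain text)
#' @return \code{path}, invisibly
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=popsweep",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- matrix(gt_code[as.character(panel$geno)], nrow = nrow(panel$geno))
  g[is.na(panel$geno)] <- "./."
  has_dp <- !is.null(panel$dp)
  if (has_dp) {
    d <- matrix(as.character(panel$dp), nrow = nrow(panel$dp))
    d[is.na(panel$dp)] <- "."
    g <- matrix(paste(g, d, sep = ":"), nrow = nrow(g))
  }
  info <- ifelse(is.na(panel$sites$mq), ".",
                 sprintf("MQ=%g", panel$sites$mq))
  body <- paste(panel$sites$chrom, panel$sites$pos, ".",
                panel$sites$ref, panel$sites$alt, ".", ".", info,
                if (has_dp) "GT:DP" else "GT",
                apply(g, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Genotype-level depth filter
#'
#' Sets genotypes with read depth below \code{min_dp} or above \code{max_dp}
#' to missing; the boundaries themselves are retained (depth in
#' \code{[min_dp, max_dp]} passes). Genotypes with no recorded depth pass
#' through unchanged. The filter is applied per genotype, not per site, so a
#' bad sample at a site does not remove the site.
#'
#' @param panel a \code{genotype_panel}
#' @param min_dp,max_dp inclusive depth bounds (defaults 3 and 50)
#' @return the filtered panel
#' @export
filter_genotypes <- function(panel, min_dp = 3, max_dp = 50) {
  if (is.null(panel$dp)) {
    .ps_msg("filter_genotypes: no per-genotype depths; panel passed through")
    return(panel)
  }
  bad <- !is.na(panel$dp) & (panel$dp < min_dp | panel$dp > max_dp)
  n_masked <- sum(bad & !is.na(panel$geno))
  panel$geno[bad] <- NA_integer_
  .ps_msg("filter_genotypes: %d genotype(s) set missing by depth [%g, %g]",
          n_masked, min_dp, max_dp)
  panel
}

#' Site-level quality filter
#'
#' A site is kept iff RMS mapping quality >= \code{min_mq}, minor-allele
#' frequency over called alleles >= \code{min_maf}, and fraction of missing
#' genotypes <= \code{max_miss}. Removal is attributed to the first failing
#' rule in the order mq, maf, miss so tallies are deterministic. Sites with
#' no recorded MQ pass the MQ rule; sites with zero called genotypes fail
#' the MAF rule (their frequency is undefined).
#'
#' @param panel a \code{genotype_panel} (normally after
#'   \code{\link{filter_genotypes}})
#' @param min_mq minimum RMS mapping quality (default 20)
#' @param min_maf minimum minor-allele frequency (default 0.05)
#' @param max_miss maximum missing-genotype fraction (default 0.1)
#' @return the filtered panel; attribute \code{"filter_tally"} is a
#'   data.frame with the per-rule removal counts.
#' @export
filter_sites <- function(panel, min_mq = 20, min_maf = 0.05, max_miss = 0.1) {
  ns <- n_samples(panel)
  called <- rowSums(!is.na(panel$geno))
  miss_frac <- (ns - called) / ns
  af <- ifelse(called > 0, rowSums(panel$geno, na.rm = TRUE) / (2 * called), NA_real_)
  maf <- pmin(af, 1 - af)
  mq <- panel$sites$mq

  fail_mq <- !is.na(mq) & mq < min_mq
  fail_maf <- !fail_mq & (is.na(maf) | maf < min_maf)
  fail_miss <- !fail_mq & !fail_maf & miss_frac > max_miss
  keep <- !(fail_mq | fail_maf | fail_miss)

  tally <- data.frame(rule = c("mq", "maf", "miss"),
                      removed = c(sum(fail_mq), sum(fail_maf), sum(fail_miss)),
                      stringsAsFactors = FALSE)
  out <- subset_sites(panel, keep)
  attr(out, "filter_tally") <- tally
  attr(out, "filter_summary") <- c(input = n_sites(panel), kept = sum(keep))
  .ps_msg("filter_sites: %d -> %d sites (mq %d, maf %d, miss %d removed)",
          n_sites(panel), sum(keep), tally$removed[1], tally$removed[2],
          tally$removed[3])
  if (!sum(keep)) .ps_msg("filter_sites: no sites survive")
  out
}

#' Read gene models from GFF3
#'
#' Loads \code{gene} features and their exon/CDS/UTR children (linked
#' through \code{mRNA} parents where present). Coordinates stay 1-based
#' inclusive as in GFF3.
#'
#' @param path GFF3 file
#' @return object of class \code{gene_models}: list with \code{genes}
#'   (gene_id, chrom, start, end, strand) and \code{features}
#'   (gene_id, type, start, end)
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  for (i in body) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed GFF3 line ", i, ": fewer than 8 fields")
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    if (e < s) stop("malformed GFF3 line ", i, ": end < start")
  }
  g <- as.data.frame(rtracklayer::readGFF(path))
  idcol <- function(x) if (is.null(x)) rep(NA_character_, nrow(g)) else as.character(x)
  g$ID <- idcol(g$ID)
  parent <- if (is.null(g$Parent)) rep(NA_character_, nrow(g)) else
    vapply(g$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")

  is_gene <- g$type == "gene"
  if (!any(is_gene)) stop("no gene features in GFF3: ", path)
  genes <- data.frame(gene_id = g$ID[is_gene],
                      chrom = as.character(g$seqid[is_gene]),
                      start = g$start[is_gene], end = g$end[is_gene],
                      strand = as.character(g$strand[is_gene]),
                      stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute in ", path)

  # resolve each feature to its owning gene, hopping through mRNA parents
  owner <- stats::setNames(rep(NA_character_, nrow(g)), g$ID)
  to_gene <- stats::setNames(genes$gene_id, genes$gene_id)
  resolve <- function(pid) {
    seen <- character()
    while (!is.na(pid) && !pid %in% names(to_gene)) {
      if (pid %in% seen) return(NA_character_)
      seen <- c(seen, pid)
      k <- match(pid, g$ID)
      if (is.na(k)) return(NA_character_)
      pid <- parent[k]
    }
    if (is.na(pid)) NA_character_ else to_gene[[pid]]
  }
  child_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  is_child <- g$type %in% child_types
  feats <- data.frame(gene_id = vapply(parent[is_child], resolve, ""),
                      type = as.character(g$type[is_child]),
                      start = g$start[is_child], end = g$end[is_child],
                      stringsAsFactors = FALSE)
  feats <- feats[!is.na(feats$gene_id), , drop = FALSE]
  if (nrow(feats)) {
    m <- match(feats$gene_id, genes$gene_id)
    if (any(feats$start < genes$start[m] | feats$end > genes$end[m]))
      stop("child feature outside its gene span in ", path)
  }
  rownames(genes) <- rownames(feats) <- NULL
  structure(list(genes = genes, features = feats), class = "gene_models")
}

#' @exportS3Method base::print
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d child features on %s\n",
              nrow(x$genes), nrow(x$features),
              paste(unique(x$genes$chrom), collapse = ",")))
  invisible(x)
}
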