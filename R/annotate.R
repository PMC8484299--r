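#' Annotate SNPs by genomic region
#'
#' Assigns every panel SNP one category by precedence
#' \code{exonic > splicing > UTR5 > UTR3 > intronic > upstream > downstream
#' > intergenic}. "Exonic" means coding exon (CDS) for genes that carry CDS
#' children, exon otherwise, and the whole gene span for genes without any
#' child features. "Splicing" covers the first \code{splice} bp on the
#' intronic side of every exon/intron boundary. Upstream/downstream extend
#' \code{upstream} bp from the gene span, strand-aware.
#'
#' @param panel a \code{genotype_panel}
#' @param models a \code{gene_models} object
#' @param upstream flank size in bp (default 1000)
#' @param splice splice-region size in bp (default 2)
#' @return object of class \code{snp_annotation}: list with \code{sites}
#'   (chrom, pos, category) and \code{tally} (category, n, fraction);
#'   categories are exhaustive and mutually exclusive, so the tally sums to
#'   the SNP count.
#' @export
annotate_snps <- function(panel, models, upstream = 1000, splice = 2) {
  genes <- models$genes
  feats <- models$features
  gr <- function(chrom, start, end) {
    if (!length(start))
      return(GenomicRanges::GRanges())
    keep <- end >= start
    GenomicRanges::GRanges(chrom[keep], IRanges::IRanges(start[keep], end[keep]))
  }

  has_cds <- genes$gene_id %in% feats$gene_id[feats$type == "CDS"]
  has_exon <- genes$gene_id %in% feats$gene_id[feats$type == "exon"]

  cds <- feats[feats$type == "CDS", , drop = FALSE]
  exo <- feats[feats$type == "exon", , drop = FALSE]
  chrom_of <- genes$chrom[match(feats$gene_id, genes$gene_id)]
  cds_gr <- gr(chrom_of[feats$type == "CDS"], cds$start, cds$end)
  bare <- genes[!has_cds & !has_exon, , drop = FALSE]
  exonic_gr <- c(cds_gr,
                 gr(chrom_of[feats$type == "exon"], exo$start, exo$end)[
                   !(exo$gene_id %in% genes$gene_id[has_cds])],
                 gr(bare$chrom, bare$start, bare$end))

  utr5 <- feats[feats$type == "five_prime_UTR", , drop = FALSE]
  utr3 <- feats[feats$type == "three_prime_UTR", , drop = FALSE]
  utr5_gr <- gr(chrom_of[feats$type == "five_prime_UTR"], utr5$start, utr5$end)
  utr3_gr <- gr(chrom_of[feats$type == "three_prime_UTR"], utr3$start, utr3$end)

  # introns = gene span minus exons, per gene with exon children
  intron_list <- list()
  for (k in which(has_exon)) {
    gid <- genes$gene_id[k]
    ex <- exo[exo$gene_id == gid, , drop = FALSE]
    exr <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    ir <- IRanges::gaps(exr, start = genes$start[k], end = genes$end[k])
    if (length(ir))
      intron_list[[gid]] <- GenomicRanges::GRanges(genes$chrom[k], ir)
  }
  intron_gr <- if (length(intron_list))
    do.call(c, unname(intron_list)) else GenomicRanges::GRanges()

  splice_gr <- GenomicRanges::GRanges()
  if (length(intron_gr) && splice > 0) {
    s <- GenomicRanges::start(intron_gr); e <- GenomicRanges::end(intron_gr)
    w <- pmin(splice, e - s + 1)
    splice_gr <- c(gr(as.character(GenomicRanges::seqnames(intron_gr)), s, s + w - 1),
                   gr(as.character(GenomicRanges::seqnames(intron_gr)), e - w + 1, e))
  }

  gene_gr <- gr(genes$chrom, genes$start, genes$end)
  plus <- genes$strand != "-"
  up_gr <- c(gr(genes$chrom[plus], genes$start[plus] - upstream,
                genes$start[plus] - 1),
             gr(genes$chrom[!plus], genes$end[!plus] + 1,
                genes$end[!plus] + upstream))
  dn_gr <- c(gr(genes$chrom[plus], genes$end[plus] + 1,
                genes$end[plus] + upstream),
             gr(genes$chrom[!plus], genes$start[!plus] - upstream,
                genes$start[!plus] - 1))

  snp_gr <- GenomicRanges::GRanges(panel$sites$chrom,
                                   IRanges::IRanges(panel$sites$pos,
                                                    panel$sites$pos))
  hit <- function(target) {
    if (!length(target)) return(logical(length(snp_gr)))
    GenomicRanges::countOverlaps(snp_gr, target) > 0
  }
  levels <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
              "upstream", "downstream", "intergenic")
  cat <- rep("intergenic", length(snp_gr))
  # ascending precedence; later assignments overwrite earlier ones
  cat[hit(dn_gr)] <- "downstream"
  cat[hit(up_gr)] <- "upstream"
  cat[hit(gene_gr)] <- "intronic"
  cat[hit(utr3_gr)] <- "UTR3"
  cat[hit(utr5_gr)] <- "UTR5"
  cat[hit(splice_gr)] <- "splicing"
  cat[hit(exonic_gr)] <- "exonic"

  tab <- table(factor(cat, levels = levels))
  tally <- data.frame(category = levels, n = as.integer(tab),
                      fraction = as.numeric(tab) / length(cat),
                      stringsAsFactors = FALSE)
  structure(list(sites = data.frame(chrom = panel$sites$chrom,
                                    pos = panel$sites$pos,
                                    category = cat,
                                    stringsAsFactors = FALSE),
                 tally = tally),
            class = "snp_annotation")
}

#' @exportS3Method base::print
print.snp_annotation <- function(x, ...) {
  cat("snp_annotation of", nrow(x$sites), "SNPs\n")
  print(x$tally, row.names = FALSE)
  invisible(x)
}
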