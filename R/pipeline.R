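#' Build a pipeline run configuration
#'
#' Aggregates every tunable of the pipeline with its default: the genotype
#' and site filters (depth 3/50, MQ 20, MAF 0.05, missingness 0.1), the
#' 20-kb/10-kb window specification, the joint top-5 percent scan rule with
#' its 10-SNP eligibility floor, the 5000-kb LD pairing window, PCA k = 3,
#' and either input paths (VCF, group table, GFF3) or simulation
#' parameters.
#'
#' @param out_dir output directory (created if absent)
#' @param seed RNG seed; mandatory whenever the simulate stage runs
#' @param vcf,groups,gff3 input paths (ignored when \code{simulate = TRUE})
#' @param simulate run the forward simulator to produce the inputs
#' @param sim extra arguments passed to \code{\link{sim_params}}
#' @param min_dp,max_dp,min_mq,min_maf,max_miss filter thresholds
#' @param window_size,step window specification (bp)
#' @param ref_group reference (A) group label for the pi-ratio; default
#'   alphabetically first
#' @param q,min_snps joint-outlier tail fraction and SNP floor
#' @param ld_max_dist,ld_bin_width LD decay settings (bp)
#' @param pca_k number of principal components
#' @param stages character vector of stages to run, a subset of
#'   \code{c("simulate","filter","stats","ldscan","sweep","structure",
#'   "annotate","markers")}, or \code{"all"}
#' @return object of class \code{run_config}
#' @export
run_config <- function(out_dir, seed = NULL, vcf = NULL, groups = NULL,
                       gff3 = NULL, simulate = is.null(vcf), sim = list(),
                       min_dp = 3, max_dp = 50, min_mq = 20, min_maf = 0.05,
                       max_miss = 0.1, window_size = 20000, step = 10000,
                       ref_group = NULL, q = 0.05, min_snps = 10,
                       ld_max_dist = 5e6, ld_bin_width = 10000, pca_k = 3,
                       stages = "all") {
  cfg <- list(out_dir = out_dir, seed = seed, vcf = vcf, groups = groups,
              gff3 = gff3, simulate = simulate, sim = sim,
              min_dp = min_dp, max_dp = max_dp, min_mq = min_mq,
              min_maf = min_maf, max_miss = max_miss,
              window_size = window_size, step = step,
              ref_group = ref_group, q = q, min_snps = min_snps,
              ld_max_dist = ld_max_dist, ld_bin_width = ld_bin_width,
              pca_k = pca_k, stages = stages)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

.all_stages <- c("simulate", "filter", "stats", "ldscan", "sweep",
                 "structure", "annotate", "markers")

#' Validate a run configuration
#' @param cfg a \code{run_config}
#' @return \code{cfg}, invisibly; errors on any invalid setting
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config: out_dir is required")
  if (cfg$step > cfg$window_size || cfg$step <= 0)
    stop("config: need 0 < step <= window_size")
  if (cfg$q <= 0 || cfg$q >= 0.5) stop("config: q must be in (0, 0.5)")
  if (cfg$min_dp > cfg$max_dp) stop("config: min_dp > max_dp")
  if (cfg$min_maf < 0 || cfg$min_maf >= 0.5) stop("config: bad min_maf")
  if (cfg$max_miss < 0 || cfg$max_miss > 1) stop("config: bad max_miss")
  stages <- if (identical(cfg$stages, "all")) .all_stages else cfg$stages
  bad <- setdiff(stages, .all_stages)
  if (length(bad)) stop("config: unknown stage(s): ", paste(bad, collapse = ", "))
  if (cfg$simulate && is.null(cfg$seed))
    stop("config: seed is mandatory when the simulate stage runs")
  if (!cfg$simulate && "simulate" %in% stages && !identical(cfg$stages, "all"))
    stop("config: simulate stage requested but simulate = FALSE")
  if (!cfg$simulate && (is.null(cfg$vcf) || is.null(cfg$groups)))
    stop("config: vcf and groups inputs required when not simulating")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' A flat key set mirroring the arguments of \code{\link{run_config}};
#' unknown keys are an error. Keys under \code{sim:} are forwarded to
#' \code{\link{sim_params}}.
#'
#' @param path YAML file
#' @return a \code{run_config}
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: simulate (or load)
#' the inputs, apply genotype- and site-level filters, compute windowed
#' diversity/Fst/Tajima's D, LD decay per group, the joint sweep scan with
#' region merging and gene overlap, population structure (distances, NJ
#' tree, GRM + PCA), SNP region annotation, and diagnostic marker
#' screening. Every table named by the module interfaces is written under
#' \code{cfg$out_dir} together with a YAML manifest (config echo plus
#' record counts per stage) and a run log. Identical (config, seed) pairs
#' produce identical outputs.
#'
#' @param cfg a \code{run_config}
#' @return (invisibly) list with \code{out_dir}, \code{manifest} and the
#'   main in-memory results
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  stages <- if (identical(cfg$stages, "all")) .all_stages else cfg$stages
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  cat(sprintf("popsweep run %s\n", format(Sys.time())), file = logf)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    .ps_msg("%s", line)
  }
  counts <- list()
  res <- list(out_dir = cfg$out_dir)

  vcf <- cfg$vcf; groups <- cfg$groups; gff3 <- cfg$gff3
  truth <- NULL
  if (cfg$simulate) {
    params <- do.call(sim_params, c(list(seed = cfg$seed), cfg$sim))
    sw <- sample_and_write(params, file.path(cfg$out_dir, "sim"))
    vcf <- sw$files$vcf; groups <- sw$files$groups; gff3 <- sw$files$gff3
    truth <- sw$truth
    counts$simulated_sites <- truth$n_segregating
    log("simulate: %d segregating sites, sweep at %d (final freq A=%.3f B=%.3f)",
        truth$n_segregating, params$sweep_pos,
        truth$freq_final$A[truth$sweep_idx],
        truth$freq_final$B[truth$sweep_idx])
    if (!"simulate" %in% stages)
      log("note: simulation ran to provide inputs for later stages")
  }
  res$truth <- truth

  need_panel <- length(intersect(
    stages, c("filter", "stats", "ldscan", "sweep", "structure",
              "annotate", "markers"))) > 0
  if (!need_panel) {
    manifest <- list(config = unclass(cfg), counts = counts,
                     package_version = as.character(utils::packageVersion("popsweep")))
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
    return(invisible(res))
  }

  if (is.null(vcf)) stop("no VCF available for the requested stages")
  panel <- read_vcf(vcf, groups)
  counts$vcf_sites <- n_sites(panel)
  panel <- filter_genotypes(panel, cfg$min_dp, cfg$max_dp)
  panel <- filter_sites(panel, cfg$min_mq, cfg$min_maf, cfg$max_miss)
  tally <- attr(panel, "filter_tally")
  counts$filtered_sites <- n_sites(panel)
  if ("filter" %in% stages) {
    .write_tsv(tally, file.path(cfg$out_dir, "filter_tally.tsv"))
    write_vcf(panel, file.path(cfg$out_dir, "filtered.vcf"))
  }
  log("filter: %d -> %d sites", counts$vcf_sites, counts$filtered_sites)
  res$panel <- panel
  gs <- group_names(panel)
  ref <- if (is.null(cfg$ref_group)) gs[1] else cfg$ref_group
  alt <- setdiff(gs, ref)
  chrom_lengths <- tapply(panel$sites$pos, panel$sites$chrom, max)
  if (cfg$simulate) chrom_lengths[] <- truth$params$L

  if (any(c("stats", "sweep") %in% stages)) {
    scan <- sweep_scan_table(panel, ref_group = ref,
                             window_size = cfg$window_size, step = cfg$step,
                             chrom_lengths = chrom_lengths,
                             min_snps = cfg$min_snps)
    res$scan <- scan
    counts$windows <- nrow(scan)
  }

  if ("stats" %in% stages) {
    windows <- res$scan[c("chrom", "start", "end")]
    stats_tab <- data.frame(res$scan[c("chrom", "start", "end", "n_snps")],
                            stats::setNames(res$scan[c("pi_a", "pi_b")],
                                            paste0("pi_", c(ref, alt))),
                            fst = res$scan$fst)
    .write_tsv(stats_tab, file.path(cfg$out_dir, "window_stats.tsv"))
    taj <- rbind(cbind(group = ref, tajima_windows(panel, ref, windows)),
                 cbind(group = alt, tajima_windows(panel, alt, windows)))
    .write_tsv(taj, file.path(cfg$out_dir, "tajima_d.tsv"))
    res$tajima <- taj
    log("stats: %d windows written", nrow(stats_tab))
  }

  if ("ldscan" %in% stages) {
    res$ld <- lapply(stats::setNames(gs, gs), function(g)
      ld_decay(panel, g, max_dist = cfg$ld_max_dist,
               bin_width = cfg$ld_bin_width, min_maf = cfg$min_maf))
    for (g in gs)
      .write_tsv(res$ld[[g]]$curve,
                 file.path(cfg$out_dir, sprintf("ld_decay_%s.tsv", g)))
    counts$ld_half_decay <- lapply(res$ld, `[[`, "half_decay")
    log("ldscan: half-decay %s", paste(sprintf("%s=%s", gs,
        vapply(res$ld, function(x) format(x$half_decay), "")), collapse = " "))
  }

  if ("sweep" %in% stages) {
    scan <- joint_outliers(res$scan, q = cfg$q, min_snps = cfg$min_snps)
    res$scan <- scan
    .write_tsv(scan, file.path(cfg$out_dir, "scan_table.tsv"))
    regions <- merge_regions(scan)
    res$regions <- regions
    .write_tsv(regions, file.path(cfg$out_dir, "sweep_regions.tsv"))
    bed <- regions[c("chrom", "start", "end", "direction")]
    utils::write.table(bed, file.path(cfg$out_dir, "sweep_regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    counts$outlier_windows <- sum(scan$direction != "none")
    counts$regions <- nrow(regions)
    if (!is.null(gff3)) {
      models <- read_gff3(gff3)
      rg <- genes_in_regions(regions, models)
      res$region_genes <- rg
      .write_tsv(rg, file.path(cfg$out_dir, "region_genes.tsv"))
      counts$region_genes <- length(unique(rg$gene_id))
      res$models <- models
    }
    log("sweep: %d outlier windows -> %d regions (%s)",
        counts$outlier_windows, counts$regions,
        paste(sprintf("%s=%d", c(ref, alt),
                      c(sum(regions$direction == ref),
                        sum(regions$direction == alt))), collapse = " "))
  }

  if ("structure" %in% stages) {
    d <- pairwise_distance(panel)
    res$dist <- d
    utils::write.table(d$d, file.path(cfg$out_dir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    tr <- nj_tree(d)
    res$tree <- tr
    ape::write.tree(tr, file.path(cfg$out_dir, "nj_tree.nwk"))
    g <- grm(panel)
    res$grm <- g
    pc <- grm_pca(g, k = min(cfg$pca_k, n_samples(panel)))
    res$pca <- pc
    ev <- data.frame(sample = panel$samples, pc$vectors)
    names(ev)[-1] <- paste0("PC", seq_len(ncol(pc$vectors)))
    .write_tsv(ev, file.path(cfg$out_dir, "pca_vectors.tsv"))
    .write_tsv(data.frame(component = seq_along(pc$all_values),
                          eigenvalue = pc$all_values),
               file.path(cfg$out_dir, "pca_values.tsv"))
    log("structure: NJ tree + PCA (k=%d) written", length(pc$values))
  }

  if ("annotate" %in% stages) {
    if (is.null(gff3)) stop("annotate stage requires a GFF3 input")
    if (is.null(res$models)) res$models <- read_gff3(gff3)
    ann <- annotate_snps(panel, res$models)
    res$annotation <- ann
    .write_tsv(ann$sites, file.path(cfg$out_dir, "snp_annotation.tsv"))
    .write_tsv(ann$tally, file.path(cfg$out_dir, "snp_annotation_tally.tsv"))
    counts$annotated <- nrow(ann$sites)
    log("annotate: %d SNPs; intergenic fraction %.3f", nrow(ann$sites),
        ann$tally$fraction[ann$tally$category == "intergenic"])
  }

  if ("markers" %in% stages) {
    mk <- diagnostic_markers(panel, max_miss = cfg$max_miss)
    res$markers <- mk
    .write_tsv(mk, file.path(cfg$out_dir, "diagnostic_markers.tsv"))
    if (nrow(mk)) {
      keep <- paste(panel$sites$chrom, panel$sites$pos) %in%
        paste(mk$chrom, mk$pos)
      write_vcf(subset_sites(panel, keep),
                file.path(cfg$out_dir, "diagnostic_markers.vcf"))
    }
    counts$markers <- nrow(mk)
    log("markers: %d strict group-diagnostic site(s)", nrow(mk))
  }

  manifest <- list(config = unclass(cfg), counts = counts,
                   package_version = as.character(utils::packageVersion("popsweep")))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
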