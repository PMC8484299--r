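#' Parameters of the two-population forward simulation
#'
#' Defaults describe the study condition the scan expects: two diploid
#' populations of N = 200 split t = 200 generations ago, one 1-Mb
#' chromosome carrying m = 5000 standing biallelic SNPs, recombination at
#' 1e-8 per bp per generation, and a beneficial allele (selection
#' coefficient s = 0.2 per copy, multiplicative fitness) starting at
#' frequency 0.05 in both populations but selected only in population B
#' (the VO-like group). Sampling mirrors a 12 + 13 two-group resequencing
#' panel with ~14x mean depth.
#'
#' @param seed RNG seed (required; all downstream draws are reproducible
#'   from it)
#' @param N diploid individuals per population
#' @param t generations since the split
#' @param L chromosome length in bp
#' @param m number of standing segregating sites at initialization
#' @param r recombination rate per bp per generation
#' @param s selection coefficient per beneficial allele (fitness 1, 1+s,
#'   (1+s)^2), acting in population B only
#' @param sweep_pos position of the selected site (default: mid-chromosome)
#' @param p0_sweep initial beneficial-allele frequency in both populations
#' @param n_sample named length-2 integer vector of diploids sampled per
#'   group, in (A, B) order
#' @param mean_depth Poisson mean of synthesized per-genotype read depth
#' @param group_labels labels for populations A and B
#' @param n_fixed_diff number of engineered fixed-difference marker sites
#'   injected into the sampled genotypes (default 0)
#' @param lowq_rate fraction of emitted sites turned into low-quality
#'   records (MQ or depth violations) to exercise the filters (default 0)
#' @param chrom chromosome name used in all outputs
#' @return object of class \code{sim_params}
#' @export
sim_params <- function(seed, N = 200, t = 200, L = 1e6, m = 5000, r = 1e-8,
                       s = 0.2, sweep_pos = NULL, p0_sweep = 0.05,
                       n_sample = c(12, 13), mean_depth = 14,
                       group_labels = c("CO", "VO"), n_fixed_diff = 0,
                       lowq_rate = 0, chrom = "chr1") {
  if (missing(seed)) stop("seed is required")
  if (is.null(sweep_pos)) sweep_pos <- floor(L / 2)
  p <- list(seed = as.integer(seed), N = as.integer(N), t = as.integer(t),
            L = as.integer(L), m = as.integer(m), r = r, s = s,
            sweep_pos = as.integer(sweep_pos), p0_sweep = p0_sweep,
            n_sample = as.integer(n_sample), mean_depth = mean_depth,
            group_labels = as.character(group_labels),
            n_fixed_diff = as.integer(n_fixed_diff),
            lowq_rate = lowq_rate, chrom = chrom)
  stopifnot(p$N >= 2, p$t >= 0, p$L >= 1, p$m >= 1, p$r >= 0, p$s >= -1,
            p$p0_sweep >= 0, p$p0_sweep <= 1, length(p$n_sample) == 2,
            all(p$n_sample >= 1), p$mean_depth > 0,
            length(p$group_labels) == 2, p$lowq_rate >= 0, p$lowq_rate <= 1,
            p$sweep_pos >= 1, p$sweep_pos <= p$L)
  if (p$m > p$L) stop("more sites than base pairs (m > L)")
  if (any(p$n_sample > p$N)) stop("n_sample exceeds population size N")
  class(p) <- "sim_params"
  p
}

#' Initialize the ancestral standing variation
#'
#' Seeds the RNG from \code{params$seed}; site positions are uniform
#' without replacement on \code{[1, L]} (the sweep position is always
#' included), ancestral frequencies follow the neutral site-frequency
#' density proportional to 1/x truncated to \code{[1/2N, 1 - 1/2N]}, and
#' the 2N haplotypes of each population are drawn site-wise Bernoulli
#' (linkage equilibrium at t = 0). The sweep-site frequency is overridden
#' to \code{p0_sweep} in both populations.
#'
#' @param params a \code{sim_params}
#' @return list: \code{pos}, \code{ref}, \code{alt}, \code{f0},
#'   \code{sweep_idx}, \code{H} (list of two 2N x m 0/1 haplotype
#'   matrices), \code{params}
#' @export
init_population <- function(params) {
  set.seed(params$seed)
  pos <- sample.int(params$L, params$m)
  if (!params$sweep_pos %in% pos) pos[sample.int(params$m, 1)] <- params$sweep_pos
  pos <- sort(pos)
  sweep_idx <- match(params$sweep_pos, pos)

  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, params$m, replace = TRUE)
  alt <- sample(nuc, params$m, replace = TRUE)
  clash <- alt == ref
  alt[clash] <- nuc[(match(ref[clash], nuc)) %% 4 + 1]

  a <- 1 / (2 * params$N); b <- 1 - a
  f0 <- a * (b / a)^stats::runif(params$m)   # density ~ 1/x on [a, b]
  f0[sweep_idx] <- params$p0_sweep

  draw <- function() {
    H <- matrix(stats::rbinom(2L * params$N * params$m, 1L,
                              rep(f0, each = 2L * params$N)),
                nrow = 2L * params$N)
    storage.mode(H) <- "integer"
    H
  }
  list(pos = pos, ref = ref, alt = alt, f0 = f0, sweep_idx = sweep_idx,
       H = list(A = draw(), B = draw()), params = params)
}

# one Wright-Fisher generation: fitness-weighted parent choice, one gamete
# per parent pick, Poisson(r*L) crossovers at uniform positions
.wf_generation <- function(H, N, sel, sweep_idx, r, L, pos) {
  w <- NULL
  if (sel != 0) {
    g <- H[seq(1L, 2L * N, by = 2L), sweep_idx] +
      H[seq(2L, 2L * N, by = 2L), sweep_idx]
    w <- (1 + sel)^g
  }
  par <- sample.int(N, 2L * N, replace = TRUE, prob = w)
  hap <- sample.int(2L, 2L * N, replace = TRUE)
  k <- stats::rpois(2L * N, r * L)
  Hn <- H[2L * par - 2L + hap, , drop = FALSE]
  for (i in which(k > 0L)) {
    bp <- sort(stats::runif(k[i], 0, L))
    src <- ((hap[i] - 1L + findInterval(pos, bp)) %% 2L) + 1L
    r1 <- H[2L * par[i] - 1L, ]
    r2 <- H[2L * par[i], ]
    Hn[i, ] <- ifelse(src == 1L, r1, r2)
  }
  Hn
}

#' Evolve the two populations forward in time
#'
#' Runs \code{t} Wright-Fisher generations per population: parents are
#' drawn with probability proportional to fitness (uniform except at the
#' sweep site of population B), each transmitted gamete recombines with a
#' Poisson(\code{r * L}) crossover count, and no new mutations arise
#' (standing variation only), so the site set is fixed throughout.
#'
#' @param pool output of \code{\link{init_population}}
#' @param params a \code{sim_params} (defaults to \code{pool$params})
#' @return list: evolved \code{H}, plus a \code{truth} list carrying the
#'   per-site final allele frequencies of both populations and the sweep
#'   bookkeeping
#' @export
evolve_population <- function(pool, params = pool$params) {
  H <- pool$H
  for (gen in seq_len(params$t)) {
    H$A <- .wf_generation(H$A, params$N, 0, pool$sweep_idx,
                          params$r, params$L, pool$pos)
    H$B <- .wf_generation(H$B, params$N, params$s, pool$sweep_idx,
                          params$r, params$L, pool$pos)
  }
  truth <- list(params = params, pos = pool$pos, ref = pool$ref,
                alt = pool$alt, f0 = pool$f0, sweep_idx = pool$sweep_idx,
                sweep_pos = params$sweep_pos,
                freq_final = list(A = colMeans(H$A), B = colMeans(H$B)))
  list(pos = pool$pos, ref = pool$ref, alt = pool$alt,
       sweep_idx = pool$sweep_idx, H = H, truth = truth, params = params)
}

# draw the sample, synthesize depths, inject engineered/low-quality sites;
# shared by simulate_panel() and sample_and_write()
.sample_panel <- function(evolved, params) {
  lab <- params$group_labels
  nA <- params$n_sample[1]; nB <- params$n_sample[2]
  idxA <- sort(sample.int(params$N, nA))
  idxB <- sort(sample.int(params$N, nB))
  gmat <- function(H, idx)
    H[2L * idx - 1L, , drop = FALSE] + H[2L * idx, , drop = FALSE]
  G <- t(rbind(gmat(evolved$H$A, idxA), gmat(evolved$H$B, idxB)))  # sites x samples
  samples <- c(sprintf("%s%02d", lab[1], seq_len(nA)),
               sprintf("%s%02d", lab[2], seq_len(nB)))
  groups <- stats::setNames(rep(lab, c(nA, nB)), samples)

  eng_idx <- integer(0)
  if (params$n_fixed_diff > 0) {
    cand <- setdiff(seq_len(params$m), evolved$sweep_idx)
    eng_idx <- sort(sample(cand, params$n_fixed_diff))
    G[eng_idx, seq_len(nA)] <- 0L
    G[eng_idx, nA + seq_len(nB)] <- 2L
  }

  ac <- rowSums(G)
  seg <- which(ac > 0L & ac < 2L * (nA + nB))
  G <- G[seg, , drop = FALSE]
  m_out <- length(seg)
  if (!m_out) stop("no segregating sites in the sample")

  dp <- matrix(stats::rpois(m_out * (nA + nB), params$mean_depth),
               nrow = m_out)
  mq <- rep(60, m_out)
  lowq <- rep(FALSE, m_out)
  if (params$lowq_rate > 0) {
    lowq <- stats::runif(m_out) < params$lowq_rate
    kind <- stats::runif(m_out) < 0.5
    bad_mq <- which(lowq & kind)
    mq[bad_mq] <- stats::runif(length(bad_mq), 0, 19.5)
    bad_dp <- which(lowq & !kind)
    for (i in bad_dp)
      dp[i, ] <- sample(c(0:2, 51:60), nA + nB, replace = TRUE)
  }

  sites <- data.frame(chrom = params$chrom, pos = evolved$pos[seg],
                      ref = evolved$ref[seg], alt = evolved$alt[seg],
                      mq = mq, stringsAsFactors = FALSE)
  panel <- genotype_panel(G, sites, samples, groups, dp = dp)

  truth <- evolved$truth
  truth$sample_idx <- list(A = idxA, B = idxB)
  truth$site_table <- data.frame(
    chrom = params$chrom, pos = evolved$pos[seg],
    ref = evolved$ref[seg], alt = evolved$alt[seg],
    freq_A = truth$freq_final$A[seg], freq_B = truth$freq_final$B[seg],
    is_sweep = seg == evolved$sweep_idx,
    engineered = seg %in% eng_idx,
    lowq = lowq, stringsAsFactors = FALSE)
  truth$n_segregating <- m_out
  truth$engineered_pos <- evolved$pos[intersect(eng_idx, seg)]
  truth$sweep_in_sample <- evolved$sweep_idx %in% seg
  list(panel = panel, truth = truth)
}

#' Simulate a two-population panel in memory
#'
#' Convenience wrapper: \code{init_population}, \code{evolve_population}
#' and sampling in one call, fully deterministic given \code{params$seed}.
#'
#' @param params a \code{sim_params}
#' @return list with \code{panel} (a \code{genotype_panel}) and
#'   \code{truth} (ground-truth bookkeeping: final frequencies, sweep
#'   site, engineered markers, sampling indices)
#' @export
simulate_panel <- function(params) {
  evolved <- evolve_population(init_population(params))
  .sample_panel(evolved, params)
}

#' Simulate and write a panel to disk
#'
#' Writes \code{<prefix>.vcf} (GT:DP, INFO/MQ), \code{<prefix>_groups.tsv},
#' \code{<prefix>_truth.tsv}, a toy GFF3 (\code{<prefix>_genes.gff3},
#' 3-kb genes tiled every 10 kb with exon/CDS/UTR children) and a YAML run
#' manifest echoing the parameters and the sweep window coordinates under
#' the default 20-kb/10-kb window specification.
#'
#' @param params a \code{sim_params}
#' @param out_prefix path prefix for every output file
#' @return (invisibly) list with \code{files}, \code{panel}, \code{truth}
#' @export
sample_and_write <- function(params, out_prefix) {
  sim <- simulate_panel(params)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  files <- list(vcf = paste0(out_prefix, ".vcf"),
                groups = paste0(out_prefix, "_groups.tsv"),
                truth = paste0(out_prefix, "_truth.tsv"),
                gff3 = paste0(out_prefix, "_genes.gff3"),
                manifest = paste0(out_prefix, "_manifest.yaml"))
  write_vcf(sim$panel, files$vcf)
  utils::write.table(data.frame(sample = sim$panel$samples,
                                group = unname(sim$panel$groups)),
                     files$groups, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$site_table, files$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_toy_gff3(files$gff3, params$L, params$chrom)

  sw <- params$sweep_pos
  wstart <- seq(0, params$L - 1, by = 10000)
  contains <- wstart < sw & sw <= pmin(wstart + 20000, params$L)
  manifest <- list(
    params = unclass(params),
    n_segregating = sim$truth$n_segregating,
    sweep_pos = sw,
    sweep_final_freq = list(A = sim$truth$freq_final$A[sim$truth$sweep_idx],
                            B = sim$truth$freq_final$B[sim$truth$sweep_idx]),
    sweep_windows = data.frame(start = wstart[contains],
                               end = pmin(wstart[contains] + 20000, params$L)),
    engineered_pos = sim$truth$engineered_pos)
  yaml::write_yaml(manifest, files$manifest)
  invisible(list(files = files, panel = sim$panel, truth = sim$truth))
}

#' Write the toy gene annotation used by the simulator
#'
#' Tiles 3-kb genes every 10 kb along the chromosome with alternating
#' strand and a fixed internal structure (UTR5 1-200, CDS 201-1200, intron
#' 1201-1800, CDS 1801-2800, UTR3 2801-3000 in gene-local coordinates,
#' mirrored on the minus strand), exercising every annotation category.
#'
#' @param path output GFF3 path
#' @param L chromosome length (bp)
#' @param chrom chromosome name
#' @param gene_len,spacing gene length and tile spacing in bp
#' @return number of genes written, invisibly
#' @export
write_toy_gff3 <- function(path, L, chrom = "chr1", gene_len = 3000,
                           spacing = 10000) {
  starts <- seq(1, L - gene_len + 1, by = spacing)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + gene_len - 1
    strand <- if (i %% 2 == 1) "+" else "-"
    gid <- sprintf("gene%04d", i)
    mid <- sprintf("mRNA%04d", i)
    seg <- function(a, b) c(s + a - 1, s + b - 1)
    if (strand == "+") {
      u5 <- seg(1, 200); c1 <- seg(201, 1200); c2 <- seg(1801, 2800)
      u3 <- seg(2801, 3000)
    } else {
      u3 <- seg(1, 200); c2 <- seg(201, 1200); c1 <- seg(1801, 2800)
      u5 <- seg(2801, 3000)
    }
    e1 <- seg(1, 1200); e2 <- seg(1801, 3000)
    line <- function(type, a, b, id, parent = NULL)
      paste(chrom, "popsweep", type, a, b, ".", strand, ".",
            if (is.null(parent)) paste0("ID=", id)
            else paste0("ID=", id, ";Parent=", parent),
            sep = "\t")
    writeLines(c(
      line("gene", s, e, gid),
      line("mRNA", s, e, mid, gid),
      line("exon", e1[1], e1[2], paste0(mid, ".e1"), mid),
      line("exon", e2[1], e2[2], paste0(mid, ".e2"), mid),
      line("five_prime_UTR", u5[1], u5[2], paste0(mid, ".u5"), mid),
      line("CDS", c1[1], c1[2], paste0(mid, ".c1"), mid),
      line("CDS", c2[1], c2[2], paste0(mid, ".c2"), mid),
      line("three_prime_UTR", u3[1], u3[2], paste0(mid, ".u3"), mid)), con)
  }
  invisible(length(starts))
}
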