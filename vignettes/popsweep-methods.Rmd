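---
title: "Methods: two-group selective-sweep scanning with popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-group selective-sweep scanning with popsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popsweep contrasts two groups of resequenced diploid individuals — the
motivating use case is two cultivar groups of a crop species, such as
late-ripening versus mid-ripening sweet orange varieties — and asks where
in the genome one group carries the footprint of directional selection.
This vignette is the package's own account of the statistical methods, the
choices made where a method is underdetermined by convention, and what the
simulation-based tests do and do not demonstrate.

## The genotype panel and hard filters

All statistics operate on a `genotype_panel`: a sites-by-samples matrix of
alternate-allele dosages (0/1/2, `NA` = uncalled) for biallelic SNPs, with
per-site RMS mapping quality (MQ), optional per-genotype read depth (DP),
and a two-group sample assignment. Indels and multiallelic records are
dropped on VCF import.

Filtering happens in two passes, mirroring common practice for mid-depth
(~14x) resequencing panels:

* **Genotype level** (`filter_genotypes`): a genotype with DP < 3 or
  DP > 50 becomes missing. The bounds are inclusive — DP = 3 and DP = 50
  survive. The filter is per genotype, not per site: one bad sample should
  degrade, not delete, a site. Whether a depth bound of this magnitude is
  per genotype or per site is ambiguous in principle; at ~14x per sample a
  3–50 range only makes sense per genotype (a 25-sample site would sum to
  ~350x), so that reading is used.
* **Site level** (`filter_sites`): keep a site iff MQ >= 20, minor-allele
  frequency >= 0.05 computed over *called* alleles (missing genotypes are
  excluded from the denominator), and missing-genotype fraction <= 0.1.
  Removal is attributed to the first failing rule in the fixed order
  mq, maf, miss, which makes removal tallies deterministic and additive:
  input sites = kept + mq + maf + miss. A site with no called genotypes has
  an undefined frequency and is attributed to the maf rule. Sites lacking
  MQ (or a panel lacking DP entirely) pass the corresponding rule
  unchanged, with a log message.

Applying the two filters twice is a no-op; the test suite asserts this
idempotence on randomized panels.

## Windowed statistics

Windows are 20 kb with a 10 kb step by default (each SNP therefore sits in
two windows), represented 0-based half-open internally; file outputs use
each format's native convention (VCF 1-based, BED 0-based half-open). The
final window of a chromosome is truncated at the chromosome end, and
truncated windows are normalized by their actual span.

**Nucleotide diversity.** Per site, with j alternate alleles among n
called alleles, pi = 2j(n−j)/(n(n−1)) — the unbiased mean pairwise
difference. Window theta-pi is the sum of per-site values divided by the
window span in bp, the convention of windowed-pi utilities in standard VCF
toolchains. Sites with fewer than two called alleles are skipped and
counted in the log.

**Fst.** Weir & Cockerham's (1984) two-population variance components a
(among populations), b (among individuals within populations), c (within
individuals) are computed per site from the called diploid counts, allele
frequencies and observed heterozygosities of the two groups; sites need at
least two called diploids per group. Windows are weighted ratio-of-sums:
Fst = sum(a) / sum(a+b+c) over the window's usable sites. Windows with a
zero denominator are undefined (`NA`), and negative estimates — expected
under no differentiation — are reported, never clamped to zero.

**Tajima's D.** D = (pi_hat − S/a1) / sqrt(e1 S + e2 S(S−1)) with the 1989
constants a1, a2, b1, b2, c1, c2, e1, e2 derived from the allele count n.
S and pi_hat are computed per window from called alleles within the group;
the constants use the nominal n = 2 x (group size). This is an
approximation under missingness, but the 10% missingness ceiling imposed
by the site filter bounds its bias; it is the same compromise standard
windowed implementations make. D is undefined for S = 0 or n < 4.

**LD decay.** r2 between two SNPs is the squared Pearson correlation of
unphased genotype dosages over pairwise-complete samples (the Rogers–Huff
composite measure; no haplotype phasing or EM). Pairs are restricted to
the same chromosome, distances up to 5,000 kb, and sites passing a
per-group MAF floor of 0.05. Pairs are binned by physical distance
(default 10 kb bins) and averaged. Because "LD decay distance" has no
single standard definition, the package defines the half-decay distance as
the midpoint of the first bin whose mean r2 falls to half the maximum bin
mean; it is `NA` when the curve never falls that far. Zero-variance sites
and pairs with fewer than two complete samples are skipped.

## The sweep scan

The scan table assigns each window its per-group diversity, its weighted
Fst, and its SNP count. A window is *eligible* when Fst is defined, both
diversities are positive, and it carries at least `min_snps` SNPs (default
10). The eligibility floor exists because log2 diversity ratios are
infinite for empty or monomorphic windows; exclusion, rather than
clamping, keeps the quantile machinery meaningful. Both knobs are
configurable.

Over eligible windows:

* Z(Fst) = (Fst − mean) / sd, using the sample standard deviation; a zero
  sd is a hard error (a degenerate scan should stop, not emit NaNs).
* the diversity ratio is log2(pi_A / pi_B), with A the reference group
  (CO-like by convention) in the numerator.
* empirical quantiles are type-7 order statistics; ties at a threshold are
  included (>= / <=).

A window is flagged **B-selected** when Z(Fst) reaches its upper 95%
quantile *and* the ratio reaches its upper 95% quantile (diversity lost in
B); **A-selected** when Z(Fst) reaches its upper 95% quantile and the
ratio falls at or below its 5% quantile. The two ratio tails are read
per-tail, not two-sided. Same-direction flagged windows that overlap or
abut merge into sweep regions; a gene is reported for a region when its
full gene span (not CDS only) overlaps it by at least 1 bp, because
selected-gene counts conventionally refer to whole genes in regions.

Under exchangeable (null) statistics at most ceiling(qN) windows can clear
one tail, so the flagged fraction per direction is structurally bounded by
q; the joint rule concentrates near q^2 for independent statistics.

## SNP region annotation and diagnostic markers

`annotate_snps` assigns one category per SNP by fixed precedence: exonic >
splicing > UTR5 > UTR3 > intronic > upstream > downstream > intergenic.
"Exonic" means CDS for genes carrying CDS children, exons for genes with
exons but no CDS, and the whole span for bare genes without child
features (single-exon gene reading). "Splicing" is the first 2 bp on the
intronic side of each exon/intron boundary; flanks extend 1 kb from the
gene span, strand-aware. Categories are exhaustive and mutually exclusive
by construction, so the tally sums to the SNP count.

`diagnostic_markers` screens for group-diagnostic SNPs. Strict mode
requires every called genotype in one group homozygous for one allele and
every called genotype of the other group homozygous for the opposite
allele, with per-group missingness <= 0.1; relaxed mode replaces fixation
with an absolute frequency difference threshold (default 0.8).

## Population structure

The pairwise distance is the allele-sharing p-distance
d(i,j) = 1 − sum(2 − |g_i − g_j|) / (2 m_ij) over pairwise-complete sites
m_ij; it is zero-diagonal, symmetric, bounded in [0,1], and a pair with no
complete sites is a hard error naming the pair. The neighbor-joining tree
(Saitou–Nei, Studier–Keppler criterion, via ape) may produce slightly
negative branch lengths on non-additive inputs; these are clamped to zero
and the clamp count logged. NJ is consistent on additive matrices — the
test suite verifies exact branch-length recovery on a 4-taxon additive
matrix.

The GRM follows the standard single-component definition
G_ij = mean_k (x_ik − 2p_k)(x_jk − 2p_k) / (2 p_k (1 − p_k)) over
polymorphic sites, with missing dosages mean-imputed to 2p_k. PCA is the
eigendecomposition of the GRM; eigenvector signs are fixed by making each
vector's largest-magnitude loading positive, so results do not depend on
the LAPACK build. No LD pruning is applied before PCA — the pipeline
operates on everything that survives the hard filters.

## The forward simulator

`simulate_panel` / `sample_and_write` produce two-population diploid
panels with known truth. The model is a discrete-generation Wright–Fisher
population per group: parents drawn with probability proportional to
fitness, one transmitted gamete per parent draw, Poisson(rL) crossovers
per gamete at uniform positions, and **standing variation only** — no new
mutations — so the site set is fixed and truth bookkeeping is exact.
Fitness is multiplicative in the beneficial-allele count (1, 1+s, (1+s)^2)
and acts only in population B, making sweep direction unambiguous for
recovery tests.

Default parameters are the study condition the scan targets: N = 200
diploids per population, t = 200 generations since the split, one 1-Mb
chromosome with m = 5,000 standing SNPs, r = 1e-8 per bp per generation,
s = 0.2, beneficial-allele start frequency 0.05 in both populations,
sampling 12 + 13 diploids with Poisson(14) synthesized depths and MQ 60 —
mirroring a two-group crop resequencing panel of 25 varieties at ~14x.
Ancestral frequencies follow the neutral SFS density proportional to 1/x
truncated to [1/(2N), 1 − 1/(2N)]; haplotypes are drawn site-wise
Bernoulli, i.e. linkage equilibrium at initialization, with LD generated
by drift and selection during the run. The emitted VCF contains the sites
segregating in the sample; optional engineered fixed-difference sites
(for marker-recovery tests) and low-quality records (MQ/DP violations at a
configurable rate, for filter tests) are recorded in the truth table.
Everything downstream is byte-reproducible from (params, seed).

**Calibration results the tests verify.** Heterozygosity decays at the
Wright–Fisher rate exp(−t/2N); a split with s = 0 at t = 0 shows mean
windowed Fst within ±0.01 of zero and per-direction joint-outlier
fractions bounded by q; a drift split (s = 0, t = 100, N = 100, 5 seeds)
gives mean windowed Fst ~0.40, bracketing 1 − exp(−t/2N) = 0.39; with
selection at defaults the beneficial allele fixes in population B
(s·t = 40 makes the logistic trajectory essentially certain) while
staying rare in A; and structure recovery (NJ bipartition, PC1 sign
partition) is exact at drift-scale differentiation.

**What the generator does not emulate — a known limitation.** Two
properties of the default parameterization interact to make the *local*
sweep signature weak, and users should understand both before
interpreting scan output on simulated data:

1. With p0 = 0.05 at linkage equilibrium, the beneficial allele starts on
   2N·p0 = 20 independent haplotype backgrounds — a *soft* sweep. The
   expected reduction of linked diversity after fixation is only the
   founder-concentration term (roughly the probability two final lineages
   trace to the same founder, ~5–15% here), not the near-total loss a
   hard sweep from a single copy produces.
2. r·L = 0.01 crossovers per meiosis means the whole 1-Mb chromosome is
   ~0.01 cM: on the sweep timescale it behaves as a single locus, so
   whatever diversity reduction occurs is chromosome-wide rather than a
   localized trough, and a scan that ranks windows *within* that same
   chromosome sees no contrast. (A hard-sweep initialization was
   considered and rejected: with this r·L it collapses population B's
   diversity chromosome-wide to ~0, which makes every window ineligible
   for the ratio and degrades the scan further.)

Consequently, passing tests demonstrate the correctness and calibration of
the estimators and of the scan machinery (null behavior, quantile logic,
direction assignment, merging, truth bookkeeping), and demonstrate
end-to-end recovery of *engineered* outlier configurations; they do not
demonstrate recovery of a de novo sweep under the default single-1-Mb
parameterization, and the parameter-recovery acceptance check documents
exactly this. On real multi-chromosome data with centimorgan-scale
recombination the same scan logic faces a very different (and easier)
localization problem; the simulation results should not be read as a
statement about its power there.

## Numerical and degenerate-input policy

* Quantiles: type-7 interpolation; ties included at thresholds.
* Undefined windows (`NA` Fst, zero diversity) propagate as `NA` and are
  excluded from moments and quantiles, never silently zeroed.
* Fewer than 20 eligible windows is a hard error for the joint scan —
  empirical 5% quantiles of fewer windows are meaningless.
* Zero scan variance (constant Fst), no polymorphic site for the GRM, a
  sample pair with no complete sites, k exceeding the sample count, and a
  VCF sample missing from the group table are all hard errors with
  specific messages, caught before partial output is written.
* The pipeline writes a YAML manifest (config echo, per-stage counts,
  package version) whose content is a pure function of (config, seed);
  two identical runs produce identical manifests and tables.

## Problem sizes used by the test suite

Module tests run on toy panels (tens of sites) and small simulations
(N = 30–100, m = 300–2,000, L = 0.05–1 Mb). The acceptance checks use the
full default generator (N = 200, m = 5,000, 1 Mb) — once for the null
calibration, once per seed for ten parameter-recovery seeds, and once for
structure recovery — sizes chosen so the whole suite completes in a few
minutes on a single core while keeping every window-level quantity at the
scan's native 20-kb/10-kb resolution.
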