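# popsweep

Two-group selective-sweep scanning from resequencing SNP panels.

`popsweep` is built for the common comparative-resequencing design in
which two groups of individuals of one species — for example ~a dozen
late-ripening (Valencia-type, "VO") and ~a dozen mid-ripening ("CO")
sweet orange varieties — are whole-genome resequenced at moderate depth
and contrasted to find genomic regions under directional selection in
either group. It covers the full post-variant-calling path:

* **variant IO & hard filters** — biallelic SNPs from a multi-sample VCF;
  per-genotype depth filter (DP in [3, 50]), site filters (MQ >= 20,
  MAF >= 0.05 over called alleles, missingness <= 0.1) with deterministic
  per-rule removal tallies;
* **windowed statistics** (20-kb windows, 10-kb step) — nucleotide
  diversity θπ per group, Weir–Cockerham Fst (ratio-of-sums over the
  variance components a, b, c), Tajima's D, and genotype-r² LD decay
  within 5,000 kb;
* **the sweep scan** — Z(Fst) = (Fst − µ)/σ over eligible windows crossed
  with the log2 diversity ratio log2(θπ,CO / θπ,VO); windows in the top
  5% of Z(Fst) *and* the top (respectively bottom) 5% of the ratio are
  flagged as VO-selected (respectively CO-selected), merged into sweep
  regions, and intersected with GFF3 gene models;
* **marker screening & annotation** — strict group-diagnostic SNPs
  (opposite homozygous fixation) and ANNOVAR-style region categories
  (exonic / splicing / UTR / intronic / up-/downstream / intergenic);
* **population structure** — allele-sharing distances, neighbor-joining
  tree (Newick), GRM and its principal components;
* **a forward Wright–Fisher simulator** of two diploid populations with
  drift, recombination and an optional selected locus, emitting
  VCF + GFF3 + ground-truth tables for calibration and recovery testing.

See `vignettes/popsweep-methods.Rmd` for the estimators, the numerical
conventions, and the simulator's assumptions and known limitations.

## Worked example

Simulate a default two-group panel (12 + 13 diploids, 1 Mb, 5,000
standing SNPs, selection s = 0.2 on the mid-chromosome locus in the VO
group), filter it, and scan:

```r
library(popsweep)

params <- sim_params(seed = 1)
sim    <- simulate_panel(params)
sim$panel
#> genotype_panel: 1821 sites x 25 samples (CO=12, VO=13)
#>   chroms: chr1; missing genotype rate: 0.000

panel <- filter_sites(filter_genotypes(sim$panel))
#> [popsweep] filter_genotypes: 5 genotype(s) set missing by depth [3, 50]
#> [popsweep] filter_sites: 1821 -> 1663 sites (mq 0, maf 158, miss 0 removed)

scan <- joint_outliers(sweep_scan_table(panel, ref_group = "CO",
                                        chrom_lengths = c(chr1 = params$L)))
scan[47:52, c("start", "end", "n_snps", "pi_a", "pi_b",
              "fst", "zfst", "log2_ratio", "direction")]
#>     start    end n_snps     pi_a     pi_b   fst   zfst log2_ratio direction
#> 47 460000 480000     27 0.000314 0.000354 0.558  0.653     -0.173      none
#> 48 470000 490000     35 0.000484 0.000379 0.493 -0.111      0.353      none
#> 49 480000 500000     48 0.000719 0.000567 0.427 -0.885      0.342      none
#> 50 490000 510000     40 0.000586 0.000450 0.470 -0.372      0.383      none
#> 51 500000 520000     29 0.000413 0.000258 0.536  0.399      0.681      none
#> 52 510000 530000     28 0.000411 0.000296 0.417 -0.995      0.474      none
```

Each row is one sliding window: its SNP count, per-group diversity per bp
(`pi_a` = CO, `pi_b` = VO), weighted Weir–Cockerham Fst, standardized
Z(Fst), the log2 CO/VO diversity ratio, and the joint-outlier direction
("none" unless the window clears the Fst tail *and* one ratio tail; the printed
rows flank the selected locus at 500 kb — after 200 generations of drift
at N = 200 the background Fst is ~0.5, and with the soft, fully-linked
sweep the defaults produce, the sweep window does not stand out from its
own chromosome; the methods vignette discusses exactly why). Downstream:

```r
merge_regions(scan)                       # outlier windows -> regions
diagnostic_markers(panel)                 # strict group-diagnostic SNPs
#> 51 markers at seed 1
tr <- nj_tree(pairwise_distance(panel))
#> [popsweep] nj_tree: clamped 2 negative branch length(s) to 0
tree_split_agreement(tr, panel$groups)
#> [1] 1        # one tree edge splits CO from VO perfectly
```

Or run everything (simulate → filter → stats → LD → sweep → structure →
annotate → markers) as one pipeline writing TSV/BED/Newick/manifest files:

```r
cfg <- run_config(out_dir = "run1", seed = 1)   # or read_run_config("cfg.yaml")
run_pipeline(cfg)
```

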