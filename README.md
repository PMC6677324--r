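# circatac

Diurnal transcriptome rhythms and ATAC-seq footprint dynamics, end to end.

Brains of diurnal insects express hundreds of genes rhythmically across the
light:dark cycle, yet bulk chromatin accessibility can stay essentially
constant — the time-of-day information lives one level down, in how deeply
transcription factors (TFs) occupy their binding sites inside open
chromatin. `circatac` implements both halves of that analysis for
time-series RNA-seq and ATAC-seq data, plus a synthetic-data generator with
planted ground truth so the whole pipeline is testable without sequencing
data.

**Rhythm arm.** Genes are called rhythmic by combining two statistics at a
fixed 24-h period — a cosinor fit
`y = m + a·cos(ωt) + b·sin(ωt)` with an F-test of `(a, b) = (0, 0)`, and a
circular umbrella rank test (Mack–Wolfe extension of Jonckheere–Terpstra,
scanned over candidate peak times and calibrated against its
distribution-free null) — via the minP rule
`p = 1 − (1 − min(p₁, p₂))²`, BH-adjusted, and gated on a peak/trough fold
change ≥ 1.3 at adjusted p ≤ 0.05. Differential rhythmicity between
wild-type and clock-mutant genotypes is a robust (Huber) Wald test of equal
cosinor coefficients on each genotype's own sampling grid.

**Chromatin arm.** Mapped fragments become Tn5 cut sites (+4/−5 bp shift);
peaks are called by Poisson sliding windows against a naked-DNA control;
differential accessibility uses a negative-binomial Wald test with
median-of-ratios normalisation (significance: FDR < 0.05 and
|log2FC| > 0.3785 = log2 1.3); peaks are annotated to
promoter-TSS/TTS/exon/intron/intergenic with length-normalised enrichment.
TF footprints (11–25 bp, 35-bp flanks) are detected inside peaks by
two-sided strand-imbalance binomial tests
(`p = max(p⁺, p⁻) ≤ 1e-10`) with an empirical FDR ≤ 0.01 from circular
rotation nulls. Footprint depth is quantified by the footprint occupancy
score `FOS = (C+1)/L + (C+1)/R` (inverse FOS: higher = deeper), compared
across genotype × time-of-day groups by Kruskal–Wallis + Dunn tests with a
compact letter display, and time-specific footprints are scanned for motifs
whose enrichment is the doubly-normalised fold change
`(p_fp/p_bg) / (p_gw/p_gwbg) > 1.5` against GC- and length-matched
backgrounds.

## Worked example

```r
library(circatac)

## rhythm arm: 500 simulated genes, 10% rhythmic, on the 8 x 2 diurnal grid
sim  <- simulate_expression(sim_expression_config(n_genes = 500,
                                                  frac_rhythmic = 0.1,
                                                  seed = 1))
expr <- filter_expressed(sim$matrix, min_rpkm = 3)
res  <- call_rhythmic(expr)
sum(res$is_rhythmic)
#> [1] 45
head(res[res$is_rhythmic, c("gene_id", "adjP", "fold_change", "phase_h")], 3)
#>   gene_id     adjP fold_change phase_h
#> 1  g00001 0.010085        4.64    12.7
#> 2  g00002 0.000857        6.41    16.3
#> 3  g00003 0.001652        4.95    10.0
```

45 of the 50 planted rhythmic genes pass both gates (adjusted combined
p ≤ 0.05 and fold change ≥ 1.3); `phase_h` is the estimated peak time in
ZT hours.

```r
## chromatin arm: toy genome with clock-driven morning-deep footprints
g    <- simulate_genome(sim_genome_config(seed = 1))
wt04 <- simulate_cut_tracks(g$truth, genotype = "WT", zt = 4,  seed = 2)
wt16 <- simulate_cut_tracks(g$truth, genotype = "WT", zt = 16, seed = 3)

fp04 <- footprint_fdr(wt04, g$peaks, seed = 4)   # p <= 1e-10, eFDR <= 0.01
fp16 <- footprint_fdr(wt16, g$peaks, seed = 5)
c(nrow(fp04), nrow(fp16))
#> [1] 48  0

ft <- fos_table(list(WT_ZT04 = wt04, WT_ZT16 = wt16), fp04)
st <- compare_fos_groups(ft)
st$letters
#> WT_ZT04 WT_ZT16
#>     "a"     "b"
round(tapply(ft$inv_fos, ft$group, mean), 2)
#> WT_ZT04 WT_ZT16
#>    2.03    0.67
```

The generator plants 50 footprints whose protection is deep at ZT04
(depth factor 0.9) and shallow at ZT16 (0.3): 48 are detected at ZT04 and
none at ZT16, and the inverse footprint occupancy score separates the two
conditions into distinct Dunn letter groups — deeper footprints in the
morning, exactly the planted dynamics.

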