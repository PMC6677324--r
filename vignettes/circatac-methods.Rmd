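---
title: "Methods: rhythm detection and ATAC-seq footprint dynamics in circatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection and ATAC-seq footprint dynamics in circatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circatac)
```

# Scope

`circatac` implements the two analysis arms of a diurnal regulatory-genomics
study of the insect brain:

1. **Rhythm arm** — calling rhythmically expressed genes from time-series
   RNA-seq (RPKM-scale values, zeitgeber-time labels) and testing whether
   those rhythms change in clock-mutant genotypes.
2. **Chromatin arm** — from stranded Tn5 cut-site tracks: accessibility
   peaks, differential accessibility, transcription-factor footprints,
   footprint-occupancy dynamics across genotype and time of day, and
   motif-class enrichment.

A synthetic-data module generates expression matrices, toy genomes, and cut
tracks with planted ground truth, so every stage is testable without
sequencing data. This vignette records the models, the tunable parameters,
and the design decisions taken where several implementations were
defensible.

# The rhythm arm

## Sampling design

The default design mirrors a diurnal brain time course: wild-type samples
every 3 h across one 24-h light:dark cycle (ZT1, ZT4, ..., ZT22), two
replicates per timepoint (16 observations per gene); mutant genotypes every
6 h (ZT4, ZT10, ZT16, ZT22), also in duplicate (8 observations). Sample
labels follow `<genotype>_ZT<hh>_<replicate>`.

## Expression filter and fold-change gate

`filter_expressed()` keeps genes whose replicate-mean expression reaches 3
RPKM at one or more timepoints. `fold_change()` is the ratio of the maximal
to minimal per-timepoint expression; the default collapses replicates to
their timepoint mean first, because replicates estimate the timepoint mean
and raw extremes grow with replication. A `mode = "raw"` option exposes the
uncollapsed alternative, since either reading of "maximal/minimal values
within a time series" is defensible. A gene is called rhythmic when its
BH-adjusted combined p-value is at most 0.05 **and** its fold change is at
least 1.3.

## Two rhythm statistics

**Cosinor (harmonic regression).** `harmonic_fit()` fits
$y = m + a\cos(\omega t) + b\sin(\omega t)$, $\omega = 2\pi/24\,h^{-1}$, by
least squares at the fixed 24-h period. Amplitude is $\sqrt{a^2+b^2}$,
phase (peak time) $\hat\varphi = \omega^{-1}\mathrm{atan2}(b, a)$ mapped to
$[0, 24)$, and the p-value is the F-test of $(a,b) = (0,0)$. With the
period fixed, a multi-method rhythm meta-analysis collapses to exactly this
fit, which is why it stands in for a fixed-period meta2d-style arm. A
constant series has zero model sum of squares and is assigned $p = 1$.

**Circular umbrella rank test.** `umbrella_test()` targets monotone
rise-then-fall alternatives without assuming sinusoidal shape. For each
candidate peak timepoint $k$ the timepoints are rotated so the antipodal
trough comes first, and the Mack–Wolfe umbrella extension of the
Jonckheere–Terpstra statistic is computed:
$A_k = \sum_{i<j\le p} U_{ij} + \sum_{p\le i<j} U_{ji}$, with $U_{ij}$ the
Mann–Whitney count (midranks for ties) and $p$ the rotated position of $k$.
Each $A_k$ gets a one-sided normal-approximation p-value with the standard
tie correction of the variance.

The scan statistic is $\min_k p_k$. Multiplying it by the number of
candidate peaks (Bonferroni, `method = "bonferroni"`) is valid but very
conservative, because adjacent umbrella orderings are strongly correlated
and the capped product piles null mass at 1. The default
`method = "calibrated"` therefore
maps the scan statistic through its **distribution-free null
distribution**: under exchangeability the statistic depends only on the
ranks, so a single Monte Carlo table (20,000 draws, fixed internal seed,
cached per sampling design) serves every gene measured on the same grid.
Because the minimum alone takes only a few dozen distinct values on the
8x2 design (rank statistics are coarsely discrete with two replicates per
group), the statistic is refined by
an order-preserving tie-breaker — the mean of the per-peak p-values, scaled
far below the spacing of distinct minima — which resolves rank
configurations sharing the same minimum and makes the calibrated p-value
effectively continuous. The tests verify both modes: the calibrated
p-values are KS-consistent with U(0,1) on simulated flat genes, and a
direct permutation of the observed values reproduces the calibrated
p-value within Monte Carlo error.

## Combination, adjustment, gates

`combine_minp()` implements the two-test Tippett/minP form
$p_c = 1 - (1 - \min(p_1, p_2))^2$, the exact distribution of the smaller
of two independent uniforms; with positively correlated statistics it is
conservative, which is the safe direction for the downstream FDR.
`bh_adjust()` wraps `stats::p.adjust(method = "BH")` (the brute-force
step-up definition lives in the test suite as its oracle).
`call_rhythmic()` runs both statistics per gene, combines, adjusts across
all tested genes, applies both gates, and attaches z-scored series plus a
phase histogram in 1-h bins. Per-gene failures become NA rows; the batch
never aborts.

# Differential rhythmicity

`robust_harmonic_fit()` fits the cosinor by Huber M-estimation
(`MASS::rlm`, tuning constant $k = 1.345$, at most 50 IRLS iterations,
least-squares fallback with a `converged = FALSE` flag). The covariance of
$(a, b)$ is the Huber sandwich
$\hat\sigma^2\,(X^\top X)^{-1}$ with
$\hat\sigma^2 = \kappa\, s^2 \frac{\sum\psi(u_i)^2/(n-3)}{(\overline{\psi'})^2}$
and the classical small-sample correction
$\kappa = 1 + p\,\mathrm{var}(\psi')/(n\,\overline{\psi'}^2)$.

`dodr_test()` is a Wald test of equal rhythm coefficients,
$H_0: (a,b)_{\mathrm{wt}} = (a,b)_{\mathrm{mut}}$, using the two robust
fits on their own sampling grids (no interpolation) and summed
covariances. The reference distribution is a deliberate small-sample
choice: $W/2$ is compared to $F(2, \min(\mathrm{df}_a, \mathrm{df}_b))$
rather than $\chi^2(2)$, because the summed covariance is dominated by the
sparser (8-observation) mutant series and the asymptotic reference is
markedly anticonservative there; the package's tests check the resulting
type-I rate by simulation at the study's own design. Among the several
tests a differential-rhythmicity package could run, this robust
Wald-on-cosinor-coefficients form is the implemented one — it is the
common, fully specifiable core of the approach.

`dodr_table()` BH-adjusts across the rhythmic gene set and emits empirical
cumulative distribution curves of $-\log_{10}$ adjusted p for the rhythmic
set and for an arrhythmic background set, plus a two-sample KS statistic
labelled descriptive: the comparison of the two curves has no canonical
test, so none is asserted.

# The chromatin arm

## Cut tracks and peaks

`shift_fragments_to_cuts()` converts mapped fragments to Tn5 cut sites
with the standard dyad correction: +4 bp on the plus strand, −5 bp on the
minus strand; cuts shifted off a scaffold are dropped and counted, and the
shift conserves total mass otherwise.

`call_peaks()` is a deliberately simple stand-in for a model-based peak
caller: 200-bp windows stepped by 50 bp, a Poisson upper-tail p-value per
window against $\lambda = \max(\text{genome-wide rate},$ depth-scaled
naked-DNA control rate in the window$)$, BH over all windows, and merging
of touching significant windows (summit = maximal-count bp; score =
$-\log_{10}$ best window q). It makes no attempt to reproduce a specific
external tool's model building. `merge_consensus()` coalesces overlapping
intervals into their envelope (idempotent, order-invariant);
`quantify_and_correlate()` normalises per-peak combined-strand counts to
10 million cuts per sample and reports Pearson correlations on
$\log_2(x+1)$.

`diff_access()` is an explicit negative-binomial Wald stand-in for a full
shrinkage-based differential package: median-of-ratios size factors, a
single method-of-moments common dispersion, and a per-peak Wald z on the
log2 fold change, BH-adjusted, with significance requiring adjP < 0.05 and
$|\mathrm{log_2FC}| > 0.3785$ (= $\log_2 1.3$ to four decimals). The
common dispersion is a **trimmed mean** of the per-peak moment estimates:
with two replicates the per-peak estimates are chi-square-noisy and their
median is biased low, which makes the test anticonservative; the trimmed
mean is nearly unbiased while ignoring strongly differential peaks.
Per-peak dispersion shrinkage is intentionally out of scope.

`annotate_peaks()` assigns each peak to exactly one category by midpoint
containment in strand-aware windows — promoter-TSS (−1 kb to +100 bp of
the TSS, in gene orientation), TTS (−100 bp to +1 kb), exon, intron — with
the precedence promoter-TSS > TTS > exon > intron > intergenic. Midpoint
containment was chosen because "within a window" is otherwise ambiguous
for partially overlapping peaks. Intergenic peaks are assigned to the
nearest TSS within 10 kb (our choice; the upstream tool's nearest-gene
rule is not documented), else left unassigned.
`feature_enrichment()` computes
$\log_2\frac{n_{\text{cat}}/n_{\text{tot}}}{\ell_{\text{cat}}/\ell_{\text{tot}}}$.

## Footprints

`wellington_scan()` implements the strand-imbalance principle of
protected-site detection: a bound factor blocks Tn5 inside its site while
cutting continues in the flanks, and the evidence is required on **both**
strands. For every candidate start and size $\ell \in [11, 25]$ inside a
peak, the plus-strand cuts inside the site ($f^+$) are tested for
depletion against the upstream 35-bp flank ($F^+$):
$p^+ = \mathrm{BinomCDF}(f^+;\, f^+ + F^+,\, \ell/(\ell+35))$, and
symmetrically $p^-$ against the downstream flank on the minus strand; the
combined p is $\max(p^+, p^-)$. Per start the best size is kept and
candidates are selected greedily by ascending p under a non-overlap
constraint. Windows with zero cuts on a strand carry no evidence and are
not candidates. This is a simplification of the original
sum-of-log-binomial scoring — same alternative, simpler score — and is
documented as such. Footprint centers use `start + floor(length/2)`
(left-biased for even lengths, deterministic).

`footprint_fdr()` gates detections ($p \le 10^{-10}$) on an empirical FDR
estimated from circular rotations of the cut counts within each peak
(each strand rotated independently), requiring the estimate to be at most
0.01. Naive independent rotations have a subtle self-contamination: with
probability roughly (footprint + flank)/peak-width per peak, the two
rotations re-align the plus pattern of one genuine footprint with the
minus pattern of another (or itself), so true signal leaks into the null.
The implementation therefore enumerates, per peak, the circular
offset-differences that would bring any pair of protected strand patterns
within `min_sep` (60 bp) of re-alignment and samples only outside them —
the self-overlap exclusion standard for circular permutation nulls,
generalised to multi-footprint peaks. The protected set comes from a
looser candidate scan ($p \le 10^{-4}$), so sub-threshold footprints are
protected too; the exclusion margin shrinks stepwise for short peaks, and
a peak admitting no valid rotation is excluded from both sides of the FDR
ratio.

`timepoint_specific()` partitions two footprint sets by ≥1-bp overlap
(each footprint is shared or specific; the partition is exhaustive). Set
algebra follows the detection sets: a "specific" footprint may well carry
sub-threshold signal at the other timepoint. `extract_profiles()` returns
combined-strand cut counts over center ±100 bp (201 columns), and
`rolling_average()` smooths with a centered window that shrinks at the
edges.

## Footprint occupancy score

`fos()` computes, per footprint and condition,
$$\mathrm{FOS} = \frac{C+1}{L} + \frac{C+1}{R},$$
where $C$, $L$, $R$ are mean combined-strand cuts/bp over the footprint
and its 35-bp left and right flanks; the inverse FOS is reported so that
**higher values mean deeper footprints**. Strands are summed before
averaging per bp (a per-strand mode of the profiles exists for
diagnostics). A zero flank mean is replaced by $1/35$ (one pseudo-cut)
and the record flagged; flagged records are excluded from group statistics
by default. `compare_fos_groups()` runs a tie-corrected Kruskal–Wallis
test on inverse FOS across genotype-by-timepoint groups, Dunn pairwise
z-tests BH-adjusted (the adjustment choice is ours; only the test family
is fixed), and a compact letter display in which groups sharing a letter
are not significantly different at 0.05.

## Motif-class enrichment

`pwm_scan()` scores log2 odds against a uniform background with a small
pseudocount; a hit reaches at least 80% of the maximal achievable score,
on either strand; `N` scores as the worst base. The bundled library
(`inst/extdata/motifs.txt`, read by `read_pwms()`) holds twelve exemplar
PWMs across the bHLH, forkhead, HTH, MADS, bZIP, homeodomain,
nuclear-receptor, zinc-finger, ETS, POU and GATA classes. It is an
illustrative library in a documented text format — the enrichment logic is
library-agnostic — and its matrices are consensus-with-degeneracy
exemplars, not measured binding models. Motif-to-class mapping is carried
in the PWM headers; a blocklist argument is the hook for removing
sequence-bias artifacts.

`select_background()` draws, per target footprint sequence, a
length-identical substring from a disjoint pool with GC within 0.05
(relaxing stepwise to at most 0.25 with warnings), excluding
lowercase-masked (repeat) sequence. `motif_fold_change()` computes the
doubly-normalised enrichment
$$\mathrm{FC} = \frac{p_{\mathrm{fp}}/p_{\mathrm{bg}}}
                    {p_{\mathrm{gw}}/p_{\mathrm{gwbg}}},$$
the motif's background-normalised frequency in target footprints relative
to genome-wide footprints, with $1/(2n)$ pseudo-proportions substituted
(and flagged) for zero denominators; enrichment means FC > 1.5, and no
p-value is attached — the fold-change rule is the criterion.
`collapse_by_class()` retains one hit per TF class per footprint (lowest
motif id, for determinism) and `class_distribution()` converts class
counts to percentages per footprint set.

# The synthetic-data generator

**Expression.** Rhythmic genes follow
$\mathrm{mesor}\cdot(1 + a\cos(2\pi(t-\varphi)/24))\cdot\varepsilon$ with
relative amplitude $a < 1$ (so expectations stay positive), lognormal
multiplicative noise $\varepsilon$ (mean 1, CV = `noise_cv`; RNA-seq
RPKM variance is approximately multiplicative), and per-genotype amplitude
attenuation (1 = intact, 0 = flat; an optional mesor shift models
constitutive-low clock-mutant expression). Defaults: 8 timepoints x 2
replicates, mesor 5–50 RPKM, amplitudes 0.3–0.8, `noise_cv = 0.2` — a
moderate within-condition variability typical of pooled-tissue bulk
RNA-seq.

**Genome and cut tracks.** Toy scaffolds carry i.i.d. nucleotides at a
target GC, non-overlapping two-exon gene models (lengths and spacing scale
down on small scaffolds so placement always succeeds), non-overlapping
peaks, and footprints planted ≥45 bp inside their peaks (so the 35-bp
flanks plus the flank-boost window stay within the peak), lengths 11–25
bp, with a consensus motif written into a configurable fraction. Cut
counts are Poisson per bp and strand (an optional negative-binomial mode
with stated dispersion exists for robustness checks): a low uniform rate
outside peaks (10% of peak depth), `depth` inside peaks, a +50% boost in
the 10 bp flanking each footprint (bound factors increase integration in
their immediate surroundings), and
$\mathrm{depth}\times(1-\mathrm{occupancy}\times d_{g,\mathrm{ZT}})$
inside footprints, where the per-(genotype, ZT) depth factor defaults to
0.9 for wild-type at ZT04 and 0.3 elsewhere — a clock-driven morning-deep
footprint that mutants lose. The default `depth = 5` cuts/bp/strand
represents deeply covered open chromatin: the strand-imbalance binomial
needs roughly $z \le -6.4$ for $p \le 10^{-10}$, which requires about 4
cuts/bp/strand for an 11–25-bp footprint — shallower libraries simply
cannot yield footprints at these detection thresholds. A naked-DNA mode
emits a uniform rate everywhere.

**Footprint sequences for enrichment.** `simulate_footprint_sequences()`
generates footprint-length sequences and plants a motif block into a
fraction of them. Real footprints are occupied binding sites, so the
genome-wide compendium must carry bound-motif blocks too: with
`motif = NULL` the generator plants decoy blocks with the same GC content
**and the same border dinucleotides** (CA…TG) as the default target
motif. Both matter: a planted 6-bp block fragments the short remaining
sequence and deflates every other motif's hit rate, and block borders
create junction matches with the flanks; using border-matched decoys makes
both effects cancel between numerator and denominator of the
doubly-normalised fold change, which is what centres unplanted motifs at
FC ≈ 1. The border-matched decoys necessarily match the degenerate E-box
(CANNTG), so the genome-wide sets behave like E-box-family-bound sites;
the strict planted E-box is still recovered as strongly enriched because
the decoys do not match it.

**What the generator does not emulate.** No read-level sequencing error or
FASTQ simulation; no sequence-dependent Tn5 insertion bias; no
overdispersion by default; no repeats, GC heterogeneity along scaffolds,
or realistic gene structure beyond two exons; expression noise is
independent across genes and timepoints. Passing tests therefore show the
statistical machinery is correct under its stated model, not that the
pipeline is robust to every artifact of real libraries.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the checked properties are statistically stable:
2,000 genes for null-calibration and recovery checks; 200/1,000
simulations for differential-rhythmicity power/null rates; a toy genome of
2 x 200 kb with 40 peaks and 50 planted footprints; 10 simulation seeds
with 200 target and 600 genome-wide footprint sequences per seed for
motif enrichment. The umbrella calibration table uses 20,000 Monte Carlo
draws per sampling design and is cached for the session. Degenerate
inputs are handled by convention rather than error where a convention is
standard: constant series (p = 1, zero amplitude), all-zero series (NA
fold change with a warning), zero flanks (pseudo-count, flagged),
all-zero count rows (NA), empty sets (empty outputs).

# Known limitations

- The umbrella test's normal approximation is coarse for designs much
  smaller than 8 timepoints x 2 replicates; the calibrated mode absorbs
  this for the p-value, but the per-peak p-values themselves remain
  approximate.
- The common-dispersion NB Wald test does not shrink per-peak dispersions
  and will be anticonservative if dispersion varies strongly across peaks.
- The footprint scanner's greedy non-overlap selection returns one of
  several near-equivalent windows at single-cut resolution; its location
  is guaranteed only up to overlap with the true protected site.
- The empirical-FDR rotation null assumes footprint-free peak sequence is
  exchangeable under rotation; structured backgrounds (e.g. strong
  sequence bias) would require a bias-aware null.
- The bundled PWM library is illustrative; class-level conclusions from it
  apply to the synthetic data, not to any organism's real TF complement.
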