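---
title: "Methods: inferring enhancer miswiring from fusion-driven cohorts"
author: "miswire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring enhancer miswiring from fusion-driven cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miswire)
```

# The problem

Fusion-positive rhabdomyosarcoma (FP-RMS) is driven by translocations that
join the 5' end of *PAX3* or *PAX7* to the 3' end of a partner gene
(*FOXO1*, *NCOA1*, *INO80D*). The oncogenic consequence is not only a
chimeric protein: the translocation moves the *PAX3* promoter into the
regulatory reach of a strong super enhancer (SE) near the partner locus,
inside a newly formed CTCF-bounded insulated neighborhood. miswire
implements the analytical machinery of that model: fusion-transcript
construction from gene models, an exon-level imbalance statistic that
infers allele-specific epigenetic states (epistates) from bulk RNA-seq,
ROSE-style SE calling and rank percentiles, CTCF convergence logic for the
derivative chromosome, and dropout analysis for a pooled CRISPR tiling
screen — all exercised against a synthetic cohort generator that records
its ground truth.

# Gene models and fusion construction

Gene models are single-transcript ordered exon chains. Internally all
coordinates are 0-based half-open; GTF input is converted on read (BED-like
tables are used natively), so exactly one convention exists inside the
package. A breakpoint is mapped to exons by transcription order: a
5' partner retains the contiguous exon prefix upstream of the breakpoint,
a 3' partner the contiguous suffix downstream. Two conventions are worth
stating:

* Breakpoints are expected to be intronic, as described for these fusions.
  An exonic breakpoint errors unless explicitly overridden, in which case
  the containing (truncated) exon counts as retained.
* A breakpoint outside the gene span is accepted with a warning and yields
  the boundary result (empty or complete retained set). This makes the
  upstream-of-promoter case — a promoterless fusion — representable; the
  fusion constructor warns rather than errors on it.

The packaged toy models place exon *k* at `[1000k, 1000k + 200)` (mirrored
for the reverse-strand PAX7 model) so that every intron hosts an
unambiguous breakpoint, and the packaged breakpoints reproduce the
clinically described architectures (PAX3 exons 1–7 to FOXO1 exons 2–3;
1–7 to INO80D 9–11; 1–6 to NCOA1 13–22 for type 1 and 1–7 to 12–22 for
type 2).

# The exonic-imbalance statistic

## Generative picture

Each sample carries two alleles of a fusion partner gene. The wild-type
allele is promoter-driven and expresses all exons; the fusion allele is
SE-driven and expresses only the retained exons. If the SE drives the
fusion allele at *r* times the wild-type activity, the expected ratio of
retained-exon to lost-exon expression is `1 + r` (and larger still when
the remaining wild-type allele is lineage-silenced). A balanced gene —
no fusion, or both alleles in the same epistate — shows no such step.

## Normalization and statistics

Counts are normalized to `log2(RPKM + pseudocount)` (pseudocount 1 by
default; the exact normalization upstream of the published Z scoring is
not stated, and RPKM is the conventional choice for within-gene exon
comparisons since it removes exon length and library depth). Two
statistics are computed:

* **Z\*** — the headline per-gene, per-sample score. Each exon is
  standardized *across samples* with robust location/scale (median and
  MAD, with a standard-deviation fallback when the MAD is zero), and Z\*
  is the sample's largest absolute standardized deviation across the
  gene's exons.
* **Δ** — the breakpoint-aware contrast: the standardized difference
  between mean expression of retained and lost exons, with a tertiary
  epistate call (`balanced` / `imbalanced_5p` / `imbalanced_3p`) at a
  configurable threshold τ (default 1.5, roughly "the two exon blocks are
  separated by more than one and a half pooled standard deviations").

A within-sample Z variant (each gene's exons standardized against each
other inside one sample, summarized by max |z|) is available as
`method = "within"`, and its vector primitives are exported
(`exon_zscores()`, `imbalance_score()`). It is not the default for a
structural reason: a within-sample standardized score is algebraically
bounded. For a gene with *n* exons of which *k* form the deviating block,
the block's |z| is exactly `sqrt((n - k) (n - 1) / (k n))` — 1.76 for the
9-exon, 2-lost-exon PAX3 case — no matter how large the biological effect
is, while the same max-|z| statistic under the null has expectation ≈ 1.7
for n = 9. The within-sample variant therefore cannot separate strong
imbalance from noise for this exon geometry, whereas the cross-sample
score grows linearly with the (log) effect. The cohort-referenced score is
also what "Z scoring" conventionally means in outlier detection; whether
the original analysis standardized per sample or across the cohort is not
derivable from the source material, so both are implemented and the
powered one is the default.

Group comparisons use Welch's unequal-variance t test (two-tailed), the
standard choice when group sizes and variances differ (61 FN vs 23
PAX3-FOXO1, etc.). No multiple-testing correction is applied by default —
these are single-gene analyses; `stats::p.adjust` composes trivially for
gene-wide scans.

# Synthetic cohort generator

The generator is first-class, tested code. Defaults are the study
composition: group sizes FN = 61, PAX3-FOXO1 = 23, PAX7-FOXO1 = 10,
PAX3-NCOA1 = 2, PAX3-INO80D = 1. Counts are negative binomial with
variance `mu + phi mu^2`:

| parameter | default | meaning |
|---|---|---|
| `r` | 10 | SE-driven / wild-type allele expression; 0 is the null |
| `phi` | 0.1 | NB dispersion, typical of tumor RNA-seq cohorts |
| `base_rate` | 0.5 /bp | ≈100 counts per 200-bp exon at unit library factor — a well-expressed TF locus; deep enough that zero-count log artifacts do not masquerade as imbalance |
| `silenced_wt` | 0.1 | remaining wild-type 5'-partner allele activity in fusion-positive samples (these alleles are essentially silent in FP-RMS) |
| `libsize_range` | 0.5–2 | log-uniform library factors |

Every simulated effect is recorded in a truth table (group, gene, allele
activities, retained exon sets), which is what makes parameter-recovery
tests possible. The generator emulates count structure only: it does not
model mappability or GC bias, copy number, isoform mixtures, or
read-level artifacts, so passing recovery tests demonstrates statistical
correctness of the pipeline, not robustness to those real-data phenomena.

The null model is `r = 0` (fusion allele off). Note that `r = 1` is *not*
a null: an equally active fusion allele still doubles retained-exon
expression.

# Enhancer ranking and super-enhancer calling

Peaks are stitched when within 12.5 kb (the conventional ROSE parameter;
the original analysis cites the SE literature without printing its
parameters), with an optional TSS exclusion list applied before
stitching. A stitched region's signal is the **sum** of its constituent
peak signals — rank-by-load, matching SE convention — not the maximum.

Ranking sorts regions by ascending signal and min–max scales both axes to
[0, 1]. The SE cutoff is the tangent point of a slope-1 line: implemented
as the argmin of (scaled signal − scaled rank), which equals "the first
point where the discrete slope exceeds 1" on a convex curve but does not
false-trigger on local jumps in noisy empirical curves. All-equal signals
yield zero SEs with a warning. Ties in signal are broken by genomic
position so ranks are deterministic. Percentiles are
`100 (N − rank + 1)/N`, and cross-sample queries
(`rank_percentile()`) match a locus to the best-overlapping region per
sample (any shared base counts; largest overlap wins), reporting absence
explicitly.

The synthetic landscape is a log-normal bulk (median 50, sdlog 0.8) with
a 4% tail component at 20× the bulk median — enough separation that tail
membership is recoverable, while keeping the called SE fraction in the
few-percent range expected of real H3K27ac landscapes.

Spike-in normalization (`rx_normalize()`) is plain arithmetic —
`count × 1e6 / spike_in_total` — and `delta_rrpm()` subtracts two tracks
over identical bins; both preserve genuine global signal loss that
per-library RPM would hide.

# Neo-TAD logic

The derivative chromosome is the 5' source segment followed by the 3'
segment on one axis. Remapping is offset arithmetic; a flipped segment
`[s, e)` at offset `o` maps position `p` to the mirror `o + (e − p)` and
reverses motif orientations, and the mapping is exactly invertible.
Orientations are axis-relative (forward = toward increasing coordinates),
not nucleotide-strand symbols; motif scanning is out of scope and
orientations are inputs.

A pair of CTCF sites is loop-permissive when convergent: the left one
forward, the right one reverse. The insulated neighborhood around an
anchor (the fusion promoter) is the **smallest-span** permissive pair
strictly containing it — the innermost loop is taken as the operative
regulatory unit — with the outermost spanning pair reported alongside as
the TAD-boundary candidate. Containment is strict: an element exactly at
a boundary coordinate is outside. When no pair spans the anchor the
result is an explicit no-neighborhood value, modeling boundary loss,
rather than an error.

The packaged toy locus encodes the canonical geometry: a forward
promoter-side motif and three distal sites of which the first and third
(in axis order; the outermost is the TAD-boundary candidate) are
reverse-oriented, so exactly two promoter-anchored permissive pairs
exist. Which functional pair dominates in vivo is not modeled.

# CRISPR tiling-screen dropout

Counts are normalized to counts-per-million per timepoint after a 0.5
pseudocount (keeping dropped-out guides finite on the log scale), and
per-sgRNA log2 fold changes are taken against the earliest sampled day
(day 2 by default; a plasmid-style reference is any other column).
Elements aggregate their guides by the **median** (mean behind a flag):
with ≥5 guides per element a single outlier guide moves the median by
less than its own corruption. Class comparisons report both Welch t and
Mann–Whitney U, since element LFC distributions need not be normal.

The generator depletes latent abundance exponentially at `delta` per day
per class — defaults: promoter 0.30, intra-TAD SE 0.15, boundary CTCF
0.08, typical enhancer and outside-TAD SE 0.01, controls 0 — and
resamples a fixed sequencing depth multinomially at each of days 2, 5, 7,
10, 13, 17, 20, 25. The library is dominated by neutral controls (760 of
1,000 guides), as in a tiling design where most elements are dispensable.
One subtlety the closed form must respect: the observable CPM-based LFC
equals the latent `−delta (t − t0)/ln 2` *plus* a renormalization term
`−log2(F)`, where `F` is the depth-weighted mean survival of the library.
Under the control-dominated default library `F ≈ 0.88`, so the day-25
promoter LFC sits ≈ 0.19 log2 units above the latent −9.96; the recovery
test asserts the full closed form.

# Pipeline and reproducibility

`run_all()` wires the four analyses behind one config, with stage-named
errors, TSV outputs and a JSON manifest (versions, seeds, parameters,
output checksums — no timestamps, so reruns are bit-identical). Stage
seeds are derived deterministically from the master seed and stay within
32-bit integer range. Determinism is asserted at file level in the test
suite.

Problem sizes used by the test suite were chosen to keep statistical
assertions well-powered while remaining desk-scale: 100 cohort
replicates for recovery and 1,000 for null calibration (the calibration
cohort simulates the focal gene only, which leaves the statistic's null
distribution unchanged), 500 random instances for the convergence oracle,
200 for the stitching oracle, 20 seeds × 1,000 enhancers for SE recall,
and 200 seeds for screen class ordering.

# Known limitations

* Gene models are single-transcript; isoform-aware quantification,
  junction evidence and haplotype phasing are out of scope — imbalance is
  inferred purely from exon-level means.
* The cohort z-score references the full cohort; in cohorts where
  fusion-positive samples are the majority, robust location/scale would
  degrade and a designated reference group should be used instead.
* SE calling consumes peak/signal tables; alignment, peak calling and
  spike-in species separation happen upstream.
* Hi-C/HiChIP contact matrices, loop-extrusion simulation and 4C read
  processing are out of scope; the neighborhood model is purely
  orientation-combinatorial.
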