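---
title: "Allele-specific copy number from SNP arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number from SNP arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascnpipe)
```

## The measurement model

A tumor specimen is a mixture of aberrant cells (fraction $p$, the
*purity* or aberrant-cell fraction) and diploid normal cells (fraction
$1-p$). If the aberrant cells carry $n_A$ copies of one parental allele
and $n_B$ of the other on a genomic segment, a SNP array reports, per
heterozygous probe,

$$\mathrm{BAF} = \frac{(1-p) + p\,n_B}{2(1-p) + p\,(n_A+n_B)}, \qquad
\mathrm{logR} = \log_2 \frac{2(1-p) + p\,(n_A+n_B)}{2(1-p) + p\,\psi},$$

where $\psi$ is the tumor ploidy — the length-weighted mean total copy
number of the aberrant cells — because array intensities are normalized
against the sample's own average DNA content. Homozygous probes emit BAF
near 0 or 1 and carry no allelic information. Because the labelling of
parental alleles is arbitrary, BAF is reflected about 0.5 into
mBAF $= \max(\mathrm{BAF}, 1-\mathrm{BAF}) \in [0.5, 1]$ on putatively
heterozygous probes (those inside $[h, 1-h]$ with exclusion band
$h = 0.05$).

Three consequences shape everything downstream: copy-number-neutral LOH
is invisible in logR but loud in mBAF; all deviations shrink toward the
balanced point as $p \to 0$; and the model is exactly invariant under
whole-genome duplication combined with the purity substitution
$p \mapsto p/(2-p)$, so ploidy is identifiable only up to that symmetry
and must be resolved by convention (below).

## Segmentation

Profiles are partitioned per chromosome by recursive change-point
splitting. At each node the scan statistic is the larger of (a) the
scaled single-split CUSUM $|S_k| / \sqrt{k(n-k)/n}$ (equivalent to a
two-sample $t$ statistic; its argmax is exact at the edge of a clean
step) and (b) a windowed arc scan,
$\max_{w, i} |S_{i+w} - S_i| / \sqrt{w(n-w)/n}$ over a geometric grid of
window lengths, which restores sensitivity to short interior segments
(focal amplicons) that a single split dilutes — the same consideration
that motivates circular binary segmentation. Significance is assessed by
random permutation of the node's values (999 permutations; a split is
kept at $p \le \alpha$ with $\alpha = 0.001$), which is scale-free and
needs no variance estimate; permutations stop early once the exceedance
count settles the call. Splits are placed at the single-split argmax and
both halves are revisited, so arcs sharpen to their true edges over the
recursion.

logR and mBAF are segmented independently (segment level: mean for logR,
median for mBAF — the median resists residual homozygotes), breakpoints
are unioned, and statistics are recomputed per integrated segment.
Profiles are then centralized by subtracting the mode of the
marker-weighted Epanechnikov density of segment means (half-width 0.1,
searched on a 0.01 grid; ties break toward the level covering more
genome), putting the dominant copy-number level at logR 0.

Defaults: minimum 5 markers per segment, 10 heterozygous markers per
chromosome for a confident mBAF partition. These stabilize segment
medians at the default noise levels.

## Purity, ploidy and ASCN estimation

`gap_fit()` matches integrated segments to the lattice of states
$\{(n_A, n_B): n_A \ge n_B \ge 0,\ n_A + n_B \le 8\}$ (the cap at eight
total copies bounds the search; amplifications beyond it are carried by
the continuous copy number). Writing $\beta$ for the unknown logR offset
of the zero-copy state, the expected logR of a state with total $t$ is
$\log_2(2(1-p) + p\,t) + \beta$, so the search is a grid over
$p \in \{0.10, 0.11, \ldots, 1.00\}$ and over $\beta$ candidates derived
from the best-supported segments. Each candidate scores segments by
squared distance to the nearest lattice point, with the two axes scaled
by the probe-level noise SDs, length-weighted and averaged. The fitted
$\psi$ is the length-weighted mean assigned total copy number, and the
continuous copy number of a segment is the inverse of the logR model,
$\mathrm{cn} = \big( (2(1-p) + p\psi)\, 2^{\mathrm{logR} - \mathrm{baseline}} - 2(1-p) \big)/p$,
floored at zero and deliberately *not* capped — fractional values are the
footprint of subclonal mixtures.

Three numerical details matter in practice and were found necessary for
reliable recovery:

* **Fold bias.** The segment-level *median* of mirrored BAF is not the
  clean mixture value: mirroring folds the probe noise, so a balanced
  state is observed near $0.5 + 0.675\,\sigma$ rather than 0.5 (and
  intermediate deviations interpolate as the median of a folded normal).
  Lattice mBAF levels carry this correction. Without it, every balanced
  segment pays a systematic penalty that compressed high-ploidy lattices
  can absorb, and the fit drifts to spurious genome doublings.
* **Noise SDs** are estimated from within-segment residuals: pooled MAD
  for logR; for mBAF, the maximum per-segment MAD over moderately
  imbalanced segments (median mBAF in $[0.55, 0.85]$), because balanced
  segments deflate the MAD (fold effect, $\approx 0.59\sigma$) and
  segments near the homozygote-exclusion boundary inflate it (truncation
  and homozygote leakage).
* **Leverage control.** Segments with fewer than 20 markers — mostly
  breakpoint slivers whose means are unstable — are excluded from the
  score (they still receive state assignments afterwards).

**Resolving the duplication symmetry.** Scaled solutions (all states
multiplied by $s$, purity $p/(s-(s-1)p)$) reproduce every segment
position, and under noise their scores differ by more than any tight
tolerance, in either direction. Candidates within 1.5× of the best score
are therefore treated as one equivalence family: they are grouped by a
closed-form ploidy proxy (the length-weighted mean of the continuous
copy number implied by each segment's logR), and the lowest ploidy class
wins, then the best score within the class, then the higher purity. A
1.5× window is far below the score ratio of genuinely different fits
(mis-assigned states cost squared lattice gaps, orders of magnitude
above noise), so the rule only ever arbitrates between duplication
images. Tumors whose genomes contain states a doubling would push past
the 8-copy cap are anchored automatically. Profiles with no detectable
aberration cannot constrain $p$ at all and are returned flagged
degenerate with $\psi = 2$.

## Event calls and cohort summaries

Gain and loss are relative to the integer baseline
$B = \max(\mathrm{round}(\psi), 1)$: gain iff $n_A + n_B > B$, loss iff
$< B$. Rounding is the simplest rule consistent with calling relative to
tumor ploidy; segments without an integer assignment fall back to the
continuous copy number with a ±0.5 band and are flagged. LOH requires a
lost minor allele with at least one copy remaining ($n_B = 0$,
$n_A \ge 1$) and is never inferred on gains; CNN-AI is allelic imbalance
($n_A \neq n_B$) at neutral dosage. The FGA statistics are genome-length
fractions of the corresponding indicators; segments with unknown allele
split count toward CN-FGA only (conservative). Cohort tracks live on the
common 10 kb grid: each virtual probe takes the value of the segment
containing its center, and frequencies are fractions of samples.

## Subclonal copy-number loss

A deletion present in only part of the aberrant cells produces a
continuous copy number strictly between integer levels. The detector
implements the four-rule procedure on loss segments: (1) restrict to
segments called loss; (2) keep those whose continuous CN differs by at
least 0.6 from another loss segment; (3) require partitioned
logR < −0.12 and more than 100 markers; (4) flag the sample when the
extreme-CN members differ by more than 0.2 in logR. All rules run on the
integrated segment set (the thresholds are exposed as arguments). Note a
deliberate property inherited from the rule set: a tumor whose clonal
losses sit at two *different* relative depths (say single-copy and
two-copy losses below a ploidy-3 baseline) satisfies the rules too — the
procedure is a conservative screen for CN-level heterogeneity, not a
clone-deconvolution method.

## Amplicons and recurrence

Focal amplicons are segments > 50 kb with centralized logR > 0.7 (strict
inequalities throughout; boundary values are excluded). Broad amplified
events merge adjacent segments with total CN > ψ + 3 and size > 2 Mb.
An amplification is *monoallelic* when the minor allele stays at or below
its ploidy share ($n_B \le \mathrm{round}(\psi/2)$) while the major
allele carries the added copies ($n_A - n_B \ge 3$); with no
heterozygous probes the call is unknown. Cohort-recurrent amplicons
require logR > 1 in at least $\lceil 0.03\,n \rceil$ samples and report
the minimal common overlap — the coverage-maximal sub-interval of each
supported run, intersected across supporting segments; equal-height
plateaus are reported separately.

Recurrent gains and losses across a cohort are found GISTIC-style:
per-probe G-score $\sum_s \max(0, \mathrm{logR}_s - 0.12)$ (and the
mirror image for losses), a null built by cyclically shifting every
sample's probe vector by an independent random offset (preserving
within-sample segment structure while destroying cross-sample
alignment), pooled into one genome-wide distribution; per-probe
empirical p-values are BH-corrected and contiguous probes with
$q < 0.05$ form regions. After the top peak is recorded, its samples'
contributions inside the peak are removed and the scan repeats (at most
10 iterations per chromosome), so independent secondary peaks surface.
This is deliberately a lite reimplementation: the amplitude-sum score,
shift null, BH correction and greedy peel-off reproduce the *behavior*
(false-positive control, spike power, peel-off) — not the published
tool's exact output, which remains the reference for real cohorts.

## Flow-cytometry ploidy

DNA histograms summarize to FCM-ploidy
$= 2 \sum_i \mathrm{DI}_i f_i$, the DNA-index-weighted cell fraction sum
scaled so a pure diploid population reads 2N (the 2× scaling makes the
conventional DI = 1 diploid reference land on the 2N/3N axis used for
cohort comparison). Cohort distributions are smoothed with a fixed
Epanechnikov kernel, $K(u) = 0.75(1-u^2)$ on $|u| \le 1$, half-width
0.08 in N units — deliberately not a data-driven bandwidth, so curves
are comparable across cohorts.

## The simulator and what the tests mean

`simulate_tumor()` generates the exact measurement model above: clones
with fractions summing to one, per-probe mixture BAF and logR, Gaussian
noise ($\sigma_{\mathrm{logR}} = 0.15$, $\sigma_{\mathrm{BAF}} = 0.03$
by default — calibration choices in the range of array data, not
published platform values), heterozygous probes at rate 1/3, homozygous
probes near 0/1, random parental phase. The default genome is three
chromosomes of 60/50/40 Mb with probes every 10 kb. The logR reference
is the sample's own mean DNA content, so uniform-ploidy genomes have
exactly zero mean logR; for mixed profiles the mean of per-probe log
ratios differs from zero by Jensen's inequality, and centralization
handles the residual shift downstream.

The reference validation cohort (`tumor_designs()`) fixes one ASCN
layout per ploidy class (~2.0, 2.6, 3.2, 4.0), each with at least eight
distinct states, crossed with purities 0.3–0.9. Layouts are chosen to be
biologically shaped rather than adversarial: the high-ploidy layout
carries more altered genome, more LOH/CNN-AI and losses at two relative
depths (aneuploid tumors are empirically more complex), while the
diploid layout's homozygous deletion is kept short so purely clonal
diploid genomes do not trip the subclonality screen. The two-clone
subclonality design (`subclonal_design()`) puts a clonal (2,0) loss and
a second (2,0) region that a subclone deletes to (0,0) on a (2,1)
background, plus a clonal (5,1) amplification whose doubled image would
exceed the copy-number cap — a realistic high-level amplicon that also
anchors the ploidy scale when the mixture region falls between integer
states.

What passing tests show: the estimator recovers purity within ±0.05 and
ploidy within ±0.15 with ≥95 % genome-wise ASCN accuracy under this
noise model; the detectors have the stated operating characteristics
under engineered truths; the grid and recurrence machinery agree exactly
with brute-force oracles. What they do not show: robustness to wave and
GC artifacts, genotyping-error structure, germline CNVs, allelic probe
biases, or segmentation behavior matching any specific published tool on
real arrays — none of which the generator emulates.

## Problem sizes and determinism

Validation runs use the 150 Mb / 15,000-probe genome for the 20-tumor
recovery cohort, a 22 Mb chromosome for the subclonality replicates and
a 30 Mb chromosome (3,000 grid probes, 50 samples, 1,000 permutations)
for recurrence — sizes chosen so the distributions of interest are
well-resolved while whole suites stay re-runnable in minutes. Every
stochastic step takes an explicit seed: identical configuration and seed
give bit-identical simulator output, segmentations and pipeline tables;
the permutation tests draw from R's RNG under a locally restored state,
so library calls do not perturb user seeds.

## Known limitations

Purity below ~0.10 collapses the lattice and is not searched. Balanced
tetraploid genomes without odd or imbalanced states are genuinely
unidentifiable and resolve to the diploid reading by convention.
Subclonal *gains* are out of scope, as is clone reconstruction; the
continuous copy number is the only subclonal signal carried forward.
X/Y chromosomes and germline CNVs are not modeled; FGA denominators
assume autosomes. The recurrence module's null is exchangeable across
probes within a sample's shifted profile, which ignores chromosome-end
effects on real genomes.
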