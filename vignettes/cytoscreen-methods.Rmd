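---
title: "Models and methods behind cytoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

`cytoscreen` implements an advanced-immunophenotyping workflow for spectral
flow cytometry of PBMCs: panel spectral modeling and unmixing, antibody
titration, automated hierarchical gating, and the screening statistics used
in drug and patient studies. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Spectral model and unmixing

Each fluorophore is represented by a *spectral signature*: its relative
emission across the 38 detectors of a 3-laser (violet/blue/red)
configuration, clipped at zero and scaled to unit Euclidean norm. Packaged
signatures are synthesized from each dye's approximate emission peak and
primary excitation laser — a Gaussian emission bump per laser block, scaled
by a dye-specific excitation weight — because measured instrument spectra
are proprietary to each vendor/instrument pairing. They are clearly
labeled synthetic and are realistic in the properties that matter here:
same-peak dyes on different lasers stay separable, neighboring dyes on one
laser overlap strongly.

Panel overlap is summarized by the *similarity index*, defined here as the
cosine of the angle between two unit-normalized signatures, and a
*complexity score*, the sum of all pairwise indices above the diagonal.
Commercial acquisition software reports trademarked similarity/complexity
values from unpublished formulas; the cosine/upper-triangle-sum pair is a
documented surrogate with the same endpoints (0 disjoint, 1 identical;
0 for a fully orthogonal panel) and monotonicity, and its values are *not*
comparable to the vendor numbers.

Unmixing solves, per event, the ordinary-least-squares problem
`raw ≈ a · S` where `S` stacks the reference signatures. OLS (rather than
a weighted or non-negativity-constrained variant) matches standard
spectral-unmixing practice and keeps the estimator linear and exactly
invertible on noiseless mixtures — a property the tests exploit. An
autofluorescence signature row is off by default, reflecting protocols in
which low-autofluorescence cells make the extra tag unnecessary; pass one
explicitly to enable it. A signature matrix whose Gram matrix has
condition number above 1e8 is rejected as collinear, naming the most
similar pair. Reference signatures are estimated from single-stain
controls as the per-detector median difference between stained and
unstained events (clipped, renormalized), which makes the estimate robust
and invariant to a shared constant background. Visual NxN-plot unmixing QC
is replaced by a numeric per-detector residual summary.

## Titration and the stain index

The stain index is
`SI = (MFI_pos − MFI_neg) / (2 · rSD_neg)`. The robust standard deviation
is not defined in most acquisition manuals; here it is `1.4826 × MAD`
about the median, the consistent estimator of a normal standard deviation
(FlowJo's internal definition may differ — a documented surrogate). The
selection rule — lowest concentration whose SI is at least 90% of the
series maximum — operationalizes the qualitative practice of titrating
down while separation stays high. It is one defensible formalization, not
a claim of equivalence with expert judgment.

## Gating: automation of a manual hierarchy

The packaged trees encode the standard PBMC and T-cell hierarchies:
scatter/debris removal (FSC-A ≥ 45,000), an FSC-H/FSC-A ratio window
(0.75–1.25) for singlets, a viability-dye gate, then lineage quadrants and
subset gates (CD3/CD19; IgD/CD27 B subsets with CD38/CD27 plasmablasts in
IgD− B cells; HLA-DR split; CD56/CD16 NK; CD14/CD16 monocytes; CD11b/CD11c
DCs; TCRγδ exclusion before CD4/CD8; CCR7/CD45RA memory quadrants;
chemokine-receptor T-helper gates). Two deliberate simplifications: the
NK early/mature children split on CD16 alone (within an already-CD56+
gate the CD56 axis is not reliably bimodal), and γδ T cells are gated
before the CD3+ αβ gate, following the conventional plot order.

The central automation gap is threshold placement, which is manual in
practice. `auto_threshold()` places 1-D cuts on `asinh(x/150)`-transformed
values: primarily the deepest density minimum between the two highest
modes of a Gaussian-kernel KDE (Silverman bandwidth, 512 grid points),
falling back to the equal-posterior boundary of a two-component Gaussian
mixture, and finally to an empirical quantile. Fallback quantiles are set
per gate from the expected positive fraction (e.g. 0.97 for TCRγδ, 0.25
for CD127-low), mirroring how an operator would bias a cut for a rare
population; every placed threshold is reported in the gating result so the
automation stays auditable. The cofactor 150 is a conventional display
scaling for this class of instrument; gating thresholds live on the
transformed scale while MFIs are always reported raw (the median commutes
with the monotone transform, which the tests assert).

Conventions stated once: a value exactly at a threshold is *positive*
(half-open gates); quadrant siblings share their two thresholds, computed
once on the parent's events and cached per (parent, channel); overlapping
leaf gates (the T-helper gates are not a partition — Treg is defined on
CD25/CD127 while Th1/Th2/Th17 live on chemokine receptors) resolve
per-event labels by declaration order, first match wins; subsets with
fewer than 20 events report missing MFIs rather than unstable medians;
"PD-1 high" (Tph) and "CD127 low" (Treg) have no published numeric
cutoffs and are implemented as valley gates with quantile fallbacks (0.90
and 0.25).

## Screening statistics

Drug effects are *fractional differences*,
`FD = MFI_drug / MFI_DMSO − 1`, computed per donor and per
(subset, marker) feature, pooled as the donor mean, and displayed in
percent. The heatmap outlier rule removes cells with FD < −150% or
> +150% — strict inequalities, so exactly ±150% is retained; masked cells
are flagged, never zeroed. Column clustering uses complete-linkage
agglomeration on Euclidean distances over pairwise-complete rows, scaled
by `sqrt(total/observed)` — the missing-data rule of `stats::dist`, chosen
because the published analyses do not state one; both linkage and distance
are configurable. Per-feature inference is a two-sided one-sample t test
of the donor FDs against 0 (the vehicle), starred at 0.05/0.01/0.001 on
raw p values; no multiple-testing correction is applied by default to
match that annotation style, with Benjamini–Hochberg available as an
option. Patient-vs-control comparisons use the pooled-variance Student's t
(a Welch option exists, off by default, since the published wording says
"Student's t-test" without qualification).

The cohort embedding follows the published order of operations: min-max
normalize each feature across donors (a constant feature maps to 0, the
declared convention for the undefined 0/0), remove the lowest-variance 10%
of features (ties broken by column order), then a column-centered
3-component PCA with a fixed sign convention (largest-magnitude loading
positive). Because "clear separation" in a 3-D PCA plot is a visual
judgment, the package quantifies it as the mean silhouette width of the
group labels in component space: positive when groups separate, near zero
under label shuffling.

## What the synthetic generator emulates — and what it does not

Marker expression is log-normal per population, the standard first-order
model for cytometry intensities; positive/negative status is encoded
purely in the log-location (canonical levels: negative median 60, dim 400,
positive 5,000, bright 20,000 intensity units, log-SDs 0.40–0.60). This
keeps two useful exactness properties: the population median is `exp(µ)`,
and a multiplicative condition effect `k` scales the median exactly by
`k`, so the ground-truth FD of an injected effect is exactly `k − 1`.

The default compositions encode the reported healthy-donor means (T cells
70.6% of viable, B cells 7.5% with 59.4/14.6/18.5/7.5 sub-splits and
plasmablasts at 4.1% of IgD− B, NK 7.1%, monocytes 4.1%, DC 2.1%; CD4
54.5% and CD8 32.6% of αβ T cells; Th1 32.9, Th2 2.0, Th17 7.0, Treg 7.0,
Tfh 10.1, Tph 3.4% of CD4). Where reported sub-fractions do not sum to
100% they cannot define a generative partition that quadrant gates must
recover, so the package renormalizes them proportionally (monocyte
classical/intermediate/non-classical 43.5/5.4/2.1 → 85.3/10.6/4.1;
DC 28.6/45.3 → 38.7/61.3) and lets the double-negative T gate absorb the
unclassified αβ remainder; the reported identical 7.0%/1.2 figures for
Th17 and Treg are used as printed, flagged as a likely typographical
duplication in the source material. Naïve CD4 cells absorb the remainder
of the CD4 compartment, so the CD4 memory-quadrant composition is
internally consistent rather than matching every reported memory mean —
only the subset fractions listed above are recovery targets.

Donor variability is a logit-normal jitter on leaf fractions (σ = 0.15 by
default, renormalized), reflecting reports that donors "differ slightly";
debris (2%, low FSC), doublets (5%, FSC-A ≈ 2×FSC-H) and dead cells (10%,
bright viability dye) leave about 83% viable, consistent with the ~80%
viability reported for stimulated cultures. Stimulation and drug effects
are multiplicative per (population, marker); the packaged mitogen fixture
(CD69 ×5 across subsets, plus CD38/CD25/HLA-DR increases) and patient
fixture (CD69/CD95/ICOS up, CD45RA down, Th2 halved, Tfh/Tph/Treg up) use
*nominal* magnitudes — the source narratives name directions, not effect
sizes, and the drugs themselves are undisclosed. The titration generator
uses a saturating binding curve `MFI_max·c/(c+K)` for the positive median
over a background rising linearly with concentration; the linear
background is an invented, synthetic-only device that makes the SI curve
unimodal, standing in for real over-titration spread.

Not emulated: spillover-spreading error structure, instrument gain/QC
calibration, autofluorescence heterogeneity across cell types, doublets
that are true conjugates of two phenotypes, and batch effects. Passing
tests therefore demonstrate that the *pipeline* recovers known truth under
a faithful first-order data model — not that the gating would reach the
same accuracy on any real sample.

## Numerical and interface choices

Events live in a plain `event_matrix` (matrix + truth labels + metadata);
FCS support is written in-package (3.1 float writing, 3.0/3.1 float and
integer reading, escaped-delimiter keywords) since no flow-format package
is among the dependencies. All generators are pure functions of
(specification, seed) via scoped RNG, and derived seeds stay below 2^31.
The package's interface is its functions plus `scripts/acceptance.R`;
an additional shell CLI would only wrap these one-liners and is
deliberately not shipped.

Problem sizes used by the test-suite: composition-recovery checks run 6
donors × 100,000 events (matching the 6-donor design of the screening
experiments); drug-effect recovery uses 6 replicate screens of 6 donors ×
30,000 events so the per-feature false-positive rate is estimated from
about 2,000 untouched feature tests; the cohort-separation property uses
20 seeds × 10 donors × 8,000 events per panel. These sizes were chosen so
Monte-Carlo error is small relative to the tolerances being checked.

## Known limitations

* Similarity/complexity values are surrogates; do not compare them to
  vendor-reported numbers.
* Automatic valley thresholds assume reasonably bimodal marginals within a
  parent gate; heavily overlapping real-world populations (e.g. smeared
  activation markers) will need fixed or quantile gates.
* The one-sample FD test treats donors as exchangeable replicates; paired
  or mixed-effect designs are out of scope.
* The FCS writer emits float 3.1 only, and the reader supports list-mode
  float/integer data — the common cases, not the full standard.
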