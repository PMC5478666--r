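---
title: "Methods: paired methylome analysis across the receptivity transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired methylome analysis across the receptivity transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`methcycle` analyses paired 450K-style DNA methylation data from the
endometrial transition between the pre-receptive (LH+2) and receptive
(LH+8) phase of one menstrual cycle, and the *cis* relationship between
those methylation changes and gene expression. This vignette documents the
models, the assumptions behind them, the tunable parameters, and the design
choices made where more than one reading was defensible.

## Signal scales

Probe intensities `m` (methylated) and `u` (unmethylated) are converted to

* **β-values**, `β = m / (m + u + 100)` — the approximate methylation
  proportion in `[0, 1)`. The +100 offset stabilises β for dim probes at
  the cost of a small downward bias (`T/(T+100)` at total intensity `T`);
  the synthetic generator emits intensities rather than β precisely so this
  bias is exercised.
* **M-values**, `M = log2((m + o)/(u + o))` with offset `o = 1` — the
  log-odds-like, variance-stabilised scale on which all tests run. M is
  computed from intensities, not from β, so the +100 offset does not
  contaminate it. For intensities far above the offsets,
  `M ≈ log2(β/(1−β))`; a unit test asserts that link at high intensity
  within 0.01 log2 units.

Effect sizes are reported as **Δβ**: the mean paired β difference,
receptive minus pre-receptive. Whether Δβ should be computed pre- or
post-normalization is not determined by the problem; we compute it on
normalized values, and because scaling normalization preserves within-sample
`m:u` ratios the difference is confined to the +100 offset (< 0.01 at
typical intensities, asserted in tests).

## Preprocessing

Scaling normalization multiplies each sample by one scalar so all samples
share the same mean total intensity; it assumes intensity differences
between samples are global (scanner/array effects), not biological.
Probe filtering is staged and deterministic:

1. SNP-overlapping probes, cross-reactive probes, and *unreliable* probes —
   detection failure in more than `detect_frac` (default 0.05) of samples;
2. sex-chromosome (`chrX`/`chrY`) and non-CpG-context probes.

Each probe is counted once, at the first rule that removes it, so
`initial − Σremoved = remaining` always holds. The fixed failure-fraction
rule replaces iterative matrix-trimming approaches because it is
deterministic, order-stable, idempotent, and directly testable; the
threshold is exposed rather than hidden.

## Site-level inference

All three tests operate on per-subject paired differences
`d = M(LH+8) − M(LH+2)`, one vector per probe. Age is a subject-level
covariate and therefore cannot be adjusted alongside subject fixed effects;
instead each probe's differences are regressed on centred age and the
**intercept** — the age-adjusted mean difference — is tested. This respects
the pairing and the age adjustment simultaneously. The Wilcoxon arm is
necessarily unadjusted: a rank test admits no covariate.

**Moderated paired test.** Per-probe residual variances `s²` (on `n − 2`
df) are shrunk toward a pooled prior: `s̃² = (d₀s₀² + df·s²)/(d₀ + df)`,
with `(d₀, s₀²)` estimated by moment-matching on `log s²` under the scaled
inverse-χ² model (`s² ~ s₀² F(df, d₀)`), using digamma/trigamma moment
equations and a Newton inverse of the trigamma function. `t̃ = β̂₀/SE(β̂₀)`
is referred to a t distribution on `d₀ + df` df. At `d₀ = 0` this is the
ordinary t-test (asserted to machine precision); at `d₀ → ∞` all probes
share `s₀²`. If the observed log-variance spread is below the theoretical
χ² spread, `d₀ = ∞` is used. Zero variances are excluded from the moment
equations and are rescued by the moderation itself (`s̃² > 0`). An
independent cross-check against limma's empirical-Bayes machinery runs in
the test suite; limma is never used in the implementation.

**Wilcoxon signed-rank.** Zeros are dropped (the original convention), ties
in `|d|` take midranks. With ≤ 25 non-zero differences and no ties the
two-sided p comes from the exact signed-rank null
(`p = 2·min(P(W ≤ w), P(W ≥ w))`, capped at 1); otherwise a normal
approximation with tie and continuity corrections. All-zero rows get
`p = 1` and are flagged. A property test checks the exact branch against a
2ⁿ sign-enumeration oracle.

**Segment test.** Consecutive probes are grouped greedily while the
inter-CpG gap stays ≤ `max_gap` (default 500 bp, the same window used for
DMRs) *and* the per-probe mean difference keeps its sign; each segment's
per-subject mean difference is tested with the unmoderated age-adjusted
model and the segment p is propagated to members. Because multi-CpG
segments are *selected* for same-signed effects, the plain t reference is
anti-conservative for them. Their p-values are therefore computed against
the conditional null of t given that selection event. The key observation
is that conditioning k independent mean-zero Gaussian probe vectors on
"all row means share a sign" is, by per-probe sign-flip symmetry,
equivalent to flipping each row to a positive mean — so the conditional
null can be sampled exactly, with no rejection step (`n_null = 20000` draws
per distinct segment size, fixed internal seeds, hence deterministic).
Singleton segments keep the analytic t p-value; the unconditional p is
retained as `p_unadjusted`. The boundary part of the selection event (that
the run is *maximal*) is ignored; the residual effect is a slight
conservativeness for two-CpG segments, visible in the calibration test.

Each method's p-values are BH-adjusted — across probes for the first two,
across unique segments (then propagated) for the third. The **consensus**
set is the intersection at `q < α` (default 0.05) in all three, the
direction the sign of Δβ.

## DMR calling

On the position-ordered significant CpGs of each chromosome (by default the
consensus set), maximal runs are formed in which every adjacent pair is
≤ `max_gap` bp apart and shares a direction; runs with ≥ `min_cpgs`
(default 3) members become DMRs. "Within a 500 bp window" is read as the
adjacent-gap rule — it matches "consecutive" and makes runs of any length
well defined; the total-span reading is available via
`window_rule = "span"`. Sign consistency is required because regions are
reported as increased or decreased, never mixed. Region p-values retest the
per-subject region-mean differences (age-adjusted), region q-values are BH
across emitted DMRs, and BED6 export converts the 1-based inclusive CpG
span to 0-based half-open coordinates with score `−10·log10(q)` capped at
1000. A brute-force enumeration oracle verifies the caller on hundreds of
random instances.

## Methylation–expression correlation

Candidate pairs are consensus CpGs with `|Δβ| > 0.1` carrying at least one
gene annotation (open-sea CpGs, being unannotated, are excluded), paired
with every annotated gene present in the expression matrix. Methylation
enters as β (the natural scale for interpretation; rank correlation makes
the β-vs-M choice nearly immaterial since the map is monotone), expression
as CPM (`count/library·10⁶`). Spearman's ρ is computed over all samples
with both data types, both phases pooled. Significance comes from a
permutation null: the expression vector is permuted jointly across samples,
`p = (1 + #{|ρ_b| ≥ |ρ|})/(B + 1)` (two-sided, add-one, so `p ≥ 1/(B+1)`),
with exhaustive enumeration when `n! ≤ B`. Permuting across all samples
breaks the subject pairing; since the statistic pools phases, the
exchangeability assumption is of samples, not pairs — a pair-preserving
scheme would test a different (narrower) null. Constant vectors leave ρ
undefined; such records are flagged with `p = 1`. Significant correlations
are aggregated per (gene, region) by the median ρ, and summarised per
subregion and per super-group (5′ region = TSS1500 + TSS200 + 5′UTR +
1stExon; gene body = Body + 3′UTR) as counts with percentages of tested
(correlated) and of correlated (positive/negative).

## Descriptive profiling

"Consistently hypermethylated" is operationalised as phase-mean β > 0.8 in
*both* phases (hypomethylated: < 0.2 in both). The alternative
every-sample-unanimity reading is stricter and noise-sensitive at n = 17;
phase means are the simpler and more stable choice. Probes with multiple
distinct subregion annotations are pooled into `Others`, unannotated probes
into `Unknown`. Distribution comparisons use the two-sample KS test;
category enrichment of significant sites uses a goodness-of-fit χ² against
proportions from all analysed probes. Sample clustering uses Euclidean
distance on β over a probe subset with average linkage (the metric/linkage
are exposed, as no single convention is canonical) and reports the
two-branch cut's agreement with phase labels under the best
branch-to-phase assignment.

## The synthetic generator

`simulate_study()` emulates the paired study the analysis assumes:

* **Cohort** — `n_subjects = 17`, one sample per phase, ages uniform on
  24–35 years.
* **Manifest** — probes laid in positional clusters (mean ~6 CpGs,
  within-cluster spacing 20–180 bp, between-cluster gaps 2–50 kb) across 5
  autosomes plus a 2% sex-chromosome fraction; per-cluster CGI-relation
  categories; per-cluster gene/subregion annotations with open-sea clusters
  mostly unannotated; 1% SNP-flagged, 6% cross-reactive, 0.5% non-CpG
  context, 0.3% detection-unreliable probes.
* **Methylation** — baselines drawn on the M scale from a tri-modal
  landscape (hypo/intermediate/hyper weights 0.33/0.48/0.19, matching the
  descriptive fractions the analysis reports); per-subject random effects
  (`subject_sd = 0.3`) and residual noise (`sigma_m = 0.3`) on the M scale,
  values chosen as a plausible array-scale noise level since no per-probe
  variance estimates were available to copy — they are configuration, not
  constants. 5% of probes carry true effects, 84.5% increasing, |Δβ|
  uniform on 0.05–0.25, converted to M-scale shifts through the logit link;
  30 planted blocks give ≥ 3 consecutive probes within 500 bp the same
  signed effect. Intensities are emitted by splitting a log-normal total
  (median 3000, log-sd 0.25).
* **Expression** — log relative expression of a coupled gene follows a
  Gaussian-copula construction with latent Pearson `r = 2·sin(π·ρ/6)`
  targeting Spearman `ρ = coupling_strength` (default 0.8) against the
  probe's M-values; coupling sign is positive with probability 0.56 in the
  gene body and 0.44 in the 5′ region. Counts are the library-size-scaled
  relative expression rounded to integers, so with all noise at zero a
  coupled gene's CPM is strictly monotone in methylation and the
  strength-1 case yields ρ = ±1 exactly.

What the generator does **not** emulate: Infinium I/II chemistry
differences, batch/chip effects, control probes, IDAT-level artefacts,
count overdispersion beyond the log-normal layer, or trans-regulation.
Passing recovery tests therefore demonstrates correctness of the
algorithms under the stated generative assumptions, not robustness to every
artefact of real arrays.

## Problem sizes and checks

The test suite verifies, among others: formula fidelity on edge cases;
exact Wilcoxon against sign enumeration (200 random instances, n ≤ 10); BH
against hand step-up values and an independent oracle; the DMR caller
against brute-force enumeration (500 instances up to 200 CpGs); null
calibration of all three site tests on a 5,000-probe, 17-pair null study
(each within [0.035, 0.065] at nominal 0.05) and of the permutation
correlation over 1,000 null pairs at B = 999; and parameter recovery on a
20,000-probe study with |Δβ| ∈ [0.15, 0.25] (consensus empirical
FDR ≤ 0.10, sensitivity ≥ 0.5, ≥ 80% of planted blocks recovered, ≥ 95%
of significant planted correlations with the correct sign). These sizes
were chosen so the whole suite runs in minutes on one core while keeping
binomial Monte Carlo tolerances tight; `scripts/acceptance.R` re-runs the
pipeline end-to-end at the default scale and writes all quantities it
computes.

## Known limitations

* The segment test's conditional null assumes Gaussian paired differences;
  heavy-tailed noise would make the calibration approximate (the
  site-level Wilcoxon arm is the robust counterweight).
* The moderation moment equations assume variances exchangeable across
  probes; strong variance structure (e.g. probe-type effects) would call
  for stratified priors.
* Age adjustment is linear; non-linear age effects are absorbed into
  residual variance.
* The correlation stage tests association, not causation, and only in
  *cis* as defined by the manifest's annotations.
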