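---
title: "Branch-model selection tests and hotspot clustering: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-model selection tests and hotspot clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The codon model and the branch test

Selection on protein-coding genes is quantified by ω = dN/dS, the ratio of
nonsynonymous to synonymous substitution rates; ω > 1 on a branch is the
signature of positive diversifying selection. The substitution process is a
continuous-time Markov chain on the 61 sense codons of the standard genetic
code. Instantaneous rates between codons differing at exactly one
nucleotide are proportional to the target codon's equilibrium frequency
π_j, multiplied by κ for transitions and by ω for nonsynonymous changes;
rates to stop codons and multi-step changes are zero. Each generator is
scaled so one unit of branch length equals one expected substitution per
codon.

Equilibrium frequencies default to **F3x4**: the product of position-specific
nucleotide frequencies observed in the alignment, renormalized over sense
codons. `f1x4` (pooled nucleotide frequencies) and `empirical` (observed
codon frequencies) are available behind a flag because published per-gene
likelihoods can be sensitive to this choice and reconciliation may require
sweeping it.

Two nested models are fitted per gene by maximum likelihood:

* **one-ratio (M0)** — a single ω for every branch (null);
* **two-ratio branch model** — separate ω_fg on the labeled foreground
  branches, ω_bg elsewhere (one extra free parameter).

κ, the ω's, and *all branch lengths* are maximized jointly. The test
statistic 2(lnL₁ − lnL₀) is referred to χ²(1); no boundary-mixture
correction is applied, because ω_fg is interior to its parameter space in
the two-sided branch test and this matches the calibration used in the
analyses this package reproduces. Raw P-values are Benjamini–Hochberg
adjusted over exactly the family of genes screened in one run; genes whose
fits fail are excluded from the family with a warning.

### Assumptions worth stating

* Sites are independent and identically distributed; there is no among-site
  rate or ω variation (site and branch-site models are out of scope).
* One ω per branch class — rate homogeneity across background lineages.
  Violations are a documented source of false positives for this test.
* The alignment is a curated, in-frame, orthologous CDS alignment; the
  package deliberately does not build or trim alignments.
* Codons containing gaps, ambiguity codes, or stops at a tip are treated as
  missing data at that tip (`gap_policy = "missing"`, the codeml
  `cleandata = 0` analogue). A strict mode (`"strip"`) drops such columns
  globally; this is exposed because the upstream study did not state its
  setting.

## 2. Parameters, units, defaults

| parameter | unit / range | default | why |
|---|---|---|---|
| κ | rate ratio, [1e-3, 100] | init 2 | typical mammalian ts/tv |
| ω (each class) | rate ratio, [1e-4, 50] | init 0.4 | lower bound 1e-4 because published fits print ω = 0.0001 |
| branch lengths | subs/codon, [1e-8, 50] | NNLS init from 3× JC nucleotide distances | joint ML refines them |
| α (candidate threshold) | — | 0.01 | the screen's published operating point |
| window length | bp | 12 Mb | the hotspot window size |
| permutation iterations | — | 1000 | published null size |
| linkage gap threshold | bp | 10 Mb | the figure convention for "distant on the same group" |
| coverage bands | relative dose | [0.35, 0.65] and [0.85, 1.15], min_frac 0.2 | calibrated defaults; the original X call was visual, so the bands are ours, not published values |

Convergence is declared when the optimizer's relative improvement
corresponds to ΔlnL below ~1e-8 (`factr = 1e7`); up to `max_restarts`
seeded random restarts are attempted when the first optimization fails.
Refitting from a returned optimum reproduces lnL to well below 1e-6.

## 3. Numerical choices

* **Pruning in C++.** The likelihood is computed by Felsenstein pruning
  over compressed site patterns, with per-pattern rescaling against
  underflow. Branch-length gradients are analytic (a standard two-pass
  algorithm); κ/ω gradients use central finite differences on the log
  scale. This combination is what makes 400 maximum-likelihood fits in the
  acceptance suite affordable on one CPU.
* **Matrix exponentials** use the eigendecomposition of the symmetrized
  reversible generator, D^{1/2} Q D^{-1/2}; P(t) then costs two 61×61
  multiplications per branch. Entries are clamped at zero.
* **Zero frequencies.** If a nucleotide is absent at a codon position,
  F3x4 would put π_j = 0 and the symmetrization would divide by zero;
  frequencies are floored at 1e-10 and renormalized (codeml applies an
  analogous guard).
* **Coordinates** are 0-based half-open internally; GFF I/O converts at the
  boundary. Genes are assigned to windows by `midpoint = floor((start+end)/2)`
  only, for every window operation — the published 1-Mb binning rule,
  extended uniformly for consistency.
* **Degenerate inputs.** Alignments whose length is not divisible by 3 are
  frame errors; duplicated taxa are format errors; observed stop codons are
  warned about and treated as missing; an all-identical-codon alignment
  yields near-degenerate but usable frequencies via the floor.
* **Negative LRT statistics** (possible only through optimizer noise, since
  the models are nested) are clamped to zero with a warning rather than
  raised as errors.
* **Empirical p-values** use the add-one convention
  (#{null ≥ obs} + 1)/(N + 1), so p is never exactly zero; the published
  summary ("0 of 1,000 windows") corresponds to p = 1/1001 here.
* **Permutation RNG.** One seeded generator drives each iteration in a fixed
  documented order — chromosome order first, then the window start, drawn
  uniformly over integer bp in [0, L_total − W]. Windows crossing
  chromosome junctions are intentional: the null concatenates chromosomes
  precisely so windows may span them.

## 4. Design decisions where the design was open

* **Foreground labeling** accepts both an explicit tip/clade list and the
  PAML `#1` newick tag dialect, because published control files imply tag
  usage while programmatic callers prefer names. Both routes produce the
  same edge labeling and round-trip through the writer.
* **BH family.** Whether a multi-table study adjusts families jointly or
  separately is ambiguous in prose; `bh_adjust` operates on exactly the
  vector passed, so callers choose the family composition explicitly.
* **Observed clustering statistic.** The calibrated usage is the count in a
  *pre-specified* window. A scan mode (`max_window_count`) reports the
  densest window anywhere, but the single-random-window permutation null is
  *not* calibrated for that maximum — the scan maximum is stochastically
  larger than a random window's count, so treating it as the observed value
  biases p downward. The pipeline records which mode produced the observed
  value.
* **Breakpoint distance** is computed on signed adjacencies canonicalized
  up to reading direction, restricted to landmarks present in both
  instances. This makes the distance invariant to whole-group reversal,
  which is required because the plus-strand designation of a linkage group
  is arbitrary. Fissions appear as missing adjacencies across groups rather
  than being folded into a single event count.
* **Linkage gaps** are measured edge-to-edge between nearest landmark
  boundaries (measurement points were not defined in the source figures).
* **Ortholog completeness** follows the published rule: a gene missing one
  required taxon is kept with that taxon pruned from its guide tree; a gene
  missing more than `max_missing` (default 1) is dropped.
* **Coverage bimodality** is a two-band occupancy rule rather than a formal
  dip test: transparent, testable, and adjustable. It assumes hemizygous
  samples sit near 0.5× of their own autosomal baseline; it will miss sex
  chromosomes in balanced samples (all-male or all-female cohorts with no
  dose contrast), by construction — as does any coverage-only method.

## 5. What the synthetic generators emulate — and what they don't

`simulate_codon_alignment` evolves sites under the *same* rate matrices and
transition probabilities the fitters use (one shared model definition), so
parameter-recovery failures indicate estimation problems rather than
simulator drift. It does **not** emulate: alignment error, among-site rate
variation, GC-biased gene conversion or compositional non-stationarity
(lineage-specific GC shifts are measured by `gc_content`, not modeled),
indels, or paralogy. A green recovery test therefore establishes correctness
of the estimator under its own model, not robustness to real-data
violations.

The default simulation tree is an 8-tip pectinate tree with branch lengths
0.05–0.3 substitutions/codon and one terminal foreground branch. The
foreground tip was assigned the longest terminal branch (0.3) to emulate a
fast, well-separated focal lineage; this choice was fixed before any
acceptance measurement. `simulate_genome_annotation` defaults to a 14-
chromosome, ~2.1-Gb layout mimicking a bat-scale chromosome-level assembly,
with uniform gene placement — no gene-density, GC, or repeat structure.
`simulate_coverage` plants a clean 0.5×/1× dose mixture with lognormal
noise; real coverage has mappability and repeat artifacts it does not
attempt.

## 6. Known limitations

* With a single foreground terminal branch of length 0.3, the ML estimator
  of ω_fg at 1,000 codons has a sampling SD of roughly 0.44 around a true
  value of 2 — unbiased, scaling as 1/√n (verified empirically), but a
  single branch simply carries limited information. Expectations of tight
  (±20%) per-replicate recovery at that length are not achievable in this
  design; detecting ω_fg > 1, by contrast, is reliable.
* The branch LRT referred to χ²(1) runs conservative at moderate alignment
  lengths in this setting (empirical null quantiles fall below the χ²(1)
  curve), a documented property of the test; P-values near a threshold
  should be read accordingly.
* Published per-gene likelihood reproduction depends on unstated upstream
  settings (frequency model, cleandata, branch-length initialization);
  the frequency-model sweep exists for exactly that reconciliation, but the
  required supplementary alignments must be supplied by the user.
* Synteny comparison is landmark-driven and human-centric by construction;
  it does not detect rearrangements among unlisted intervening genes, and
  ancestral-rearrangement reconstruction is out of scope.
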