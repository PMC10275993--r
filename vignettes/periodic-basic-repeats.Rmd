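---
title: "Periodic basic-residue repeats: scanning, enrichment and charge comparison"
author: "basicrepeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periodic basic-residue repeats: scanning, enrichment and charge comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basicrepeats)
```

## The model

Arginine-rich dipeptide repeat proteins (R-DPRs) such as poly(PR)
partition into membrane-less organelles, and natural proteins carry the
same targeting signal as *periodic* basic residues: tandem (X-R/K) units
in which every second residue is arginine or lysine and the alternating
residue is free. The signal is the periodicity, not merely the net
charge — a charge-clustered variant with the same arginine count, such as
(P~16~R~16~)~3~, carries only short periodic runs. This package provides
the three computational stages used to study that signal: a tandem-motif
scanner, an exact localization-enrichment test, and a charge-feature
comparison of ranked interactome extremes, plus a generator of synthetic
proteomes with known ground truth.

## Repeat scanning

A `motif_pattern` is an ordered list of residue classes with period
$p \ge 2$; a *unit* starting at position $s$ is valid when every
constrained slot is satisfied. For each of the $p$ reading phases,
`scan_motif()` reports every maximal run of at least `min_units`
consecutive valid units. Design choices, each of which changes counts on
real proteomes and is therefore pinned:

* **Maximal-run semantics.** "Repeat length" is the unit count of a
  maximal run; per-protein statistics use the maximum over phases
  (`max_units()`). The alternative reading — summing all units in a
  protein — is emitted alongside as `total_units`, so both conventions
  of counting (one maximal run versus a whole-protein total, which
  matters for multi-repeat proteins such as US11 with its (X-P-R)
  units) are available.
* **ANY slots include R and K.** A homopolymeric run R~16~ therefore
  scores 8 (X-R/K) units, consistent with poly-arginine behaving as a
  repeat-bearing (and nucleolus-seeking) sequence. No exclusion is
  applied to the spacer.
* **Cross-phase hits are retained.** R~16~ yields overlapping hits in
  both phases (8 and 7 units); the residue census over repeat regions
  (`repeat_residue_census()`) counts the *union* of spans once, so
  overlap never double-counts a residue.
* **Nonstandard letters** (B, Z, X, U, O) never satisfy a constrained
  slot; by default they do satisfy ANY slots (`strict_any = TRUE`
  excludes them). Sequences keep them on input: I/O is lossless and each
  consumer states its rule.
* **Coordinates** are 0-based half-open internally; the CLI adds 1-based
  inclusive columns for reading.

The scanner is validated against an exhaustive oracle that steps through
every (start, unit-count) pair with per-character checks; the suite runs
it on 1,000 random sequences up to length 300 for both the (X-R/K) and
(X-P-R) patterns.

## Localization enrichment

For a category with $K$ members among $N$ annotated proteins, and $k$
hits in an annotated sample of $n$, `hypergeom_upper()` gives the exact
upper tail $P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$ — a
one-sided overrepresentation test, reported raw (a Bonferroni column in
the CLI is advisory only; no FDR machinery is implied by a handful of
categories). Two rules matter:

* Proteins without localization data are excluded from **both**
  population and sample before counting, so the annotated population
  size is data-driven (annotation coverage differs between releases, and
  the two plausible published values of that size differ by two; nothing
  is hard-coded).
* A sample that is empty after exclusion makes the category "not
  determined": the row is flagged, never silently dropped.

Term matching is case-insensitive exact equality after trimming, with the
category vocabulary supplied by the caller — no substring heuristics, so
"nuclear speckle" does not swallow "nuclear speckles" unless the
vocabulary says so.

## Charge metrics

Net charge at pH $x$ is the Henderson–Hasselbalch sum over ionizable
groups: $+\sum 1/(1+10^{x-pK_a})$ for the N-terminus, K, R, H and
$-\sum 1/(1+10^{pK_a-x})$ for the C-terminus, D, E, C, Y. The pI is the
zero of this strictly decreasing function, found by bisection on
$[0, 14]$ to a net-charge tolerance of $10^{-4}$ elementary charges (or a
bracket below $10^{-6}$ pH units). The pKa set is the EMBOSS table by
default, with a named alternative (`pka_table("sillero")`): published pI
analyses rarely state their table, pI is used here only for ordering and
group comparison — robust to the choice — but the choice must still be
pinned for bit-reproducibility. Nonstandard residues contribute no
charge, are excluded from composition vectors, and break acidic
stretches.

The longest D/E stretch is the maximal run of consecutive
aspartate/glutamate residues. Composition enrichment pools residues
across each group (long proteins weigh more — the "occurrences in the
proteome" convention) and divides by a background composition, flagging
residues with zero background frequency as undefined rather than
inventing a ratio.

## Interactome extremes

`rank_by_ratio()` orders proteins by $(a + c)/(b + c)$ with an explicit
pseudocount $c$: a zero intensity with $c = 0$ is a hard error, because
silent imputation of one-condition proteins would be invisible; the CLI
preset `"auto"` uses the smallest nonzero intensity in the table. Ties
break lexicographically so rankings are deterministic. The ≥2-fold set is
boundary-inclusive ("at least doubled"). `select_extremes()` restricts
first (e.g. to nucleolar proteins), then splits; when fewer than $2n$
remain the groups shrink symmetrically with a warning, keeping them
disjoint. `compare_extremes()` then reports per-group sorted pI curves,
unit-binned stretch histograms (stretch lengths are small integers), a
pooled-variance unpaired two-tailed t test on stretch lengths (Welch by
flag — the pooled Student form is the generic "unpaired t test" of
standard statistics packages), and composition ratios against the whole
proteome by default. Raw ratios are reported with a log2 column; ordering
is identical either way.

## The synthetic generator

`simulate_proteome()` draws residues i.i.d. from a background
composition (default: Swiss-Prot average frequencies) with lengths
uniform on 150–600, then plants, in a `prevalence` fraction of proteins,
an exact tandem repeat (unit count uniform on `units_range`) at a uniform
position. Planting is exact — the scanner is exact-match, so a mutation
model would only test the generator. Each protein also receives a planted
acidic (D/E) run with length uniform on 0–20: real proteomes show
longest-D/E stretches across that whole range (nucleolar proteins
especially), whereas an i.i.d. background alone concentrates them below
~4, far too narrow for stretch-driven enrichment to be an interesting
recovery problem. `generate_localization()` labels proteins with
probability $\mathrm{logit}^{-1}(\mathrm{logit}(b) + r \log \mathrm{OR})$
for base rate $b$ and repeat flag $r$, with an optional missing-data
fraction to exercise the exclusion rule. `generate_intensities()` sets
each protein's log2 ratio to `effect_per_stretch * stretch +
N(0, noise_sigma)` over a fixed baseline. One seed per call pins every
draw; equal seeds give byte-identical FASTA/TSV output.

What the generator does *not* emulate: domain architecture, repeat
degeneracy, phosphorylation (serine acting as a conditional acidic
residue is out of scope), label-free-quantification noise structure, or
correlated annotations. Passing recovery tests therefore shows the
pipeline's statistical machinery is correct and calibrated, not that any
particular biological proteome will show an effect.

## Problem sizes and numerical choices

The test suite runs the scanner–oracle comparison on 1,000 sequences
(length ≤ 300), verifies the hypergeometric tail against full subset
enumeration for every parameter tuple with N ≤ 12, measures enrichment
power over 100 seeded proteome-scale (n = 20,000, prevalence 0.04, base
rate 1.1%, odds ratio 8) label draws and type-I error over 2,000 null
draws, and measures stretch-effect recovery (effect 0.2 log2/residue,
noise 0.3, groups of 100) over 200 replicates of 400-protein tables —
about the size of a nucleolar interactome. These sizes give stable
empirical rates while keeping the whole suite in a few minutes on one
core. Degenerate inputs are errors, not guesses: empty sequences, zero
intensities without a pseudocount, two constant groups in the t test,
categories with an empty post-exclusion sample (flagged), and bound
violations in the hypergeometric arguments all refuse to return numbers.

## Limitations

The scanner is exact-match by design; approximate or interrupted repeats
are out of scope, as are nucleotide-level repeats and low-complexity
masking. pI is sequence-only (no structural pKa shifts or modifications).
Absolute repeat counts on a real proteome depend on the sequence
snapshot used; the package treats them as data, not constants.
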