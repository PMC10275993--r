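# basicrepeats

Arginine-rich dipeptide repeats — poly(PR), poly(GR) and relatives of the
C9ORF72-derived R-DPRs — target proteins to membrane-less organelles such
as the nucleolus, and natural proteins carry the same signal as periodic
basic residues. `basicrepeats` is an R toolkit for the three computational
analyses behind that observation:

1. **Repeat scanning.** Detect maximal tandem periodic motifs in protein
   sequences. The canonical pattern is the (X-R/K) dipeptide repeat —
   every second residue arginine or lysine, the alternating "spacer"
   unconstrained — with the per-protein *repeat length* defined as the
   largest number of consecutive units over all reading phases.
   Generalizations such as the (X-P-R) tripeptide of herpesvirus US11 are
   a one-line pattern definition away.
2. **Localization enrichment.** Test repeat-bearing proteins for
   overrepresentation in localization categories (nucleolus, nuclear
   speckle, PML body) with the exact upper-tail hypergeometric probability
   P(X ≥ k) for k category hits in an n-protein sample from an N-protein
   population with K category members. Proteins lacking localization data
   are excluded from both population and sample; untestable categories are
   reported as "not determined", never dropped.
3. **Interactome charge comparison.** Rank proteins by a between-condition
   intensity ratio (a + c)/(b + c), take the 100 most and 100 least
   enriched (optionally after restricting to a localization category), and
   compare their charge features: Henderson–Hasselbalch isoelectric
   points, longest contiguous D/E stretches (with an unpaired two-tailed t
   test), and amino-acid composition normalized to a proteome background.

A seeded synthetic-proteome generator (planted repeats, localization
labels with a controlled odds ratio, acidic-stretch-driven intensity
tables) makes every stage testable with known ground truth and no
downloads.

## Worked example

```r
library(basicrepeats)

sim <- simulate_proteome(2000, prevalence = 0.04, seed = 7)
loc <- generate_localization(sim$truth, base_rate = 0.011, odds_ratio = 8,
                             seed = 8, category = "nuclear speckle")

mined <- mine_proteome(sim$proteome, pattern_xrk(), thresholds = c(5, 10))
mined$counts
#>  5 10
#> 87 45

rep_acc <- mined$per_protein$accession[mined$per_protein$max_units >= 5]
localization_enrichment(rep_acc, sim$proteome$accession, loc,
                        "nuclear speckle")
#>          category    N  K  n k population_fraction sample_fraction fold p_upper
#> 1 nuclear speckle 2000 31 87 6              0.0155           0.069 4.45 0.00174
```

87 of 2,000 proteins reach five (X-R/K) units (80 planted plus a few
arising by chance from the background composition); 6 of those 87 carry
the planted "nuclear speckle" label versus a 1.55% population rate, a
4.5-fold overrepresentation with exact hypergeometric p = 1.7e-3.

```r
tab <- generate_intensities(sim$proteome, effect_per_stretch = 0.2,
                            noise_sigma = 0.3, seed = 9)
ranked <- rank_by_ratio(tab[c("accession", "intensity_a", "intensity_b")])
groups <- select_extremes(ranked, n = 100)
compare_extremes(groups, sim$proteome)
#> <extremes_report>
#>   groups: 100 top vs 100 bottom proteins
#>   median pI: top 4.52, bottom 6.67
#>   longest D/E stretch: top mean 19.9, bottom mean 2.54 (student t = 158, p = 3.95e-210)
```

Because the simulated enrichment grows with each protein's longest D/E
stretch, the 100 most enriched proteins are far more acidic (lower pI,
longer stretches) than the 100 least enriched — the direction expected
for an arginine-rich bait.

The command-line wrapper exposes the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","basicrepeats.R",package="basicrepeats"))')" \
  scan --fasta proteome.fasta --pattern XRK --min-units 5 \
  --out hits.tsv --summary summary.tsv
```

Subcommands: `scan`, `charge`, `enrich`, `compare`, `simulate`.

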