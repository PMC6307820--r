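---
title: "Mapping meiotic crossover hotspots on panmolecule coordinates"
author: "panxo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meiotic crossover hotspots on panmolecule coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Pollen typing measures meiotic recombination at a single hotspot locus with
molecule-level resolution. Genomic DNA is extracted from the pollen of an F1
hybrid that is heterozygous across the locus, and allele-specific PCR
primers anchored on polymorphisms at the two ends amplify either
*crossover* molecules (one parental haplotype at one end, the other at the
other end) or *parental* molecules (the same haplotype end to end). Three
kinds of data come out of such an experiment, and `panxo` implements the
analysis of all three:

1. **Titration series** — serial dilutions of the template with counts of
   positive PCR reactions, from which the concentrations of amplifiable
   crossover and parental molecules are estimated.
2. **Sanger-sequenced single crossover molecules** — ordered allele calls
   at each polymorphism, locating each breakpoint between two markers.
3. **Pooled sequencing of mass-amplified crossover molecules** — paired-end
   reads from sonicated amplicons, classified into crossover read pairs by
   an exact-match filter cascade.

All positional analysis happens on a **panmolecule**: a union coordinate
system over the two parental alleles that contains every base present in
either, so insertions from both sides occupy coordinates and profiles from
different haplotype combinations are comparable.

# The panmolecule

`align_haplotypes()` computes a global (Needleman–Wunsch/Gotoh) alignment
of the two parental amplicon sequences with affine gap penalties (defaults:
match +1, mismatch −2, gap open −6, gap extend −1, all configurable).
`build_panmolecule()` then assigns one pan coordinate per alignment column
and records, per position, the parental coordinates, bases, SNP status and
an insertion code (1 = parent-B-only base, 2 = parent-A-only base, the
published key-table dialect). Two conservation identities hold by
construction and are validated on every object:

* `length_bp − (#B-only bases) = length(parent A)`
* `length_bp − (#A-only bases) = length(parent B)`

Liftover in both directions (`lift_to_pan()`, `lift_from_pan()`) is a
strictly monotone partial bijection per parent.

Published key tables for such loci were hand-curated from Sanger reads, and
no alignment convention is stated for them; gap placement in regions where
several placements score equally is genuinely ambiguous. We therefore made
the aligner deterministic by convention — among equally optimal alignments,
gaps in parent A are placed as far right as possible — and exposed the
scoring as configuration rather than guessing a published convention.
Mismatch columns are always annotated as SNPs and never folded into
adjacent indels, since the key-table dialect separates the two.
Ambiguous bases are rejected at load: downstream read classification relies
on exact matching, which is undefined for IUPAC codes.

`polymorphism_track()` collapses the per-position annotation into records
weighted the way all windowed analyses count divergence: each SNP
contributes 1 and each indel its length in base pairs.

# Quantifying molecules: the limiting-dilution estimator

The titration experiment reports, per dilution level, how many of `n`
reactions amplified. Under limiting dilution the number of template
molecules per reaction is Poisson, so the positive fraction at a level with
true per-reaction mean λ is `1 − exp(−λ)`. The per-level zero-class MLE is

    λ̂ = −log(1 − k/n)

scaled by the level's dilution factor to the stock concentration. Levels
where every reaction is positive (saturated) or negative carry no
information and are excluded; if no informative level exists the estimator
refuses and asks for re-dilution. Informative levels are combined by
inverse-variance weighting (a plain mean is available via `combine =
"mean"`), with per-level variances from the delta method applied to the
binomial positive fraction: `var(λ̂) = d² p / (n (1 − p))`.

Genetic distance follows the crossover-fraction formula

    cM = crossovers / (crossovers + parentals) × 100

with a delta-method standard deviation propagated from both estimator
variances, and `cm_per_mb()` divides by the panmolecule span in megabases
(reported to two decimals, the precision used in rate tables). Genotypes
are compared with a Pearson χ² test (df 1, no continuity correction) on the
2×2 table of integer-rounded per-unit-volume molecule means; the rounding
digit count is an argument.

# Breakpoint calling from single molecules

`call_breakpoint()` reads the ordered allele calls of one molecule,
skipping unknowns. Exactly one A→B transition makes a *simple* crossover
whose interval is bounded by the two flanking markers — the breakpoint lies
strictly between them, so downstream window assignment uses the open span
between the markers, and interval lengths are counted as the bases strictly
between them. Zero transitions is *parental*; more than one is *complex*.
Complex molecules are reported but excluded from rate tables (their count
travels as an attribute): the published interval tables tabulate only
clean crossovers, and excluding multi-transition molecules with a logged
count is the conservative default.

`interval_rates()` distributes the titration-derived total cM over
intervals proportionally to their crossover counts, so total cM and total
crossover count are conserved exactly.

# Classifying crossover read pairs

Reads from pooled crossover amplicons are classified by a sequential
cascade, each rejection attributed to exactly one stage, with a per-stage
ledger (`Total`, `Mapped`, `Unique`, `Matched`, `Orientate`, `Strand`):

* **Mapped** — each end has at least one zero-mismatch occurrence on either
  strand of either parental template (reads with ambiguous bases fail
  here).
* **Unique** — each end matches one template only, at exactly one location.
  Reads from regions identical in both parents match both templates and
  are discarded here.
* **Matched** — one end matches parent A, the other parent B.
* **Orientate** — the end matching the configured `lower_parent` sits at
  the lower pan coordinate. The published coordinate rule has the
  Ler-matching (parent-B) read lower, which is the default; the prose
  descriptions of the same filter in terms of centromere-proximal/distal
  matches are orientation-dependent and conflict between sections, so the
  coordinate rule is taken as operative and the parent is a configuration
  option rather than hard-coded.
* **Strand** — the two ends lie on opposite strands.

Survivors are crossover read pairs. Their *breakpoint span* is the open pan
interval between the inner ends of the two reads — the only region in
which the breakpoint can lie given that both reads matched their templates
exactly — and a configuration switch (`span = "fragment"`) scores the full
outer footprint instead. `accumulate_coverage()` adds 1 over each span,
`normalize_profile()` divides by the number of crossover pairs and weights
by the amplicon cM, making profiles comparable across genotypes and
library sizes. When libraries of different depth are combined, raw reads
are pooled before normalization.

# Windowed divergence analysis

`window_counts()` cuts the panmolecule into adjacent windows (defaults: 500
bp for Sanger-interval analyses, 250 bp for sequencing profiles, both
arguments). A crossover whose breakpoint interval straddles a window
boundary is split proportionally to the overlap — two crossovers in a 150
bp interval with 50 bp in one window contribute 2×(50/150) = 0.67 there
and 1.33 next door — so window totals conserve the crossover count
exactly. Polymorphism weights count SNPs as 1 and indels by their bp
overlap with the window. The final window is usually shorter than the
rest; it is flagged and excluded from correlations and fits but still
receives values so totals are conserved. `percent_normalize()` rescales
the included windows to percentages for cross-hybrid overlays, and
cross-hybrid comparisons against one parent's reference coordinates are
supported by `project_interval_to_parent()`.

The divergence–crossover relationship is modelled as

    y = log(a) + b · x^(−c),   a > 0, c > 0

with y the per-window crossover value and x the polymorphism weight.
`fit_divergence_model()` uses bounded nonlinear least squares
(Levenberg–Marquardt) with a deterministic multi-start grid (a ∈ {0.1, 1,
10}, b ∈ {0.1, 1, 10, 100}, c ∈ {0.25, 0.5, 1, 2}); the best converged
start by residual sum of squares is kept, so results are reproducible.
Numerical properties worth knowing:

* Windows with zero polymorphism weight are excluded (x^(−c) is undefined
  at 0) rather than pseudocounted, and their count is reported. The loci
  this model was built for have no such windows, so behaviour there is
  a free choice.
* A flat response (b = 0) leaves c unidentifiable; this is detected and
  reported (`c_identifiable = FALSE`) instead of returning an arbitrary c.
* The model has a soft identifiability ridge: as c → 0 and a → 0,
  log(a) + b·x^(−c) approaches a function linear in log x, so weakly
  curved, noisy data can push a to its lower bound while the fitted curve
  itself remains sensible. Interpret (a, b, c) jointly, not separately,
  when the fit sits at a bound.

`spearman_windows()` reports the rank correlation (mid-ranks for ties,
two-sided asymptotic p) used to test the negative
polymorphism–crossover relationship.

# The synthetic-data generator

Every input the pipeline consumes can be generated with known ground
truth, fully deterministic under a seed. The defaults emulate the measured
experiment:

* amplicon of 9,482 bp (parent A) — the size of the larger assayed locus;
* SNP rate 0.0274/bp, the interhomolog density observed there (the second
  locus runs at 34.5/kb; both loci sit far above the 3.85/kb genome
  average);
* indel events at 0.004/bp with geometric lengths of mean 8 bp, giving a
  few hundred inserted/deleted bases over the amplicon, matching the
  worked example's 195 + 100 inserted bases over ~5.4 kb;
* sonication fragments uniform on 300–400 bp (the gel size-selection
  window approximated by hard bounds), 2×75 bp reads;
* sequencing error off by default, so exact-match classification is
  lossless; an error rate can be switched on to study robustness (reads
  with errors simply fail exact matching — errors cost mappability, never
  create false crossovers).

Generated breakpoints are placed in the gaps between polymorphisms — the
resolution at which breakpoints are observable — and only within the
SNP-bracketed region, mirroring the allele-specific amplification that
selects recombinants between genotypable sites. Each recombinant molecule
is the parent-A sequence left of its breakpoint joined to the parent-B
sequence right of it, so it carries exactly one genotype transition. The
landscape over gaps is configurable: uniform, an explicit weight table, or
the inverse-divergence model itself (intensity `log(a) + b·x^(−c)` with x
the polymorphism weight in a surrounding window, floored at 0).

Two generator details exist purely to make ground truth exact. First, the
generator builds the true panmolecule directly from its edit list, without
alignment, so aligner output can be scored against an independent truth.
Second, indels are emitted in canonical rightmost form (the first inserted
or deleted base is forced to differ from the base following the run):
without this, an indel whose boundary base coincides with its neighbour
can slide without changing the alignment score, and the optimal alignment
— though correct — would differ from the recorded truth.

What the generator does *not* emulate: PCR chimeras and polymerase errors,
quality-score structure, biased sonication, primer failure, and
gene-conversion tracts (no multi-transition molecules are generated). Tests
passing on synthetic data therefore demonstrate the correctness of the
coordinate arithmetic, estimators and filters under the stated model, not
robustness to these artefacts.

# Verification strategy and problem sizes

The test suite checks each operation against independent oracles: the
aligner against exhaustive enumeration of all alignments (tiny sequences)
and against an independent alignment implementation (long pairs); exact
matching against a naive substring scan; the titration estimator against
repeated simulation (bias under 2%, nominal-interval coverage at least
90%); and the model fit against data generated from the model (noiseless
recovery to 1e-4 relative error; under Gaussian noise of σ = 0.1 the
median relative parameter error over 200 replicates is required to stay
under 15%, a tolerance fixed when the check was designed). End-to-end
properties run at 10⁴ read pairs, 10³ molecules and 10⁴ titration
reactions — sizes chosen so the whole suite completes in about a minute
while keeping the binomial/Poisson noise far below the tested margins.

# Known limitations

* Exactly two haplotypes; no multi-parent panmolecules or pangenome
  graphs.
* Exact-match read classification only — by design, since the filter
  cascade is defined by it; there is no mismatch-tolerant mode.
* The χ² comparison uses integer-rounded per-volume means; with very small
  crossover concentrations the rounded counts carry little power, which is
  a property of the published test, not of the implementation.
* The open-span interval-length convention (bases strictly between
  flanking markers) matches the published worked examples, but tables
  produced under a closed convention would differ by 1–2 bp per interval.
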