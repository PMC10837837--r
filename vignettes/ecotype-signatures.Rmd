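---
title: "Delineating poly-extremophile ecotypes from genomic and structural signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating poly-extremophile ecotypes from genomic and structural signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosig)
library(dplyr)
```

## The problem

Some bacterial genera span wildly different habitats — glacial permafrost,
temperate soil, saline lakes, hydrothermal vents — with clades of very close
relatives adapted to opposite physico-chemical extremes. `ecosig` implements a
reverse-ecology workflow for such genera: given genome assemblies with
annotations, proteomes, protein structures and a clade assignment, it asks
*which measurable features separate the ecotypes*, at four levels:

1. **Genome scale** — size, coding density, GC content (whole genome and per
   codon position), codon usage, CRISPR counts, plus the assembly-quality
   gate and average-amino-acid-identity (AAI) deduplication that define the
   analysis set in the first place.
2. **Regulatory elements** — GC of rRNA and tmRNA genes, AT content of
   predicted promoters, counts of insertion sequences, sRNAs and operons.
   These are consumed as annotation features; the predictors themselves
   (promoter/IS/sRNA/operon callers) are out of scope.
3. **Proteome composition** — amino-acid frequencies, isoelectric point,
   GRAVY hydropathy, composition ratios (Lys/Arg, Glu/Asp, Asn/Gln), and
   family-level conservation from greedy centroid clustering.
4. **Protein structure** — solvent accessibility and the core/surface
   partition, three-state secondary structure, six classes of
   residue–residue interactions, and aggregation of externally computed
   per-residue stability scores.

A contrast engine turns any of these feature tables into a signature report:
for an ordered set of clade contrasts (by default psychrophilic Ib vs. Ia,
halophilic IIa vs. Ia, thermophilic IIb vs. IIa) it computes clade means, the
percentage difference `d = 100 (mean_target − mean_ref)/mean_ref`, a
two-sample test, significance stars, and an arrow class.

Because the interesting claims are comparative ("surface aspartate is ~10%
enriched in the halophilic clade"), every stage is paired with a seeded
synthetic-data generator that *plants* such signatures with machine-readable
truth, so the whole pipeline is testable without downloading a single genome.

## The contrast model

For a feature `f`, a target clade `T` and reference clade `R`:

* `d(f) = 100 · (mean_T − mean_R) / mean_R` (missing when `mean_R = 0`);
* a two-sided test p-value: Wilcoxon rank-sum for per-isolate features
  (clades have unequal sizes, so the unpaired test is the only option),
  two-sample Kolmogorov–Smirnov for per-protein features (large n);
* stars: `ns` for p > .05, then `*`, `**`, `***` at .05, .01, .001;
* arrows: `-` unless p ≤ .05 **and** |d| ≥ 1; `↑`/`↓` for 1 ≤ |d| < 5;
  `↑↑`/`↓↓` for |d| ≥ 5. Both band edges are closed (|d| = 5 maps to the
  double arrow, |d| = 1 to the single one): the verbal rule "more than 5%"
  leaves the boundary undefined, and a closed outer interval makes the
  mapping deterministic.
* Benjamini–Hochberg adjusted p-values are reported in an extra column but
  arrows and stars use the raw p, matching the way such panels are usually
  published; readers can re-threshold on `p_adj`.

```{r contrast-demo}
sim <- make_protein_families(seed = 1)
scheme <- clade_scheme(distinct(sim$proteins, isolate_id, clade))
report <- run_contrasts(stratum_frequencies(sim, "surface"), scheme, test = "ks")
tidy(report) |> filter(feature %in% c("D", "E", "K")) |>
  select(label, feature, d, p_value, arrow)
```

## Statistical choices

**Test unit.** KS contrasts default to per-protein values (n in the
hundreds), which is what produces the very small p-values typical of
proteome-wide comparisons; rank-sum contrasts operate on per-isolate values
(n per clade in the tens at most). Both units are available; which one a
feature table uses is the caller's choice via `test =`.

**Small samples.** `rank_contrast()` uses exact enumeration when both groups
have ≤ 8 tie-free observations, otherwise the normal approximation with tie
and continuity correction. `ks_contrast()` uses the asymptotic p-value at
≥ 50 observations per side, the exact distribution below that when the data
are tie-free, and a seeded 10,000-permutation p-value under ties.

**Size calibration.** The test suite verifies empirical type-I error in
[0.035, 0.065] at α = .05 over 2,000 null replicates — for the rank-sum test
at n = 15 per side, and for KS at n = 39 per side. The KS size matters: the
two-sample KS statistic is discrete, and at very small equal sizes its null
distribution can have *no attainable level* anywhere near .05 (at 15 vs. 15
the levels bracketing .05 are 0.076 and 0.026; no valid p-value, exact or
permutation, can land between them). At 39 vs. 39 the attainable level just
below .05 is 0.0493, so the nominal size is meaningful there.

**Ordination.** Non-metric multidimensional scaling is delegated to
`vegan::metaMDS` (Kruskal stress-1, monotone regression, 10 seeded random
restarts by default) on Bray–Curtis or Euclidean distances; coordinates are
centred. All-identical rows are rejected as degenerate rather than embedded.

## Structure-level definitions

**SASA.** Shrake–Rupley point sampling with a 1.4 Å probe and 960
quasi-uniform (Fibonacci lattice) points per atom; van der Waals radii
C 1.70, N 1.55, O 1.52, S 1.80 Å; hydrogens ignored. A sample point exactly
on another atom's expanded sphere counts as exposed (strict inequality for
burial), which makes boundary behaviour deterministic. The engine reproduces
the closed-form sphere area exactly for an isolated atom and the analytic
two-sphere cap overlap to < 1%; per-residue values change by < 3% between
240 and 960 points on extended-peptide fixtures.

**Relative accessibility.** `RSA = SASA / maxASA(residue type)`, where the
reference maxASA is computed *by the same engine* on extended
(φ = ψ = 180°) Gly-X-Gly tripeptides built from ideal geometry — not taken
from a literature table — so that RSA = 1 is self-consistent by
construction. Core means RSA ≤ 0.20 (boundary inclusive, with a 10⁻⁹
floating-point tolerance); surface means RSA > 0.20.

**Secondary structure.** Torsion-window assignment, chosen over
hydrogen-bond energies because it needs no hydrogen placement: helix
candidates have φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]; strand candidates
φ ∈ [−180°, −90°] with ψ ∈ [90°, 180°] or [−180°, −170°]. Runs of ≥ 4 helix
candidates become H, runs of ≥ 3 strand candidates become E, everything else
(including termini lacking a full torsion) is loop C. CA–CA distances above
4.5 Å split runs. Window edges and run lengths are arguments; borderline
residues may differ from assigners based on hydrogen-bond energetics.

**Interactions.** Six classes with inclusive distance criteria
(hydrophobic ≤ 5.0 Å between side-chain carbons of
Ala/Val/Leu/Ile/Met/Phe/Trp/Pro/Tyr; ionic ≤ 6.0 Å between cationic and
anionic group centroids, His counting as cationic; aromatic–aromatic ring
centroids within 4.5–7.0 Å; aromatic–sulfur ≤ 5.3 Å; cation–π ≤ 6.0 Å;
disulfide SG–SG ≤ 2.2 Å), sequence separation |i−j| ≥ 2 except disulfides,
one contact per residue pair per class at the closest qualifying distance.
All thresholds are configuration keys (`interaction_thresholds()`) so other
tools' defaults can be matched. Interaction *density* is contacts per
residue; clade averages are unweighted over proteins.

**Stability scores.** Per-residue stability contributions (kcal/mol,
negative = stabilising) are consumed from an external table, averaged per
protein and per clade, with percentage change against the reference clade;
their computation (statistical potentials) is out of scope.

## What the generators emulate — and what they do not

The generators are first-class, tested code, and their defaults are the
study conditions used throughout the test suite and the acceptance script.

`make_clade_genomes()` builds four clades × 6 isolates of 100 kb genomes
(2 contigs) with planted genome GC (0.470/0.473/0.520/0.480), tmRNA GC
offset −0.05 in the three extremophilic clades, promoter AT 0.68 in the
psychrophile vs. 0.62 elsewhere, raised insertion-sequence and operon counts
in the extremophiles, raised sRNA counts in the psychrophile, and habitat
metadata centred exactly on MAT 8.9/−1.6/12.1/45.5 °C and salinity
0.5/0.5/6/8% NaCl (clade I < 1%, clade II > 5%). Feature counts are Poisson
at the planted means; per-isolate MAT/salinity jitter is mean-centred so
clade means equal the planted values exactly.

`make_protein_families()` builds 20 families × 10 members in each of the
four clades (200 proteins per clade), length 300 with half the positions
designated surface, within-family pairwise identity 0.80 ± 0.08, and
surface-restricted composition shifts: Lys ×1.08 in the psychrophile,
Asp ×1.10 and Glu ×1.10 in the halophile, and Asp ×1.10 / Glu ×1.21 in the
thermophile so its Glu/Asp ratio sits ~10% above its reference clade.

Two generator design points deserve emphasis:

* **The substitution rate is derived, not 1 − identity.** Members are
  derived from a shared ancestor; two members that each differ from the
  ancestor at rate *s* agree at only ≈ (1−s)² + coincidences. Planting a
  *pairwise* identity of 0.80 therefore requires s ≈ 0.11, solved from the
  coincidence-corrected quadratic, not s = 0.20.
* **Composition is variance-controlled.** Ancestors and substitution fills
  are exact-count multisets with randomised systematic rounding
  (expectation exactly n·p, each count within 1 of it), and substitution
  positions are chosen so the retained ancestor residues never exceed the
  member's target counts. Every member then carries its clade's planted
  composition up to integer rounding, and a planted +10% shift is recovered
  within ±1–2 points at 200 proteins per clade. Under a plain i.i.d.
  substitution model the sampling noise of `d` alone is several percent and
  small planted shifts would be unrecoverable at desk scale. The flip side
  is a granularity floor: for the rarest residues (expected surface count
  below ~3 per protein, e.g. Cys or Trp) integer occupancy makes the null
  `d` noise itself ~3%, which the null-recovery tests account for.

What the generators do **not** emulate: phylogenetic correlation between
isolates (sequences are exchangeable within a clade), gene content
differences between clades, indels (families are gap-free, so clustering
coverage is exercised separately), realistic chromosome organisation, or
structure beyond idealised backbone geometry with simplified side chains
(side chains carry exactly the functional-group atoms the interaction
detector consults, placed at idealised positions — no rotamers, no packing).
A green suite therefore shows that the *measurements and statistics* are
correct and well-calibrated on data with known truth; it does not certify
biological conclusions on real genomes, where confounding between phylogeny
and habitat is the dominant inferential risk.

## Other conventions and degenerate inputs

* Annotations are stored 1-based inclusive end-to-end (the GFF3 and
  Bioconductor convention); minus-strand features are reverse-complemented
  on extraction, which leaves GC invariant but matters for codon-position
  statistics.
* Ambiguity codes are retained in storage; every statistic excludes them
  from both numerator and denominator and returns an explicit `NA` (never a
  silent zero) when nothing is countable.
* The assembly QC gate combines its four criteria (≤ 300 contigs,
  N50 ≥ 20 kb, completeness ≥ 95%, contamination ≤ 5%) with OR — any
  violation removes the genome — and a missing metric fails with its own
  reason. Relaxing any threshold can only turn failures into passes.
* AAI deduplication builds a graph at the 99.5% threshold and keeps one
  representative per connected component (higher completeness, then lower
  contamination, then lexicographic id), so the result is independent of
  input order and idempotent.
* Family clustering uses greedy centroid assignment over length-sorted
  input with explicit scoring (match +1, mismatch 0, gap open −10, gap
  extend −0.5); identity is identical columns over the alignment length
  excluding terminal gaps, coverage is the aligned span over the shorter
  sequence. These conventions follow common clustering practice; the
  external tools they stand in for document only the two cut-offs.
* The isoelectric point solves the Henderson–Hasselbalch net charge by
  bisection on pH ∈ [0, 14] to |Q| < 10⁻⁴; the pKa set (EMBOSS-style) and
  the Kyte–Doolittle hydropathy scale ship as versioned CSV tables, never
  hard-coded.
* Interaction and region boundaries carry a 10⁻⁹ tolerance so fixtures
  placed exactly at a criterion classify per the inclusive rule rather than
  by floating-point luck.

## Problem sizes

The default test and acceptance workloads are deliberately desk-scale: 24
genomes of 100 kb, 800 proteins of length 300, structures of a few dozen
residues, 2,000-replicate null calibrations, 10⁵-sample Monte-Carlo SASA
oracles on 50-atom clusters. These sizes concentrate the planted signals
well inside their recovery tolerances while keeping a full run in minutes.

## Reproducing the report

```{r pipeline, eval = FALSE}
gs <- make_clade_genomes(seed = 1)
reg <- bind_rows(lapply(names(gs$genomes), function(iso) {
  regulatory_features(gs$genomes[[iso]], gs$annotations[[iso]], iso)
}))
habitat_summary(gs$metadata)$subclades
```

`scripts/acceptance.R --seed <s> --out <path>` runs this end to end and
writes the headline quantities as JSON; the README shows a worked example.
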