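# ecosig

Comparative genomic and structural signatures of poly-extremophile ecotypes.

Some bacterial genera harbour closely related clades adapted to opposite
extremes — subzero permafrost next to hydrothermal brines. `ecosig` is a
reverse-ecology toolkit for delineating such ecotypes: it contrasts clades of
a pangenome across four feature levels (genome, regulatory elements, proteome
composition, protein structure) and reports, per contrast and feature, the
percentage difference, a significance test and a discrete arrow class. It is
aimed at comparative microbial genomicists who have assemblies, annotations,
proteomes and (optionally) structural models in hand and want calibrated,
reproducible clade contrasts.

## The core model

For each ordered contrast (target clade *T*, reference clade *R*; by default
psychrophilic Ib vs Ia, halophilic IIa vs Ia, thermophilic IIb vs IIa) and
each feature *f*:

```
d(f) = 100 · (mean_T(f) − mean_R(f)) / mean_R(f)
```

with a two-sided Wilcoxon rank-sum test (per-isolate features) or two-sample
Kolmogorov–Smirnov test (per-protein features), significance stars
(`*`, `**`, `***` at p ≤ .05/.01/.001), and arrows: `−` unless p ≤ .05 and
|d| ≥ 1; single arrow for 1 ≤ |d| < 5; double arrow for |d| ≥ 5, in the sign
of d.

Upstream of the contrasts the package computes, among others: genome GC and
per-codon-position GC, codon usage and RSCU, N50 and the assembly QC gate
(≤ 300 contigs, N50 ≥ 20 kb, completeness ≥ 95%, contamination ≤ 5%), AAI
deduplication at 99.5%, rRNA/tmRNA GC and promoter AT, amino-acid
frequencies, GRAVY, isoelectric points, greedy protein-family clustering
(identity 0.50 / coverage 0.80) with within-family identity, Shrake–Rupley
solvent accessibility with the core/surface rule (RSA ≤ 20% against extended
Gly-X-Gly references), torsion-window secondary structure, and six classes of
residue–residue interactions. Seeded generators plant all of these signatures
in synthetic data with machine-readable truth.

## Worked example

Generate the synthetic study conditions (four clades, 200 proteins each,
surface-restricted planted shifts), run the surface-stratum composition
contrasts, and read the report:

```r
library(ecosig)
library(dplyr)

sim    <- make_protein_families(seed = 1)
scheme <- clade_scheme(distinct(sim$proteins, isolate_id, clade))
report <- run_contrasts(stratum_frequencies(sim, "surface"), scheme, test = "ks")

tidy(report) |> filter(feature %in% c("D", "E", "K")) |>
  select(label, feature, d, p_value, star, arrow)
#> # A tibble: 9 × 6
#>   label         feature      d p_value star  arrow
#>   <chr>         <chr>    <dbl>   <dbl> <chr> <chr>
#> 1 halophilic    D        9.88   0      ***   ↑↑
#> 2 halophilic    E       10.00   0      ***   ↑↑
#> 3 halophilic    K       -1.41   0.0879 ns    -
#> 4 psychrophilic D       -0.371  1.000  ns    -
#> 5 psychrophilic E       -0.437  0.997  ns    -
#> 6 psychrophilic K        7.91   0      ***   ↑↑
#> 7 thermophilic  D        0.450  0.997  ns    -
#> 8 thermophilic  E        9.79   0      ***   ↑↑
#> 9 thermophilic  K       -1.03   0.393  ns    -
```

The generator planted Asp/Glu ×1.10 on surface positions of the halophilic
clade, Lys ×1.08 in the psychrophile and a Glu/Asp tilt in the thermophile —
the report recovers each planted shift at its planted size with a double
arrow, and leaves the unshifted amino acids flat. `glance(report)` summarises
per contrast; `autoplot(report)` draws the arrow/effect grid.

The genome-level pipeline works the same way:

```r
gs <- make_clade_genomes(seed = 1)
habitat_summary(gs$metadata)$subclades
#> # A tibble: 4 × 5
#>   clade mean_MAT n_MAT mean_salinity n_salinity
#>   <chr>    <dbl> <int>         <dbl>      <int>
#> 1 IIa       12.1     6           6            6
#> 2 IIb       45.5     6           8            6
#> 3 Ia         8.9     6           0.5          6
#> 4 Ib        -1.6     6           0.5          6
```

so the cold-adapted clade averages −1.6 °C at its isolation sites, the
thermophilic one 45.5 °C, and the two major clades separate cleanly in
salinity (< 1% vs > 5% NaCl m/v).

See `vignettes/ecotype-signatures.Rmd` for the model, the statistical
calibration, what the generators emulate (and do not), and numerical
conventions.

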