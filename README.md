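# diglyq

Quantitative analysis of diGLY (K-ε-GG) ubiquitylome experiments measured
by 11-plex TMT with MS3 reporter-ion quantification — the workflow used to
map ubiquitylation of neuronal mitochondria upon depolarization-induced
PINK1/Parkin activation. The package takes searched peptide-spectrum match
(PSM) tables through to regulated sites, their submitochondrial
classification, cross-species conservation, protein copy numbers and
absolute ubiquitin chain-linkage amounts, and ships a synthetic-data
generator with planted ground truth so every stage can be validated and
calibrated.

## What it computes

* **PSM processing** — quality filters (isolation specificity ≥ 0.7,
  summed reporter S/N ≥ 150, MS3 present, charge 3–6 in diGLY mode),
  target-decoy FDR thresholding at PSM/peptide/protein level, binomial
  site-localization scores (`ascore`, −10·log₁₀ P(X ≥ k), threshold 13 ↔
  95% confidence), parsimonious protein grouping, and aggregation of
  reporter S/N and MS1 intensity to protein sites.
* **Normalization and abundance** — equal-loading channel normalization of
  the total proteome, site-to-protein ratio normalization, median
  centering, MS1-apportionment site ranking
  A(s,c) = MS1(s)·SN(s,c)/ΣcSN(s,c), and histone proteomic-ruler copy
  numbers copiesᵢ = Iᵢ·N_A·m_DNA/(MWᵢ·Σ_h I_h).
* **Differential statistics** — the S0-modified Welch statistic
  d = (x̄−ȳ)/(s_Welch + S0) with permutation-based FDR control
  (S0 = 2, FDR 1% for site volcanoes; S0 = 1 for genotype comparisons;
  S0 = 0.585, 5% for proteomes), and a moderated-t / Benjamini-Hochberg
  route via limma.
* **Annotation & conservation** — MitoCarta-style subcompartment
  annotation (MOM/MIM/Matrix/IMS/Membrane/unknown) and cross-species site
  mapping by global alignment (BLOSUM62, affine gaps), counting a site as
  conserved when the aligned position is lysine in both orthologs and both
  sites pass log₂ > 1.0, p < 0.05 (strict).
* **UB-AQUA** — absolute quantification from heavy-reference peptides
  (fmol = light/heavy × spike), total ubiquitin as the mean over locus
  peptides, phospho-Ser65 stoichiometry phospho/(phospho+unmodified), and
  per-locus fold changes.

## Worked example

```r
library(diglyq)

sim <- simulate_experiment(sim_config(seed = 1))       # 11-plex, 5 UT / 5 AO
bundle <- run_pipeline(sim$psms, sim$proteins, sim$channels,
                       annotation = sim$annotation,
                       s0 = 2, fdr_level = 0.01, n_permutations = 250, seed = 1)
bundle$log
#> # A tibble: 10 × 3
#>    stage                      n_in n_out
#>    <chr>                     <int> <int>
#>  1 filter_psms                 671   532
#>  2 target_decoy_fdr            532   422
#>  3 aggregate_to_sites          422   271
#>  ...
glance(bundle$diff_perm)
#> # A tibble: 1 × 7
#>   n_features n_significant  n_up n_down    s0 fdr_level n_permutations
#>        <int>         <int> <int>  <int> <dbl>     <dbl>          <int>
#> 1        271            24    24      0     2      0.01            250
```

The stage log shows how many records each step consumed and produced (no
silent drops). `glance()` summarizes the permutation test: with the default
simulation, ~10% of sites carry a planted 2–8-fold up-regulation on
depolarized (AO) channels and the significant calls are up-regulated, as
planted. `tidy(bundle$diff_perm)` gives per-site fold changes, modified
statistics and q values; `plot_volcano()`, `plot_rank_abundance()` and
`autoplot()` methods draw the standard displays;
`export_resource_tables(bundle, dir)` writes the filterable flat-file
tables (master site table, matrices, copy numbers, Venn summaries,
manifest).

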