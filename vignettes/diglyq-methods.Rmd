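---
title: "Methods: quantitative diGLY ubiquitylome analysis with diglyq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative diGLY ubiquitylome analysis with diglyq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diglyq)
```

## The analysis problem

Ubiquitylation leaves a Gly-Gly remnant (+114.0429 Da) on the modified
lysine after tryptic digestion. Enriching diGLY-bearing peptides and
quantifying them across an 11-plex TMT experiment with MS3 reporter-ion
readout yields a site-level picture of a ubiquitylome — here, the
ubiquitylome of neuronal mitochondria before and after depolarization,
which activates the PINK1/Parkin pathway on the outer mitochondrial
membrane. `diglyq` implements the full downstream analysis: from searched
peptide-spectrum match (PSM) tables to differentially regulated sites,
submitochondrial classification, cross-species site conservation, absolute
copy numbers, and absolute ubiquitin chain-linkage quantification.

The pipeline consumes *already searched* PSM tables; database searching,
spectrum processing and chromatographic peak integration are out of scope.

## PSM processing

**Quality filters.** A PSM enters quantification only if its MS3 isolation
specificity is at least 0.7, its summed reporter signal-to-noise is at
least 150, an MS3 spectrum was acquired, and — in diGLY mode — the
precursor charge lies in [3, 6]. The protocol states these exclusions as
strict "less than", so boundary values are kept. `filter_psms()` records
every exclusion reason per record; filtering is idempotent.

**Target-decoy FDR.** Search-score thresholding against reversed-sequence
decoys: records are ranked by score and the largest prefix with estimated
FDR (decoys above cutoff / targets above cutoff) at or below the level
(default 1%) is kept, at PSM, peptide or protein granularity (groups scored
by their best PSM). The published workflow rescored PSMs with a linear
discriminant over several search features before thresholding; the
discriminant's training data and weights are not available, so `diglyq`
thresholds on the single search score. The 1% FDR contract — the part that
determines what enters quantification — is preserved.

**Site localization.** The binomial localization score
$-10\log_{10} P(X \ge k)$, $X \sim \mathrm{Binomial}(n, p)$, over $n$
site-determining ions of which $k$ matched at chance probability $p$. A
score of 13 corresponds to 95% confidence ($-10\log_{10} 0.05 = 13.0$).
Because spectra are out of scope, the peak-depth optimization of the
original algorithm is reduced to a caller-supplied $p$; the binomial core
and the 13 ↔ 95% anchor are exact. PSMs scoring below 13 are excluded from
site quantification and reported separately — the source protocol does not
state how sub-threshold PSMs are handled, so exclusion is this package's
choice, flagged rather than silent.

**Parsimony and aggregation.** Protein groups are formed by greedy set
cover (ties broken lexicographically), the standard approximation to the
smallest protein set explaining all peptides. Site quantification sums
per-channel reporter signal-to-noise and MS1 precursor intensity over all
PSMs supporting the same (protein, site); peptide-to-protein coordinates
come from exact substring search (first occurrence, with a warning on
ambiguity). Site coordinates are 1-based residue indices in the protein
("K122" style).

## Normalization

* `equal_loading_normalize()` rescales each channel of the *total
  proteome* matrix so all column sums equal the mean of the original sums
  (equal-loading assumption). The target is the mean rather than an
  arbitrary constant so magnitudes stay interpretable; any common target
  is equivalent up to a constant. This correction is **not** applied to the
  diGLY site matrix, whose column sums carry real regulation: applying it
  there demonstrably biases planted effects downward (the depolarized
  channels' sums are inflated by genuine up-regulation).
* `normalize_site_to_protein()` divides each site's channel values by its
  parent protein's, when the protein was quantified in the parallel total
  proteome; orphan sites pass through flagged `normalized = FALSE`
  (the "not determined" squares of the published volcano plots).
* `median_center()` subtracts per-channel medians on the log scale. It
  feeds the moderated-t route only. With one-sided regulation (many more
  up- than down-regulated sites) the contaminated channels' medians shift,
  so centering before the permutation test would bias fold-change
  estimates; the permutation route therefore tests protein-normalized log
  ratios directly.

**Site ranking.** The absolute-scale site metric apportions each site's
total MS1 intensity across channels by reporter share:
$A(s,c) = \mathrm{MS1}(s)\, \mathrm{SN}(s,c) / \sum_c \mathrm{SN}(s,c)$.
The source prose ("divided the total MS1 abundance … by their respective
TMT summed signal-to-noise to each TMT channel") is ambiguous between
division and apportionment; apportionment is implemented because it
conserves total MS1 mass per site ($\sum_c A(s,c) = \mathrm{MS1}(s)$) and
matches the stated intent that MS1 abundance represents the sum of all
TMT-labeled copies of a peptide. The channel group defining a published
ranking (untreated vs depolarized) is likewise unstated; the function
exposes the choice.

**Copy numbers.** The histone proteomic ruler anchors summed MS intensity
to histone signal, which scales with DNA mass:
$m_\mathrm{DNA} = \mathrm{ploidy} \times \mathrm{genome\ size} \times
615.8771 / N_A$ grams per cell, and
$\mathrm{copies}_i = I_i N_A m_\mathrm{DNA} / (\mathrm{MW}_i \sum_h I_h)$.
Mean base-pair mass 615.8771 g/mol and a 1:1 histone:DNA mass ratio follow
the ruler method; defaults are mouse (ploidy 2, 2.7 Gbp), all overridable.
The estimate is invariant to global intensity rescaling and linear in
ploidy.

## Differential statistics

Two routes, as in the study.

**S0-modified Welch statistic with permutation FDR** (the volcano-plot
route). Per feature, $d = (\bar{x}-\bar{y}) / (s_\mathrm{Welch} + S_0)$
with $s_\mathrm{Welch} = \sqrt{s_1^2/n_1 + s_2^2/n_2}$. The figure
captions name $S_0$ without a formula; the significance-analysis
convention (fudge constant added to the standard error) is used, which
damps features whose tiny variance would otherwise make trivial fold
changes significant. Published settings: $S_0 = 2$ at 1% FDR for diGLY
site volcanoes, $S_0 = 1$ at 1% for the genotype comparison, $S_0 = 0.585$
at 5% for the proteome.

The null is built by relabeling samples — the same permutation applied to
all features, preserving feature correlation. All distinct relabelings are
enumerated when their number is at most `n_permutations`; otherwise
distinct relabelings are sampled (excluding the observed labeling and, for
equal group sizes, its mirror — those are not null relabelings, and
including planted effects in the null destroys power). For threshold
$\tau$:
$\widehat{\mathrm{FDR}}(\tau) = \frac{\overline{\#\{|d_\mathrm{null}| \ge \tau\}}}
{\max(1, \#\{|d_\mathrm{obs}| \ge \tau\})}$,
with the add-one correction $(1 + \#)/(B + 1)$ on the null exceedance rate
when permutations are sampled, so the rate is never estimated as exactly
zero. A feature's q value is the minimum estimated FDR over thresholds at
or below its own $|d|$, making the significant set downward-closed in
$|d|$.

**Moderated t with Benjamini-Hochberg** (the searchable-database route).
Per-feature linear models with empirical-Bayes variance shrinkage
($\tilde{s}^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, moderated t on
$d_0 + d_g$ degrees of freedom), computed by limma; adjusted p values by
the step-up procedure. A test verifies the closed-form posterior update
independently given the estimated prior. Features are tested only when
each group retains at least two values; others are reported untested.

## Annotation, conservation, absolute quantification

**Subcompartments.** Sites join a MitoCarta-style table on gene symbol
(case-insensitive; gene-keyed because that is how such inventories are
distributed), with an empty synonym-map hook. Distributions are reported
on two denominators — all regulated sites, and mitochondrial sites only —
because published percentage statements do not always say which
normalization they use.

**Cross-species conservation.** The study compares regulated sites between
mouse cortical neurons and human iNeurons but does not describe its
site-matching procedure. The reproducible formalization implemented here:
global Needleman-Wunsch/Gotoh alignment (BLOSUM62, gap open 11 / extend 1,
a gap of length $L$ costing $\mathrm{open} + L\cdot\mathrm{extend}$;
delegated to Biostrings and verified against exhaustive path enumeration),
positional mapping through alignment columns, and a site counted as shared
only when the mapped position carries lysine in both orthologs. Site sets
are pre-filtered by the published criteria — strictly $\log_2 > 1.0$ and
$p < 0.05$; a value of exactly 1.0 is excluded. Proteins shared with
distinct sites are reported separately in the protein rollup, alongside
both pre- and post-exclusion counts.

**UB-AQUA.** Heavy-reference quantification:
$\mathrm{fmol} = (\mathrm{light\ area}/\mathrm{heavy\ area}) \times
\mathrm{spike}$. Total ubiquitin is the mean over the total-locus
peptides; phospho-Ser65 stoichiometry is
$\mathrm{phospho}/(\mathrm{phospho} + \mathrm{unmodified})$ at the locus,
with 0/0 reported not-determined ("n.d."), matching the published figure
annotations. Fold changes are on the fmol scale (the published ~52-fold
phospho-ubiquitin increase is not restated in methods as fmol or percent;
fmol is chosen and both inputs are exported). Replicates are summarized as
mean ± SEM. The peroxide oxidation-equalization step is chemistry, not
computation, and is not modeled.

## The synthetic-data generator

`simulate_experiment()` emulates the study design so that every pipeline
stage is exercised against planted truth:

* **Design**: 11 channels, default 5 untreated / 5 depolarized / 1 spare;
  the genotype design (WT 3+3, KO 3+2) is configuration.
* **Effects**: a configurable fraction of sites (default 10%) carries a
  multiplicative $2^{e}$ up-regulation on depolarized channels with $e$
  uniform on [1, 3] (2- to 8-fold, the published range of regulated MOM
  sites); 90% of responsive sites are silenced entirely (multiplier 1.0)
  in KO channels, mirroring the observation that loss of the kinase
  abolishes regulated sites.
* **Noise**: reporter signal-to-noise is true abundance times
  multiplicative log-normal noise (CV default 0.1). The instrument's true
  reporter noise model is not published; log-normal is a stand-in
  consistent with nonnegative S/N behavior, not an inference about the
  data.
* **Plumbing for every module**: decoy PSMs with a shifted score null so
  target-decoy FDR does real work; isolation specificity from a mixture
  putting ~7.5% of records below 0.7; MS1 intensity proportional to summed
  channel abundance; charge, MS3 and localization-score jitter so each
  filter excludes something; histone proteins whose total mass equals the
  DNA mass, making noise-free ruler recovery exact; responsive sites
  placed on MOM-annotated proteins; ortholog pairs with conserved lysines
  and recorded correspondence; AQUA tables with planted linkage amounts
  and stoichiometry.

What the generator does **not** emulate: raw spectra, chromatography,
isotope envelopes, reporter-ion isotope impurity, co-isolation structure,
missing-value mechanisms of real MS runs, or realistic peptide chemistry
(sequences are random). Passing tests therefore demonstrate the
correctness and calibration of the *computations*, not instrument-level
realism.

## Numerical and design choices

* Filter boundaries keep-if-≥ (0.7, 150); charge window inclusive.
* Target-decoy cutoffs are score values: tied scores are kept or dropped
  as a block.
* Alignment tie-breaks follow Biostrings' deterministic traceback; scores
  (the quantity all downstream logic uses) are verified optimal by brute
  force.
* Degenerate inputs fail loudly: zero column sums, missing histones,
  nonpositive molecular weights, zero heavy areas, empty compartment
  distributions are errors; zero AQUA baselines and 0/0 stoichiometries
  are "n.d.", not exceptions.
* Simulation sizes in the routine test suite (up to 1000 features, 250
  permutations, 10-20 replicate simulations) were chosen as the smallest
  sizes at which calibration and recovery statements are statistically
  stable; the null-calibration check uses 100 simulations to stabilize the
  Monte Carlo estimate of mean realized FDP.

## Worked example

```{r, eval = FALSE}
sim <- simulate_experiment(sim_config(seed = 1))
bundle <- run_pipeline(sim$psms, sim$proteins, sim$channels,
                       annotation = sim$annotation, s0 = 2,
                       fdr_level = 0.01, n_permutations = 250, seed = 1)
glance(bundle$diff_perm)
compartment_distribution(
  dplyr::filter(bundle$annotated, significant), direction = "up")
plot_volcano(bundle$diff_perm)
export_resource_tables(bundle, "results/")
```

## Known limitations

* Single-score target-decoy thresholding is simpler than the published
  discriminant rescoring; with a single well-separated score the kept set
  is comparable, but borderline PSMs may differ.
* The localization score does not optimize over peak depths (no spectra).
* No isotope-impurity correction of reporter channels, no isoform
  resolution, no ortholog inference (pairing is an input), no enrichment
  analysis, and no multi-factor designs in the moderated route.
* Headline dataset counts of the motivating study (thousands of sites,
  hundreds regulated) derive from raw MS data that are not re-analyzable
  here; the package reproduces the *methods* and verifies them on
  synthetic data and analytic anchors, not those counts.
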