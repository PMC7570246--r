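---
title: "Methods: scoring, diversity and differentiation of MSAP/TMD band profiles"
author: "epidiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, diversity and differentiation of MSAP/TMD band profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidiv)
```

## The measurement model

Methylation-sensitive amplified polymorphism (MSAP) profiles a plant's CCGG
methylation landscape by digesting genomic DNA in parallel with two
isoschizomer combinations — MseI/MspI (the "M" digest, insensitive to
internal cytosine methylation) and MseI/HpaII (the "H" digest, blocked by
it) — and scoring each amplified locus as band present (1) or absent (0) in
each digest. Transposon methylation display (TMD) is the same assay anchored
at a retroelement-specific primer, so its loci sample hypermethylated
repetitive neighbourhoods. The joint (M, H) pattern at a locus defines four
band types:

| type | M | H | interpretation |
|------|---|---|----------------|
| I    | 1 | 1 | non-methylated |
| II   | 1 | 0 | fully (internally) methylated |
| III  | 0 | 1 | hemi-methylated |
| IV   | 0 | 0 | no band in either digest |

Pooled over the samples of a group, the counts (I, II, III, IV) give the
rate statistics: total methylated = (II + III + IV)/total,
fully methylated = II/total, hemi-methylated = III/total, non-methylated =
I/total (all x 100). Type IV is conventionally folded into "methylated",
although an absent band can equally reflect restriction-site sequence
mutation; `methylation_rates()` therefore also reports the type-IV share on
its own so users can judge its weight. Indistinct bands are missing calls
(`NA`): they are excluded from counting, and distances use pairwise deletion
with rescaling to the full band count.

Two deliberate conventions:

* **Display rounding is half-up** (`round_half_up()`): 58.695 prints as
  58.70. Published methylation tables in this field round ties upward, and
  reproducing printed two-decimal tables exactly requires matching that.
  Internal values always keep full precision. The implementation snaps to 9
  decimals before applying the tie rule so that binary representation error
  (16.455 stored as 16.4549999...) cannot flip a tie.
* **Class contrasts average *reported* rates** (`rate_contrasts()`): a
  treatment class's mean rate is the unweighted mean of its member groups'
  rates after rounding to the 2 decimals at which such tables are reported.
  This is how published group averages are actually formed from their
  tables; averaging at full precision can differ by one unit in the last
  digit (the two conventions cannot both be matched — published averages
  themselves mix them — and we chose the one consistent with the majority).

## Diversity indices

Each band column (locus x digest) is a two-state dominant phenotype with
presence frequency p. We use the phenotype frequencies directly — Nei's gene
diversity H = 1 − p² − q², Shannon's information index
I = −p ln p − q ln q, effective allele number ne = 1/(p² + q²), biallelic
PIC = 1 − p² − q² − 2p²q² — with no Hardy–Weinberg back-transformation of
dominant genotypes. Under this model H ≤ 0.5, I ≤ ln 2, ne ≤ 2 and
PIC ≤ 0.375; selfing rice violates the equilibrium assumptions a dominant
back-transformation would need, and published H values for such data sit
inside the two-state range. Dominant-marker software that prints PIC above
0.375 is using an undocumented multi-allele formula; we report our formula's
definition in the output metadata rather than guessing at another one.
`diversity_summary()` reports means over all bands by default and over
polymorphic bands on request, since conventions differ between programs.

## Distances, ordination, Mantel

The default distance between two samples is the count of differing calls
over the concatenated M and H vectors — on binary data this *is* the squared
Euclidean distance, the convention dominant-marker AMOVA expects. A
`band_dist` matrix carries its metric, and every consumer honours it:
`pcoa()` and `amova()` use `squared_euclidean` entries as squared
dissimilarities directly and square other metrics first. PCoA is classical
scaling (Gower double-centering of −D²/2, eigendecomposition, coordinates
scaled by the square roots of positive eigenvalues); negative eigenvalues
are dropped with their magnitudes reported, and no Cailliez/Lingoes
correction is applied by default because the analyses this package mirrors
apply none. The Mantel statistic is the Pearson correlation of off-diagonal
entries with one-tailed (greater) permutation significance
p = (1 + #{r* ≥ r})/(B + 1); the permutation engine is vegan's, seeded for
reproducibility.

## AMOVA

`amova()` is the one-level dominant-marker decomposition: with N samples in
k groups and squared distances d²,
SS_total = Σ_{i<j} d²(i,j)/N, SS_within = Σ_g Σ_{i<j∈g} d²(i,j)/n_g,
SS_among by difference; df = (k − 1, N − k);
σ²_within = MS_within, σ²_among = (MS_among − MS_within)/n₀ with
n₀ = (N − Σn_g²/N)/(k − 1); PhiPT = σ²_among/(σ²_among + σ²_within).
Negative among-group components are truncated to zero before percentages
(standard practice), with the raw value retained in the result. The p-value
permutes whole samples among groups holding group sizes fixed and counts
permuted among-group components ≥ observed, using the *untruncated*
component on both sides so ties at zero are handled consistently. With 999
permutations the smallest attainable p is 0.001.

## Neighbor joining and delta-K

`neighbor_joining()` is the Saitou–Nei agglomeration with the standard
Q-criterion and branch-length split; ties in Q are broken by the lowest
(row, column) index so results are bit-reproducible across platforms, and a
negative branch length is clamped to zero with the deficit moved to its
sister branch (their sum, the joined distance, is preserved) and counted in
`attr(tree, "negative_clamped")`. The tree is returned as an `ape` `phylo`
object and built on *distances*, so the pipeline feeds it the square root
of the squared-Euclidean matrix. `delta_k()` post-processes a K × replicate
table of log Pr(X|K) values from an external Bayesian clustering run:
ΔK(K) = mean_r |L_r(K+1) − 2L_r(K) + L_r(K−1)| / sd_r L_r(K), undefined at
the boundary Ks and flagged (not infinite) where the replicate sd is zero.
The per-replicate second difference (rather than the second difference of
means) is used; the two agree in expectation and identically for
replicate-offset data. The clustering sampler itself is out of scope — any
program's log-probability table can be supplied.

## The simulator

`simulate_band_matrix()` generates the data-generating process the analyses
assume, for a design of an untreated control (n = 5), gamma-ray doses of
100/150/250 Gy (n = 8 each), two DNA-methyltransferase inhibitors (DNMTis)
at 80 µM (n = 8 each) and four combined treatments (n = 12 each) — 93
samples. Its components:

* **Baseline**: each locus draws a state I–IV from π, shared across samples
  (loci have identities); defaults are the control-group state proportions
  of the two assays (MSAP π = 0.413/0.131/0.191/0.265 over 102 loci; TMD
  π = 0.427/0.233/0.070/0.269 over 60 loci). Each sample redraws its state
  from π with probability ε (epimutation noise).
* **Dose response**: a treated sample demethylates each locus with
  probability p_dem = 1 − exp(−(β_γ·Gy + β_d·µM)·s^[both]) — bounded,
  monotone, one parameter per mutagen, with a multiplicative synergy factor
  s ≥ 1 applied only when both mutagens are present.
* **Transitions**: II → III with probability p_dem·α and II → I otherwise;
  III → I with p_dem; IV → III with p_dem·α (partial demethylation of dense
  regions). α near 1 is the repetitive-region regime in which full
  methylation converts to hemi (TMD default α = 0.8); α near 0 the
  euchromatic regime in which both decline (MSAP default α = 0.2).

Marginally the redraw noise leaves the state distribution at π, so
`expected_state_probs()` gives closed-form post-treatment expectations, and
`recover_parameters()` checks scored rates against them. Its standard error
uses the locus count as the effective sample size: baseline sharing
correlates samples within a locus, so n_loci bounds the information content
and the 3 SE band is conservative.

**Calibration of defaults.** The effect sizes and dispersion were chosen
once, jointly, so that the default design's among-class AMOVA variance lands
in the 20–40% band that dominant-marker studies of this kind report:
β_d = 10⁻² per µM, β_γ = 10⁻³ per Gy, s = 1.5, ε = 0.02 give ≈ 28% (MSAP)
and ≈ 30% (TMD) among classes, preserving the empirical ordering
MSAP < TMD. This is a deliberate trade-off: with per-sample Bernoulli
transition noise, effect sizes small enough to mimic published few-percent
rate reductions leave only ~5% of variance among classes at any ε — the
variance partition, not the rate scale, is the property the simulator is
calibrated to reproduce. What the simulator does *not* emulate: linkage or
genomic clustering of loci, correlated baselines between the MSAP and TMD
systems (they are simulated independently), scoring error beyond missing
calls, and survival censoring at high combined doses. Passing tests
therefore certify the statistical machinery, not fidelity to any particular
real dataset.

## Pipeline and reproducibility

`run_pipeline()` drives scoring, diversity, distances, AMOVA, PCoA, Mantel
(when both systems are present) and NJ from one configuration, writing CSV,
JSON and Newick outputs plus a manifest. A single global seed is fanned out
per stage through a fixed hash of the stage name, so adding a stage never
perturbs existing stages' randomness; two runs with one seed are
byte-identical in every numeric output (logs carry timestamps and are
excluded). Numeric CSVs are written at 12 significant digits.

Problem sizes used by the test suite were chosen to exercise each property
at the scale at which it is informative: exact-arithmetic table checks at
the published counts; oracle comparisons on 50 random instances of 5–12
samples (AMOVA) and 5–8 leaves (NJ); Mantel null calibration with 200
replicates of 999 permutations; and rate recovery with 10⁴ loci and 100
replicates.

## Worked example

```{r example}
sim <- simulate_band_matrix(sim_config("TMD", seed = 42))
m <- sim$matrix
m

methylation_rates(count_band_types(m, "treatment_class"))

res <- amova(band_distance(m), group_labels(m, "treatment_class"),
             n_permutations = 199, seed = 42)
res
```

## Known limitations

* Rates treat every (sample, locus) pair as exchangeable within a group;
  no per-sample rate intervals are provided.
* The AMOVA is one-level; hierarchical designs (groups within regions) are
  out of scope.
* PIC above the biallelic maximum, as printed by some dominant-marker
  programs, is not reproduced (formula unknown); our PIC is the biallelic
  definition and says so in the output.
* Mantel, PCoA and AMOVA all assume the squared-distance convention is
  carried by the input matrix; plain matrices without a `metric` attribute
  are treated as distances and squared.
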