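---
title: "Trait-based zooplankton community analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based zooplankton community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zooniche)
```

## The problem this package addresses

Estuarine zooplankton surveys produce long tables of per-sample,
per-species counts together with a species trait inventory. The questions
ecologists ask of such tables are remarkably standardised: which
trait-defined functional groups dominate where and when, how diverse and
even are the communities, how wide are the groups' realised niches and how
much do they overlap, and do the species co-occur more or less often than
independence would predict — the classical reading of competition versus
facilitation, and of community stability versus succession. `zooniche`
implements this whole chain as composable, tested operations, plus a
seeded synthetic-survey generator so that every stage can be validated
against known structure.

## The classification model

Species are mapped to functional groups from three traits: taxon class,
body size, and feeding habit.

* Rotifers split by habit: filter feeders (RF), carnivores (RC), and
  algivorous "predators" (RP).
* Copepods and cladocerans split by body-size class — small (< 0.7 mm),
  middle (0.7–1.5 mm), large (> 1.5 mm) — crossed with filter/carnivore
  habit: SCF, SCC, MCF, MCC, LCF, LCC. Both boundary values (0.7, 1.5)
  are assigned to the middle class; the printed class labels
  ("<0.7", "0.7~1.5", ">1.5") leave the boundaries ambiguous, and a
  closed middle interval is the convention that keeps the mapping total.
* Protozoans split by trophic mode: photosynthetic (PP), algivore (PA),
  bacterivore (PB), detritivore (PD), fungivore (PF), saprotroph (PS),
  raptorial (PR), nonselective omnivore (PN).
* Larvae and other taxa are excluded from group-level analysis — with one
  deliberate exception: a trait record flagged `nauplius` joins SCF.
  Survey practice consistently treats copepod nauplii as the main small
  filter feeders even while excluding other larvae, and the flag
  reproduces that usage while leaving the decision in the user's trait
  table. Heterotrophic bloom dinoflagellates (a *Noctiluca*-type taxon)
  are conventionally carried in PP; because assignment is entirely
  trait-table-driven, users who disagree simply edit one row.

Excluded mass is tracked per sample so that group totals plus excluded
mass always reconcile with the species matrix (relative tolerance 1e-9);
excluded species never enter group-level statistics, while species-level
diversity always uses all species.

## Metrics and their conventions

Abundance is `N = n / v` (individuals per m³). All logarithms are base 2,
following the classical marine-survey formulation: Shannon–Wiener
`H' = -Σ p_i log2 p_i` (bits), Margalef `d = (S - 1)/log2 N`, Pielou
`J' = H'/log2 S` (undefined — `NA`, never 0 — for S = 1), Simpson
`D = 1 - Σ p_i²`. Dominance is `Y = (n_i/N) f_i` with a **strict**
`Y > 0.02` rule: a tie at exactly 0.02 is not dominant. Proportions are
computed on volume-normalised abundance by default so unequal filtered
volumes are handled; a `use = "counts"` switch is exposed because survey
reports rarely state which was used. Bray–Curtis similarity
`1 - Σ|x-y|/Σ(x+y)` compares functional-group composition between pooled
stratum–season units.

## Niche breadth and overlap

Resource states are sampling units; an entity's profile is its abundance
distribution across states, normalised to sum to one. Levins' breadth
`B_i = 1/Σ P_ij²` runs from 1 (specialist) to r (uniform generalist).
The default overlap is `O_ik = 1 - ½ Σ|P_ij - P_kj|` — the
proportional-similarity (Schoener) form. The survey literature this
package follows frequently labels that formula "Pianka's index"; the two
are different statistics, and the package implements the formula as
printed while providing the true Pianka product-moment form behind
`method = "pianka"` for comparison. Overlap is computed on normalised
profiles because only proportions keep the statistic in [0, 1]. Pairs
with overlap strictly above 0.7 are reported as high-overlap pairs.

## Association statistics

On presence/absence over N sites: with occupancies `p_i` and per-site
richness `T_j`, the variance ratio is
`VR = S_T² / σ_T²`, where `σ_T² = Σ p_i(1 - p_i)` and
`S_T² = mean((T_j - mean T)²)`; `W = N · VR` is referred to χ²(N).
Two printing errors in the source formulation are corrected: the stray
exponent in "Σ p_i(1-p_i)²" (which would break the VR = 1 independence
null) and the duplicated definition of cell `b` in the 2×2 table
(standard convention used: `a` both, `b` first only, `c` second only,
`d` neither).

One deliberate deviation: the χ² bounds. The source prints
"W < χ²₀.₉₅(N) or W > χ²₀.₀₅(N) ⇒ p < 0.05", i.e. 5% in *each* tail —
a 10% two-sided test reported as 5%. Simulation confirms the printed
bounds reject ≈10% of independent communities. `zooniche` treats `alpha`
as the *total* two-sided size (bounds at α/2 and 1-α/2), which makes the
test honestly sized (empirically ≈0.047 at α = 0.05 under the null);
passing `alpha = 0.1` reproduces the printed bounds exactly.

Pairwise association uses the phi (point) correlation of binary patterns,
`(ad - bc)/√((a+b)(a+c)(b+d)(c+d))`, which equals the Pearson correlation
of the 0/1 vectors; degenerate marginals give `NA`, never ±Inf. The
pairwise significance rule — `N·Φ² > χ²_{1-α}(1 df)` — is a documented
package choice (the source never states one); it is the usual 2×2
chi-square with the sign taken from Φ. Φ = 0 is classed positive by
convention and flagged. The stability heuristic counts positive versus
negative pairs: more positive than negative reads as a stable community,
fewer as successional, a tie as indeterminate. Pearson pair summaries use
`log10(x + 1)` by default, the source's normalising transform.

## The synthetic-data generator: what it emulates

The generator's defaults state one world — a 5-estuary × 4-season ×
3-station survey (60 sampling units), 69 species in the ratio
19 rotifers : 19 copepods : 13 protozoans : 11 other taxa : 7
cladocerans, baseline occupancy 0.5, per-class lognormal abundances
(sdlog 1; location log 20–log 200 ind m⁻³, protozoans most numerous), a
June peak (seasonal multipliers 1, 3, 1.5, 0.6), and one September bloom
in the THK stratum driving the photosynthetic-protozoan group to 95% of
the community — the survey design and headline structure of the study
system it emulates. Occupancy 0.5 and the lognormal locations are the
package's own choices where no value was stated; 0.5 is the centre of
the range where presence data are most informative, and lognormal
abundance is the standard skewed community model.

Pairwise coupling is injected on presence (association statistics are
presence-based): the second member of a coupled pair copies (ρ > 0) or
negates (ρ < 0) the first with probability |ρ|, else draws independently.
At equal marginals this yields expected Φ = ρ exactly for ρ ≥ 0; the
negative branch is exact only at occupancy 0.5 and attenuates away from
it — a documented limitation. The bloom is implemented by rescaling the
bloom species so its functional *group* hits the target share of included
abundance within the stratum–season (the share the emulated report
quotes), solved in closed form and spread over the unit's stations.

What the generator does **not** emulate: environmental covariates and
their gradients, spatial autocorrelation between neighbouring stations,
zero-inflation beyond Bernoulli presence, taxonomic abundance
correlations beyond the configured pairs, and observation error in
counting. A green test therefore establishes that the statistics recover
known structure from idealised surveys — not that they are robust to the
full messiness of field data.

## Numerical choices

* Proportion vectors are validated to sum to 1 within 1e-9; conservation
  checks use 1e-9 relative; oracle equivalences are asserted to 1e-12.
* Counts are stored as integers; present cells that would round to zero
  are floored at 1 individual so presence survives integer storage.
* Strict inequalities throughout (Y > 0.02, O > 0.7, r > 0.7, abundance
  > threshold for presence): ties fall below every cutoff.
* All-zero units yield flagged `NA`s rather than silent zeros (Pielou at
  S = 1, Bray–Curtis of two empty vectors, composition of an empty unit).
* Generator reproducibility is bit-exact under a seed; the trait and
  community draws use consecutive derived seeds so they can be
  regenerated independently.

## Known limitations

* The 57-species/11-group arithmetic of the emulated survey is not
  recoverable from its report; group membership here is entirely
  trait-table-driven, and the preset populates at least 11 groups without
  pinning the exact count.
* Ordination (DCA/RDA/NMDS), PERMANOVA, Mantel tests and random-forest
  importance modelling are out of scope by design; established packages
  (`vegan`) already serve those needs.
* The niche-overlap significance question (null-model randomisation) is
  not addressed, matching the scope of the survey literature followed.
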