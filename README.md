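# zooniche

Trait-based analysis of zooplankton survey data: functional-group
classification, diversity and dominance statistics, niche breadth and
overlap, and interspecific-association tests — the standard analytical
chain of estuarine and coastal plankton surveys — as a tested, composable
R package with a seeded synthetic-survey generator for end-to-end
validation.

## Who it is for

Community ecologists working from long-format survey tables (one row per
sample × species, with counts and filtered volumes) plus a species trait
inventory (taxon class, body size, feeding habit). The package takes
those two tables to the full set of report-ready statistics; everything
in between is an exported, unit-tested operation.

## The statistics at its core

With abundance `N = n/v` (ind m⁻³) and proportions `p_i`:

| Statistic | Form |
|---|---|
| Shannon–Wiener | `H' = -Σ p_i log₂ p_i` (bits) |
| Margalef | `d = (S-1)/log₂ N` |
| Pielou | `J' = H'/log₂ S` (NA for S = 1) |
| Simpson | `D = 1 - Σ p_i²` |
| Dominance | `Y = (n_i/N) f_i`, dominant iff `Y > 0.02` (strict) |
| Bray–Curtis | `1 - Σ|x-y| / Σ(x+y)` |
| Levins breadth | `B_i = 1/Σ P_ij²` ∈ [1, r] |
| Niche overlap | `O_ik = 1 - ½ Σ|P_ij - P_kj|` (Pianka form optional) |
| Variance ratio | `VR = S_T²/σ_T²`, `W = N·VR` vs χ²(N) bounds |
| Phi association | `Φ = (ad-bc)/√((a+b)(a+c)(b+d)(c+d))`, class by `N·Φ²` vs χ²(1) |

Functional groups follow the 17-code trait classification (RF/RC/RP for
rotifers; S/M/L × filter/carnivore for copepods–cladocerans, size bounds
0.7 and 1.5 mm; PP/PA/PB/PD/PF/PS/PR/PN for protozoans; larvae excluded
except `nauplius`-flagged records, which join SCF).

## Worked example

Simulate the built-in survey preset (5 estuaries × 4 seasons × 3
stations, 69 species, a September bloom in the THK stratum) and run the
chain:

```r
library(zooniche)

scen   <- qinhuangdao_preset(seed = 1)
traits <- generate_traits(scen)
ds     <- generate_community(scen, traits)
ds
#> <community_dataset> 69 species x 60 samples (2094 records)
#>   strata:   DHK, LHK, SHK, THK, YHK
#>   seasons:  Dec, Jun, Mar, Sep

gm   <- aggregate_by_group(abundance_matrix(ds), traits)
comp <- relative_composition(gm, by = "stratum_season", samples = ds$samples)
comp[comp$unit == "THK:Sep" & comp$group == "PP", ]
#>     unit group     share
#>  THK:Sep    PP 0.9500199
```

The configured bloom (PP driven to a 0.95 share of the THK September
community) is recovered to four decimals. Diversity per stratum–season:

```r
head(diversity_table(ds, by = "stratum_season"), 4)
#>     unit  S     N H_prime d_margalef J_prime D_simpson
#>  DHK:Dec 62  7346   5.365      4.750  0.9011    0.9699
#>  DHK:Jun 60 33815   5.043      3.921  0.8537    0.9564
#>  DHK:Mar 61 17448   4.990      4.258  0.8414    0.9536
#>  DHK:Sep 59 27428   5.022      3.934  0.8537    0.9430
```

`H'` is in bits; `N` is pooled abundance (ind m⁻³ summed over the unit's
samples). The bloom species dominates the survey-wide dominance table
(`Y = n-share × occurrence`, dominant iff Y > 0.02):

```r
head(dominance(ds), 3)
#>  species_id n_share f_occurrence      Y is_dominant
#>       pro01  0.4813        0.500 0.2407        TRUE
#>       pro12  0.0236        0.567 0.0134       FALSE
#>       pro04  0.0219        0.583 0.0128       FALSE
```

Niche and association at the functional-group level:

```r
niche_analysis(gm$values)
#> <niche_result> 14 entities, overlap method 'schoener'
#>   breadth range: [3.176, 40.44]
#>   high-overlap pairs (>0.7): 2

pm <- presence_absence(gm$values)
overall_variance_ratio(pm)
#> <overall_association> VR = 1.24 (W = 74.41, N = 60)
#>   verdict: positive (not significant, alpha = 0.05)

stability_summary(classify_pairs(pm))$verdict
#> [1] "stable"
```

VR > 1 reads as overall positive association (here not significant at
the two-sided 5% level); 30 positively vs 25 negatively associated group
pairs give a "stable" community verdict. Species-inventory composition
percentages, as printed in survey reports:

```r
composition_percentages(c(rotifer = 19, copepod = 19, protozoan = 13,
                          other = 11, cladoceran = 7))
#>       class count  fraction percent
#>     rotifer    19 0.2753623   27.54
#>     copepod    19 0.2753623   27.54
#>   protozoan    13 0.1884058   18.84
#>       other    11 0.1594203   15.94
#>  cladoceran     7 0.1014493   10.14
```

One-call pipeline (writes every stage table plus `summary.json`):

```r
run_pipeline(run_config(scenario = qinhuangdao_preset(seed = 1),
                        out = "results/run1"))
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/zooniche report --preset --seed 1 --out results/run1
Rscript inst/cli/zooniche simulate --seed 7 --out data/
Rscript inst/cli/zooniche diversity --community data/community.csv --out results/
```

## Documentation

The methods vignette
(`vignettes/zooplankton-community-analysis.Rmd`) documents the models and
their assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the numerical conventions (strict thresholds, base-2 logarithms, NA
semantics, corrected χ² bounds for the W test).
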