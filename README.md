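# dietniche

Quantitative trophic ecology from stomach contents and prey-availability
samples: who eats what, how selectively, and how much two sympatric
predators' diets overlap.

`dietniche` was built for the classic field design in which stomach contents
(obtained by non-lethal stomach flushing) are compared with semi-quantitative
environmental sampling of potential prey (benthos cores, nekton sweeps,
filtered zooplankton). It ships, as a worked case study, the site-level prey
tables of a study of the African clawed frog (*Xenopus laevis*) living in
sympatry with the endangered Cape platanna (*Xenopus gilli*) at two sites in
the south-western Cape — a setting where dietary competition from the larger
*X. laevis* is a direct conservation concern.

## What it computes

Given a taxon × group table of prey counts *N*, volumes *V* and stomach
occurrence frequencies *Freq* (built from tidy per-item records, or supplied
directly), the package provides:

- **Utilization profiles** — diet proportions *rᵢ* and availability
  proportions *pᵢ* per taxon, on a count or volume basis; prey volumes
  estimated from calliper measures as ellipsoids,
  *V = (4/3)·π·(L/2)(W/2)(H/2)*.
- **Diversity** — Simpson (1 − Σpᵢ², with the inverse form 1/Σpᵢ² as an
  option) and Shannon (*H′* = −Σpᵢ·log pᵢ).
- **Electivity** — the Vanderploeg–Scavia index
  *E\* = (r − p)/(r + p − 2rp)* ∈ [−1, 1], computed only for taxa whose
  pooled dietary count across the compared predator groups is ≥ 10;
  significance by a chi-square goodness-of-fit test against availability with
  95% simultaneous Bonferroni intervals (Neu's method) giving per-taxon
  verdicts: preferred / avoided / proportional.
- **Niche overlap** — the symmetric Pianka / MacArthur–Levins index
  *O_jk = Σpᵢⱼpᵢₖ / √(Σpᵢⱼ²·Σpᵢₖ²)* ∈ [0, 1], tested against randomization
  null models RA1–RA4 (RA3, permutation of the utilization proportions among
  resource categories, is the default) with two-tailed empirical p-values.
- **Stratification and anurophagy** — predator size classes on half-open SVL
  intervals (default small 30–52 mm, medium 52–72 mm, large > 72 mm) and the
  anuran-to-total prey ratio per group.
- **Synthetic data** — a generator with known ground truth (multinomial
  diets, negative-binomial stomach totals, empty stomachs, non-prey
  contamination) for validating the whole pipeline.

## Worked example

```r
library(dietniche)

cogh <- xenopus_counts("CoGH")      # bundled Cape of Good Hope table
cogh
#> Abundance table: 19 taxa x 3 groups
#> Groups: CoGH.environment, CoGH.X_laevis, CoGH.X_gilli
#> Total N per group:
#> CoGH.environment    CoGH.X_laevis     CoGH.X_gilli
#>             2873             1014             1641

niche_overlap_test(cogh, "X_laevis", "X_gilli", seed = 1)
#> Niche overlap X_laevis vs X_gilli: O = 0.496
#>   null (RA3, 1000 iter): mean 0.226, 95% CI [0.044-0.713]
#>   p_lower = 0.8372, p_upper = 0.1638
```

The two species share about half their trophic niche at this site, no more
than expected for two generalist predators drawing on the same prey pool
(the observed overlap sits inside the RA3 null band). Selectivity is strong
and concordant, though:

```r
ea <- electivity_analysis(cogh, c("CoGH.X_laevis", "CoGH.X_gilli"),
                          "CoGH.environment")
subset(ea$taxa[["CoGH.X_laevis"]], included,
       select = c(taxon, r, p, estar, verdict))
#>          taxon       r       p  estar      verdict
#>   Coleoptera 0.01972 0.00313  0.730    preferred
#>    Zygoptera 0.02367 0.82423 -0.990      avoided
#>    Ostracoda 0.57791 0.06022  0.911    preferred
#>        Acari 0.13708 0.00452  0.944    preferred
#>        ... (12 testable taxa in total)
```

*X. laevis* takes ostracods and water mites far in excess of availability
(E\* ≈ 0.91, 0.94) while almost completely avoiding the superabundant
damselfly larvae (E\* ≈ −0.99). At the second site the picture sharpens into
near-complete overlap and heavy frog-eating:

```r
km <- xenopus_counts("Kleinmond")
pianka_overlap(make_profile(km, "X_laevis"), make_profile(km, "X_gilli"))
#> [1] 0.9664748
anurophagy_summary(km, "X_laevis")
#> Anurophagy in X_laevis: 1131 / 1680 items (ratio 0.67)
```

`run_study()` orchestrates all of the above (abundance tables, diversity,
electivity, overlap with size-class strata, anurophagy, JSON manifest) from
a config list or YAML file; `simulate_study()` writes a synthetic dataset
with a `truth.json` for end-to-end validation.

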