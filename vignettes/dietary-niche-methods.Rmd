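---
title: "Methods: dietary niche analysis from stomach contents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary niche analysis from stomach contents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietniche)
```

## The design this package models

The package targets a two-source field design. On one side, stomach contents
of individually measured predators (here, two sympatric *Xenopus* species),
obtained by stomach flushing or dissection, identified to Order level and
counted. On the other, semi-quantitative samples of potential prey from the
same ponds — benthos cores, nekton dip-net sweeps and filtered zooplankton —
pooled per site into an availability sample. Every downstream statistic is a
function of the taxon × group `abundance_table`: item counts `N`, summed
volumes `V` (mm³) and, for predator groups, the number of stomachs
containing each taxon (`Freq`).

Three bookkeeping rules are applied when tables are built, all of which
matter for reproducibility:

* **Non-prey items** (sloughed skin, plant matter, stones) are kept in the
  record tables — they are biologically informative — but never enter `N`,
  `V` or `Freq`.
* **Unidentifiable items** are carried as an `"Unidentified"` pseudo-taxon
  but excluded from proportion denominators by default. Published diet
  tables are frequently ambiguous about whether percentage columns include
  unidentifiable material; identified-only denominators are the one
  convention that can be recomputed exactly from a printed table, so that is
  the default, with `include_unidentified = TRUE` as the escape hatch.
* **Trap bias**: prey taxa known to be attracted into baited traps can be
  dropped when flagged as undigested (`drop_trap_suspect`); the default is
  off, matching the practice of inspecting items for digestion before
  inclusion rather than discarding them wholesale.

## Prey volume

Items are measured with callipers along at most three axes and modelled as
ellipsoids, $V = \tfrac{4}{3}\pi\,\tfrac{L}{2}\tfrac{W}{2}\tfrac{H}{2}$.
Field measurements often record only length and width; the package then sets
$H := W$ (a prolate spheroid). This is a documented convention, not an
estimate of the missing axis: for dorsoventrally flattened taxa it
overstates volume. No other shape model is provided, deliberately — mixing
shape formulas per taxon creates more researcher degrees of freedom than it
removes error. Volume-basis profiles are available everywhere, but all
selectivity and overlap statistics default to the count basis, which is the
basis on which diet tables are conventionally published.

## Diversity

Simpson concentration $\lambda = \sum_i p_i^2$ is reported either as the
complement $1-\lambda$ (default) or the inverse $1/\lambda$. Both transforms
circulate in the trophic literature under the same name and symbol — one is
bounded by 1, the other is a Hill number ≥ 1 — so the package implements
both rather than silently choosing. Shannon diversity is the standard
$H' = -\sum_i p_i \log p_i$ (natural log by default; bases 2 and 10
switchable); zero-proportion taxa contribute nothing. Note that diversity
values are sensitive to taxonomic resolution: two analyses of the same
stomachs that split or lump a single Order can differ substantially, which
is why the package reports `k` (the number of non-zero taxa) alongside every
index value.

## Electivity and prey selection

Selectivity is measured by the Vanderploeg–Scavia index
$E^* = (r-p)/(r+p-2rp)$, with $r$ the taxon's diet proportion and $p$ its
availability proportion. $E^*$ is exactly $+1$ when a taxon is eaten but
absent from the availability sample ($p = 0 < r$) and $-1$ in the converse
case; it is undefined (returned as `NA`) only when $r = p = 0$.

Three procedural choices deserve justification:

* **Inclusion threshold.** $E^*$ is unstable for rarely eaten taxa, so it is
  computed only for taxa whose dietary total pooled across the compared
  predator groups at a site reaches `min_total = 10`. The threshold is
  applied to summed item counts `N` by default rather than stomach
  occurrence `Freq`: in the bundled case-study tables there are taxa whose
  pooled `Freq` is below 10 but whose electivity was clearly evaluated,
  while the pooled-`N` reading is consistent throughout, so `N` is the
  default and the basis is a configuration switch.
* **Chi-square test.** Observed diet counts over the tested taxa are
  compared with expectations $E_i = n\,\hat p_i$ where availability is
  renormalized over the tested subset, keeping $\sum_i E_i = n$. Taxa whose
  renormalized expectation is zero (eaten but unavailable in the sample)
  cannot be tested under the multinomial model and are dropped with a
  warning; their $E^*$ of $+1$ already tells the story. Pearson residuals
  $(O_i-E_i)/\sqrt{E_i}$ are reported per taxon; note that residuals depend
  on the expected-count construction, so residuals from other software are
  only comparable if that construction matches.
* **Bonferroni intervals.** Selection verdicts come from Neu-style
  simultaneous intervals $\hat p_i \pm z_{1-\alpha/(2k)}
  \sqrt{\hat p_i(1-\hat p_i)/n}$, clipped to $[0,1]$, with availability
  below / inside / above the interval read as preferred / proportional /
  avoided. A zero observed count gives the degenerate interval $[0,0]$ and
  a verdict of avoided whenever the taxon was actually available. The
  normal approximation is poor for $\hat p_i$ very close to 0 or 1 at small
  $n$; with the ≥ 10-count inclusion rule in place this regime is rare.

Report tables round to two decimals with ties away from zero
(`round_half_up()`), matching how published diet tables are typeset.

## Niche overlap and its null models

Pairwise overlap is the symmetric Pianka / MacArthur–Levins index
$O_{jk} = \sum_i p_{ij}p_{ik} / \sqrt{\sum_i p_{ij}^2 \sum_i p_{ik}^2}$,
computed on count-basis diet profiles over the union of taxa observed in
either diet at the site. Taxa present only in the environment contribute
zero to every term and are excluded; this is an identity, not an
approximation.

An observed overlap is interpretable only against a null. Four standard
randomization algorithms are implemented; each iteration randomizes both
species' utilization vectors independently and recomputes $O$:

| algorithm | zero categories | non-zero categories |
|---|---|---|
| RA1 | redrawn | redrawn uniformly, renormalized |
| RA2 | retained | redrawn uniformly, renormalized |
| RA3 | shuffled | proportions permuted over all categories |
| RA4 | retained | proportions permuted among non-zero categories |

RA3 — which retains each species' niche breadth exactly (the proportion
multiset is invariant) while destroying which resource is which — is the
default, with 1,000 iterations, following the convention of the
null-model literature for niche overlap. Tail probabilities use add-one
continuity, $p_{upper} = (\#\{O_{null} \ge O_{obs}\}+1)/(n+1)$, so a
reported p can never be exactly zero; both tails are always reported. The
95% interval attached to an overlap result is the 2.5th–97.5th percentile
band of the *null* distribution — it describes what no-structure data would
produce, not the sampling uncertainty of the observed index.

For profiles over $k \le 3$ taxa the RA3/RA4 null support is the finite set
of $k!\times k!$ permutation pairs; the test suite checks the sampled null
against exhaustive enumeration.

## Size classes and anurophagy

SVL strata use half-open intervals with boundaries assigned upward: the
default scheme is small $[30, 52)$, medium $[52, 72)$, large $[72, \infty)$
mm, so a 52.0 mm frog is medium. Overlap per size class compares like
classes across species (small vs small, …), which is the comparison that
addresses whether the smaller species competes mainly with the juveniles of
the larger one. Frogs below the smallest bound are left unclassified with a
warning rather than silently pooled.

The anurophagy ratio is anuran items over total identified items per group.
Anuran taxa are recognized by label (`"Anura"` or colon-qualified
subcategories such as `"Anura:nonXenopus_tadpole"`), and the subcategory
breakdown is reported whenever the input data carry it. All ratios are
derived from the abundance table itself; where a narrative summary and a
table disagree (as happens in published studies), the table-derived number
is what this package reports.

## The bundled case study

`xenopus_counts()` returns the two site tables (19–20 Order-level taxa;
2,873 and 1,723 environmental items; 1,014/1,641 and 1,680/868 diet items)
with the studied group sizes (94/111 and 89/105 stomachs). Recomputing from
these counts with identified-only denominators gives site overlaps of 0.496
and 0.966, within 0.01 of the originally reported 0.491 and 0.965 — the
residual difference traces to category-resolution choices that a printed
Order-level table cannot encode. The worked electivity values (e.g.
Ostracoda 0.91, Coleoptera 0.73 for *X. laevis* at the Cape of Good Hope)
reproduce exactly at two decimals. Diversity indices and chi-square
residuals recomputed from printed Order-level counts are *not* expected to
match originally published values in general, for the resolution and
expected-count reasons above; the package therefore treats them as
recomputable statistics of the bundled table, not as reproduction targets.
Habitat-class assignments in the bundled tables are the package's own
Order-level classification.

## The synthetic-data generator

`community_config()` + `simulate_study()` emulate the study design with
fully known truth: per-site availability distributions sampled
multinomially; per species, SVLs uniform within the species' range, a
configurable fraction of empty stomachs (default 3%), per-stomach item
totals drawn negative-binomially (default mean 12, size 1.5) — overdispersed
because in real stomach data a few individuals dominate the counts of
swarming prey such as cladocerans or tadpole cohorts, which a Poisson
cannot mimic — and item taxa drawn multinomially from the group's true
utilization vector. Non-prey contamination (default rates 0.16 sloughed
skin, 0.14 plant matter, 0.01 stones per stomach, the incidence pattern
typical of suction-feeding pipids) exercises the non-prey exclusion path.
`example_community_config()` sets availability and utilization to the
bundled case-study proportions so the synthetic world statistically
resembles the real one.

What the generator deliberately does **not** emulate: temporal dynamics and
seasonal prey turnover, individual diet specialization (items within a
stomach are exchangeable given the group's utilization vector), digestion-
dependent detectability, taxon-specific trap attraction, and spatial
structure among ponds. Consequently, passing parameter-recovery tests shows
the estimators are consistent under multinomial sampling with realistic
overdispersion — it does not certify behaviour under individual
specialization or detectability bias, which inflate apparent selectivity in
real data.

## Numerical choices and test scale

All randomized procedures take explicit integer seeds and are reproducible
bit-for-bit; `run_study()` records every parameter and seed in its JSON
manifest and produces byte-identical outputs for identical configs.
Profiles must sum to 1 within 1e-9; degenerate inputs (all-zero profiles,
empty groups, unknown predator IDs, out-of-vocabulary labels) raise typed
errors naming the offending rows. The test suite sizes its simulations for
tightness-per-second: 2,000 replicates for the chi-square type-I
calibration (n = 150 items, 5 taxa), 1,000 replicates for p-value
uniformity of the overlap test, 3,000 draws against exhaustive permutation
enumeration, and three-point consistency checks (n from tens to thousands
of items) for parameter recovery.

## Known limitations

Order-level taxonomy caps what selectivity can mean: a predator may select
strongly within an Order and appear unselective at Order level. Availability
from pooled semi-quantitative sampling is itself an estimate with error the
electivity machinery treats as fixed. The Bonferroni intervals are
conservative as $k$ grows. And overlap indices quantify shared *use*, not
competition: high overlap with superabundant prey implies no resource
limitation by itself.
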