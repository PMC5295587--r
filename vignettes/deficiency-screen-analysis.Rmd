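---
title: "Mapping temperature-dependent hybrid incompatibilities with a deficiency screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping temperature-dependent hybrid incompatibilities with a deficiency screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defscreen)
```

## The screen and its statistical model

A deficiency screen maps recessive alleles by hemizygosis: females from a
*D. melanogaster* stock carrying a known deletion (a *deficiency*, df)
balanced over a dominant-marked *balancer* (Bal) chromosome are crossed to
males of a second species. Daughters inherit either the deficiency or the
balancer from their mother, in a 1:1 Mendelian ratio, together with a full
haploid genome from the father. A deficiency-class daughter is hemizygous
for the paternal alleles across the deleted region; if that region harbours
a recessive hybrid-incompatibility (HI) allele, deficiency-class daughters
die or are depleted while their balancer-class sisters act as an internal
control. The balancer:deficiency ratio among surviving daughters is
therefore a per-region viability assay, and running the same panel of
deletions at two rearing temperatures turns it into an assay for
gene-by-environment effects on HI penetrance.

`defscreen` implements the full analysis path for such a screen:

1. **Per-cross viability inference.** Counts are pooled over vials per
   stock × species × temperature. Relative viability is
   $\hat v = n_{df} / (n_{df} + n_{bal})$, 0.5 under equal survival. The
   segregation test is the one-degree-of-freedom goodness-of-fit
   chi-square against 1:1, $X^2 = (n_{df} - n_{bal})^2/(n_{df}+n_{bal})$,
   without continuity correction. The HI call is one-sided: a cross is HI
   only when the *deficiency* class is significantly depleted
   ($p < \alpha$ **and** $n_{df} < n_{bal}$); a significant excess is
   reported but never called HI. Complete-lethal crosses ($n_{df} = 0$
   with an adequate balancer count) are always HI.
2. **Minimal causal regions.** Overlapping HI deficiencies plausibly share
   a causal locus. The package reports both the connected components of
   the interval-overlap graph and the *minimum stabbing number* — the
   smallest set of point loci such that every HI interval contains one —
   computed by the classical greedy sweep over interval ends.
3. **Between-condition comparison.** HI sets at the two temperatures are
   partitioned into shared and condition-specific calls over the universe
   of stocks testable in both conditions, and the overlap is tested
   against a randomization null (uniform redraw of one set's labels), with
   the closed-form hypergeometric tail as oracle.
4. **Effect models.** Paired t-tests of per-stock viability between
   temperatures within each species; a sequential (Type I) factorial
   ANOVA `response ~ temperature + species + temperature:species`;
   cell-means models on the crossed factors; and simultaneous max-|t|
   (Tukey-HSD-style) contrasts between cells via `multcomp::glht`.
5. **Synthetic screens.** A seeded simulator generates panels and
   vial-level progeny counts with planted loci, for validation and power
   exploration.

## The synthetic generator: what it emulates

`screen_scenario()` encodes the study conditions: a panel of 223
deficiencies tiled across the five major arms (X, 2L, 2R, 3L, 3R, with
deficiencies apportioned by arm length), two hybrid genotypes crossed at
two temperatures, 20 vials per cross of which on average half produce
progeny, and latent HI loci with condition-specific penetrance.

The count model is two independent Poisson classes per producing vial:
$n_{bal} \sim \mathrm{Pois}(\lambda)$ and
$n_{df} \sim \mathrm{Pois}(\lambda v)$ with
$v = \prod_{\ell \text{ uncovered}} (1 - \text{penetrance}_\ell)$.
This is equivalent to binomial thinning of a common clutch and is the
simplest model consistent with count data; no clutch-size distribution is
implied by the screen design itself, so Poisson is a default, not an
inference. Survival across multiple uncovered loci is multiplicative
(independent lethality); balancer-class viability is fixed at 1, i.e.
dominant balancer costs are not modelled. Under this model the expected
pooled viability of a deficiency with survival $v$ is $v/(1+v)$.

Defaults: $\lambda = 15$ daughters per class per producing vial (pooled
totals of roughly 150 per class per cross, the order of magnitude a
multi-vial fly cross yields), vial failure probability 0.5, tiling overlap
0.35 so neighbouring deficiencies share regions. Two presets package the
contrast the analysis is designed to detect:

* `san_like` — 70 loci, 60 of them with identical penetrance at both
  temperatures and 5 restricted to each temperature: a dense,
  temperature-insensitive incompatibility map.
* `sim_like` — 15 loci, 9 expressed only at 24°, 5 only at 18°, 1 shared:
  a sparse map dominated by temperature-restricted penetrance, which
  drives a strong temperature × species interaction downstream.

What the simulator does **not** emulate: balancer viability costs, meiotic
drive, hybrid male lethality (only females are scored), sterility
phenotypes, within-vial overdispersion beyond Poisson, and real cytology —
coordinates are abstract 0-based half-open integers, and the synthetic
tiling covers each arm completely, so the synthetic panel's euchromatic
coverage is 1.0 rather than the partial coverage of a real stock list.
Passing tests on synthetic screens therefore validate the inference
machinery under the stated count model, not the idiosyncrasies of any real
panel.

## Numerical and design choices

* **HI call threshold.** $\alpha = 0.05$ per cross, no multiple-testing
  correction by default: the per-stock call is treated as a screening
  decision, and a Benjamini–Hochberg sensitivity re-run is available by
  re-calling `classify_hi()` on adjusted p-values. `min_total = 20`
  pooled daughters is required for a testable cross; below that the
  chi-square approximation is unreliable and the stock is reported as
  untestable rather than negative.
* **Minimal regions.** "Number of causal regions" is reported under two
  conventions: overlap-graph components and the minimum stabbing number.
  A chain of pairwise-overlapping intervals with no common base is one
  component but needs at least two loci; the stabbing count captures
  this, so it is the headline `minimal_count`. The greedy rule is exact
  for interval stabbing; an exhaustive-search oracle
  (`brute_force_min_cover`) guards the implementation for up to 12
  intervals.
* **Simulated p-values.** Both the arm-uniformity test (default 2000
  multinomial replicates) and the overlap randomization (default
  $10^5$ permutations) use the $(1 + b)/(B + 1)$ estimator, which never
  returns zero. Ties at the observed statistic are counted as exceeding,
  with a small relative tolerance against floating-point drift.
* **Randomization null.** Simple label shuffling — redraw one HI set
  uniformly from the universe of stocks testable in both conditions —
  holding the other fixed. This null is exactly hypergeometric, and the
  package reports the closed-form tail alongside the Monte-Carlo
  estimate; agreement between the two is asserted in the test suite. No
  per-arm-structured null is provided.
* **ANOVA.** Sequential (Type I) sums of squares via `stats::anova` on an
  OLS fit. The complete-case frame (stocks with a defined viability in
  all four species × temperature cells) is balanced, so Type I/II/III
  decompositions coincide for these factors. The chromosome factor
  collapses arms to X, 2, 3; stocks on other chromosomes are excluded
  from chromosome models only.
* **Contrasts.** Single-step max-|t| adjustment over the supplied family
  (quasi-Monte-Carlo multivariate-t integration, seeded for
  reproducibility). A degenerate self-contrast is reported as estimate 0,
  p 1 without entering the integration.
* **Determinism.** Every stochastic step takes a seed derived from the
  run's master seed. Reruns reproduce all text artifacts (TSV/BED/JSON)
  byte for byte; the PDF histograms embed a creation timestamp and are
  the one artifact excluded from that guarantee.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(scenario = "sim_like", seed = 7,
                  permutations = 10000, out_dir = "sim-report")
res <- run_pipeline(cfg)

# HI calls per condition
sapply(res$hi_sets, function(h) length(h$members))

# minimal causal regions vs overlap clusters
res$loci$sim_24

# between-temperature overlap within the sim-type cross
res$comparisons$sim

# temperature x species interaction
res$models$anova
```

The report bundle written to `out_dir` contains the per-cross viability
table, per-condition BED tracks of HI deficiencies, cluster and
representative-point tables, overlap partitions, ANOVA and contrast
tables, viability histograms (mean and mean ± SD marked), and a
machine-readable `summary.json` validated by the schema shipped under
`inst/schema/`.

## Problem sizes used in validation

The test suite validates the pipeline at the study's own scale — 223
deficiencies, four conditions, 20 vials per cross — and uses 8–50
replicate screens for the Monte-Carlo properties (null false-positive
rate, interaction-F direction), 1000 random instances for the
stabbing-vs-exhaustive equivalence, and $10^5$ permutations for the
randomization-vs-hypergeometric agreement. These sizes put Monte-Carlo
standard errors well below the asserted tolerances while keeping a full
run of the suite to well under ten minutes.

## Known limitations

* The chi-square segregation test is asymptotic; for totals near
  `min_total` its p-values deviate from the exact binomial by up to a few
  hundredths (the mid-p binomial is the matched exact counterpart, and
  the suite checks agreement for totals ≥ 50).
* The one-sided call rule halves the nominal false-positive rate but
  cannot detect incompatibilities expressed as a deficiency-class
  *excess* (e.g. balancer-linked effects); such crosses are flagged in
  the viability table only.
* Minimal-region counts are lower bounds: distinct linked loci inside one
  stabbing point's interval neighbourhood are indistinguishable without
  finer deletions.
* The universe for between-temperature comparisons excludes untestable
  stocks; if testability itself correlates with HI (e.g. near-sterile
  crosses), the overlap test inherits that ascertainment.
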