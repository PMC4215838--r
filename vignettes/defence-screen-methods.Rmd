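---
title: "Screening epibacterial communities against algal defence chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening epibacterial communities against algal defence chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpibiontScreen)
```

## The scientific problem

Brown algae such as *Fucus vesiculosus* carry three surface metabolites that
inhibit bacterial settlement: DMSP (dimethylsulfoniopropionate), proline and
fucoxanthin. Two questions arise when the host is grown under temperature or
light stress: does the chemical defence stay strong enough to deter fouling
bacteria, and do the metabolite concentrations shape which bacteria live on
the surface? EpibiontScreen implements the analytical chain that answers
both from (i) rarefied 16S amplicon OTU tables with per-sample metabolite
concentrations and (ii) published strain-level EC50 values.

Because treatment level (temperature or light) affects both the host's
chemistry and the bacteria directly, any across-level correlation would be
confounded. The screen therefore works strictly *within* treatment levels:
with five algal replicates per level, each detected OTU's relative abundance
is Spearman-correlated with each compound's surface concentration across
those five replicates only.

## The screening and classification model

For each OTU, compound and experiment we collect the per-level correlation
signs. An OTU detected at a level (nonzero count in at least one of the
level's replicates) contributes a sign there: positive, negative, zero (an
exact tie of rank covariance), or undefined (a constant abundance or
concentration vector). The classification is a pure sign-consistency rule:

* **positive** — at least one evaluable level, all evaluable signs positive;
* **negative** — all evaluable signs negative;
* **neutral** — mixed signs, or any exactly-zero correlation;
* **unevaluable** — no level with a defined sign.

Only the sign of Spearman's rho is used; no per-correlation significance is
tested, because with n = 5 replicates individual correlations have almost no
power — the information is in the consistency across levels and in the
clade-level aggregation that follows. An exactly zero rho counts as breaking
consistency since the dichotomy of interest is strictly
positive-versus-negative. OTUs evaluable at a single level are classified
from that level by default (`min_levels = 1`); the published community-scale
subgroup fractions (about 30% of OTUs in each directional class) are only
attainable when single-level OTUs are classified, because the probability of
a consistent sign across many levels decays geometrically under the null.
Users wanting stricter evidence can raise `min_levels`, which demotes
consistent-but-thin calls to unevaluable.

## Clade enrichment by odds of presence

To ask *which* bacteria respond to a compound, OTUs are grouped into clades
(mixed taxonomic ranks — families where resolution permits, otherwise
orders, classes, phyla, plus "other" and "unclassified" buckets; the default
scheme has 26 entries and is fully configurable). For a clade with `A`
members in a community of `M` OTUs, of which `a` fall in a subgroup of size
`m` (say the DMSP-negative OTUs), the odds of presence are

$$\mathrm{odds} = \frac{a/(m-a)}{A/(M-A)},$$

the clade's odds inside the subgroup against its odds in the whole
community. Odds above 1 mean over-representation. Zero cells receive the
Haldane–Anscombe +0.5 correction on all four terms (flagged in the output),
which keeps the odds strictly positive as the geometric-mean pooling
requires.

One odds value is computed per stratum — by default per treatment level (5
temperature + 6 light = 11 strata), with the universe restricted to OTUs
detected at that level and subgroup membership taken from the
experiment-wide classification. Strata are pooled as a geometric mean with a
t-based 95% confidence interval on the log scale; a single stratum
degenerates to its point estimate and is flagged. Divergence of observed
from expected clade counts is tested once per (clade, compound, subgroup)
with a 1-df goodness-of-fit statistic on counts pooled across experiments,

$$\chi^2 = (a-E)^2\left(\frac1E + \frac1{m-E}\right), \qquad E = \frac{mA}{M},$$

with stars at p < 0.05 / 0.025 / 0.001 and no multiple-testing correction by
default (`p_adjust = "BH"` is available). Both the stratification
(`per_level` or `per_experiment`) and the scheme are exposed as options
because the aggregation conventions admit more than one defensible choice;
the defaults above are this package's documented reconstruction.

## EC50 threshold assessment

Defence sufficiency compares treatment-level *mean* concentrations against
strain-specific EC50 values, boundary inclusive (a mean exactly at the EC50
counts as inhibitory). Comparing means, not replicates, mirrors how such
panels are interpreted; a per-replicate sensitivity mode can be derived from
the same calls if needed. The bundled panel covers five Baltic isolates:
DMSP at 0.05 ng cm⁻² for four strains and 0.38 ng cm⁻² for *Cytophaga* sp.;
proline spanning 0.01–0.13 ng cm⁻² for the four less resistant strains
(*Cytophaga* sp. is more resistant and has no published value, so it has no
proline row); fucoxanthin spanning 1.4–6 µg cm⁻², with isolate ISA 7311 at
6 µg cm⁻². Where only a range is published per strain, calls are reported at
both the range minimum (default, most sensitive reading) and the maximum;
we deliberately expose both rather than guess a single intended rule.
Fucoxanthin units are normalized from µg cm⁻² to ng cm⁻² on ingest, so
entering 1.4 µg cm⁻² or 1400 ng cm⁻² yields identical calls.

## Treatment statistics

Concentration-versus-level effects use the standard univariate battery:
one-way ANOVA with Shapiro–Wilk (pooled residuals) and Levene
(mean-centred) checks at alpha = 0.05; a Box-Cox transform of the response
when homoscedasticity fails, with lambda maximizing the profile
log-likelihood on a grid from −3 to 3 in steps of 0.01; and Tukey HSD with
a compact letter display. The letter display uses the greedy insert–absorb
construction (split every letter set containing a significantly different
pair, then drop sets contained in others). Letter sets are not unique in
general; this deterministic construction is the documented convention.

## What the synthetic generator emulates — and what it does not

Real rarefied OTU tables from this kind of study cannot be regenerated at
desk scale from the deposited raw reads, so the package ships a generator
with known ground truth instead. It emulates, with these defaults chosen to
match the study design:

* **Design**: a temperature experiment (5 levels × 5 replicates, 1352 reads
  per sample) and a light experiment (6 levels × 5 replicates, 1024 reads);
* **Concentrations**: lognormal per replicate, moment-matched to the
  measured per-level means and SDs of the bundled condition table (the
  within-level variability was considerable in the measured data, and the
  lognormal respects non-negativity with such large CVs);
* **Community**: 2000 OTUs with lognormal base intensities (sdlog 2 gives
  the long-tailed rank-abundance curve typical of amplicon surveys),
  per-OTU occupancy thinning (Beta(0.5, 1), mean 1/3) so most OTUs are
  absent from most samples, and clade shares dominated by Rhodobacteraceae
  and Flavobacteriaceae as in *Fucus* microbiomes;
* **Planted effects**: responder OTUs' intensities are multiplied by
  exp(beta·z) with z the within-level z-score of the sample's compound
  concentration. Coupling to within-level z-scores (not raw concentrations)
  is deliberate: it produces exactly the within-level correlations the
  screen measures, without inducing across-level abundance trends that the
  screen is designed to ignore;
* **Counts**: multinomial at fixed depth — the simplest model that
  exercises every pipeline contract (an optional Dirichlet overdispersion
  knob adds realism when wanted).

It does **not** emulate sequencing error, chimeras, taxonomy
misassignment, phylogenetic correlation of responses, or compositional
interactions between planted and background OTUs beyond the shared
multinomial denominator. Passing calibration tests on these simulations
therefore demonstrates that the statistical machinery is correct and
calibrated under the stated model, not that the biological effect sizes in
any real survey are recoverable.

## Numerical conventions and degenerate inputs

* Spearman's rho is the Pearson correlation of midranks; values are clamped
  to [−1, 1] and an absolute tolerance of 1e−12 around zero absorbs
  floating-point noise before the exact-zero rule applies.
* Rarefaction is a seeded multivariate-hypergeometric draw (subsampling
  reads without replacement) done once per sample; samples below the target
  depth are dropped with a warning, never padded — padding would fabricate
  reads. A single seeded draw is used rather than averaging over draws.
* Zero-total samples are rejected at container validation; constant vectors
  propagate as "undefined" signs rather than errors.
* Chi-squared tests are skipped (with a warning) when the expected count is
  degenerate (E = 0 or E = m); odds cells with m = 0 or M = 0 are skipped.
* All simulation entry points take explicit integer seeds; identical seeds
  give byte-identical outputs.

## Problem sizes used in the shipped checks

The packaged calibration checks run 50 null studies (2000 OTUs, one
5-level × 5-replicate experiment) for subgroup-fraction symmetry and
chi-squared size, 200 studies of 500 OTUs with a 20-OTU planted clade at
beta = −3 for enrichment recovery, and 10 000 replicates of 11-stratum
lognormal odds for confidence-interval coverage. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands while
keeping a full run on a single CPU in the minutes range.

## Known limitations

* The sign-consistency rule treats a single evaluable level as sufficient
  evidence by default; this maximizes sensitivity but inflates directional
  classes relative to stricter conventions (see `min_levels`).
* The chi-squared statistic treats the community composition as a fixed
  reference; when a subgroup is a large fraction of a small community the
  test is conservative.
* EC50 panel ranges are bracketed per strain, not resolved to individual
  strains, because only panel-level ranges are published for proline and
  fucoxanthin.
* The enrichment is presence-based (OTU membership), not abundance-
  weighted, and is blind to phylogenetic structure within clades.
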