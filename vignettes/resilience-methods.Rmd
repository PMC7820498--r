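---
title: "Seasonal milk-performance resilience: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal milk-performance resilience: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoresil)
```

## The problem

Dairy sheep in Mediterranean systems lamb from September to May and are
milked monthly for five to six months. Over a lactation an individual ewe
meets a wide band of air temperatures, and how her daily milk yield responds
to that weather — her *performance resilience* — varies between animals and
between calendar seasons of lambing. `thermoresil` turns routine test-day
milk records, a pedigree, and daily weather-station data into:

1. **seasonal reaction norms**: population and individual curves of test-day
   milk yield against air temperature (or a temperature–humidity index);
2. **resilience phenotypes**: the slope of each animal's curve (kg milk per
   °C) at a cold (10 °C) and a hot (25 °C) query temperature, separately for
   the same-day covariate and its week-preceding average (traits `Tavg10`,
   `Tavg25`, `Tavg10_lag7`, `Tavg25_lag7`, per lambing season);
3. **genetic parameters** of those phenotypes and of lifetime milk yield:
   heritabilities, genetic and phenotypic correlations, with standard errors
   and significance tests, from pedigree-based animal-model REML.

All stages run on synthetic data with known ground truth, so the whole
pipeline is testable end to end without access to the (request-only) field
data that motivated it.

## Weather covariates

The temperature–humidity index combines daily mean temperature $T$ (°C) and
relative humidity $RH$ (%):

$$THI = T - \big(0.55\,(1 - RH/100)\big)\,(T - 14.4).$$

At $RH = 100$ the index equals the air temperature and at $T = 14.4$ °C the
humidity correction vanishes; both identities are tested exactly. Farms are
matched to their nearest weather station by great-circle (haversine)
distance, with ties broken deterministically by station id; the synthetic
generator may use planar coordinates instead via the `method` argument.

Each test-day record receives a same-day covariate and a *week-preceding*
covariate. We read "the week preceding" strictly: the arithmetic mean over
the 7 calendar days $d-7,\dots,d-1$, excluding the test day itself, because
daily and cumulative exposure are treated as distinct phenotypes downstream.
The alternative window (6 prior days plus the test day) is available as
`window = "including"`. A record whose station, day, or any lag-window day is
missing is dropped and counted in the run log rather than interpolated —
the conservative choice, since interpolation would manufacture exposure
values that feed directly into the phenotypes.

## Record edits and lifetime yield

Three sequential filters mirror standard test-day quality edits: records
taken less than 42 days after lambing (the suckling period) are removed;
within each month of lactation (`floor(dim / 30.44) + 1`, matching the
monthly recording cadence), records beyond four standard deviations from the
group mean are removed; and animals left with fewer than three records over
their productive life are excluded. The filters run once, in that order,
without recomputing group statistics after removals — the single-pass
reading is deterministic and makes the edit idempotent, which the tests
verify. Group standard deviations use the $n-1$ denominator and groups with
fewer than three records are exempt (their SD is unstable or undefined). The
4-SD grouping pools flocks by default; a `sd_grouping = "within_flock"`
switch is provided since the original edit rule does not state the pooling.

Lifetime milk yield per animal and lambing season accumulates
test-interval (Fleischmann) lactation yields: $dim_1 y_1$ for the first
interval, $\Delta\,(y_i + y_{i+1})/2$ for interior intervals, and a tail of
15 days (configurable) at the last recorded yield, capped so a lactation
credits at most 210 days — consistent with a 5–6-month lactation plus tail.
The exact tail convention used by any given recording cooperative varies;
this is documented as a simplification. Lambing seasons are autumn
(September–November), winter (December–February) and spring (March–May);
June–August lambings fall outside the normal season and are excluded. An
animal lambing in different seasons contributes one lifetime record per
season.

## The reaction-norm model

For one season and one covariate, test-day yield is modelled as

$$y = Xb + \Phi\beta + Z(\Phi \circ a) + e,$$

where $\Phi$ is a second-degree Legendre basis in the covariate rescaled to
$t = 2(x - x_{\min})/(x_{\max} - x_{\min}) - 1$, $\beta$ is the population
curve, and each animal $i$ carries a random coefficient vector
$a_i \sim N(0, G_0)$ with an unstructured $3\times 3$ covariance,
independent across animals, plus residual $e \sim N(0, \sigma^2_e I)$. Fixed
effects are farm, lactation number, lambing year, lambing month and 30-day
days-in-milk classes, each with a set-to-zero constraint on its first level;
confounded columns are detected by QR and dropped with a warning. The
leading basis function is a constant and serves as the model intercept.

Design choices worth stating explicitly:

* **Full 3-coefficient random deviation.** The individual deviation gets
  intercept, linear and quadratic terms with unstructured covariance —
  standard random-regression practice, and required for animal-specific
  curvature.
* **Identity relationships at this stage.** Animal effects are i.i.d. here;
  genetic structure enters only in the second stage, on the derived slope
  phenotypes. This mirrors the two-step design in which genetic parameters
  are estimated on the phenotypes, not inside the reaction-norm model, and
  keeps the two stages separately testable.
* **Covariate range per fit.** The basis spans the observed covariate range
  after editing and is stored with the fit; slope queries outside it are
  refused rather than extrapolated, so a 25 °C trait is simply absent for a
  season that never saw 25 °C.
* **Basis normalisation.** The orthonormal scaling
  $\phi_k = \sqrt{(2k+1)/2}\,P_k$ is the default (better conditioned
  covariance components); the plain $P_k$ basis is available, and slopes and
  curves are invariant to the choice.

Individual slopes are analytic derivatives of the fitted curve with the
chain-rule factor $2/(x_{\max}-x_{\min})$, validated against central finite
differences at $10^{-6}$ kg/°C. The default slope mode differentiates the
*total* curve (population + deviation): the seasonal phenotype means in the
motivating data are far from zero, which is inconsistent with pure BLUP
deviations whose weighted mean is near zero; `mode = "deviation"` is kept as
an option, and the ambiguity is inherent in defining "the individual
response curve".

## Genetic parameters

The derived phenotypes (and lifetime milk) enter univariate and bivariate
animal models $y = Xb + Za + e$, $a \sim N(0, \sigma^2_a A)$ — or, for two
traits, $\mathrm{var}(a) = G_0 \otimes A$ with an unstructured $2\times 2$
residual covariance per animal, animals recorded for only one trait
contributing marginal residual blocks. $A^{-1}$ is assembled sparsely by
Henderson's rules with inbreeding-adjusted Mendelian-sampling variances
(diagonal of $A$ via the Meuwissen–Luo traversal) and is verified against a
dense tabular-method oracle to $10^{-10}$. Heritability is
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$; correlations are

$$r_A = \frac{\sigma_{a12}}{\sqrt{\sigma^2_{a1}\sigma^2_{a2}}}, \qquad
r_P = \frac{\sigma_{a12} + \sigma_{e12}}
      {\sqrt{(\sigma^2_{a1}+\sigma^2_{e1})(\sigma^2_{a2}+\sigma^2_{e2})}}.$$

Standard errors come from the inverse average-information matrix by the
delta method (numeric Jacobian for the bivariate transformations). Each
estimate gets a two-tailed t-test on residual degrees of freedom
($n$ records minus fixed-effect rank — the df convention is logged with the
p-value since conventions differ), with estimates significant at $P < 0.01$
starred; the animal effect gets a likelihood-ratio test against the
fixed-effects-only model with the 50:50 $\chi^2_0$:$\chi^2_1$ mixture null,
standard for a variance bounded at zero. "Total lactations" and "total
milking days", where used as fixed effects, are covariates by default with a
factor-coding switch, since factor-versus-covariate coding is a free choice
here. No multiple-testing correction is applied; estimates are reported
per cell.

## REML numerics

Both stages share one REML engine for models with a single structured
random term $u \sim N(0, \Sigma_0 \otimes A)$ and either an i.i.d. or an
unstructured per-animal residual. The restricted log-likelihood is evaluated
exactly from the mixed-model equations via
$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$, with $C$ factored
by sparse Cholesky (fill-reducing permutation; $\log|A|$ falls out of the
pedigree decomposition at no cost). Updates are Newton steps using the
average-information matrix $\mathrm{AI}_{jk} = \tfrac12 f_j' P f_k$ with
$f_j = \dot V_j P y$, which needs only extra MME solves. The score is
obtained by central differences of the exact log-likelihood (step
$10^{-4}$ of the parameter scale): at the problem sizes this package
targets, the trace identities behind the analytic score require
selected-inverse machinery that buys nothing over a handful of extra sparse
factorisations, and the finite-difference error is orders of magnitude below
the Newton step tolerance. Proposals outside the admissible region (or that
decrease the likelihood) are handled by capping the step length at ten times
the phenotypic variance, halving up to 30 times, and falling back to a
scaled gradient step; variances are floored at $10^{-8}\,\mathrm{var}(y)$
and pairwise correlations clamped to $|r| \le 0.999$, with boundary
convergence flagged. Convergence requires a relative log-likelihood change
below $10^{-8}$ and a relative parameter change below $10^{-6}$, or a
log-likelihood flat over three consecutive iterations (a flat ridge or
boundary), within 200 iterations. Components start at
$\sigma^2_e = 0.5\,\mathrm{var}(y)$ and
$\Sigma_0 = \mathrm{diag}(0.5\,\mathrm{var}(y)/k)$.

Two degenerate regimes are worth knowing about. With completely unrelated
animals and one record each, $\sigma^2_a$ and $\sigma^2_e$ are not
separately identifiable (the likelihood is flat along their sum); the engine
then stops at a flat point rather than inventing an answer, and the
likelihood-ratio test correctly reports no support for the animal effect.
And with two identical traits the AI matrix is singular; the step cap plus
gradient fallback drive the correlations to the $0.999$ ceiling, which is
the honest answer to machine tolerance.

## The synthetic study

The generator emulates the study design the package targets, with one RNG
stream per sub-generator so that, e.g., adding flocks does not perturb the
weather. Defaults (all in `sim_config()`):

* **Pedigree**: 3 discrete generations, 400 founders, 700 offspring per
  generation from 25 sires per generation and random mating. Recovery runs
  scale this to ~3,000–5,000 phenotyped females.
* **Weather**: daily sinusoid with annual mean 16.5 °C and amplitude
  10.5 °C peaking in mid-July (an eastern-Mediterranean climate), AR(1)
  anomalies ($\phi = 0.7$, innovation SD 1.8 °C), humidity negatively
  coupled to the temperature anomaly and truncated to [0, 100]. These make
  both query temperatures (10 and 25 °C) interior to every season's
  observed range in a typical draw.
* **Recording**: lambings September–May in proportions 0.35 : 0.49 : 0.16
  (autumn : winter : spring, the ratio of animal counts in the motivating
  recording scheme), monthly tests from day 42 to day 200, one to three
  lactations per ewe.
* **Yield model**: flock, parity and lambing-year effects, a Wilmink
  lactation baseline $a + b e^{-k\,dim} + c\,dim$ (peak near day 50, mean
  around 1.5 kg/day), plus a season-specific population reaction norm with
  per-animal genetic and permanent-environment Legendre deviations and
  0.35 kg residual SD. The default deviation covariances give slope SDs
  near 0.014–0.018 kg/°C at the query temperatures, the spread reported
  for real seasonal resilience phenotypes; the winter population curve has
  negative curvature (an interior optimum near 20 °C followed by
  heat-stress decline), autumn is monotone increasing, spring shallow.

What the generator deliberately does *not* emulate: culling and selection
(no genetic trend), seasonal feed or management shifts beyond the flock and
year effects, heterogeneous residual variance across the temperature range,
and genotype-by-flock interaction. Passing tests therefore demonstrate that
the estimation machinery recovers known parameters under the stated model —
not that the model is a complete description of any real flock.

## Validation strategy and problem sizes

Because the motivating field data (420k records) are available only on
request, validation is by oracle checks and parameter recovery, with the
published genetic parameters used as simulation ground truth: heritabilities
0.15, 0.17 and 0.03 (the last near the boundary) for univariate recovery,
and genetic correlations 0.84, 0.51 and 0.97 for bivariate recovery, each
averaged over replicate simulations on 3-generation pedigrees with ~3,000
(or 5,000 for the boundary case) phenotyped females. The testthat suite
uses 5 replicates per design and the standalone acceptance script 10; both
sizes put the replicate-mean within twice the published standard error of
the generating value when the machinery is correct, while keeping a full
run in minutes on one CPU. The end-to-end check runs the default pipeline
configuration (~700 animals per generation, ~8,000 records) and requires
the fitted population slopes at 10 and 25 °C to land within 0.015 kg/°C of
the generating values — three times the Monte-Carlo spread observed for
this configuration.

## Worked example

```{r example, eval = FALSE}
library(thermoresil)

res <- run_pipeline(out_dir = "run1", seed = 1)
res$summary          # season x trait slope means and SDs
res$heritability     # univariate animal-model estimates per trait
res$correlations     # representative bivariate runs

# or stage by stage:
ped <- sim_pedigree(seed = 101)
weather <- sim_weather("2011-01-01", "2018-12-31", seed = 102)
records <- sim_testdays(ped, weather, sim_config(), seed = 103)
records <- add_weather(records, weather,
                       station_map = tibble::tibble(
                         farm_id = unique(records$flock_id),
                         station_id = "S01"))
edited <- edit_records(records)
edited$season <- assign_season(edited$lambing_date)
fit <- fit_reaction_norm(dplyr::filter(edited, season == "autumn"), "tavg")
autoplot(fit)
derive_phenotypes(list(fit)) |> phenotype_summary()
```

## Known limitations

* The reaction-norm stage fits i.i.d. animal effects; permanent-environment
  and genetic components are not separated there, so the slope phenotypes
  carry both (the second stage then partitions variance across the
  pedigree).
* Slope SDs from BLUP coefficients are shrunken relative to the generating
  dispersion; phenotype summaries should be read as descriptive, not as
  variance-component estimates.
* Bivariate fits on small phenotype sets (a few hundred animals with
  $h^2 \approx 0.1$) often push the genetic correlation to the boundary
  with very large standard errors — visible in the default desk-scale
  pipeline run and expected at that size.
* Degree-2 polynomials only; no splines, no heterogeneous residual
  variance, no maternal effects, no genomic relationships.
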