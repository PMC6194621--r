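---
title: "Measuring availability, prices and affordability of essential medicines from procurement panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring availability, prices and affordability of essential medicines from procurement panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medaccess)
library(dplyr)
```

## The problem and the measurement model

Classical WHO/HAI medicine access surveys visit a sample of facilities on
a survey day and record, for a fixed basket of essential medicines,
whether each medicine is on the shelf and at what price. `medaccess`
adapts that methodology to *longitudinal procurement records*: monthly
purchase lines submitted by a fixed panel of hospitals over several
years. Three indicator families are computed.

**Availability.** A procurement panel never observes shelf stock, only
purchases. We therefore define a hospital as "having" a medicine in a
year if it recorded at least one purchase of it in that calendar year,
and availability as the percentage of the *panel roster* (not of
hospitals with data) meeting that definition. The window is a deliberate
modelling choice: a one-year window smooths over the quarterly purchase
cycles common in hospital pharmacy logistics, at the cost of counting a
single January purchase as year-round access. Both the roster denominator
and the annual window are fixed conventions of the package;
`availability_table()` takes the roster as an explicit input so that
hospitals with zero records still count in the denominator. Brand-level
availability (innovator vs generic) uses the same denominator as pooled
availability, so brand cells are directly comparable with each other and
with the pooled cells.

**Prices.** All strengths of a chemical entity are pooled by *smallest
unit*: each purchase line is converted to a price per reference-strength
amount of active moiety,
$$p_{\text{unit}} = \frac{\text{pack price}}{\text{pack size}} \cdot
  \frac{s_{\text{ref}}}{s},$$
with mass units (mg, g, µg) interconverted and activity units (IU) kept
as their own family — converting IU to mg would require a potency
assumption we refuse to guess, so incompatible units are a hard error.
The median price ratio of a medicine in a stratum-year is the
facility-first median (each hospital contributes the median of its own
transactions; the stratum takes the median of hospital medians) divided
by the international reference price. Facility-first medians are the
WHO/HAI convention; they stop one high-volume hospital from dominating
the stratum, and they are what makes the indicator robust to transaction
outliers — a minority of corrupted hospital values cannot move an
interior basket median. A `aggregate = "transactions"` switch provides
pooled-transaction medians for comparison.

Reference prices exist in USD for 2011–2013 only. They are converted to
CNY with purchasing-power-parity rates (defaults 3.506, 3.524, 3.545 CNY
per international dollar for 2011–2013), and local prices from 2014–2016
are deflated onto the 2013 basis with discount factors
$DF(y) = (1+r)^{2013-y}$, $r$ defaulting to 0.03/yr; an explicit
per-year DF table can be supplied instead. MPRs for 2011–2013 therefore
compare same-year prices with same-year reference prices, and MPRs for
2014–2016 compare deflated prices with the 2013 reference prices.
`deflate_prices()` stamps the batch and refuses to run twice: double
deflation silently understates recent prices, so it is an error, not a
warning.

**Affordability.** For chronic treatments we cost one defined daily dose
(DDD) at the stratum's median unit price, annualize at 365 days/yr
(lifelong daily therapy; the day count is configurable), and ask what
fraction of the population the cost would push past a budget-share
threshold $\tau$: a person with annual per-capita income $x$ crosses the
threshold exactly when $x \le c/\tau$, so
$$\text{incidence} = 100 \cdot F(c/\tau),$$
with $F$ the income distribution and the boundary closed ("a share of
10% or more"). The default threshold is 0.10 with 0.075/0.125 as
sensitivity settings. Costs are *nominal same-year* prices compared with
same-year incomes — the 2013-basis deflation exists only to bridge the
missing post-2013 reference prices in the MPR chain — and are
pre-reimbursement drug expenditures, which avoids modelling
province-specific copayment schedules. Income is per-capita; if a
household-level share is wanted, a household-size multiplier can be
folded into the cost before calling `cde_incidence()`.

## Reconstructing income distributions from grouped tables

Statistical yearbooks publish income as grouped tables: ordered groups
with a population share and a mean income. Two reconstructions are
provided.

* `method = "lognormal"` (default): fits $(\mu, \sigma)$ by minimising
  the summed squared *relative* error of the analytic group means under
  the share partition,
  $$\mathbb{E}[X \mid q_{p_{i-1}} < X \le q_{p_i}] =
    e^{\mu+\sigma^2/2}\,
    \frac{\Phi(z_i-\sigma)-\Phi(z_{i-1}-\sigma)}{p_i-p_{i-1}},$$
  using Nelder–Mead restarted once from its own optimum (relative
  tolerance 1e-14). Relative error is used so the poorest groups — the
  ones that determine catastrophic-expenditure incidence — are not
  swamped by the top group. With a single group the model is
  unidentified and `sdlog` must be fixed, in which case $\mu$ comes in
  closed form from the overall mean.
* `method = "piecewise"`: makes no distributional assumption. Bin edges
  sit at midpoints between adjacent group means, income is uniform
  within each bin, and the top group is closed with a Pareto tail whose
  mean matches the top group mean ($\alpha = m_K/(m_K - b)$). The strict
  alternative — choosing edges so every bin mean is reproduced exactly
  under uniformity — is infeasible for right-skewed tables (it requires
  $m_{i+1} > 2m_i$ all the way up), which is why the midpoint rule is
  used and the achieved relative RMSE of the implied group means is
  recorded in the `fit` element, with a warning above 5%. The piecewise
  cdf necessarily spreads the first group's mass down toward zero, so it
  overstates the extreme-poor tail relative to a lognormal; for
  incidences driven by that tail the lognormal fit is the better
  default, and that is why it is the default.

Every fitted distribution exposes `cdf` and `quantile` closures that
round-trip exactly on the fitted support, with `cdf(0) = 0`.

## Rank-based comparisons

Brand-vs-generic and regional contrasts are rank-based, applied to
per-drug values. `wilcoxon_rank_sum()` uses midranks for ties, the exact
enumeration null when the combined sample is ≤ 12 and tie-free, and the
normal approximation with tie correction and (by default) continuity
correction otherwise. `k_sample_rank_test()` is Kruskal–Wallis H with
tie correction against $\chi^2_{k-1}$; the three-region comparison is
reported with it because a single P across more than two groups calls
for a k-sample rank test, and for $k = 2$ it coincides with the
two-sided Wilcoxon normal approximation without continuity correction.
The degenerate input in which every pooled value is identical would make
the tie-corrected variance zero; both tests return $p = 1$ there — no
separation, no evidence — rather than NaN. Both are thin, contractual
surfaces over the base R implementations; the test suite validates them
against independent brute-force oracles (exhaustive rank-split
enumeration, hand-ranked H) rather than against the functions they wrap.

## What the synthetic generator emulates — and what it does not

`simulation_config()` describes a panel of 396 secondary and 763
tertiary public hospitals spread over 28 provinces grouped into
eastern/central/western regions, observed monthly 2011–2016 over a
30-medicine basket (18 acute, 12 chronic, 10 therapeutic classes, 27 on
the essential list, 4 chronic-disease medicines flagged for
affordability). Defaults were chosen once to be realistic for this
setting and are not tuned per test:

* base generic stocking probabilities spread 0.08–0.82 across the
  basket, with azithromycin at 0.85 and glibenclamide at 0.03 echoing
  the reported extremes; innovator-brand factor 0.7; region factors
  1.25/0.90/0.95 (E/C/W); a year wiggle (1, 1.08, 0.97, 0.90, 1.05,
  0.93) reproducing the observed up–down pattern; probabilities
  truncated to [0, 1];
* generic price levels log-spread 0.8–40 × IRP, innovator premium 4.5×,
  region price factors 2.1/0.95/0.95; transaction prices lognormal with
  σ = 0.2 around the cell median; post-2013 inflation 0.03/yr, exactly
  inverted by the generated discount factors;
* stocked hospital-drug-brand-years emit a Poisson(6) (truncated ≥ 1,
  capped at 12) number of monthly lines; packs alternate between one and
  two reference strengths, with ≥ 1 g strengths expressed in grams so
  the unit conversion path is exercised;
* urban/rural incomes lognormal with means equal to published per-capita
  figures 2011–2014 (urban 21,810→28,844; rural 6,977→9,892 CNY/yr) and
  σ = 0.5/0.55; quintile tables are built from the *analytic*
  conditional means, not from samples, so income-fit recovery tests
  carry no Monte-Carlo noise.

The generator's truth object records, per cell, the stocking probability
(with Poisson-binomial moments for pooled-brand and nationwide cells,
since hospitals differ by region) and the price level, which *is* the
MPR truth by construction. Two caveats matter when reading recovery
results. First, the nationwide median over hospital medians estimates
the median of a mixture across regions with different price levels —
not any single cell's `level` — so price recovery is assessed at
(drug, brand, region) level, where the truth is exact, on cells with an
expected ≥ 200 stocking hospitals per year, using the whole six-year
panel per cell. Second, the generator draws independent Bernoulli
stocking and lognormal prices: real procurement data have serial
correlation within hospitals, stock-out spells, volume discounts,
entry/exit of manufacturers and correlated regional shocks, none of
which are modelled. Passing recovery tests therefore demonstrates that
the *pipeline arithmetic* is right under known conditions, not that the
indicators are unbiased on real data.

## Numerical conventions and degenerate inputs

* Medians everywhere use the mean-of-central-pair convention for even
  counts; ties broadcast naturally through midranks.
* Reported tables round half-to-even at 2 decimals at the reporting
  layer only (`ib_generic_ratio(digits = 2)`); all internal arithmetic
  is full precision.
* The product-specific Δ excludes medicines absent in either year of a
  pair and reports how many were excluded; a pair with no common
  medicine is an error.
* Malformed procurement rows are collected into a line-numbered rejects
  report and never abort a run — observational procurement data are
  dirty — but an unknown province is a hard error naming the province,
  because it means the region map is wrong for the whole file. The
  packaged province→region map follows the standard Chinese statistical
  grouping (10 eastern / 8 central / 10 western provinces here) and can
  be overridden.
* Dosage forms with non-mass units (inhalers in µg per actuation,
  insulin in IU) are unitized per drug through the reference-strength
  declaration in the drug table rather than by any global rule.

## Problem sizes in the test suite

The suite validates each operation against independent oracles (closed
forms, brute-force enumeration, generator ground truth). Full-scale runs
use the default panel (1,159 hospitals × 30 medicines × 6 years, about
10⁶ records, a few seconds to generate and under half a minute to push
through the whole pipeline); property tests use smaller panels of 40–300
hospitals and 3–10 medicines, 100-replicate income-fit recovery, and
2,000 null simulations for the empirical size of the rank-sum test.

## Known limitations

* Availability from purchases is an upper bound on shelf availability
  within the window and carries no stock-out duration information.
* The MPR chain depends on the discount-rate assumption for 2014–2016;
  if the true price-index path differed from 3%/yr, post-2013 MPR levels
  shift proportionally (supply an explicit DF table when one exists).
* CDE uses one medicine at a time against per-capita income: no
  multi-drug regimens, no insurance reimbursement, no household pooling.
* The rank tests are exposed per-drug-value; how medicines are assigned
  to comparison groups is the caller's responsibility.
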