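---
title: "Ascertainment bias in family-based fertility estimates of schizotypy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertainment bias in family-based fertility estimates of schizotypy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertbias)
```

## The scientific question

Evolutionary accounts of schizophrenia face a puzzle: the disorder is
highly heritable, clearly fertility-reducing, and yet persists at a stable
prevalence of about 1%. One family of explanations treats schizotypy —
psychosis-prone personality traits — as amplifying a sexually selected
fitness indicator: schizotypy-increasing alleles enhance courtship-related
traits in high-fitness individuals but raise the risk of schizophrenia in
low-fitness individuals. Under that hypothesis schizotypy can be selectively
neutral or even positively selected, despite the reproductive costs of
schizophrenia itself.

The standard empirical objection is that fertility is reduced not only in
patients but also in their unaffected relatives, which is usually read as
strong negative selection on schizotypy-increasing alleles. `fertbias`
implements the counter-argument in quantitative form: **if diagnosis risk
is concentrated in low-fitness families, then sampling families through
diagnosed patients over-represents exactly the families with the lowest
fertility, and the resulting estimate is biased downward** — potentially
far enough to make neutral or positively selected schizotypy look
negatively selected. The package provides the closed forms of this bias, a
family-population simulator with the assumed structure, proband-based
ascertainment and estimation on simulated data, and parameter sweeps that
map the misclassification region.

## The model

Families are the unit of analysis. Schizotypal families are split into a
high-fitness class (fraction `1 - p_low`) and a low-fitness class
(fraction `p_low`; default 0.5, the symmetric-fitness assumption). A member
of a high-fitness schizotypal family is diagnosed with probability
`P(D|H)`; in a low-fitness family the probability is `r` times larger,
`P(D|L) = r P(D|H)` with `r >= 1`. In non-schizotypal families the
diagnosis probability is negligibly small. Class mean fertilities, relative
to the population mean of 1, are `W_H` and `W_L = W_H - d` with `d >= 0`;
the fertility difference `d` includes the fertility-reducing effects of
schizophrenia itself, so no separate within-family coupling between
diagnosis and fertility is modelled.

Given a diagnosed patient, Bayes' theorem gives the probability that their
family is low-fitness:

$$P(L|D) = \frac{r\,P(L)}{r\,P(L) + 1 - P(L)},$$

which reduces to $r/(r+1)$ under the symmetric prior. The true mean
relative fertility of a random schizotypal-family member is the
prior-weighted class mean

$$W = (1 - p_{low})\,W_H + p_{low}\,W_L,$$

whereas a study that samples families through patients effectively weights
the classes by the posterior, estimating

$$\hat W = P(H|D)\,W_H + P(L|D)\,W_L.$$

The difference is the ascertainment bias

$$W - \hat W = d\,\bigl(P(L|D) - P(L)\bigr)
            \;=\; \frac{d\,(r-1)}{2\,(r+1)} \quad (p_{low} = 0.5),$$

always positive when `r > 1` and `d > 0`, increasing in `r` and linear in
`d`, and independent of `W` and of the absolute baseline `P(D|H)`. The
study's verdict flips — apparent negative selection (`w_hat < 1`) despite
true neutrality or positive selection (`W >= 1`) — exactly when

$$1 \le W < 1 + d\,\bigl(P(L|D) - P(L)\bigr).$$

At `r = 3`, `d = 1` the bias is 0.25: true neutrality (`W = 1`) is
reported as `w_hat = 0.75`.

```{r worked-example}
bias_result(ssm_params(r = 3, d = 1, W = 1))
```

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `r` | relative diagnosis risk `P(D|L)/P(D|H)` | — | the model's central quantity; `r = 1` (no signal) is allowed so the degenerate case is testable |
| `d` | class fertility difference `W_H - W_L` | — | relative-fertility units; includes schizophrenia's own fertility cost |
| `W` | true mean relative fertility of schizotypal-family members | 1 | neutrality as the reference point |
| `p_low` | prior `P(L)` | 0.5 | the symmetric-fitness assumption; other priors are a documented generalisation |
| `prop_schizotypal` | fraction of schizotypal families | 0.5 | not pinned down by the theory; the closed forms do not depend on it, only the simulator's sample sizes do |
| `family_size` | members per family | 5 | a realistic nuclear-family scale; fixed rather than random because the algebra treats members exchangeably |
| `p_diag_high` | baseline `P(D|H)` | 0.01 | order of lifetime prevalence; the closed forms are invariant to it, the simulator only needs it small enough that multi-patient families are rare |
| `base_mean_offspring` | population mean offspring count | 2 | near-replacement fertility; a pure scale factor that cancels in every relative-fertility estimate |
| `tol` (`classify_regime`) | neutrality half-width | 0.01 | `W = 1` is measure-zero in floating point; sweeps that must match the analytic flip region exactly use `tol = 0` |

The `W, d` parameterisation is canonical (the headline formulas are
expressed in it); `w_high` and `w_low` are derived, and constructions that
would imply a negative `w_low` are rejected.

## The simulator, and what it does not emulate

`simulate_population()` draws each family's schizotypy label, fitness
class, per-member diagnosis indicators (Binomial within family) and
per-member offspring counts (Poisson with class-specific mean). Poisson is
the minimal-assumption count law for a mean-parameterised fertility; the
analytic results depend only on class means, so any mean-parameterised law
would validate the same identities. Diagnosis and fertility are independent
within class by design — all fertility structure flows through class
membership.

Real family studies differ in ways the simulator deliberately omits: family
sizes vary; relatives come in degrees (parents, siblings, offspring) that
studies may weight differently; fitness is continuous rather than
two-class; diagnosis within a family is correlated beyond the class effect;
and realised fertility is censored by observation windows and, in modern
populations, decoupled from mating success by contraception. Passing the
Monte-Carlo checks therefore shows that the closed forms are internally
correct under the model's assumptions — not that the bias in any particular
empirical study equals the closed-form value.

## Ascertainment and estimation choices

* **Proband-wise sampling.** Every diagnosed individual is a proband and a
  family enters the sample once per proband, so family inclusion weight is
  proportional to its diagnosed count. This is the sampling law under which
  the low-fitness fraction among draws converges to `P(L|D)`; family-wise
  inclusion ("any family with at least one patient, once") is offered for
  comparison but diverges from the posterior whenever families can hold
  several patients.
* **Patients are included** in family fertility means, consistent with `d`
  absorbing schizophrenia's own fertility cost.
* **Normalisation** is by the whole-population mean offspring count
  (schizotypal and non-schizotypal members alike), matching the definition
  of relative fertility.
* **Uncertainty.** Standard errors come from a nonparametric bootstrap over
  families (default 500 resamples) — families, not individuals, are the
  independent units. `compare_analytic_mc()` instead uses the spread across
  independent replicates, which is the relevant uncertainty for checking
  the Monte-Carlo means against the analytic values.

```{r mc, eval = FALSE}
sp <- simulation_params(ssm_params(r = 3, d = 1, W = 1),
                        n_families = 10000, seed = 1)
compare_analytic_mc(sp, n_replicates = 200, seed = 42)$summary
```

The validation study in `analysis/03_monte_carlo_validation.R` uses 100
replicates of 5,000 families, which puts the 99% confidence intervals on
the Monte-Carlo means at a few thousandths of a relative-fertility unit —
narrow enough to detect any real discrepancy from the closed forms while
keeping the script interactive.

## Numerical choices

Floating point cannot make all three identities — the closed-form bias, the
posterior-weighted estimate, and `w_hat = W - bias` — bit-exact
simultaneously, so one route is primary: `fertility_bias()` evaluates
`d * (P(L|D) - P(L))`, which is exactly zero at `r = 1` (the posterior then
equals the prior to the last bit) and at `d = 0`; `estimated_fertility()`
is defined as `true_fertility() - fertility_bias()`, making the consistency
identity exact by construction. The posterior-weighted form is verified
against this route to floating-point tolerance in the test suite.
`flip_condition()` evaluates `W < 1 + bias` in its rearranged form
`w_hat < 1`, so its verdict agrees bit-for-bit with classifying the
estimate itself; cells lying exactly on the flip boundary are then resolved
consistently everywhere. Sweeps skip (with a warning) or reject (under
`strict = TRUE`) grid cells that would imply negative low-class fertility.

## Limitations

The model is deliberately coarse: two fitness classes, one scalar bias, no
genetic architecture, no multigenerational dynamics. It demonstrates that
patient-family fertility estimates are downward-biased under its
assumptions and by how much within the model — it does not provide a
correction estimator for real study data, and it cannot quantify the bias
in any specific empirical study, where `r` and `d` are unknown.
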