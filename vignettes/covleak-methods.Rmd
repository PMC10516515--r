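---
title: "Auditing covariance-based reconstruction in federated analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing covariance-based reconstruction in federated analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covleak)
```

## The threat model

A federation consists of `n_h` data-owner servers; server `j` holds a matrix
`X_j` with `n_j` observations (rows) of `n_p` variables (columns). A central
analyst — the *client* — cannot see raw data but may call three primitives
that essentially every federated-analysis platform offers:

* **T1** a sample mean `Mean(x)` of a server-side vector,
* **T2** a sample covariance `Cov(x, y)` of two server-side vectors
  (denominator `n − 1`; we state this explicitly because platforms differ),
* **T3** a way to install client-known vectors server-side (a broadcast /
  client-to-server matrix transfer, as used routinely for parameter updates).

A malicious client can combine these into exact data reconstruction. For any
client-known probe `y_i`,

$$\mathrm{Cov}(x, y_i) \;=\; \tfrac{1}{n-1}\, y_i^\top x \;-\;
  \tfrac{n}{n-1}\, \overline{x}\, \overline{y}_i ,$$

so `n` linearly independent probes turn `n` covariance answers plus one mean
answer into a nonsingular linear system for `x`:

$$x \;=\; (n-1)\,(Y^\top)^{-1} \tilde V \;+\; n\,\overline{x}\,(Y^\top)^{-1}
  \tilde m ,$$

where `Ṽ` stacks the returned covariances and `m̃` the probe means, which
the client computes itself. Standard-normal probes are used by default: they
are almost surely linearly independent, almost surely have all-distinct
entries (so they pass dichotomous-level checks), and they mimic what an
attacker would actually send.

The testbed (`federation()`, `query_mean()`, `query_cov()`, `broadcast()`,
`query_regression_coefficient()`) is deliberately in-process — no
networking, no bindings to real platforms — because the audit target is the
*endpoint contract*, not a wire protocol. Every endpoint call is appended to
a query log, so the linear-in-`n` communication claim is checkable: a
single-variable attack is exactly `n` covariance queries plus one mean
query (the broadcast is a separate record).

## Disclosure control

The mock policy mirrors DataSHIELD-style answer rules: a mean is released
only when the sample size strictly exceeds 3, a covariance only when it
strictly exceeds 6 (condition C1), and every dichotomous vector involved in
a release must show each of its two levels at least 3 times (condition C2).
All thresholds are configurable (`disclosure_policy()`). Two modelling
choices:

* a vector is *dichotomous* iff it takes exactly two distinct non-missing
  values — continuous probes therefore pass C2 trivially, which is exactly
  why the attack is compatible with these checks;
* endpoints operate on listwise complete cases of the referenced vectors,
  and the `n` entering every formula is the complete-case count. The
  reconstruction itself requires a fully observed target column (the client
  cannot know the server-side missingness pattern), so the supported route
  for incomplete data is complete-case loading (`load_cnsim_csv()`).

## Numerical choices in the solve

The reconstruction is computed by a QR factorization of `Yᵀ` with one step
of iterative refinement — never by forming `(Yᵀ)⁻¹`. Additionally, the mean
term is evaluated through an exact identity: since `m̃ = Yᵀ 1 / n`, it holds
that `(Yᵀ)⁻¹ m̃ = 1/n`, so

$$\hat x \;=\; (n-1)\,(Y^\top)^{-1}\tilde V \;+\; \overline{x}\,\mathbf 1 .$$

This is the same equation, but it avoids pushing the numerically large
`n·x̄·m̃` entries through the solve; empirically it reduces the worst-case
elementwise error at `n = 250` from ~1e-11 (under an ill-conditioned probe
draw) to ~1e-13, and it makes the identity-probe closed form
`x̂_s = (n−1)Cov(x, e_s) + x̄` hold exactly. Rank deficiency of a probe draw
(probability ~0) triggers a redraw with a derived sub-seed, bounded at 10
attempts; an explicit `probe_matrix()` is validated at relative tolerance
1e-8. An orthonormalized-probe mode is deliberately *not* the default:
plain standard-normal probes are what the audited platforms would receive.

Dichotomous target columns are reconstructed as reals and reported as-is —
no rounding to levels — since exactness, not classification, is the claim
being audited.

## The model-fit side channel

Some platforms expose no covariance endpoint but do return simple
linear-model fits. Hard-coding a probe `y_i` as the regressor for the
private response `x` yields
`β̂ = Cov(x, y_i) / Var(y_i)`, and the client recovers
`Cov(x, y_i) = β̂ · Var(y_i)` because `Var(y_i)` is known
(`covariance_from_regression()`). `reconstruct_variable(channel =
"regression")` runs the whole attack through this channel; it agrees with
the covariance channel to ~1e-10, which the tests assert.

## Noise averaging

If the server adds zero-mean noise `ε_i` to each covariance and `γ` to the
mean, the client observes

$$x^{\mathrm{noisy}} \;=\; x \;+\; (n-1)(Y^\top)^{-1}\varepsilon \;+\;
  n\,\gamma\,(Y^\top)^{-1}\tilde m ,$$

an unbiased, finite-variance perturbation of the truth. Averaging `R`
independent runs (fresh noise per run, probes fixed — the estimator
averages over noise, not probes; a probe-redraw option exists but is off by
default) therefore converges to `x` with MSE ∝ 1/R.
`run_noise_experiment()` measures this: *relative MSE* is defined as the
mean squared error divided by the sample variance (denominator `n − 1`) of
the true vector, since the platforms being emulated plot a relative error
without fixing units. Default noise levels are sds
`{0.01, 0.1, 1, 10} × sd(x)` — chosen to span negligible-to-overwhelming
perturbation — and the experiment reports the median and the 5th–95th
percentile over 200 replicates per level. The package's standard study size
for this experiment is `n = 50`, `R ∈ {1, 10, 100}`, 200 replicates, which
resolves the `1/R` slope to well within ±0.3 on the log-log scale.

Within a replicate the estimators at different `R` are nested prefix means
of one noise stream; this makes the decay curve smooth without biasing any
single cell. Experiment drivers temporarily disable the per-query
transcript (≈10⁶ endpoint calls per experiment would otherwise be logged);
single attacks always keep the full log.

## Privacy accounting

The accountant (`privacy_accountant()`) implements ε-differential privacy
via the Laplace mechanism with *sequential additive composition* — no
advanced or Rényi composition, matching how such budgets are specified in
the platforms being audited. A release of sensitivity Δ with Laplace scale
`b` costs `ε = Δ/b`; a query whose charge would exceed the remaining budget
is refused before being answered. The noise policy is parameterized by
standard deviation for both distributions, so the Laplace scale is
`b = sd/√2`.

Sensitivities assume records clipped to public per-variable bounds `[a, b]`
(width `w = b − a`); clip bounds are treated as domain knowledge (e.g. BMI
in [15, 50]), not data-derived:

* mean: `Δ = w/n`;
* covariance of two private clipped variables: replacing one record
  `(x_s, y_s)` changes the `n−1`-denominator covariance by
  `[x_s'y_s' − x_s y_s − δ_x ȳ − δ_y x̄ − δ_xδ_y/n]/(n−1)`; maximizing over
  the clip box (the maximum is attained at corners) gives the exact bound
  `Δ = w_x w_y / n`, which the tests cross-validate by corner enumeration
  and random one-record perturbations;
* covariance against a *public* probe `y`: only the private record moves,
  and the change is exactly `δ (y_s − ȳ)/(n−1)`, so
  `Δ = w · max_s |y_s − ȳ| / (n−1)`.

Probe-only releases (means or covariances of broadcast vectors) are charged
`ε = 0`: differential privacy protects the dataset, and broadcast vectors
are client-known public inputs. These formulas sit behind one interface so
a platform's own sensitivity calculus can be swapped in.

One full attack iteration costs
`ε_att = Σ_i ε_cov(x, y_i) + ε_mean(x)`, and a budget `ε_A` admits
`⌊ε_A / ε_att⌋` iterations. `run_dp_attack_experiment()` evaluates the
trade-off over budgets in `[ln(1.01), ln(3)]` (the conventional audit
range) — a dedicated test verifies that this closed form equals the number
of attacks a live accountant actually admits before refusing. The noise-sd
grid `{500, 1500, 5000}` (absolute, on BMI-scale data with clip width 35)
was chosen once so that admitted iterations span 0 to a few dozen across
the budget range at the package's study size `n = 30`; medians are over 200
replicates, and a replicate admitting zero iterations scores *infinite*
relative error (no reconstruction is worse than any reconstruction), which
keeps near-threshold cells honest. Two directions are asserted: more noise
admits at least as many iterations at fixed budget, and more budget never
increases the median error at fixed noise. Under every such cell the
DP-limited attack error stays orders of magnitude above the noiseless
attack's — the budget genuinely blocks reconstruction.

The flip side, `run_standard_analysis_budget()`, charges the same
accountant for routine work: two means, two variances and one covariance of
two metric variables, and separately all pairwise covariances among the
five metric variables. At tight noise a single BMI-scale covariance costs
`(35²/100)/b ≫ ln 3`, exhausting the whole budget — differential privacy at
these budgets precludes even basic descriptive analysis, which is precisely
the dilemma the audit is meant to expose.

## Synthetic federations

`generate_federation()` builds CNSIM-like federations so every experiment
runs without any download: by default 3 servers totalling 9379 observations
of 11 obesity-related variables — five continuous columns (BMI-like
Normal(27, 4²) clipped to [15, 50]; total cholesterol, triglycerides, HDL
and glucose with analogous lab-scale parameters) and six dichotomous
columns with fixed prevalences. Only the *structure* mimics the well-known
tutorial federation; the distribution parameters are this package's own
choices and are fully configurable. Dichotomous columns are drawn Bernoulli
and then minimally adjusted so each level occurs at least 3 times whenever
`n_j ≥ 6` — C2 holds by construction, as it would in any dataset that
passed intake QC. Missingness is injected completely at random (MCAR), the
simplest mechanism consistent with complete-case analysis. Ground truth is
archived per server alongside the served (possibly incomplete) copies, and
the same seed reproduces CSV output byte for byte.

What the generator does **not** emulate: real covariance structure between
variables, non-normal tails, informative missingness, or coding quirks of
real exports. None of these affect the attack's algebra — it is exact for
*any* numeric column — but error magnitudes on real data depend on scale
and conditioning, so passing tests here demonstrate the mechanism, not a
bound for every dataset. The loader (`load_cnsim_csv()`) ingests real
CSV exports (header row, empty cell = missing, non-numeric columns recoded
as 0-based level codes) with listwise complete-case filtering for audits of
actual federations.

## Study sizes and determinism

All randomness flows from explicit seeds: probe seeds, experiment base
seeds (with derived per-replicate sub-seeds kept below 2³¹), and an
optional dedicated server-side noise stream (`noise_policy(rng_seed = )`)
that makes endpoint noise reproducible independently of client-side RNG
use. With noise sd 0 and the policy disabled, endpoint answers are
deterministic bit for bit; `sd = 0` consumes no RNG draw at all.

The package's default experiment sizes — reconstruction demonstrations at
`n = 250`, the noise-averaging study at `n = 50` with 200 replicates, the
privacy trade-off at `n = 30` with 200 replicates — were chosen as the
smallest sizes at which each quantity of interest (exactness, the `1/R`
slope, the budget/accuracy directions) is resolved cleanly; all are
configurable.

## Known limitations

* The federation is in-process; timing, serialization and transport-layer
  defenses are out of scope (so wall-clock scaling is not benchmarked, only
  query counts).
* A Krylov-subspace solve for very large `n_j` is not implemented; the dense
  QR is cubic, though in practice communication dominates long before that
  matters.
* The accountant implements pure ε-DP with simple composition only.
* Sensitivity formulas are the package's own derivations for the clipped
  mean/covariance; platforms with different release definitions should swap
  in their own calculus behind the same interface.
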