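---
title: "Methods: Bayesian network meta-analysis of minimally invasive HCC therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian network meta-analysis of minimally invasive HCC therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The evidence base and its data model

Most patients with unresectable hepatocellular carcinoma (HCC) are treated
with minimally invasive procedures rather than surgery: transarterial
chemoembolization (TACE) as the standard of care, ablative techniques (RFA,
PEI, PAI, HIFU), radiation-based approaches (RT, EBRT, TARE-90Y), drug-eluting
bead TACE, sorafenib, and combinations of TACE with these. Head-to-head
randomized trials exist only for a minority of the possible pairings, so the
relative efficacy of the full set of 13 therapies can only be estimated by a
network meta-analysis (NMA) that propagates evidence through shared
comparators.

`hcc_network()` loads the packaged evidence base: 42 randomized articles
(5,666 patients) forming 16 head-to-head designs, each article flagged with
the yearly overall-survival horizons it reports (OS-1 to OS-4). Two details
of the transcription matter for every downstream count and are data, not
heuristics:

* The four genuinely three-arm articles print three pairwise sub-rows each,
  but every physical arm is stored exactly once in the canonical arms table
  and referenced by its comparisons. This is what makes the patient totals
  (5,666 overall, 2,392 TACE, 891 RFA) come out right; summing the printed
  rows double-counts shared arms.
* One article randomized the same treatment pair twice with disjoint
  patients. Its arms table carries a `subtrial` index: one article for
  descriptive counting, two independent trials for estimation.

The loader cross-validates the printed comparison rows against the arms
table (same treatments, same sizes) and refuses to load on any disagreement.

At the 4-year horizon the only article containing PAI drops out (it reports
OS-1..3 only), which disconnects PAI from the rest of the network.
`connected_component()` therefore restricts each horizon's analysis to the
component containing the reference treatment: 13 treatments at OS-1..3, 12
at OS-4.

## From survival proportions to hazard ratios

The trials report survival *proportions* at yearly horizons, not hazard
ratios. The package reconstructs trial-level log HRs with the complementary
log-log transform, the standard aggregate-data route: with survival
proportion $S = s/n$ at horizon $t$ and cumulative hazard $H = -\ln S$,

$$\widehat{\ln \mathrm{HR}}_{ab} = \ln H_a - \ln H_b,
\qquad
\widehat{\mathrm{Var}}(\ln H) = \frac{1 - S}{n\,S\,(\ln S)^2},$$

the per-arm variances adding. This assumes proportional hazards up to the
horizon and uses exactly the quantities the trials publish; it cannot use
censoring information, which aggregate proportions do not carry. Arms with
$s = 0$ or $s = n$ receive a continuity correction (+0.5 survivors, +1 at
risk) and are flagged. Within a multi-arm trial all contrasts share the
baseline arm, so their sampling covariance has the baseline arm's
log-cumulative-hazard variance off the diagonal; a Monte-Carlo test checks
this covariance against binomial resampling.

Orientation convention throughout: a log HR of $b$ versus $a$ below zero
means $b$ has the lower hazard (better survival).

## Direct pooling

Per design, trial-level contrasts are pooled by inverse-variance fixed
effect and by DerSimonian–Laird random effects
($\tau^2 = \max(0, (Q - (k-1))/C)$, $C = \sum w - \sum w^2 / \sum w$).
Random effects is the reporting default; both are exposed because
single-design heterogeneity is of interest in its own right. Confidence
intervals use the normal 1.96 quantile on the log scale, without a
Knapp–Hartung adjustment. The implementation is checked against hand-derived
closed forms and against `metafor::rma` (FE and DL) as an independent
oracle.

## The Bayesian consistency model and its sampler

The NMA is contrast-based: trial $i$ contributes its observed baseline
contrast vector $y_i$ with likelihood

$$y_i \sim \mathcal N\!\big(X_i d,\; S_i + \tau^2 P_i\big),$$

where $d$ holds the basic parameters (log HR of each treatment versus TACE,
$d_{\mathrm{TACE}} \equiv 0$), $X_i$ maps contrasts to differences of basic
parameters, $S_i$ is the sampling covariance, and $P_i$ has unit diagonal
with 1/2 off-diagonals for contrasts sharing a baseline arm (the standard
exchangeable random-effects structure for multi-arm trials). One $\tau$ is
shared across all contrasts of a horizon. A contrast-based normal
approximation was chosen over an arm-based binomial likelihood because the
evidence base *is* a set of horizon-specific log HRs, and it keeps the
sampler conjugate.

Priors: $d_k \sim \mathcal N(0, 10^2)$ and $\tau \sim \mathrm{U}(0, 5)$ on
the log-HR scale — vague at the scale of plausible hazard ratios. Both are
configurable in `nma_spec()`; a `method = "fixed"` switch sets
$\tau \equiv 0$ (the common-effect model), which is also what the
degenerate-network oracles below require, since $\tau$ is unidentified with
a single contrast.

The sampler is Metropolis-within-Gibbs:

* $d \mid \tau$ is drawn **jointly** from its exact multivariate-normal full
  conditional (the model is linear-Gaussian given $\tau$), so the $d$
  component mixes essentially as an independence sampler;
* $\tau \mid d$ takes a random-walk Metropolis step with a uniform prior,
  the proposal scale adapting toward 44% acceptance by Robbins–Monro
  *during burn-in only*, so the post-burn-in kernel is fixed and valid.

Defaults are 4 chains of 20,000 kept iterations after 5,000 burn-in.
Because of the conjugate joint update, far shorter chains carry adequate
effective sample size; the test suite and the recovery experiment use 2
chains of 1,200 after 400 — a deliberate problem-size choice that keeps a
140-fit simulation study cheap while leaving rank probabilities accurate to
a few permille. Chains are seeded deterministically from the spec seed, so
every fit is bit-reproducible. Convergence is summarized by split
$\hat R$ per parameter with a warning above 1.05.

Correctness is anchored to independent closed forms rather than to another
NMA package: a one-design network must match the direct pooled estimate
(conjugate normal algebra); an A–B–C chain with direct data only must give
the indirect A–C estimate with added means and added variances; a consistent
triangle with tiny errors must reproduce its generating parameters; and the
per-draw consistency identity $d_{ac} = d_{ab} + d_{bc}$ holds by
construction because all contrasts are formed from basic parameters.

## Ranking

`rank_probabilities()` ranks treatments within each draw (lower hazard =
rank 1; exact ties, which arise only from degenerate draws, are broken by a
seeded jitter of magnitude 1e-12), giving a doubly stochastic matrix
$P[t, r]$. SUCRA is its cumulative summary,

$$\mathrm{SUCRA}_t = \frac{1}{T-1} \sum_{r=1}^{T-1} P(\mathrm{rank}_t \le r),$$

equal to 1 for a certain winner, 0 for a certain loser, averaging exactly
0.5. Tested properties include double stochasticity, label invariance,
stochastic-dominance monotonicity, and the $T = 2$ closed form
$\mathrm{SUCRA} = p(\text{best})$.

## Design-level inconsistency and the net heat decomposition

Consistency — that indirect and direct estimates of the same contrast agree
— is the load-bearing assumption of any NMA. The package assesses it at the
design level: trials sharing a design are pooled fixed-effect
(`design_estimates()`), and the design-level estimates are regressed on the
consistency design matrix by weighted least squares. The residual
$Q = \sum_d w_d (y_d - \hat y_d)^2$ is zero exactly when the design network
is a tree and decomposes additively over designs. Design-level fixed-effect
aggregation (rather than folding within-design heterogeneity into the
weights) is what makes this decomposition exact; within-design
heterogeneity is reported separately through the pairwise $\tau^2$.

`net_heat()` produces the two matrices behind a net heat display: the
contribution matrix, from row-normalized absolute hat-matrix entries
($H = X(X'WX)^- X'W$, pseudo-inverse with tolerance 1e-10, reference column
dropped to fix the gauge), and the change matrix, from refitting with each
design's direct evidence detached in turn — entry $(r, c)$ is the change in
design $r$'s inconsistency contribution when design $c$ is removed (warm
colours = decrease). Detaching can never increase the refitted $Q$ on the
remaining designs, since the refit minimizes it. The toy single-loop network
(directs 0, 0, 1 with unit variances; fitted 1/3 and 2/3, $Q = 1/3$) is
verified against a brute-force quadratic minimizer, and hat-matrix
idempotence and $Q$ additivity are checked on random connected networks.
No graphics are produced; the matrices are the tested product.

## The synthetic-data generator

`simulate_network()` generates what the analysis assumes: trial-specific
contrasts $\delta \sim \mathcal N(d\text{-contrast}, \tau^2)$ (covariance
$\tau^2/2$ within three-arm trials), arm survival curves tied to the
reference curve on the cumulative-hazard scale,
$S_{\mathrm{arm}}(t) = S_{\mathrm{ref}}(t)^{\exp(\mathrm{effect})}$
(proportional hazards by construction), and per-patient survival intervals
drawn multinomially so survivor counts are binomial at each horizon *and*
monotone across horizons. It emits the same two-file CSV schema the loader
reads, so synthetic networks exercise the identical code path as user data.

`fixture_scenario()` mirrors the packaged network's topology exactly — same
designs, same outcome-reporting pattern, including the OS-4 disconnection of
PAI. Its defaults are the package's chosen study conditions: true effects
spread over the log-HR range seen in this literature (HR roughly 0.24–1.33
versus TACE), $\tau = 0.1$, arm size 100, and a TACE survival curve of
(0.65, 0.45, 0.30, 0.20) over years 1–4, a typical unresectable-HCC course
under chemoembolization. What the generator does *not* emulate: censoring
and accrual processes, non-proportional hazards, outcome-dependent
reporting, and systematic (rather than random) differences between designs
— so passing recovery tests validate the estimation machinery under the
model's own assumptions, not robustness to their violation.

`recovery_experiment()` runs the full pipeline per replicate and reports
bias, RMSE, and 95% credible-interval coverage with Monte-Carlo standard
errors; non-converged replicates are flagged, never dropped. At the default
conditions (100 replicates, $n = 100$/arm) coverage of every basic parameter
stays within [0.90, 0.99], and at $n = 1600$/arm (40 replicates) the maximum
absolute bias is well under 0.05 log-HR units.

## What is and is not numerically reproducible

The published per-study hazard ratios and the original model settings
behind the source league tables are not recoverable from aggregate data, so
those tables are not an exact target. Three things *are* reproduced and
continuously tested:

1. every descriptive count of the evidence base, exactly;
2. the behaviour of each pipeline stage against independent closed forms
   and simulation oracles;
3. the qualitative ranking statement, by refitting the NMA from the
   *published design-level direct estimates* bundled with the package
   (`published_direct_estimates()`): PEI comes out clearly last at OS-1 and
   OS-2, and TACE+HIFU first — though at this design-level resolution
   TACE+HIFU and TACE+RT are statistically tied for the top (their SUCRAs
   differ by less than Monte-Carlo error even at very long chains),
   matching the reported near-equivalence of the leading TACE combinations.
   One transcribed interval (PAI vs PEI at OS-2) does not bracket its point
   estimate in the source; it is kept verbatim and only its width is used.

## Numerical and degenerate-input choices

* Continuity correction 0.5/1.0 only at boundary counts; corrected arms are
  flagged in the output.
* Pseudo-inverse tolerance 1e-10 in the consistency fit; the reference
  column is dropped rather than constrained.
* The tau proposal scale is clamped to [1e-4, tau_upper]; acceptance
  collapsing to zero after adaptation is an error, not a warning.
* Disconnected networks are an error at model-building time; the intended
  route is `connected_component()` first, which logs what it drops.
* A single-trial design passes through pooling unchanged (Q = 0,
  $\tau^2 = 0$) under either model.

## Known limitations

Design-level inconsistency uses fixed-effect aggregation, so strong
within-design heterogeneity inflates apparent consistency of the design
estimate rather than the net-heat Q. The cloglog reconstruction ignores
censoring, as any aggregate-proportion method must. The qualitative ranking
check inherits the width of the published intervals, which encode the
original authors' (unpublished) study-level weighting. And the sampler is
specialized to the contrast-based normal likelihood; arm-based binomial
modelling would need a different update for $d$.
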