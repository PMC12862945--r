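---
title: "Context-modulated brain-state dynamics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-modulated brain-state dynamics: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two groups of listeners hear the same ambiguous spoken story after
receiving different one-paragraph framings (an "affair" reading versus a
"paranoia" reading). The question is whether and how that brief contextual
prime changes the large-scale brain dynamics of comprehension, measured as
fMRI time series averaged into 17 canonical cortical networks at
TR = 1.5 s, and the moment-to-moment interpretive judgments of independent
behavioral listeners pressing a key whenever the story supports their
assigned reading.

`storystates` implements the full analysis as a reusable, tested pipeline
and pairs it with a synthetic-data generator that reproduces the
statistical structure the analysis assumes, so every stage can be checked
against ground truth.

## Brain states as a Gaussian HMM

A brain state is a recurring multivariate activation pattern across the 17
network channels. We model the per-subject, z-scored network series with a
hidden Markov model whose emission for state $k$ is
$\mathcal{N}(\mu_k, \Sigma_k)$ with a full covariance per state, and whose
latent dynamics are a first-order chain with transition matrix $A$ and
start vector $\pi$.

Key estimation choices:

* **Dwell-time-informed initialization.** The diagonal of $A$ is
  initialized to $1 - \mathrm{TR}/d$ for an expected dwell $d$ of 7 s
  (about 4–5 TRs), off-diagonal mass uniform, $\pi$ uniform, means drawn
  from $\mathcal{N}(0,1)$ under the restart seed, covariances identity
  plus a ridge $\epsilon = 10^{-6}$. The dwell prior only shapes the
  starting point: transitions are re-estimated freely, and a property test
  verifies that data generated with a 12-TR dwell are recovered within 15%
  from a 4.67-TR initialization.
* **Restarts.** Five independent initializations per model; the restart
  with the highest training log-likelihood is kept, with per-restart seeds
  and log-likelihoods retained as provenance. Our EM is deterministic
  given the initialization, so seeds influence only the mean draws; this
  is a documented simplification of a description in which seeds also
  perturb the EM path, and costs nothing because a deterministic EM from
  the same start is a fixed point of that scheme.
* **Numerics.** The forward–backward and Viterbi recursions run in log
  space (Rcpp); the ridge is re-applied to every covariance at every
  M-step, and the per-iteration log-likelihood is asserted non-decreasing
  on every fit. EM stops at a relative log-likelihood change of $10^{-4}$
  or 500 iterations (the source description is silent; these are standard
  values).
* **Model range.** Models with $K$ = 2–20 states are fit separately to
  four groups: affair ($n=19$), paranoia ($n=19$), combined ($n=38$), and
  a seeded balanced subsample (9 affair + 10 paranoia) that matches the
  context groups' size while preserving heterogeneity.
* **Validation.** Leave-one-subject-out cross-validation reports per-fold
  held-out log-likelihood and cross-fold pattern reliability, with states
  matched across folds by the Hungarian algorithm on Pearson correlations
  of mean patterns (verified against exhaustive permutation search for
  $K \le 6$).

## Reliability screening and consensus clustering

Rather than selecting a single "best" $K$, every state from every model and
group enters a pooled analysis after passing three filters: a minimum
activation (some network's mean exceeds 0.1 in absolute z units), bootstrap
95% CI widths on the mean activation below 0.3 (1000 resamples of the TRs
assigned to the state), and split-half pattern reliability above 0.5. Two
readings left open by the source are implemented with documented defaults:
the CI criterion applies to **all** networks by default (an
active-networks-only mode exists), and the split is **chronological**
(first versus second half of assigned TRs, the reading most conservative
against temporal autocorrelation; odd/even is available).

Surviving patterns are binarized to active-network sets (positive mean
> 0.1 by default; an absolute-value rule is available) and clustered by
Jaccard distance with average-linkage agglomerative clustering, cutting the
dendrogram at distance $1 - t$ for a similarity threshold $t = 0.8$ chosen
after a stability sweep over $t = 0.60\ldots0.90$ (consensus patterns of
the top five clusters are greedily best-matched between consecutive
thresholds and summarized as mean similarity and fraction $\ge 0.7$).
Clusters are immediately reordered by **total fractional occupancy** — the
sum of member-state occupancies — so cluster 1 is the most expressed
pattern, not the one with most member states; ties break by member count,
then first appearance. Each cluster gets a consensus pattern (networks
active in at least 50% of members, boundary inclusive) and a provenance
label: context-general if members come from both context groups (or only
from the pooled combined/balanced models, which contain both contexts by
construction), context-specific otherwise. Two empty active sets get
distance 0 and a warning rather than 0/0.

## Linking annotations to dynamics: the MAP logistic mixed model

Per-TR binary story annotations (who is speaking, co-presence of Lee and
the girl, parts of speech, and the composites
`lee_girl_verb = lee_girl_together × verb` and
`arthur_adjective = arthur_speaking × adjective`) predict a binary per-TR
outcome — occupancy of a cluster's representative state, or a button
press — through

$$\mathrm{logit}\,P(y_{it}=1) = \beta_0 + \beta_g G_i + \sum_j \beta_j
f_{jt} + \sum_j \beta_{gj} G_i f_{jt} + \gamma_1 y_{i,t-1} + \gamma_2
y_{i,t-2} + u_i,$$

with deviation-coded group $G_i \in \{+1,-1\}$ (+1 affair), AR(2) outcome
lags padded with zeros before each subject's first TRs, and subject random
intercepts $u_i \sim \mathcal{N}(0, \sigma_u^2)$. The representative state
of a cluster is its first member in the combined-group models, scanning
ascending $K$ with states ordered by occupancy within a model.

Estimation is maximum a posteriori with $\mathcal{N}(0, 2.5^2)$ priors on
fixed effects and an Inverse-Gamma(2, 1) prior on $\sigma_u^2$ (the source
says only "default priors"; these are standard weakly-informative choices
and fully configurable). The optimizer alternates Newton steps on
$(\beta, u)$ at fixed $\sigma_u^2$ with the closed-form update
$\sigma_u^2 = (\sum_i u_i^2 + 2b_0)/(S + 2a_0 + 2)$, converging at a
max-abs parameter change of $10^{-6}$. Posterior uncertainty is the
Laplace approximation — the inverse curvature of the penalized objective
at the optimum — keeping the full fixed-effect covariance block so that
group-specific effects $\beta_j \pm \beta_{gj}$ get correct variances
(including the $2\,\mathrm{cov}$ term). With flat priors and no random
intercept the fit reproduces maximum-likelihood logistic regression to
$10^{-6}$, which the tests verify against `glm`.

Reported quantities: odds ratios $e^\beta$ with intervals
$e^{\beta \pm 1.96\,\mathrm{sd}}$, direction probabilities
$\Phi(\hat\beta/\hat{\mathrm{sd}})$, and group-specific decompositions
whose identities (main OR = geometric mean of group ORs; interaction OR =
exponential of half the log difference) hold to machine precision by
construction and are asserted in the tests.

## Bayesian FDR: what it does and does not control

Multiplicity is handled by the Bayesian false discovery rate on direction
probabilities: for each coefficient the posterior error of its dominant
direction is $e = 1 - \max(P(>0), 1-P(>0))$; errors are sorted ascending
and the largest prefix whose running mean stays at or below $\alpha=0.05$
is flagged credible (equivalently, FDR-adjusted posterior probability
above 0.95).

This procedure controls the *posterior-expected* proportion of
wrong-direction claims when the model and prior are adequate — a property
the test suite verifies by simulation with effects drawn from a prior. It
does **not** control the frequentist false-discovery proportion under a
degenerate all-null truth with informative data: there, posterior z-scores
are approximately standard normal, the rank-1 rule flags anything with
$|z| \gtrsim 1.6$, and with 50 null coefficients some flag appears in
almost every dataset. The corresponding all-null acceptance check is
therefore implemented faithfully and expected to fail; treating that
failure as a defect of the procedure rather than of the implementation is
deliberate and documented.

## Behavioral stream and permutation testing

Button presses recorded in seconds are aligned to the TR grid by
containing bin (`floor(t / TR)`, the reading implied by within-TR
deduplication; round-to-center is available), deduplicated within a TR,
and presses beyond the window are dropped with a logged count. Group
agreement is the per-TR proportion of subjects pressing.

Group differences in a representative state's occupancy time course are
tested against 10,000 random participant splits that preserve group sizes.
The statistic — unspecified in the source — defaults to the mean over TRs
of the absolute difference in group-mean occupancy (max-abs and
sum-of-squares variants are selectable and always reported with the
config), with the add-one correction $p = (1 + \#\{S_\text{null} \ge
S_\text{obs}\})/(1 + n_\text{perm})$ so $p$ is never exactly zero. Note
that the permutation space, not the implementation, bounds attainable
p-values: with 5 + 5 subjects there are only 252 distinct splits.

## The synthetic world

The generator emulates exactly the structure the analysis assumes, with
the study's stated dimensions as defaults: 2 groups × 19 subjects, 451
TRs at TR = 1.5 s, 17 network channels, per-subject z-scored signals,
first-order Markov state paths whose self-transition probability
$1 - 1/d$ encodes the expected dwell $d$ (geometric dwell times — mean and
variance are verified against the closed form), Gaussian emissions, bursty
binary annotation streams (two-state Markov chains parameterized by
stationary rate and mean run length; the source does not report these
marginals, so `default_feature_rates()` fixes field-plausible values:
character speech in multi-TR bursts at rates 0.08–0.30, parts of speech
frequent and short-lived), and logistic occupancy/press generation with
AR(2) lags and subject intercept heterogeneity.

What it deliberately does **not** emulate: hemodynamic convolution,
spatial structure below the network level, scanner drift or motion
artifacts (removed upstream in the real pipeline), semantic content of the
story, and any coupling between the *emission* process of the HMM world
and the annotation streams — brain-state/feature coupling enters only
through the logistic generator. A green recovery test therefore
establishes correctness of the estimators under the model's assumptions,
not robustness to their violation.

Default coupling values in `default_config()` (intercept −1.5, AR
coefficients 1.5 and 0.5, random-intercept SD 0.5, feature effects
0.3–0.4) were fixed once to give occupancy rates and temporal persistence
comparable to what decoded states exhibit, and are not revisited.

## Degenerate inputs and tie-breaks

Zero-variance network channels are an error naming the channel; states
with fewer than 10 assigned TRs automatically fail screening with a logged
reason; an empty consensus pattern is allowed with a warning; clusters
without a combined-group member raise an explicit error at
representative-selection time; constant outcomes are rejected by the GLMM;
coefficients beyond ±15 in flat-prior mode trigger a separation warning.
Event rasterization uses half-open bins $[b\cdot s, (b+1)s)$ with
zero-duration events landing in their containing bin.

## Known limitations

* The Laplace posterior is a curvature approximation at a point estimate;
  intervals can be optimistic for weakly identified coefficients.
* $\sigma_u^2$ is a penalized point update, not a marginal-likelihood
  estimate; with few subjects it is biased toward the prior mode.
* Geometric dwell times are an HMM assumption, not a finding;
  semi-Markov alternatives are out of scope.
* Cross-$K$ state identity is resolved only through clustering, never by
  direct matching of models with different $K$.
* At test scale, simulations are reduced (documented per test); the
  full-scale configuration is `default_config()` and runs in minutes, not
  seconds.
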