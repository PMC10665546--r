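---
title: "Multilevel hidden Markov models for weekly symptom panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel hidden Markov models for weekly symptom panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Depression symptoms fluctuate within a person. Given weekly ratings of ten
depressive symptoms on a 3-point severity scale (1 = absent, 2 = subclinical,
3 = clinical) over many weeks, we want to identify *intraindividual
phenotypes*: latent states, each defined by a profile of symptom-endorsement
probabilities, that a youth moves into and out of over time. Beyond the
states themselves, the scientific quantities of interest are dynamic: the
*inertia* of each state (the probability of staying put from one week to the
next), the expected number of weeks to first reach another state
(*mean first-passage time*), the expected number of weeks for a state to
recur (*mean recurrence time*), and how these person-specific dynamics
relate to demographics and comorbid psychopathology.

`panelhmm` implements this pipeline end to end: a synthetic cohort
generator, preprocessing rules for informant-combined interview panels,
exact single-subject HMM machinery, a Bayesian multilevel HMM sampler,
AIC-based selection of the number of states, Markov dynamics summaries, and
the post hoc association models.

# The model

## Observation layer

Subject $s$ is observed at weeks $t = 1, \dots, T_s$ (integer week indices;
gaps are allowed). At each observed week, $J = 10$ symptoms are rated in
$\{1, 2, 3\}$. Conditional on the latent state $z_{st} \in \{1,\dots,K\}$,
ratings are independent across symptoms (the standard HMM emission
assumption):

$$P(y_{stj} = c \mid z_{st} = k) = \theta^{(s)}_{kjc}.$$

A missing rating cell contributes a factor of 1 to the emission probability
(it is marginalised out). A fully missing or removed week leaves a gap in
the week index; the likelihood bridges a gap of $g$ skipped weeks with the
matrix power $\Gamma^{g+1}$, preserving the weekly time base rather than
pretending the neighbouring weeks are adjacent.

## Latent layer and multilevel structure

The state sequence is a first-order Markov chain with subject-specific
transition matrix $\Gamma^{(s)}$, initialised from its stationary
distribution (the study design gives no information about week 1 being
special). Subject-level parameters are tied together on the
multinomial-logit scale, with the first category of each probability row as
the baseline:

$$\log \frac{\Gamma^{(s)}_{ij}}{\Gamma^{(s)}_{i1}} = \mu^{\Gamma}_{ij} +
  u^{(s)}_{ij}, \qquad u^{(s)}_{ij} \sim N(0, \sigma^2_{\Gamma,i}),$$

and likewise for every emission logit with state-specific variances
$\sigma^2_{\theta,k}$ shared across symptoms and categories within a state.
Random effects are independent across logits; we do not model
cross-correlations among them (they would be weakly identified at the
design's size, roughly a hundred subjects and ninety weeks). Subjects are
exchangeable: demographic covariates do not enter the HMM itself but are
analysed post hoc against the fitted per-subject dynamics, mirroring the
two-stage practice this package is built around.

## Priors

All group-level logits get diffuse normal priors, $N(0, 5^2)$. The
random-effect variances get inverse-gamma priors with shape 2 and rate 0.5
(prior mean random-effect SD about 0.6, weakly informative at this scale).
We chose the inverse-gamma family deliberately: the variances then have
closed-form conditional posteriors, keeping the Gibbs layer of the sampler
exact. Both priors are configurable through `prior_spec()`.

## Sampler

`fit_mhmm()` alternates three blocks:

1. **Latent paths** — per subject, forward filtering backward sampling
   (FFBS) using the subject's current parameters. Gap weeks are first
   bridged with matrix powers during filtering, then filled in by
   conditional bridge sampling, so the augmented path is contiguous and
   one-step transition counts are exact sufficient statistics.
2. **Subject logits** — given the path counts, each transition row and each
   (state, symptom) emission row has a multinomial likelihood and a normal
   prior; a random-walk Metropolis step updates the row's logits. These
   updates are vectorised across subjects (one accept/reject decision per
   subject per block). Proposal scales adapt during burn-in toward a 23-44%
   acceptance band and are frozen afterwards to preserve detailed balance.
3. **Group level** — conjugate updates: normal for the group mean logits,
   inverse-gamma for the random-effect variances.

Chains are deterministic given the seed in `mcmc_config()`. Multiple chains
run sequentially (seeds `seed`, `seed + 1`, ...) and are pooled with the
chain index retained for split-chain scale-reduction diagnostics
(`convergence_diagnostics()`; thresholds are reported, never enforced).

Initial values come from a quantile split of mean weekly severity into $K$
ordered bins, with transition and emission counts from the binned
assignment. This starts the chain close to a severity-ordered labelling and
makes within-chain label switching rare; recorded draws are additionally
canonicalised (below).

## Label switching

Latent-state labels are only identified up to permutation. Every recorded
draw is relabelled by sorting states on the mean probability (over symptoms)
of an at-least-subclinical rating, $\tfrac1J \sum_j (1 -
\theta_{kj1})$, in ascending order; the permutation is applied consistently
to transition, emission, random-effect and subject-level draws. For the
default three-state design this canonical order is (low-depression,
cognitive-physical, elevated-depression). `relabel_states()` applies the
same rule post hoc and is idempotent.

## Model-order selection

`select_num_states()` fits each candidate $K$ and tabulates
$\mathrm{AIC} = -2\hat\ell + 2p$, where $\hat\ell$ is the marginal
(forward-algorithm) log-likelihood of all subjects evaluated at the
posterior-median group-level parameters (medians taken on the logit scale so
probability rows stay exactly stochastic), and $p = K(K-1) + KJ(C-1)$ counts
group-level logits only. Subject-level effects are deliberately not counted:
the criterion compares population-level model structures. Counting
conditional (subject-level) parameters would be an alternative; it is out of
scope here and would not change the package's interfaces.

# The synthetic cohort generator

No subject-level data from the motivating study design are available, so
the package ships a generator (`cohort_config()`, `simulate_cohort()`)
whose defaults mirror that design:

* 124 enrolled subjects, 90 weekly assessments, 10 symptoms on 3 levels;
  about 3% of subjects are given >80% fully missing weeks, so the exclusion
  rule leaves roughly 120 analysable subjects.
* Three states with self-transition probabilities 0.887 (low), 0.865
  (elevated) and 0.870 (cognitive-physical) — the published inertias — and
  the off-diagonal mass split equally within each row. The equal split is a
  declared convention: the corresponding off-diagonal values were published
  only graphically, and we do not claim to match them.
* Emission profiles are invented numbers reproducing the qualitative
  pattern of the three states: the low state endorses little (0.90 / 0.08 /
  0.02 per symptom), the elevated state endorses everything (0.25 / 0.45 /
  0.30), and the cognitive-physical state matches the elevated state on
  worthlessness/guilt, psychomotor, appetite/weight and sleep, matches the
  low state on irritable mood and fatigue, and is intermediate otherwise.
  These are configuration values, not ground truth about any real cohort.
* Normal random effects with SD 0.4 on transition logits and 0.3 on
  emission logits. 0.4 yields subject inertias spread roughly ±0.13 around
  the group value, a spread we consider realistic for person-specific
  symptom dynamics; 0.3 does the same for endorsement probabilities.
* A +0.4 female shift on the logits of the two transitions out of the low
  state. At the default inertia this moves each transition probability by
  about +0.02 for girls — the order of magnitude of the published
  unstandardized sex coefficients — and gives the power analyses a
  realistic signal.
* MCAR masking of individual rating cells at rate 0.004. Because one
  missing rating removes the whole subject-week downstream, this leaves
  about 4% of subject-weeks incomplete, matching the share of observations
  the exclusion rules remove in the emulated design; a naive 3% cell rate
  would remove a quarter of all weeks.
* Five weekly comorbidity series (ADHD, CD, ODD, GAD, SAD) on a 1-6
  severity code: latent severity = intercept + state contrasts + subject
  random intercept + AR(1) noise (`noise_sd` is the innovation SD; the
  first week draws from the stationary AR(1) law), rounded and clamped
  to 1..6.

Randomness is organised in fixed substreams (covariates, subject
parameters, paths, emissions, missingness, comorbidity) derived from one
seed, so adding or re-running a later stage never perturbs an earlier one,
and outputs are bit-identical given the seed.

**What the generator does not emulate:** informant disagreement processes
(panels are generated post-combination), non-MCAR missingness,
developmental drift in dynamics (transition probabilities are constant over
the 90 weeks), interview-interval boundary effects, and any correlation
among random effects. Tests passing on this generator therefore certify the
estimation machinery under the model's own assumptions — not robustness to
the many ways real interview data violate them.

# Estimands and a confound worth knowing about

The fitted model is exchangeable over subjects, so its group-level
transition matrix estimates the *population mean* of the subject logits.
If a covariate effect is active in the generator (the default female
shift), the population-mean low-state inertia sits below the configured
baseline diagonal by construction — about 0.023 at the defaults — and a
fit that correctly estimates the population mean will look "biased" against
the baseline. Parameter-recovery runs in the tests and the acceptance
script therefore zero the demographic shift so that the estimand coincides
with the configured matrix; the shift stays on wherever it is the point
(the association power analyses). With the shift zeroed, group inertia
recovery errors at 40 subjects x 90 weeks and 1,500 iterations are around
0.01 absolute across seeds, against a stated tolerance of 0.03.

# Numerical choices

* Forward recursions use scaled (normalised) forward variables with the
  per-week scaling factors accumulated into the log-likelihood — the
  textbook treatment, stable for long series — rather than log-space
  arithmetic.
* Viterbi ties are broken toward the lowest state index, deterministically.
* Degenerate multinomial-logit rows (a probability of exactly 0 or 1, as in
  absorbing test configurations) are handled explicitly when transforming
  between probabilities and logits.
* `stationary_distribution()` solves the balance equations by least
  squares and refuses reducible chains, naming the non-communicating
  states; per-subject dynamics with a reducible posterior-mean matrix are
  excluded from group passage/recurrence averages with a warning.
* Mean first-passage times solve the standard linear systems target by
  target; recurrence times use the ergodic identity $r_i = 1/\pi_i$. An
  empirical decoded-path alternative (`empirical_recurrence_time()`) is
  provided because the published description does not pin down which
  definition was used; $1/\pi$ is the default.
* Occupancy is defined as the Viterbi-decoded state proportion per subject
  and always sums to 1. (Published occupancy percentages for the emulated
  study sum to more than 100%, so their denominator must differ; we
  document the discrepancy rather than reconcile it.)
* Per-subject dynamics are computed from posterior-mean subject matrices
  and then averaged across subjects. The alternative — dynamics of the
  group-mean matrix — is systematically smaller for recurrence times by
  Jensen's inequality (1/pi is convex); the package reports the
  subject-averaged version and asserts the ordering in its tests.

# Association analyses

`regress_transitions()` fits one OLS regression per ordered transition
probability (9 outcomes for K = 3) on female, age and ethnoracial minority
status, on the raw probability scale (a logit option exists). It reports
unstandardized coefficients, 95% confidence intervals, t, p, and
standardized betas. Per-outcome OLS with a shared design matrix gives the
same coefficients as a seemingly-unrelated system, which is why the
"multivariate" regression is implemented this way.

`fit_comorbidity_model()` fits, per disorder, a linear mixed model by
maximum likelihood (via `nlme::lme`): severity on elevated- and
cognitive-physical-state indicators (low state as reference), female, age,
and all three state inertias, with a subject random intercept and AR(1)
within-subject residual correlation. Decoded states come from Viterbi at
posterior-mean subject parameters. Significance flags use the
Bonferroni-adjusted level `bonferroni_adjust(alpha, n_disorders)` — 0.01
for five disorders at alpha = 0.05. Weekly comorbidity series are assumed;
an interval-constant alternative can be emulated by duplicating interval
values across weeks before the call.

# Problem sizes used in the shipped checks

The package's own test suite and acceptance script run at reduced scale,
chosen as a deliberate trade-off between statistical resolution and
wall-clock time: parameter recovery at 40 subjects x 90 weeks with 1,500
MCMC iterations (500 burn-in); model-order selection over K in 2..5 at 20
subjects with 400 iterations; association calibration with 100 simulated
replicates of 120 subjects (using generator truth directly, since those
checks target the regression layer, not the HMM); oracle comparisons
(path enumeration, 100,000-replicate passage-time simulation) at the sizes
where exact enumeration is feasible. Larger runs — the full 124-subject
design with several thousand iterations — are a matter of patience, not
code changes.

# Known limitations

* The sampler is plain R; a fit at the full design size takes tens of
  minutes rather than seconds. The vectorised-across-subjects Metropolis
  blocks keep it workable.
* Forcing the random-effect variances to (near) zero through the prior is
  not a practical way to obtain a pooled fit: it couples the subject and
  group logits so tightly that the joint random walk effectively stops
  moving. The no-heterogeneity limit is instead verified by fitting
  homogeneous data under the default priors, where the group-level means
  agree with direct pooled maximum likelihood to well within 0.01 on
  well-identified instances. Relatedly, with very few weakly separating
  symptoms the pooled likelihood itself can be multimodal; that is a
  property of the model class, not of the sampler.
* AIC at posterior-median group parameters is one defensible reading of
  information-criterion selection for multilevel HMMs; conditional or
  marginal alternatives (integrating over subject effects) are not
  implemented.
* With heavily overlapping emission profiles or very short series, state
  recovery degrades gracefully (wider posteriors) but the canonical
  ordering may become unstable between draws; `convergence_diagnostics()`
  flags the symptoms (high scale reduction, low effective sample size).
* The ordinal comorbidity severities are modelled with a Gaussian mixed
  model, as in the emulated analysis; rounding and clamping to the 1..6
  scale mildly attenuate recovered link coefficients (visible in the
  package's own recovery tests), and an ordinal-response alternative is out
  of scope.
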