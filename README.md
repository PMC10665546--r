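# panelhmm

Multilevel Bayesian hidden Markov models for weekly ordinal symptom panels.

## What this is for

Clinical follow-up interviews can yield, for each subject, many consecutive
weekly ratings of depressive symptoms (for example ten DSM symptoms each
rated 1 = absent, 2 = subclinical, 3 = clinical). Rather than classifying
*people* into subtypes, `panelhmm` identifies *intraindividual phenotypes*:
latent states, each defined by a profile of symptom-endorsement
probabilities, that a person transitions into and out of over time. The
package is aimed at researchers in developmental psychopathology and
longitudinal psychiatry who want to:

* estimate the states and each subject's own transition dynamics,
* quantify state **inertia** (diag Γ), **mean first-passage times** and
  **mean recurrence times** in weeks,
* select the number of states by AIC,
* and relate the per-subject dynamics to demographics and comorbid symptom
  severity.

## The model

For subject *s*, week *t*, symptom *j* with rating levels *c* ∈ {1, 2, 3}:

* latent first-order Markov chain `z_st` with subject-specific K×K
  transition matrix Γ⁽ˢ⁾, initialised at its stationary distribution;
* conditionally independent categorical emissions
  `P(y_stj = c | z_st = k) = θ⁽ˢ⁾_kjc`;
* multilevel tying on the multinomial-logit scale (first category as
  baseline): every subject-level transition and emission logit is normal
  around a group-level mean, with state-specific random-effect variances;
* estimation by MCMC: forward-filtering backward-sampling for the latent
  paths, random-walk Metropolis for subject logits given path counts
  (vectorised across subjects), conjugate normal / inverse-gamma updates
  for group means and variances;
* label switching resolved by sorting states on mean symptom endorsement,
  so state 1 is always the least-endorsing ("low") and state K the
  most-endorsing ("elevated") state;
* AIC = −2·ℓ̂ + 2p with ℓ̂ the forward-algorithm likelihood at
  posterior-median group parameters and p = K(K−1) + K·J·(C−1).

Missing rating cells are marginalised; removed weeks leave gaps that the
likelihood bridges with matrix powers of Γ. Details, priors and design
decisions are in `vignettes/panelhmm-methods.Rmd`.

Because no subject-level data from the motivating study design are
distributable, the package ships a synthetic cohort generator
(`cohort_config()` / `simulate_cohort()`) that mirrors the design — 124
subjects, 90 weeks, 10 symptoms, three states with inertias 0.887 / 0.865 /
0.870, subject-level heterogeneity, a female effect on transitions out of
the low state, MCAR missingness, and five linked comorbidity series — with
full ground truth for recovery scoring.

## Worked example

```r
library(panelhmm)

# a small synthetic cohort: 20 subjects x 90 weeks, known ground truth
cfg <- cohort_config(n_subjects = 20, seed = 42)
cohort <- simulate_cohort(cfg)

# preprocessing: drop >80%-missing subjects, then incomplete weeks
kept <- apply_exclusions(cohort$panel)

# fit the three-state multilevel HMM
fit <- fit_mhmm(kept$panel, K = 3,
                mcmc = mcmc_config(n_iterations = 800, n_burnin = 300,
                                   seed = 1))
fit
dyn <- summarize_dynamics(fit)
dyn
```

```
Multilevel hidden Markov model fit
  states: 3  symptoms: 10  levels: 3 
  subjects: 19  draws: 500  chains: 1 
  AIC: 27689.13 
  group-level inertia: 0.857, 0.783, 0.873 
Markov dynamics for 19 subjects, 3 states
Group-average inertia:  0.842, 0.768, 0.863 
Group-average recurrence (weeks):  2.9, 4.6, 2.5
```

State 1 is the low state (least symptom endorsement), state 2 the
cognitive-physical state, state 3 the elevated state. The group-level
inertias say a subject in a given state this week stays in it next week
with probability ≈ 0.78-0.87; recurrence times say a vacated state is
revisited after ≈ 2.5-4.6 weeks on average. For this particular 20-subject
draw the realized cohort carries subject-average inertias 0.862 / 0.843 /
0.868 (the configured group values are 0.887 / 0.870 / 0.865, pulled down
here by the default female transition effect and by drawing only 20
subjects); the fit tracks the realized values, with the
cognitive-physical state estimated least precisely at this size. The
shipped checks quantify recovery at 40 subjects, where group inertias come
back within about 0.01. Continuing:

```r
# demographic correlates of the per-subject transition probabilities
regress_transitions(dyn, cohort$covariates)

# comorbidity mixed models (random intercept + AR(1) residuals),
# Bonferroni-adjusted across the five disorders
fit_comorbidity_model(cohort$comorbidity, dyn$paths, dyn,
                      cohort$covariates)

# figure-style summaries
plot_emission_profiles(fit)
plot_transition_matrix(fit)
```

`tidy(fit)` returns posterior summaries of every group-level transition and
emission probability; `glance(fit)` a one-row model summary;
`run_pipeline()` chains all stages and writes every table as CSV.

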