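# Multilevel HMM estimation: degenerate limits, parameter recovery at small
# scale, relabeling, AIC arithmetic, model-order selection machinery,
# reproducibility and diagnostics.

test_that("K = 1 single-subject posterior means recover category frequencies", {
  em <- array(0, c(1, 2, 3))
  em[1, 1, ] <- c(.6, .3, .1)
  em[1, 2, ] <- c(.2, .5, .3)
  cfg <- cohort_config(n_subjects = 2, n_weeks = 300, n_symptoms = 2,
                       n_states = 1, group_transition = matrix(1, 1, 1),
                       group_emission = em, re_sd_transition = 0,
                       re_sd_emission = 0,
                       female_transition_effects = data.frame(
                         from = integer(), to = integer(), shift = numeric()),
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 41)
  sim <- simulate_dataset(cfg)
  one <- sim$panel[sim$panel$subject_id == "S001", ]
  fit <- fit_mhmm(one, K = 1, mcmc = fast_mcmc(seed = 42))
  th <- group_emission_array(fit)
  freq1 <- tabulate(one$symptom_01, 3) / 300
  freq2 <- tabulate(one$symptom_02, 3) / 300
  expect_equal(as.vector(th[1, 1, ]), freq1, tolerance = 0.05)
  expect_equal(as.vector(th[1, 2, ]), freq2, tolerance = 0.05)
  # closed-form categorical AIC at the posterior-median parameters
  g <- glance(fit)
  expect_equal(g$AIC, -2 * g$logLik + 2 * g$n_parameters, tolerance = 1e-8)
  expect_equal(g$n_parameters, 1 * 2 * 2)
})

test_that("group-level parameters are recovered on a small default cohort", {
  # 15 subjects is deliberately small: recovery here is qualitative (the
  # tight +/-0.03 inertia guarantee is asserted at 40 subjects elsewhere)
  cfg <- small_config(n_subjects = 15, n_weeks = 90, seed = 43)
  coh <- simulate_cohort(cfg)
  fit <- fit_mhmm(coh$panel, K = 3, mcmc = fast_mcmc(600, 200, seed = 44))
  G <- group_transition_matrix(fit)
  expect_true(all(abs(diag(G) - canonical_true_inertia()) < 0.065))
  expect_true(all(diag(G) > 0.75))
  th <- group_emission_array(fit)
  # canonical order: low endorses least, elevated most
  keys <- apply(1 - th[, , 1], 1, mean)
  expect_true(all(diff(keys) > 0))
  # emission recovery for the extreme states
  expect_equal(th[1, 1, 1], 0.90, tolerance = 0.07)
  expect_equal(th[3, 1, 1], 0.25, tolerance = 0.10)
})

test_that("group inertia bias stays small and credible intervals cover truth", {
  biases <- c(); covered <- c()
  for (rep in 1:6) {
    cfg <- small_config(n_subjects = 24, n_weeks = 90, seed = 100 + rep)
    coh <- simulate_cohort(cfg)
    fit <- fit_mhmm(coh$panel, K = 3, mcmc = fast_mcmc(700, 250,
                                                       seed = 200 + rep))
    truth <- canonical_true_inertia()
    for (k in 1:3) {
      d <- fit$draws$transition[, k, k]
      biases <- c(biases, mean(d) - truth[k])
      q <- quantile(d, c(0.05, 0.95))
      covered <- c(covered, truth[k] >= q[1] && truth[k] <= q[2])
    }
  }
  expect_lt(mean(abs(biases)), 0.03)
  expect_gte(mean(covered), 0.8)
})

test_that("fits are bit-identical given the seed", {
  cfg <- small_config(n_subjects = 6, n_weeks = 40, seed = 45)
  coh <- simulate_cohort(cfg)
  f1 <- fit_mhmm(coh$panel, K = 2, mcmc = fast_mcmc(120, 40, seed = 46))
  f2 <- fit_mhmm(coh$panel, K = 2, mcmc = fast_mcmc(120, 40, seed = 46))
  expect_identical(f1$draws$transition, f2$draws$transition)
  expect_identical(f1$draws$emission, f2$draws$emission)
})

test_that("independent chains agree on the group-level inertias", {
  cfg <- small_config(n_subjects = 12, n_weeks = 90, seed = 47)
  coh <- simulate_cohort(cfg)
  fit <- fit_mhmm(coh$panel, K = 3,
                  mcmc = fast_mcmc(500, 200, seed = 48, n_chains = 2L))
  ch <- fit$draws$chain
  for (k in 1:3) {
    d1 <- fit$draws$transition[ch == 1, k, k]
    d2 <- fit$draws$transition[ch == 2, k, k]
    se <- sqrt(var(d1) / max(effective_n(d1), 2) +
                 var(d2) / max(effective_n(d2), 2))
    expect_lt(abs(mean(d1) - mean(d2)), 2 * se + 0.01)
  }
})

test_that("homogeneous cohorts reproduce a pooled maximum-likelihood fit", {
  # data generated without heterogeneity: the multilevel group-level means
  # should agree with direct maximisation of the pooled forward likelihood.
  # (Literally pinning the random-effect variance at ~0 is not a usable test
  # vehicle: it freezes the coupled subject/group random walk; see the
  # methods vignette.)
  em <- array(0, c(2, 3, 3))
  for (j in 1:3) { em[1, j, ] <- c(.8, .15, .05); em[2, j, ] <- c(.15, .3, .55) }
  G0 <- matrix(c(.85, .15, .25, .75), 2, byrow = TRUE)
  cfg <- cohort_config(n_subjects = 8, n_weeks = 80, n_symptoms = 3,
                       n_states = 2, group_transition = G0,
                       group_emission = em, re_sd_transition = 0,
                       re_sd_emission = 0,
                       female_transition_effects = data.frame(
                         from = integer(), to = integer(), shift = numeric()),
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 49)
  sim <- simulate_dataset(cfg)
  fit <- fit_mhmm(sim$panel, K = 2, mcmc = fast_mcmc(900, 300, seed = 50))

  subj <- split(sim$panel, sim$panel$subject_id)
  obs_list <- lapply(subj, function(d)
    as.matrix(d[, paste0("symptom_0", 1:3)]))
  nll <- function(par) {
    G <- rbind(c(1, exp(par[1])), c(exp(par[2]), 1))
    G <- G / rowSums(G)
    th <- array(0, c(2, 3, 3))
    idx <- 3
    for (k in 1:2) for (j in 1:3) {
      z <- c(0, par[idx], par[idx + 1]); idx <- idx + 2
      th[k, j, ] <- exp(z - max(z)) / sum(exp(z - max(z)))
    }
    init <- stationary_distribution(G)
    -sum(vapply(obs_list, function(o)
      forward_loglik(o, G, th, init = init), numeric(1)))
  }
  start <- c(log(G0[1, 2] / G0[1, 1]), log(G0[2, 1] / G0[2, 2]),
             unlist(lapply(1:2, function(k) lapply(1:3, function(j)
               log(em[k, j, -1] / em[k, j, 1])))))
  ml <- optim(start, nll, method = "BFGS", control = list(maxit = 600))
  G_ml <- rbind(c(1, exp(ml$par[1])), c(exp(ml$par[2]), 1))
  G_ml <- G_ml / rowSums(G_ml)
  # both are canonically ordered here (state 1 = low endorsement)
  expect_equal(unname(diag(group_transition_matrix(fit))),
               unname(diag(G_ml)), tolerance = 0.03)
})

test_that("relabeling canonicalises permuted draws and is idempotent", {
  # build a small synthetic fit object directly
  K <- 3; J <- 10; C <- 3
  th <- default_group_emission()
  G <- default_group_transition()
  nd <- 4
  dr_em <- array(0, c(nd, K, J, C))
  dr_tr <- array(0, c(nd, K, K))
  perms <- list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  for (d in seq_len(nd)) {
    p <- perms[[d]]
    dr_em[d, , , ] <- th[p, , ]
    dr_tr[d, , ] <- G[p, p]
  }
  fake <- structure(list(K = K, J = J, C = C,
                         draws = list(transition = dr_tr, emission = dr_em,
                                      re_sd_transition = matrix(.4, nd, K),
                                      re_sd_emission = matrix(.3, nd, K),
                                      chain = rep(1L, nd))),
                    class = "mhmm_fit")
  rel <- relabel_states(fake)
  # every draw now equals the canonical form: generator order (low,
  # elevated, cog-phys) maps to canonical (low, cog-phys, elevated)
  can <- c(1, 3, 2)
  for (d in seq_len(nd)) {
    expect_equal(rel$draws$emission[d, , , ], unname(th[can, , ]),
                 tolerance = 1e-12)
    expect_equal(rel$draws$transition[d, , ], unname(G[can, can]),
                 tolerance = 1e-12)
  }
  again <- relabel_states(rel)
  expect_identical(again$draws$transition, rel$draws$transition)
})

test_that("AIC penalises extra states and uses the group-level count", {
  cfg <- small_config(n_subjects = 10, n_weeks = 60, seed = 51)
  coh <- simulate_cohort(cfg)
  sel <- select_num_states(coh$panel, K_range = 2:3,
                           mcmc = fast_mcmc(250, 100, seed = 52))
  expect_equal(nrow(sel), 2)
  expect_equal(sel$n_parameters, c(2 * 1 + 2 * 10 * 2, 3 * 2 + 3 * 10 * 2))
  expect_equal(sel$AIC, -2 * sel$loglik + 2 * sel$n_parameters)
  expect_equal(sum(sel$selected), 1L)
})

test_that("a one-state cohort is preferred over a two-state fit by AIC", {
  em <- array(0, c(1, 3, 3))
  for (j in 1:3) em[1, j, ] <- c(.6, .3, .1)
  cfg <- cohort_config(n_subjects = 10, n_weeks = 60, n_symptoms = 3,
                       n_states = 1, group_transition = matrix(1, 1, 1),
                       group_emission = em, re_sd_transition = 0,
                       re_sd_emission = 0,
                       female_transition_effects = data.frame(
                         from = integer(), to = integer(), shift = numeric()),
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 53)
  sim <- simulate_dataset(cfg)
  sel <- select_num_states(sim$panel, K_range = 1:2,
                           mcmc = fast_mcmc(250, 100, seed = 54))
  expect_equal(sel$K[sel$selected], 1L)
})

test_that("diagnostics report scale reduction near 1 for well-mixed draws and flag stuck chains", {
  cfg <- small_config(n_subjects = 8, n_weeks = 50, seed = 55)
  coh <- simulate_cohort(cfg)
  fit <- fit_mhmm(coh$panel, K = 2, mcmc = fast_mcmc(400, 150, seed = 56))
  dg <- convergence_diagnostics(fit)
  expect_true(all(is.finite(dg$parameters$rhat)))
  expect_lt(stats::median(dg$parameters$rhat), 1.2)
  # adapted acceptance rates end near the 23-44% target band
  expect_true(all(dg$acceptance$mean_acceptance > 0.1 &
                    dg$acceptance$mean_acceptance < 0.6))
  # a zero proposal scale cannot move: flagged as stuck
  stuck <- fit_mhmm(coh$panel, K = 2,
                    mcmc = mcmc_config(120, 40, proposal_sd = 0,
                                       adapt = FALSE, seed = 57))
  dg2 <- convergence_diagnostics(stuck)
  expect_true(any(grepl("stuck", dg2$flags)))
})

test_that("decoded occupancy and dynamics summaries are internally consistent", {
  cfg <- small_config(n_subjects = 10, n_weeks = 80, seed = 58)
  coh <- simulate_cohort(cfg)
  fit <- fit_mhmm(coh$panel, K = 3, mcmc = fast_mcmc(400, 150, seed = 59))
  dyn <- summarize_dynamics(fit)
  occ <- tapply(dyn$subjects$occupancy, dyn$subjects$subject_id, sum)
  expect_equal(as.numeric(occ), rep(1, length(occ)), tolerance = 1e-9)
  # group-average transition matrix rows sum to one
  expect_equal(unname(rowSums(dyn$group$transition)), rep(1, 3),
               tolerance = 1e-9)
  # inertia column is the diagonal of each subject matrix
  sub1 <- dyn$subjects[dyn$subjects$subject_id ==
                         dyn$subjects$subject_id[1], ]
  G1 <- dyn$transitions[dyn$transitions$subject_id == sub1$subject_id[1], ]
  expect_equal(sub1$inertia,
               G1$prob[G1$from == G1$to][order(G1$from[G1$from == G1$to])])
  # mean subject recurrence dominates recurrence of the mean matrix
  grp_rec <- recurrence_time(dyn$group$transition)
  expect_true(all(dyn$group$recurrence >= grp_rec - 1e-8))
})
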