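# Synthetic cohort generator: degenerate configurations, Monte-Carlo
# frequency oracles, missingness mechanics, reproducibility.

test_that("a one-state configuration yields constant paths and matching frequencies", {
  em <- array(0, c(1, 2, 3))
  em[1, 1, ] <- c(.6, .3, .1)
  em[1, 2, ] <- c(.2, .5, .3)
  cfg <- cohort_config(n_subjects = 5, n_weeks = 400, n_symptoms = 2,
                       n_states = 1, group_transition = matrix(1, 1, 1),
                       group_emission = em, re_sd_transition = 0,
                       re_sd_emission = 0,
                       female_transition_effects = data.frame(
                         from = integer(), to = integer(), shift = numeric()),
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 5)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$states$state == 1L))
  freq <- tabulate(sim$panel$symptom_01, 3) / nrow(sim$panel)
  expect_equal(freq, c(.6, .3, .1), tolerance = 0.03)
})

test_that("an identity transition matrix freezes every subject in its initial state", {
  cfg <- cohort_config(n_subjects = 8, n_weeks = 90, n_states = 2,
                       group_transition = diag(2),
                       group_emission = default_group_emission()[1:2, , ],
                       re_sd_transition = 0, re_sd_emission = 0,
                       female_transition_effects = data.frame(
                         from = integer(), to = integer(), shift = numeric()),
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 6)
  sim <- simulate_dataset(cfg)
  per_subj <- tapply(sim$truth$states$state, sim$truth$states$subject_id,
                     function(s) length(unique(s)))
  expect_true(all(per_subj == 1L))
})

test_that("pooled transition frequencies converge to the group matrix without random effects", {
  em <- default_group_emission()[, 1, , drop = FALSE]
  cfg <- cohort_config(n_subjects = 280, n_weeks = 360, n_symptoms = 1,
                       group_emission = em,
                       re_sd_transition = 0, re_sd_emission = 0,
                       female_transition_effects = data.frame(
                         from = integer(), to = integer(), shift = numeric()),
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 7)
  sim <- simulate_dataset(cfg)
  st <- sim$truth$states
  from <- unlist(tapply(st$state, st$subject_id, function(s) s[-length(s)]))
  to <- unlist(tapply(st$state, st$subject_id, function(s) s[-1]))
  G <- cfg$group_transition
  for (i in 1:3) {
    n_i <- sum(from == i)
    for (j in 1:3) {
      p_hat <- sum(from == i & to == j) / n_i
      se <- sqrt(G[i, j] * (1 - G[i, j]) / n_i)
      expect_lt(abs(p_hat - G[i, j]), 3 * se + 1e-9)
    }
  }
})

test_that("zero random-effect SDs reproduce the group parameters exactly", {
  cfg <- cohort_config(n_subjects = 4, n_weeks = 10,
                       re_sd_transition = 0, re_sd_emission = 0,
                       female_transition_effects = data.frame(
                         from = integer(), to = integer(), shift = numeric()),
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 8)
  sim <- simulate_dataset(cfg)
  for (sid in names(sim$truth$transition)) {
    expect_equal(unname(sim$truth$transition[[sid]]),
                 unname(cfg$group_transition), tolerance = 1e-12)
    expect_equal(sim$truth$emission[[sid]], unname(cfg$group_emission),
                 tolerance = 1e-12)
  }
})

test_that("the female logit shift raises the targeted transition probabilities", {
  cfg <- cohort_config(n_subjects = 400, n_weeks = 2,
                       re_sd_transition = 0, re_sd_emission = 0,
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 9)
  sim <- simulate_dataset(cfg)
  female <- sim$covariates$female == 1
  p12 <- vapply(sim$truth$transition, function(G) G[1, 2], numeric(1))
  expect_gt(mean(p12[female]), mean(p12[!female]))
  # size of the shift: logit +0.4 at the default low-state row
  base <- cfg$group_transition[1, ]
  shifted <- base * exp(c(0, 0.4, 0.4))
  shifted <- shifted / sum(shifted)
  expect_equal(unique(round(p12[female], 10)), unname(round(shifted[2], 10)))
  expect_equal(unique(round(p12[!female], 10)), unname(round(base[2], 10)))
})

test_that("long-run occupancy matches the subject stationary distribution", {
  em <- array(0, c(3, 1, 3))
  for (k in 1:3) em[k, 1, ] <- default_group_emission()[k, 1, ]
  cfg <- cohort_config(n_subjects = 1, n_weeks = 1e5, n_symptoms = 1,
                       group_emission = em,
                       re_sd_transition = 0.4, re_sd_emission = 0,
                       missing_rate = 0, heavy_missing_subject_fraction = 0,
                       seed = 10)
  sim <- simulate_dataset(cfg)
  G <- sim$truth$transition[[1]]
  pi <- stationary_distribution(G)
  occ <- tabulate(sim$truth$states$state, 3) / 1e5
  for (k in 1:3) {
    se <- sqrt(pi[k] * (1 - pi[k]) / 1e5)
    # occupancy counts are autocorrelated; inflate the binomial SE by the
    # integrated autocorrelation time of a sticky chain (~1/(1-inertia))
    expect_lt(abs(occ[k] - pi[k]), 3 * se * sqrt(2 / (1 - G[k, k])))
  }
})

test_that("simulation is bit-identical given the seed and stages use fixed substreams", {
  cfg <- cohort_config(n_subjects = 6, n_weeks = 20, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$comorbidity, b$comorbidity)
  expect_identical(a$truth$states, b$truth$states)
})

test_that("MCAR masking hits the configured cell fraction", {
  cfg <- cohort_config(n_subjects = 100, n_weeks = 10, missing_rate = 0.03,
                       heavy_missing_subject_fraction = 0, seed = 12)
  sim <- simulate_dataset(cfg)
  masked <- inject_missingness(sim$panel, cfg)
  sym <- setdiff(names(masked), c("subject_id", "week"))
  n_na <- sum(is.na(masked[sym]))
  n_cells <- 100 * 10 * 10
  se <- sqrt(n_cells * 0.03 * 0.97)
  expect_lt(abs(n_na - n_cells * 0.03), 3 * se)
  # rate 0 and no heavy subjects: identity
  cfg0 <- cohort_config(n_subjects = 10, n_weeks = 10, missing_rate = 0,
                        heavy_missing_subject_fraction = 0, seed = 13)
  sim0 <- simulate_dataset(cfg0)
  m0 <- inject_missingness(sim0$panel, cfg0)
  attr(m0, "heavy_missing_subjects") <- NULL
  expect_identical(as.data.frame(m0), as.data.frame(sim0$panel))
})

test_that("heavy-missing subjects exceed the 80% missing-week threshold", {
  cfg <- cohort_config(n_subjects = 20, n_weeks = 90, missing_rate = 0,
                       heavy_missing_subject_fraction = 0.2, seed = 14)
  sim <- simulate_dataset(cfg)
  masked <- inject_missingness(sim$panel, cfg)
  heavy <- attr(masked, "heavy_missing_subjects")
  expect_length(heavy, 4L)
  sym <- setdiff(names(masked), c("subject_id", "week"))
  for (sid in heavy) {
    rows <- masked[masked$subject_id == sid, sym]
    frac <- mean(rowSums(is.na(rows)) > 0)
    expect_gt(frac, 0.8)
  }
})

test_that("comorbidity severities track the latent state with AR(1) noise", {
  # all coefficients and noise zero: constant severity round(intercept)
  link0 <- default_comorbidity_link()
  for (d in names(link0)) {
    link0[[d]]$coef_elevated <- 0; link0[[d]]$coef_cogphys <- 0
    link0[[d]]$subject_intercept_sd <- 0; link0[[d]]$noise_sd <- 1e-12
    link0[[d]]$intercept <- 2.4
  }
  cfg <- cohort_config(n_subjects = 3, n_weeks = 10,
                       comorbidity_link = link0, seed = 15)
  sim <- simulate_dataset(cfg)
  com <- simulate_comorbidity(sim$truth, cfg)
  expect_true(all(com$comorbidity$severity == 2L))

  # lag-1 autocorrelation of the latent noise
  link_ar <- default_comorbidity_link()["ADHD"]
  link_ar$ADHD$ar1_rho <- 0.9
  link_ar$ADHD$coef_elevated <- 0; link_ar$ADHD$coef_cogphys <- 0
  link_ar$ADHD$subject_intercept_sd <- 0; link_ar$ADHD$intercept <- 0
  cfg2 <- cohort_config(n_subjects = 2, n_weeks = 5000,
                        comorbidity_link = link_ar, seed = 16)
  sim2 <- simulate_dataset(cfg2)
  com2 <- simulate_comorbidity(sim2$truth, cfg2)
  one <- com2$latent[com2$latent$subject_id == "S001", ]
  r1 <- stats::acf(one$latent, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1 - 0.9), 3 * sqrt((1 - 0.81) / 5000) + 0.01)

  # the elevated-state contrast on the latent scale
  link_e <- default_comorbidity_link()["ADHD"]
  link_e$ADHD$coef_elevated <- 1.5; link_e$ADHD$coef_cogphys <- 0
  link_e$ADHD$subject_intercept_sd <- 0
  cfg3 <- cohort_config(n_subjects = 40, n_weeks = 90,
                        comorbidity_link = link_e, seed = 17)
  sim3 <- simulate_dataset(cfg3)
  com3 <- simulate_comorbidity(sim3$truth, cfg3)
  lat <- dplyr::inner_join(com3$latent, sim3$truth$states,
                           by = c("subject_id", "week"))
  contrast <- mean(lat$latent[lat$state == 2]) - mean(lat$latent[lat$state == 1])
  expect_equal(contrast, 1.5, tolerance = 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(group_transition = matrix(0.6, 3, 3)), "sum to 1")
  expect_error(cohort_config(group_transition = matrix(1, 2, 2)), "3x3")
  expect_error(cohort_config(n_states = 0), "n_states")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  bad_link <- default_comorbidity_link()
  bad_link$ADHD$ar1_rho <- 1
  expect_error(cohort_config(comorbidity_link = bad_link), "ar1_rho")
  bad_link2 <- default_comorbidity_link()
  bad_link2$ADHD$intercept <- NULL
  expect_error(cohort_config(comorbidity_link = bad_link2), "missing fields")
})
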