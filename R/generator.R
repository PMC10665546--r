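## Synthetic weekly-symptom cohort generator.
##
## Emulates an intensive longitudinal design: subjects assessed weekly on 10
## depressive symptoms rated 1 (absent) / 2 (subclinical) / 3 (clinical),
## latent 3-state dynamics with subject-level heterogeneity in transition and
## emission probabilities, demographic effects on transitions, MCAR
## missingness, and weekly comorbidity severities (5 disorders, coded 1..6)
## linked to the latent state with subject random intercepts and AR(1) noise.

DEPRESSION_SYMPTOMS <- c(
  "anhedonia", "depressed_mood", "irritable_mood", "sleep", "fatigue",
  "appetite_weight", "concentration", "psychomotor", "worthlessness_guilt",
  "death_thoughts")

COMORBID_DISORDERS <- c("ADHD", "CD", "ODD", "GAD", "SAD")

#' Default group-level parameters of the synthetic cohort
#'
#' `default_group_transition()` is the 3-state transition matrix with
#' self-transition probabilities 0.887 (low), 0.865 (elevated) and 0.870
#' (cognitive-physical) and the off-diagonal mass split equally within each
#' row. `default_group_emission()` gives the per-state, per-symptom rating
#' probabilities reproducing the qualitative endorsement pattern of the three
#' states. `default_comorbidity_link()` gives the state-to-severity link
#' settings for the five comorbid disorders.
#'
#' @return A matrix, a 3 x 10 x 3 array, or a named list, respectively.
#' @export
default_group_transition <- function() {
  # diagonal inertias 0.887 (low), 0.865 (elevated), 0.870 (cognitive-physical);
  # off-diagonal mass split equally within each row
  G <- matrix(0, 3, 3)
  diag(G) <- c(0.887, 0.865, 0.870)
  for (i in 1:3) G[i, -i] <- (1 - G[i, i]) / 2
  dimnames(G) <- list(c("low", "elevated", "cognitive_physical"),
                      c("low", "elevated", "cognitive_physical"))
  G
}

#' @rdname default_group_transition
#' @export
default_group_emission <- function() {
  # rows of P(absent, subclinical, clinical) per symptom and state; profiles
  # reproduce the qualitative pattern: low endorses little, elevated endorses
  # everything, cognitive-physical matches elevated on worthlessness/guilt,
  # psychomotor, appetite/weight and sleep, matches low on irritable mood and
  # fatigue, and is intermediate otherwise
  J <- length(DEPRESSION_SYMPTOMS)
  th <- array(0, c(3, J, 3),
              dimnames = list(c("low", "elevated", "cognitive_physical"),
                              DEPRESSION_SYMPTOMS, NULL))
  for (j in seq_len(J)) th[1, j, ] <- c(0.90, 0.08, 0.02)
  for (j in seq_len(J)) th[2, j, ] <- c(0.25, 0.45, 0.30)
  cog_high <- c("worthlessness_guilt", "psychomotor", "appetite_weight", "sleep")
  cog_low  <- c("irritable_mood", "fatigue")
  for (j in seq_len(J)) {
    s <- DEPRESSION_SYMPTOMS[j]
    th[3, j, ] <- if (s %in% cog_high) c(0.30, 0.45, 0.25)
                  else if (s %in% cog_low) c(0.85, 0.12, 0.03)
                  else c(0.60, 0.30, 0.10)
  }
  th
}

#' @rdname default_group_transition
#' @export
default_comorbidity_link <- function() {
  purrr::map(stats::setNames(COMORBID_DISORDERS, COMORBID_DISORDERS),
             function(d) list(intercept = 2.0, coef_elevated = 1.0,
                              coef_cogphys = 0.5, subject_intercept_sd = 0.5,
                              ar1_rho = 0.3, noise_sd = 0.7))
}

#' Configuration of the synthetic cohort generator
#'
#' The defaults mirror the target study design: 124 enrolled subjects (a
#' fraction with substantial missingness, leaving ~120 analysable), 90 weekly
#' assessments of 10 symptoms on a 3-point scale, three latent states with
#' self-transition probabilities 0.887 / 0.865 / 0.870, normal random effects
#' of SD 0.4 (transition) and 0.3 (emission) on the multinomial logits, a +0.4
#' logit female effect on the two transitions out of the low state, MCAR
#' cell missingness at a rate leaving about 4% of subject-weeks incomplete
#' (mirroring the share of observations the exclusion rules remove), and
#' five comorbidity series coded 1..6.
#'
#' @param n_subjects,n_weeks,n_symptoms,n_levels,n_states Design dimensions.
#' @param group_transition K x K row-stochastic group-level transition matrix.
#' @param group_emission K x J x C array of group-level emission probabilities.
#' @param re_sd_transition,re_sd_emission SD of the normal subject-level
#'   deviations on the multinomial logits.
#' @param female_transition_effects data frame with columns `from`, `to`,
#'   `shift`: additive logit shifts applied to female subjects' transitions.
#' @param missing_rate MCAR probability that an individual rating cell is
#'   masked, in \[0, 1).
#' @param heavy_missing_subject_fraction fraction of subjects given >80%
#'   fully missing weeks (emulating participants later excluded).
#' @param comorbidity_link named list (one element per disorder) of lists with
#'   `intercept`, `coef_elevated`, `coef_cogphys`, `subject_intercept_sd`,
#'   `ar1_rho` (strictly inside (-1, 1)), `noise_sd` (AR(1) innovation SD).
#' @param seed Integer seed; all stages draw from substreams derived from it
#'   in a fixed order (covariates, subject parameters/paths, emissions,
#'   missingness, comorbidity), so later stages never perturb earlier ones.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 124, n_weeks = 90,
                          n_symptoms = length(DEPRESSION_SYMPTOMS),
                          n_levels = 3, n_states = 3,
                          group_transition = default_group_transition(),
                          group_emission = default_group_emission(),
                          re_sd_transition = 0.4, re_sd_emission = 0.3,
                          female_transition_effects = data.frame(
                            from = c(1L, 1L), to = c(2L, 3L),
                            shift = c(0.4, 0.4)),
                          missing_rate = 0.004,
                          heavy_missing_subject_fraction = 4 / 124,
                          comorbidity_link = default_comorbidity_link(),
                          seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_weeks = n_weeks,
              n_symptoms = n_symptoms, n_levels = n_levels,
              n_states = n_states,
              group_transition = as.matrix(group_transition),
              group_emission = group_emission,
              re_sd_transition = re_sd_transition,
              re_sd_emission = re_sd_emission,
              female_transition_effects = female_transition_effects,
              missing_rate = missing_rate,
              heavy_missing_subject_fraction = heavy_missing_subject_fraction,
              comorbidity_link = comorbidity_link,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  K <- cfg$n_states
  if (K < 1) stop("n_states must be >= 1", call. = FALSE)
  if (cfg$n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  G <- cfg$group_transition
  if (nrow(G) != K || ncol(G) != K)
    stop("group_transition must be ", K, "x", K, call. = FALSE)
  if (max(abs(rowSums(G) - 1)) > 1e-12)
    stop("group_transition rows must sum to 1", call. = FALSE)
  th <- cfg$group_emission
  if (!all(dim(th) == c(K, cfg$n_symptoms, cfg$n_levels)))
    stop("group_emission must be K x n_symptoms x n_levels", call. = FALSE)
  sums <- apply(th, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-12)
    stop("group_emission probability vectors must sum to 1", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  for (d in names(cfg$comorbidity_link)) {
    lk <- cfg$comorbidity_link[[d]]
    need <- c("intercept", "coef_elevated", "coef_cogphys",
              "subject_intercept_sd", "ar1_rho", "noise_sd")
    if (!all(need %in% names(lk)))
      stop("comorbidity link for ", d, " is missing fields", call. = FALSE)
    if (abs(lk$ar1_rho) >= 1)
      stop("ar1_rho must be strictly inside (-1, 1)", call. = FALSE)
  }
  eff <- cfg$female_transition_effects
  if (nrow(eff) && any(eff$from > K | eff$to > K | eff$from < 1 | eff$to < 1))
    stop("female transition effects reference states outside 1..", K,
         call. = FALSE)
  if (nrow(eff) && any(eff$to == 1L))
    stop("female transition effects target the baseline destination state; ",
         "use a non-baseline 'to' state", call. = FALSE)
  invisible(cfg)
}

# fixed substream order: adding a stage appends a new substream and never
# perturbs earlier ones
stage_seeds <- function(seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 8L),
                  c("covariates", "parameters", "paths", "emissions",
                    "missingness", "comorbidity", "spare1", "spare2"))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# multinomial-logit helpers; baseline = first category of each row
probs_to_logits <- function(p) log(p[-1] / p[1])
logits_to_probs <- function(eta) {
  z <- c(0, eta)
  inf <- is.infinite(z) & z > 0
  if (any(inf)) return(as.numeric(inf) / sum(inf))   # degenerate rows
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Simulate a synthetic symptom panel with known ground truth
#'
#' Draws per-subject transition and emission parameters as normal deviations
#' (on the multinomial-logit scale, baseline first category) around the
#' group-level values, applies the configured female logit shifts, simulates
#' each subject's first-order Markov state path (initialised from the
#' subject's stationary distribution) and emits symptom ratings conditionally
#' independently given the state.
#'
#' @param config A [cohort_config()].
#' @return list with
#'   \describe{
#'     \item{panel}{tibble, one row per subject-week, columns `subject_id`,
#'       `week` and one ordinal rating column per symptom.}
#'     \item{covariates}{tibble: `subject_id`, `female`, `age`,
#'       `ethnoracial_minority`.}
#'     \item{truth}{list with per-subject transition matrices and emission
#'       arrays, the latent state paths, and the config.}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ss <- stage_seeds(config$seed)
  K <- config$n_states; J <- config$n_symptoms; C <- config$n_levels
  N <- config$n_subjects; Tn <- config$n_weeks
  ids <- sprintf("S%03d", seq_len(N))

  set.seed(ss[["covariates"]])
  covariates <- tibble::tibble(
    subject_id = ids,
    female = stats::rbinom(N, 1, 0.533),
    age = sample(7:17, N, replace = TRUE),
    ethnoracial_minority = stats::rbinom(N, 1, 0.317))

  set.seed(ss[["parameters"]])
  group_tr_logits <- matrix(0, K, max(K - 1L, 0L))
  if (K > 1L) for (i in seq_len(K))
    group_tr_logits[i, ] <- probs_to_logits(config$group_transition[i, ])
  subj_transition <- vector("list", N)
  subj_emission <- vector("list", N)
  eff <- config$female_transition_effects
  for (s in seq_len(N)) {
    G <- matrix(0, K, K)
    for (i in seq_len(K)) {
      eta <- group_tr_logits[i, ] +
        stats::rnorm(max(K - 1, 0), 0, config$re_sd_transition)
      if (covariates$female[s] == 1 && nrow(eff)) {
        hit <- eff$from == i
        if (any(hit)) eta[eff$to[hit] - 1L] <- eta[eff$to[hit] - 1L] +
            eff$shift[hit]
      }
      G[i, ] <- logits_to_probs(eta)
    }
    th <- array(0, c(K, J, C))
    for (k in seq_len(K)) for (j in seq_len(J)) {
      eta <- probs_to_logits(config$group_emission[k, j, ]) +
        stats::rnorm(C - 1, 0, config$re_sd_emission)
      th[k, j, ] <- logits_to_probs(eta)
    }
    subj_transition[[s]] <- G
    subj_emission[[s]] <- th
  }

  set.seed(ss[["paths"]])
  states <- matrix(0L, N, Tn)
  for (s in seq_len(N)) {
    G <- subj_transition[[s]]
    # reducible matrices (e.g. identity) have no unique stationary law;
    # fall back to uniform over states
    pi0 <- if (K == 1L) 1 else
      tryCatch(stationary_distribution(G), error = function(e) rep(1 / K, K))
    states[s, 1L] <- sample.int(K, 1L, prob = pi0)
    for (t in seq_len(Tn - 1L))
      states[s, t + 1L] <- sample.int(K, 1L, prob = G[states[s, t], ])
  }

  set.seed(ss[["emissions"]])
  ratings <- array(0L, c(N, Tn, J))
  for (s in seq_len(N)) {
    th <- subj_emission[[s]]
    for (t in seq_len(Tn)) {
      k <- states[s, t]
      for (j in seq_len(J))
        ratings[s, t, j] <- sample.int(C, 1L, prob = th[k, j, ])
    }
  }

  symptom_names <- if (J == length(DEPRESSION_SYMPTOMS))
    DEPRESSION_SYMPTOMS else sprintf("symptom_%02d", seq_len(J))
  panel <- tibble::tibble(
    subject_id = rep(ids, each = Tn),
    week = rep(seq_len(Tn), N))
  for (j in seq_len(J))
    panel[[symptom_names[j]]] <- as.integer(t(ratings[, , j]))

  truth <- list(
    transition = stats::setNames(subj_transition, ids),
    emission = stats::setNames(subj_emission, ids),
    states = tibble::tibble(subject_id = rep(ids, each = Tn),
                            week = rep(seq_len(Tn), N),
                            state = as.integer(t(states))),
    covariates = covariates,
    config = config)
  list(panel = panel, covariates = covariates, truth = truth)
}

#' Mask ratings completely at random, plus heavy-missingness subjects
#'
#' Applies MCAR masking to individual rating cells at `missing_rate`, then
#' marks a configured fraction of subjects as heavy-missing by blanking whole
#' weeks until strictly more than 80% of their weeks are fully missing
#' (emulating participants that the exclusion rule removes).
#'
#' @param panel A panel tibble from [simulate_dataset()].
#' @param config The same [cohort_config()].
#' @return The panel with NA-masked cells, plus attribute
#'   `heavy_missing_subjects` listing the blanked subjects.
#' @export
inject_missingness <- function(panel, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$missing_rate >= 1) stop("missing_rate must be < 1")
  ss <- stage_seeds(config$seed)
  set.seed(ss[["missingness"]])
  sym_cols <- setdiff(names(panel), c("subject_id", "week"))
  X <- as.matrix(panel[sym_cols])
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(X)) < config$missing_rate,
                   nrow(X), ncol(X))
    X[mask] <- NA_integer_
  }
  ids <- unique(panel$subject_id)
  n_heavy <- round(config$heavy_missing_subject_fraction * length(ids))
  heavy <- character(0)
  if (n_heavy > 0) {
    heavy <- sample(ids, n_heavy)
    for (sid in heavy) {
      rows <- which(panel$subject_id == sid)
      n_blank <- ceiling(0.8 * length(rows)) + 1L   # strictly > 80% of weeks
      blank <- sample(rows, min(n_blank, length(rows)))
      X[blank, ] <- NA_integer_
    }
  }
  out <- panel
  out[sym_cols] <- as.data.frame(X)
  attr(out, "heavy_missing_subjects") <- heavy
  out
}

#' Simulate weekly comorbidity severities linked to the latent states
#'
#' For each disorder, the latent weekly severity is
#' `intercept + coef_elevated * I(state = elevated) + coef_cogphys *
#' I(state = cognitive-physical) + subject intercept + AR(1) noise`; the
#' observed severity is the latent value rounded and clamped to 1..6.
#' `noise_sd` is the AR(1) innovation SD; the first-week noise is drawn from
#' the stationary distribution of the AR(1) process.
#'
#' @param truth Ground-truth list from [simulate_dataset()].
#' @param config The same [cohort_config()].
#' @return list with `comorbidity` (tibble: subject_id, week, disorder,
#'   severity) and `latent` (same shape, unrounded latent severity).
#' @export
simulate_comorbidity <- function(truth, config) {
  stopifnot(inherits(config, "cohort_config"))
  ss <- stage_seeds(config$seed)
  set.seed(ss[["comorbidity"]])
  st <- truth$states
  ids <- unique(st$subject_id)
  Tn <- config$n_weeks
  elev <- as.integer(st$state == 2L)
  cog <- as.integer(st$state == 3L)
  out <- purrr::map(names(config$comorbidity_link), function(d) {
    lk <- config$comorbidity_link[[d]]
    b_subj <- stats::rnorm(length(ids), 0, lk$subject_intercept_sd)
    names(b_subj) <- ids
    rho <- lk$ar1_rho
    noise <- unlist(purrr::map(ids, function(sid) {
      e <- numeric(Tn)
      e[1] <- stats::rnorm(1, 0, lk$noise_sd / sqrt(1 - rho^2))
      for (t in seq_len(Tn - 1L))
        e[t + 1L] <- rho * e[t] + stats::rnorm(1, 0, lk$noise_sd)
      e
    }))
    latent <- lk$intercept + lk$coef_elevated * elev + lk$coef_cogphys * cog +
      b_subj[st$subject_id] + noise
    tibble::tibble(subject_id = st$subject_id, week = st$week, disorder = d,
                   latent = latent,
                   severity = as.integer(pmin(pmax(round(latent), 1L), 6L)))
  })
  out <- dplyr::bind_rows(out)
  list(comorbidity = dplyr::select(out, "subject_id", "week", "disorder",
                                   "severity"),
       latent = dplyr::select(out, "subject_id", "week", "disorder", "latent"))
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_dataset()], [inject_missingness()]
#' and [simulate_comorbidity()] in the documented substream order.
#'
#' @param config A [cohort_config()].
#' @return list with `panel` (missingness applied), `panel_complete`,
#'   `covariates`, `comorbidity`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  sim <- simulate_dataset(config)
  panel <- inject_missingness(sim$panel, config)
  com <- simulate_comorbidity(sim$truth, config)
  list(panel = panel, panel_complete = sim$panel,
       covariates = sim$covariates, comorbidity = com$comorbidity,
       truth = c(sim$truth, list(comorbidity_latent = com$latent,
                                 heavy_missing_subjects =
                                   attr(panel, "heavy_missing_subjects"))))
}
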