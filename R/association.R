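## Post hoc association analyses: demographic OLS regressions on per-subject
## transition probabilities, and linear mixed models (random subject
## intercept, AR(1) within-subject residual correlation) linking decoded
## states and state inertias to weekly comorbid symptom severity.

#' Bonferroni-adjusted significance level
#'
#' @param alpha nominal family-wise level, in (0, 1).
#' @param n_tests number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_adjust(0.05, 5)  # 0.01
bonferroni_adjust <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count", call. = FALSE)
  alpha / n_tests
}

#' Demographic regressions on per-subject transition probabilities
#'
#' For each of the K^2 ordered transition probabilities (diagonals included),
#' fits an ordinary least-squares regression on female, age and ethnoracial
#' minority status, on the raw probability scale. Reports unstandardized
#' coefficients with 95% confidence intervals, t and p (two-sided, from the t
#' distribution), and the standardized coefficient
#' `beta = b * sd(x) / sd(y)`.
#'
#' @param dyn an `mhmm_dynamics` object from [summarize_dynamics()], or a
#'   tibble with columns `subject_id`, `from`, `to`, `prob`.
#' @param covariates covariate tibble (`subject_id`, `female`, `age`,
#'   `ethnoracial_minority`).
#' @param scale `"probability"` (default) regresses the raw probabilities;
#'   `"logit"` regresses `qlogis(prob)`.
#' @return tibble with one row per (from, to, term): `estimate`, `conf.low`,
#'   `conf.high`, `statistic`, `p.value`, `std_beta`.
#' @export
regress_transitions <- function(dyn, covariates,
                                scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  trans <- if (inherits(dyn, "mhmm_dynamics")) dyn$transitions else dyn
  stopifnot(all(c("subject_id", "from", "to", "prob") %in% names(trans)))
  dat <- dplyr::inner_join(trans, covariates, by = "subject_id")
  if (anyNA(dat[c("female", "age", "ethnoracial_minority")]))
    stop("missing covariates are not allowed", call. = FALSE)
  if (length(unique(dat$subject_id)) < 10)
    stop("need at least 10 subjects for the transition regressions",
         call. = FALSE)
  terms <- c("female", "age", "ethnoracial_minority")
  purrr::map_dfr(split(dat, list(dat$from, dat$to)), function(d) {
    y <- if (scale == "logit") stats::qlogis(pmin(pmax(d$prob, 1e-8),
                                                  1 - 1e-8)) else d$prob
    if (stats::sd(y) == 0) {
      warning("constant transition outcome for ", d$from[1], "->", d$to[1],
              "; coefficients set to 0")
      return(tibble::tibble(from = d$from[1], to = d$to[1], term = terms,
                            estimate = 0, conf.low = 0, conf.high = 0,
                            statistic = 0, p.value = 1, std_beta = 0))
    }
    X <- as.matrix(d[terms])
    if (qr(cbind(1, X))$rank < ncol(X) + 1L)
      stop("collinear predictors in transition regression", call. = FALSE)
    m <- stats::lm(y ~ female + age + ethnoracial_minority, data = d)
    sm <- summary(m)$coefficients
    ci <- stats::confint(m)
    tibble::tibble(
      from = d$from[1], to = d$to[1], term = terms,
      estimate = unname(sm[terms, "Estimate"]),
      conf.low = unname(ci[terms, 1]), conf.high = unname(ci[terms, 2]),
      statistic = unname(sm[terms, "t value"]),
      p.value = unname(sm[terms, "Pr(>|t|)"]),
      std_beta = unname(sm[terms, "Estimate"] *
        apply(X, 2, stats::sd) / stats::sd(y)))
  })
}

#' Mixed models linking states and inertias to comorbid severity
#'
#' Per disorder, fits (by maximum likelihood) the linear mixed model
#' `severity ~ I(state = elevated) + I(state = cognitive-physical) + female +
#' age + inertia_elevated + inertia_low + inertia_cogphys` with a random
#' intercept per subject and an AR(1) correlation structure on the
#' within-subject residuals. The low state is the reference category.
#' Significance flags use the Bonferroni-adjusted level
#' `bonferroni_adjust(alpha, number of disorders)`.
#'
#' @param comorbidity tibble (`subject_id`, `week`, `disorder`, `severity`).
#' @param states decoded state paths (`subject_id`, `week`, `state`), states
#'   in canonical order (1 = low, 2 = cognitive-physical, 3 = elevated for
#'   the three-state depression design); see [decode_states()].
#' @param dyn an `mhmm_dynamics` (supplies per-subject inertias).
#' @param covariates covariate tibble.
#' @param alpha nominal family-wise alpha (default 0.05).
#' @param state_elevated,state_cogphys,state_low canonical indices of the
#'   elevated, cognitive-physical and reference (low) states.
#' @return tibble with one row per (disorder, term): `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`,
#'   `significant` (at the adjusted level), plus per-disorder columns
#'   `ar1_rho`, `random_intercept_sd`, `converged`.
#' @export
fit_comorbidity_model <- function(comorbidity, states, dyn, covariates,
                                  alpha = 0.05,
                                  state_elevated = 3L, state_cogphys = 2L,
                                  state_low = 1L) {
  inertia <- dyn$subjects |>
    dplyr::select("subject_id", "state", "inertia") |>
    tidyr::pivot_wider(names_from = "state", values_from = "inertia",
                       names_prefix = "in_")
  inertia <- inertia |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      inertia_elevated = .data[[paste0("in_", state_elevated)]],
      inertia_low = .data[[paste0("in_", state_low)]],
      inertia_cogphys = .data[[paste0("in_", state_cogphys)]])
  dat <- comorbidity |>
    dplyr::inner_join(states, by = c("subject_id", "week")) |>
    dplyr::inner_join(covariates, by = "subject_id") |>
    dplyr::inner_join(inertia, by = "subject_id") |>
    dplyr::mutate(elevated_state = as.integer(.data$state == state_elevated),
                  cogphys_state = as.integer(.data$state == state_cogphys))
  disorders <- unique(dat$disorder)
  adj_alpha <- bonferroni_adjust(alpha, length(disorders))
  terms_map <- c(elevated_state = "elevated_state",
                 cogphys_state = "cogphys_state",
                 female = "female", age = "age",
                 inertia_elevated = "inertia_elevated",
                 inertia_low = "inertia_low",
                 inertia_cogphys = "inertia_cogphys")
  purrr::map_dfr(disorders, function(dd) {
    d <- dat[dat$disorder == dd, ]
    fit <- tryCatch(
      nlme::lme(severity ~ elevated_state + cogphys_state + female + age +
                  inertia_elevated + inertia_low + inertia_cogphys,
                random = ~ 1 | subject_id,
                correlation = nlme::corAR1(form = ~ week | subject_id),
                data = d, method = "ML",
                control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                           msMaxIter = 100, returnObject = TRUE)),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(tibble::tibble(disorder = dd, term = unname(terms_map),
                            estimate = NA_real_, std.error = NA_real_,
                            statistic = NA_real_, p.value = NA_real_,
                            conf.low = NA_real_, conf.high = NA_real_,
                            significant = NA, ar1_rho = NA_real_,
                            random_intercept_sd = NA_real_, converged = FALSE))
    tt <- summary(fit)$tTable
    rows <- intersect(names(terms_map), rownames(tt))
    cs <- fit$modelStruct$corStruct
    rho <- unname(stats::coef(cs, unconstrained = FALSE))
    ri_sd <- sqrt(as.numeric(nlme::getVarCov(fit)[1, 1]))
    crit <- stats::qt(0.975, tt[rows, "DF"])
    tibble::tibble(
      disorder = dd, term = rows,
      estimate = tt[rows, "Value"],
      std.error = tt[rows, "Std.Error"],
      statistic = tt[rows, "t-value"],
      p.value = tt[rows, "p-value"],
      conf.low = tt[rows, "Value"] - crit * tt[rows, "Std.Error"],
      conf.high = tt[rows, "Value"] + crit * tt[rows, "Std.Error"],
      significant = tt[rows, "p-value"] < adj_alpha,
      ar1_rho = rho, random_intercept_sd = ri_sd, converged = TRUE)
  })
}
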