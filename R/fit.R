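## Multilevel Bayesian HMM estimation.
##
## Hierarchy: subject-level transition and emission probabilities are
## parameterised as multinomial logits (baseline = first category of each
## row) and drawn from normal distributions around group-level mean logits,
## with state-specific random-effect variances. The sampler alternates
##   (a) per-subject latent paths by forward-filtering backward-sampling
##       (gap weeks bridged by matrix powers and filled in by conditional
##       bridge sampling, so transition counts stay one-step),
##   (b) per-subject logits by random-walk Metropolis given the path counts
##       (vectorised across subjects),
##   (c) group mean logits and random-effect variances by conjugate
##       normal / inverse-gamma updates given the subject logits.

#' Prior specification for the multilevel HMM
#'
#' @param logit_mean,logit_sd Normal prior on each group-level logit
#'   (default diffuse: mean 0, SD 5).
#' @param var_shape,var_rate Inverse-gamma prior on each random-effect
#'   variance (default shape 2, rate 0.5: weakly informative, prior mean
#'   random-effect SD about 0.6).
#' @return list of class `mhmm_priors`.
#' @export
prior_spec <- function(logit_mean = 0, logit_sd = 5,
                       var_shape = 2, var_rate = 0.5) {
  stopifnot(logit_sd > 0, var_shape > 0, var_rate > 0)
  structure(list(logit_mean = logit_mean, logit_sd = logit_sd,
                 var_shape = var_shape, var_rate = var_rate),
            class = "mhmm_priors")
}

#' MCMC configuration
#'
#' @param n_iterations,n_burnin Total iterations and burn-in (burn-in draws
#'   are discarded; proposal adaptation happens only during burn-in).
#' @param proposal_sd Initial random-walk proposal SD for the logit blocks.
#' @param adapt Adapt proposal scales during burn-in toward a 23-44%
#'   acceptance band (frozen afterwards to preserve detailed balance).
#' @param seed Integer seed (chain c uses seed + c - 1).
#' @param n_chains Number of chains run sequentially; draws are pooled with a
#'   chain index retained for diagnostics.
#' @param thin_subject Keep every `thin_subject`-th subject-level draw.
#' @return list of class `mhmm_mcmc`.
#' @export
mcmc_config <- function(n_iterations = 1500, n_burnin = 500,
                        proposal_sd = 0.3, adapt = TRUE, seed = 1L,
                        n_chains = 1L, thin_subject = 10L) {
  stopifnot(n_iterations >= 1, n_burnin < n_iterations, n_chains >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 proposal_sd = proposal_sd, adapt = isTRUE(adapt),
                 seed = as.integer(seed), n_chains = as.integer(n_chains),
                 thin_subject = as.integer(thin_subject)),
            class = "mhmm_mcmc")
}

panel_to_subjects <- function(panel) {
  validate_panel(panel)
  sym_cols <- setdiff(names(panel), c("subject_id", "week"))
  split_idx <- split(seq_len(nrow(panel)), panel$subject_id)
  subj <- purrr::map(split_idx, function(rows) {
    list(obs = as.matrix(panel[rows, sym_cols]),
         weeks = as.integer(panel$week[rows]))
  })
  bad <- names(subj)[purrr::map_int(subj, ~ nrow(.x$obs)) < 2L]
  if (length(bad))
    stop("every subject needs at least 2 observed weeks; offending: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  subj
}

# numerically safe log(1 + sum_j exp(A_j)) per row
log_denom <- function(A) {
  if (ncol(A) == 0L) return(rep(0, nrow(A)))
  M <- pmax(0, apply(A, 1L, max))
  log(exp(-M) + rowSums(exp(A - M))) + M
}

logits_to_prob_rows <- function(A) {
  # A: n x (m-1) logits -> n x m probabilities with baseline first
  D <- log_denom(A)
  cbind(exp(-D), exp(A - D))
}

# Vectorised random-walk Metropolis for one block of multinomial logits,
# all subjects at once. counts: N x m category counts; A: N x (m-1) logits.
mh_update_block <- function(A, counts, mu, sigma2, psd) {
  N <- nrow(A); m1 <- ncol(A)
  if (m1 == 0L) return(list(A = A, acc = numeric(0)))
  loglik <- function(X)
    rowSums(counts[, -1L, drop = FALSE] * X) - rowSums(counts) * log_denom(X)
  logprior <- function(X)
    -rowSums(sweep(X, 2L, mu)^2) / (2 * sigma2)
  prop <- A + matrix(stats::rnorm(N * m1, 0, psd), N, m1)
  ratio <- loglik(prop) + logprior(prop) - loglik(A) - logprior(A)
  acc <- log(stats::runif(N)) < ratio
  A[acc, ] <- prop[acc, , drop = FALSE]
  list(A = A, acc = mean(acc))
}

# FFBS for one subject: returns the full contiguous latent path from the
# first to the last observed week (gap weeks filled by bridge sampling).
ffbs_subject <- function(e, weeks, Gamma, init) {
  Tn <- nrow(e); K <- ncol(e)
  if (K == 1L)
    return(rep(1L, weeks[Tn] - weeks[1L] + 1L))
  gaps <- diff(weeks)
  maxg <- max(gaps)
  pows <- vector("list", maxg)
  pows[[1L]] <- Gamma
  if (maxg > 1L) for (g in 2:maxg) pows[[g]] <- pows[[g - 1L]] %*% Gamma
  alpha <- matrix(0, Tn, K)
  a <- init * e[1L, ]
  alpha[1L, ] <- a / sum(a)
  for (t in 2:Tn) {
    a <- drop(alpha[t - 1L, ] %*% pows[[gaps[t - 1L]]]) * e[t, ]
    s <- sum(a)
    if (s <= 0 || !is.finite(s)) a <- rep(1, K) else a <- a / s
    alpha[t, ] <- a
  }
  st <- integer(Tn)
  st[Tn] <- sample.int(K, 1L, prob = alpha[Tn, ])
  for (t in (Tn - 1L):1L) {
    p <- alpha[t, ] * pows[[gaps[t]]][, st[t + 1L]]
    st[t] <- sample.int(K, 1L, prob = p)
  }
  span <- weeks[Tn] - weeks[1L] + 1L
  full <- integer(span)
  full[weeks - weeks[1L] + 1L] <- st
  for (t in seq_len(Tn - 1L)) {
    g <- gaps[t]
    if (g > 1L) {
      prev <- st[t]
      for (d in seq_len(g - 1L)) {
        rem <- g - d
        p <- Gamma[prev, ] *
          (if (rem == 1L) Gamma[, st[t + 1L]] else pows[[rem]][, st[t + 1L]])
        prev <- sample.int(K, 1L, prob = p)
        full[weeks[t] - weeks[1L] + 1L + d] <- prev
      }
    }
  }
  full
}

#' Fit a multilevel hidden Markov model to a symptom panel
#'
#' Bayesian estimation of a K-state hidden Markov model for multivariate
#' ordinal emissions, with subject-level random effects on every transition
#' and emission multinomial logit around group-level means. See the package
#' vignette for the model, priors and sampler details.
#'
#' @param panel panel tibble (`subject_id`, `week`, ordinal rating columns).
#' @param K number of latent states.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param n_levels number of ordinal rating levels (default 3).
#' @param relabel apply the canonical state ordering (ascending mean
#'   probability of an at-least-subclinical rating) to every recorded draw.
#' @return An object of class `mhmm_fit`; see [tidy.mhmm_fit()],
#'   [glance.mhmm_fit()], [compute_aic()], [summarize_dynamics()].
#' @export
fit_mhmm <- function(panel, K, priors = prior_spec(), mcmc = mcmc_config(),
                     n_levels = 3L, relabel = TRUE) {
  stopifnot(K >= 1)
  subj <- panel_to_subjects(panel)
  chains <- purrr::map(seq_len(mcmc$n_chains), function(ch) {
    run_mhmm_chain(subj, K, priors, mcmc, n_levels,
                   seed = mcmc$seed + ch - 1L, relabel = relabel)
  })
  fit <- pool_chains(chains, subj, K, n_levels, priors, mcmc, relabel)
  fit$AIC <- tryCatch(compute_aic(fit), error = function(e) NA_real_)
  fit
}

run_mhmm_chain <- function(subj, K, priors, mcmc, C, seed, relabel) {
  set.seed(seed)
  N <- length(subj)
  J <- ncol(subj[[1L]]$obs)
  Km1 <- K - 1L
  Cm1 <- C - 1L
  n_iter <- mcmc$n_iterations
  n_burn <- mcmc$n_burnin
  n_keep <- n_iter - n_burn

  ## ---- initial values: quantile split of mean weekly severity ----
  all_scores <- unlist(purrr::map(subj, ~ rowMeans(.x$obs, na.rm = TRUE)))
  rk <- rank(all_scores, ties.method = "first")
  bins <- pmin(K, 1L + ((rk - 1L) * K) %/% length(rk))
  em_counts <- array(1, c(K, J, C))    # +1 smoothing
  offset <- 0L
  for (s in seq_len(N)) {
    Tn <- nrow(subj[[s]]$obs)
    b <- bins[offset + seq_len(Tn)]
    offset <- offset + Tn
    for (k in seq_len(K)) {
      o <- subj[[s]]$obs[b == k, , drop = FALSE]
      if (nrow(o)) {
        code <- (col(o) - 1L) * C + o
        cnt <- tabulate(code[!is.na(code)], J * C)
        em_counts[k, , ] <- em_counts[k, , ] + matrix(cnt, J, C, byrow = TRUE)
      }
    }
  }
  # transitions start sticky (diag 0.8): weekly clinical panels are strongly
  # persistent, and bin-flip counts from the severity split would start the
  # chain at an unrealistically mobile matrix
  mu_tr <- matrix(0, K, max(Km1, 0L))
  if (K > 1L) for (i in seq_len(K)) {
    row0 <- rep(0.2 / (K - 1), K)
    row0[i] <- 0.8
    mu_tr[i, ] <- probs_to_logits(row0)
  }
  mu_em <- array(0, c(K, J, max(Cm1, 0L)))
  for (k in seq_len(K)) for (j in seq_len(J))
    mu_em[k, j, ] <- probs_to_logits(em_counts[k, j, ] / sum(em_counts[k, j, ]))
  sigma2_tr <- rep(0.16, K)
  sigma2_em <- rep(0.09, K)
  A_tr <- array(rep(mu_tr, each = N), c(N, K, max(Km1, 0L)))
  A_em <- array(rep(mu_em, each = N), c(N, K, J, max(Cm1, 0L)))

  psd_tr <- rep(mcmc$proposal_sd, K)
  psd_em <- matrix(mcmc$proposal_sd, K, J)
  acc_tr <- rep(0, K); acc_em <- matrix(0, K, J); acc_n <- 0L
  acc_tr_total <- rep(0, K); acc_em_total <- matrix(0, K, J); acc_total_n <- 0L
  adapt_interval <- 25L

  tau0sq <- priors$logit_sd^2
  mu0 <- priors$logit_mean
  a0 <- priors$var_shape; b0 <- priors$var_rate

  draw_tr <- array(NA_real_, c(n_keep, K, K))
  draw_em <- array(NA_real_, c(n_keep, K, J, C))
  draw_sd_tr <- matrix(NA_real_, n_keep, K)
  draw_sd_em <- matrix(NA_real_, n_keep, K)
  ll_trace <- numeric(n_iter)
  subj_keep <- max(1L, n_keep %/% mcmc$thin_subject)
  subj_tr_draws <- array(NA_real_, c(subj_keep, N, K, K))
  subj_draw_iter <- integer(subj_keep)
  sum_subj_tr <- array(0, c(N, K, K))
  sum_subj_em <- array(0, c(N, K, J, C))
  n_subj_rec <- 0L; subj_rec_i <- 0L

  tr_counts <- array(0, c(N, K, K))
  em_counts_s <- array(0, c(N, K, J, C))

  for (iter in seq_len(n_iter)) {
    ## (a) latent paths + sufficient counts
    ll_iter <- 0
    G_list <- vector("list", N)
    Th_list <- vector("list", N)
    for (s in seq_len(N)) {
      G <- if (K == 1L) matrix(1, 1, 1) else
        logits_to_prob_rows(A_tr[s, , , drop = FALSE][1, , , drop = TRUE] |>
                              matrix(K, Km1))
      th <- array(0, c(K, J, C))
      for (k in seq_len(K))
        th[k, , ] <- logits_to_prob_rows(matrix(A_em[s, k, , ], J, Cm1))
      G_list[[s]] <- G; Th_list[[s]] <- th
      e <- emission_probs(subj[[s]]$obs, th)
      init <- if (K == 1L) 1 else tryCatch(stationary_distribution(G),
                                           error = function(err) rep(1 / K, K))
      path <- ffbs_subject(e, subj[[s]]$weeks, G, init)
      idx <- utils::head(path, -1L) + K * (utils::tail(path, -1L) - 1L)
      tr_counts[s, , ] <- matrix(tabulate(idx, K * K), K, K)
      st_obs <- path[subj[[s]]$weeks - subj[[s]]$weeks[1L] + 1L]
      for (k in seq_len(K)) {
        o <- subj[[s]]$obs[st_obs == k, , drop = FALSE]
        cnt <- if (nrow(o)) {
          code <- (col(o) - 1L) * C + o
          tabulate(code[!is.na(code)], J * C)
        } else numeric(J * C)
        em_counts_s[s, k, , ] <- matrix(cnt, J, C, byrow = TRUE)
      }
      ll_iter <- ll_iter +
        sum(as.vector(tr_counts[s, , ]) * as.vector(log(pmax(G, 1e-300)))) +
        sum(as.vector(em_counts_s[s, , , ]) *
              as.vector(log(pmax(th, 1e-300))))
    }
    ll_trace[iter] <- ll_iter

    ## (b) subject logits, Metropolis given counts, vectorised over subjects
    if (K > 1L) for (i in seq_len(K)) {
      upd <- mh_update_block(matrix(A_tr[, i, ], N, Km1),
                             matrix(tr_counts[, i, ], N, K),
                             mu_tr[i, ], sigma2_tr[i], psd_tr[i])
      A_tr[, i, ] <- upd$A
      acc_tr[i] <- acc_tr[i] + upd$acc
      acc_tr_total[i] <- acc_tr_total[i] + upd$acc
    }
    for (k in seq_len(K)) for (j in seq_len(J)) {
      upd <- mh_update_block(matrix(A_em[, k, j, ], N, Cm1),
                             matrix(em_counts_s[, k, j, ], N, C),
                             mu_em[k, j, ], sigma2_em[k], psd_em[k, j])
      A_em[, k, j, ] <- upd$A
      acc_em[k, j] <- acc_em[k, j] + upd$acc
      acc_em_total[k, j] <- acc_em_total[k, j] + upd$acc
    }
    acc_n <- acc_n + 1L; acc_total_n <- acc_total_n + 1L

    ## (c) conjugate group-level updates
    if (K > 1L) for (i in seq_len(K)) {
      Ai <- matrix(A_tr[, i, ], N, Km1)
      v <- 1 / (N / sigma2_tr[i] + 1 / tau0sq)
      mu_tr[i, ] <- stats::rnorm(Km1,
        v * (colSums(Ai) / sigma2_tr[i] + mu0 / tau0sq), sqrt(v))
      ss <- sum(sweep(Ai, 2L, mu_tr[i, ])^2)
      sigma2_tr[i] <- 1 / stats::rgamma(1, a0 + N * Km1 / 2, b0 + ss / 2)
    }
    for (k in seq_len(K)) {
      Ak <- matrix(A_em[, k, , ], N, J * Cm1)
      muk <- as.vector(mu_em[k, , ])
      v <- 1 / (N / sigma2_em[k] + 1 / tau0sq)
      muk <- stats::rnorm(J * Cm1,
        v * (colSums(Ak) / sigma2_em[k] + mu0 / tau0sq), sqrt(v))
      mu_em[k, , ] <- muk
      ss <- sum(sweep(Ak, 2L, muk)^2)
      sigma2_em[k] <- 1 / stats::rgamma(1, a0 + N * J * Cm1 / 2, b0 + ss / 2)
    }

    ## proposal adaptation during burn-in only
    if (mcmc$adapt && iter <= n_burn && acc_n == adapt_interval) {
      rate_tr <- acc_tr / acc_n
      psd_tr[rate_tr < 0.23] <- psd_tr[rate_tr < 0.23] * 0.8
      psd_tr[rate_tr > 0.44] <- psd_tr[rate_tr > 0.44] * 1.25
      rate_em <- acc_em / acc_n
      psd_em[rate_em < 0.23] <- psd_em[rate_em < 0.23] * 0.8
      psd_em[rate_em > 0.44] <- psd_em[rate_em > 0.44] * 1.25
      acc_tr[] <- 0; acc_em[] <- 0; acc_n <- 0L
    }
    if (iter == n_burn) {
      acc_tr_total[] <- 0; acc_em_total[] <- 0; acc_total_n <- 0L
    }

    ## record post-burn-in draws (canonically relabeled)
    if (iter > n_burn) {
      d <- iter - n_burn
      G_grp <- if (K == 1L) matrix(1, 1, 1) else logits_to_prob_rows(mu_tr)
      th_grp <- array(0, c(K, J, C))
      for (k in seq_len(K))
        th_grp[k, , ] <- logits_to_prob_rows(matrix(mu_em[k, , ], J, Cm1))
      ord <- if (relabel) canonical_state_order(th_grp) else seq_len(K)
      draw_tr[d, , ] <- G_grp[ord, ord]
      draw_em[d, , , ] <- th_grp[ord, , ]
      draw_sd_tr[d, ] <- sqrt(sigma2_tr)[ord]
      draw_sd_em[d, ] <- sqrt(sigma2_em)[ord]
      for (s in seq_len(N)) {
        sum_subj_tr[s, , ] <- sum_subj_tr[s, , ] + G_list[[s]][ord, ord]
        sum_subj_em[s, , , ] <- sum_subj_em[s, , , ] + Th_list[[s]][ord, , ]
      }
      n_subj_rec <- n_subj_rec + 1L
      if (d %% mcmc$thin_subject == 0L && subj_rec_i < subj_keep) {
        subj_rec_i <- subj_rec_i + 1L
        subj_draw_iter[subj_rec_i] <- d
        for (s in seq_len(N))
          subj_tr_draws[subj_rec_i, s, , ] <- G_list[[s]][ord, ord]
      }
    }
  }

  list(draws = list(transition = draw_tr, emission = draw_em,
                    re_sd_transition = draw_sd_tr, re_sd_emission = draw_sd_em),
       subject = list(
         transition_mean = sum_subj_tr / n_subj_rec,
         emission_mean = sum_subj_em / n_subj_rec,
         transition_draws = subj_tr_draws[seq_len(subj_rec_i), , , ,
                                          drop = FALSE],
         draw_iterations = subj_draw_iter[seq_len(subj_rec_i)]),
       loglik_trace = ll_trace,
       acceptance = list(
         transition = if (acc_total_n) acc_tr_total / acc_total_n else NA,
         emission = if (acc_total_n) acc_em_total / acc_total_n else NA),
       proposal_sd = list(transition = psd_tr, emission = psd_em),
       seed = seed)
}

#' Canonical state order: ascending mean probability of endorsing symptoms
#' at subclinical-or-worse level; ties broken by prior state label.
#' @noRd
canonical_state_order <- function(emission) {
  key <- apply(1 - emission[, , 1L, drop = FALSE], 1L, mean)
  order(key, seq_along(key))
}

pool_chains <- function(chains, subj, K, C, priors, mcmc, relabel) {
  J <- ncol(subj[[1L]]$obs)
  n_each <- dim(chains[[1L]]$draws$transition)[1L]
  abind1 <- function(get) {
    parts <- purrr::map(chains, get)
    do.call(function(...) {
      arrs <- list(...)
      dims <- dim(arrs[[1L]])
      out <- array(NA_real_, c(sum(purrr::map_dbl(arrs, ~ dim(.x)[1L])),
                               dims[-1L]))
      at <- 0L
      for (a in arrs) {
        n <- dim(a)[1L]
        idx <- at + seq_len(n)
        if (length(dims) == 2L) out[idx, ] <- a
        else if (length(dims) == 3L) out[idx, , ] <- a
        else out[idx, , , ] <- a
        at <- at + n
      }
      out
    }, parts)
  }
  nch <- length(chains)
  subj_mean_tr <- Reduce(`+`, purrr::map(chains, ~ .x$subject$transition_mean)) / nch
  subj_mean_em <- Reduce(`+`, purrr::map(chains, ~ .x$subject$emission_mean)) / nch
  structure(list(
    K = K, J = J, C = C,
    subject_ids = names(subj),
    data = subj,
    draws = list(
      transition = abind1(~ .x$draws$transition),
      emission = abind1(~ .x$draws$emission),
      re_sd_transition = abind1(~ .x$draws$re_sd_transition),
      re_sd_emission = abind1(~ .x$draws$re_sd_emission),
      chain = rep(seq_len(nch), each = n_each)),
    subject = list(transition_mean = subj_mean_tr,
                   emission_mean = subj_mean_em,
                   transition_draws = chains[[1L]]$subject$transition_draws,
                   draw_iterations = chains[[1L]]$subject$draw_iterations),
    loglik_trace = purrr::map(chains, "loglik_trace"),
    acceptance = purrr::map(chains, "acceptance"),
    priors = priors, mcmc = mcmc, relabeled = relabel,
    state_labels = if (K == 3L) c("low", "cognitive_physical", "elevated")
                   else sprintf("state_%d", seq_len(K))),
    class = "mhmm_fit")
}

#' Canonicalise state labels of a fitted model's draws
#'
#' Within each posterior draw, states are sorted ascending by the mean (over
#' symptoms) probability of a subclinical-or-clinical rating, and the
#' permutation is applied consistently to the transition, emission and
#' random-effect-SD draws. Draws recorded by [fit_mhmm()] with
#' `relabel = TRUE` are already canonical, making this idempotent.
#'
#' @param fit an `mhmm_fit`.
#' @return the fit with relabeled draws.
#' @export
relabel_states <- function(fit) {
  stopifnot(inherits(fit, "mhmm_fit"))
  K <- fit$K
  nd <- dim(fit$draws$transition)[1L]
  for (d in seq_len(nd)) {
    ord <- canonical_state_order(fit$draws$emission[d, , , , drop = TRUE] |>
                                   array(c(K, fit$J, fit$C)))
    if (!identical(ord, seq_len(K))) {
      fit$draws$transition[d, , ] <- fit$draws$transition[d, ord, ord]
      fit$draws$emission[d, , , ] <- fit$draws$emission[d, ord, , ]
      fit$draws$re_sd_transition[d, ] <- fit$draws$re_sd_transition[d, ord]
      fit$draws$re_sd_emission[d, ] <- fit$draws$re_sd_emission[d, ord]
    }
  }
  fit$relabeled <- TRUE
  fit
}

#' Posterior-mean group-level transition matrix
#' @param fit an `mhmm_fit`.
#' @export
group_transition_matrix <- function(fit) {
  apply(fit$draws$transition, c(2, 3), mean)
}

#' Posterior-mean group-level emission probabilities
#' @param fit an `mhmm_fit`.
#' @export
group_emission_array <- function(fit) {
  apply(fit$draws$emission, c(2, 3, 4), mean)
}

#' Posterior-median group parameters on the probability scale
#' (medians taken on the logit scale so rows stay exactly stochastic)
#' @noRd
group_median_params <- function(fit) {
  K <- fit$K; J <- fit$J; C <- fit$C
  med_row <- function(p_draws) {
    # p_draws: n x m probabilities
    eta <- log(pmax(p_draws[, -1L, drop = FALSE], 1e-300) /
                 pmax(p_draws[, 1L], 1e-300))
    logits_to_probs(apply(eta, 2L, stats::median))
  }
  G <- matrix(0, K, K)
  for (i in seq_len(K))
    G[i, ] <- if (K == 1L) 1 else med_row(matrix(fit$draws$transition[, i, ],
                                                 ncol = K))
  th <- array(0, c(K, J, C))
  for (k in seq_len(K)) for (j in seq_len(J))
    th[k, j, ] <- med_row(matrix(fit$draws$emission[, k, j, ], ncol = C))
  list(transition = G, emission = th)
}

#' Marginal log-likelihood of the data at the posterior-median group
#' parameters (states marginalised by the forward algorithm, all subjects)
#' @noRd
group_loglik_hat <- function(fit) {
  par <- group_median_params(fit)
  init <- if (fit$K == 1L) 1 else
    tryCatch(stationary_distribution(par$transition),
             error = function(e) rep(1 / fit$K, fit$K))
  sum(purrr::map_dbl(fit$data, function(s)
    forward_loglik(s$obs, par$transition, par$emission, init = init,
                   weeks = s$weeks)))
}

#' Akaike information criterion of a fitted multilevel HMM
#'
#' `AIC = -2 * loglik + 2 * p`, where the log-likelihood is the marginal
#' (forward-algorithm) likelihood of all subjects evaluated at the
#' posterior-median group-level parameters, and
#' `p = K(K-1) + K * J * (C-1)` counts the free group-level transition and
#' emission logits (subject-level effects are not counted).
#'
#' @param fit an `mhmm_fit`.
#' @return AIC (scalar).
#' @export
compute_aic <- function(fit) {
  stopifnot(inherits(fit, "mhmm_fit"))
  ll <- group_loglik_hat(fit)
  if (!is.finite(ll)) stop("non-finite log-likelihood at posterior medians")
  p <- n_group_parameters(fit$K, fit$J, fit$C)
  -2 * ll + 2 * p
}

n_group_parameters <- function(K, J, C) K * (K - 1) + K * J * (C - 1)

#' Fit candidate state numbers and select by AIC
#'
#' Fits the multilevel HMM for each K in `K_range` and tabulates
#' log-likelihood, parameter count and AIC; the smallest AIC is marked as
#' selected. Failed fits are recorded and selection is over the successes.
#'
#' @param panel panel tibble.
#' @param K_range integer vector of candidate state numbers.
#' @inheritParams fit_mhmm
#' @return tibble of class `mhmm_selection` with columns `K`, `loglik`,
#'   `n_parameters`, `AIC`, `selected`, `error`; the fitted models are kept
#'   in the `fits` attribute.
#' @export
select_num_states <- function(panel, K_range = 2:5, priors = prior_spec(),
                              mcmc = mcmc_config(), n_levels = 3L) {
  stopifnot(length(K_range) >= 1)
  fits <- purrr::map(K_range, function(K) {
    tryCatch(fit_mhmm(panel, K, priors, mcmc, n_levels = n_levels),
             error = function(e) e)
  })
  tab <- purrr::map2_dfr(fits, K_range, function(f, K) {
    if (inherits(f, "error"))
      return(tibble::tibble(K = K, loglik = NA_real_,
                            n_parameters = NA_integer_, AIC = NA_real_,
                            error = conditionMessage(f)))
    ll <- tryCatch(group_loglik_hat(f), error = function(e) NA_real_)
    tibble::tibble(K = K, loglik = ll,
                   n_parameters = n_group_parameters(f$K, f$J, f$C),
                   AIC = -2 * ll + 2 * n_group_parameters(f$K, f$J, f$C),
                   error = NA_character_)
  })
  tab$selected <- FALSE
  if (any(is.finite(tab$AIC)))
    tab$selected[which.min(tab$AIC)] <- TRUE
  attr(tab, "fits") <- fits
  class(tab) <- c("mhmm_selection", class(tab))
  tab
}

#' Posterior-mean subject-level transition matrices
#' @noRd
subject_mean_matrices <- function(fit) {
  N <- length(fit$subject_ids)
  out <- purrr::map(seq_len(N), function(s)
    matrix(fit$subject$transition_mean[s, , ], fit$K, fit$K))
  # row-normalise away the tiny drift that averaging introduces
  out <- purrr::map(out, function(G) G / rowSums(G))
  stats::setNames(out, fit$subject_ids)
}

#' Viterbi-decoded state paths at posterior-mean subject parameters
#'
#' @param fit an `mhmm_fit`.
#' @return tibble with `subject_id`, `week`, `state`.
#' @export
decode_states <- function(fit) {
  stopifnot(inherits(fit, "mhmm_fit"))
  mats <- subject_mean_matrices(fit)
  purrr::map_dfr(seq_along(fit$subject_ids), function(s) {
    sid <- fit$subject_ids[s]
    th <- array(fit$subject$emission_mean[s, , , ], c(fit$K, fit$J, fit$C))
    # renormalise emission rows
    norm <- apply(th, c(1, 2), sum)
    for (cc in seq_len(fit$C)) th[, , cc] <- th[, , cc] / norm
    G <- mats[[sid]]
    init <- if (fit$K == 1L) 1 else
      tryCatch(stationary_distribution(G),
               error = function(e) rep(1 / fit$K, fit$K))
    v <- viterbi_decode(fit$data[[s]]$obs, G, th, init = init,
                        weeks = fit$data[[s]]$weeks)
    tibble::tibble(subject_id = sid, week = fit$data[[s]]$weeks,
                   state = v$path)
  })
}

#' @export
print.mhmm_fit <- function(x, ...) {
  cat("Multilevel hidden Markov model fit\n")
  cat("  states:", x$K, " symptoms:", x$J, " levels:", x$C, "\n")
  cat("  subjects:", length(x$subject_ids),
      " draws:", dim(x$draws$transition)[1L],
      " chains:", max(x$draws$chain), "\n")
  if (!is.null(x$AIC) && is.finite(x$AIC)) cat("  AIC:", round(x$AIC, 2), "\n")
  G <- group_transition_matrix(x)
  cat("  group-level inertia:",
      paste(sprintf("%.3f", diag(G)), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy posterior summaries of the group-level parameters
#'
#' @param x an `mhmm_fit`.
#' @param ... unused.
#' @return tibble with one row per group-level probability: `component`
#'   ("transition" or "emission"), indices, posterior `estimate`, `std.error`
#'   (posterior SD) and 90% credible bounds `conf.low` / `conf.high`.
#' @export
tidy.mhmm_fit <- function(x, ...) {
  K <- x$K; J <- x$J; C <- x$C
  qs <- function(v) stats::quantile(v, c(0.05, 0.95), names = FALSE)
  tr <- purrr::map_dfr(seq_len(K), function(i) purrr::map_dfr(seq_len(K),
    function(j) {
      v <- x$draws$transition[, i, j]
      q <- qs(v)
      tibble::tibble(component = "transition", from = i, to = j,
                     symptom = NA_character_, level = NA_integer_,
                     estimate = mean(v), std.error = stats::sd(v),
                     conf.low = q[1], conf.high = q[2])
    }))
  sym <- if (J == length(DEPRESSION_SYMPTOMS)) DEPRESSION_SYMPTOMS
         else sprintf("symptom_%02d", seq_len(J))
  em <- purrr::map_dfr(seq_len(K), function(k) purrr::map_dfr(seq_len(J),
    function(j) purrr::map_dfr(seq_len(C), function(cc) {
      v <- x$draws$emission[, k, j, cc]
      q <- qs(v)
      tibble::tibble(component = "emission", from = k, to = NA_integer_,
                     symptom = sym[j], level = cc,
                     estimate = mean(v), std.error = stats::sd(v),
                     conf.low = q[1], conf.high = q[2])
    })))
  dplyr::bind_rows(tr, em)
}

#' One-row model summary
#' @param x an `mhmm_fit`.
#' @param ... unused.
#' @export
glance.mhmm_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    n_subjects = length(x$subject_ids),
    n_obs = sum(purrr::map_int(x$data, ~ nrow(.x$obs))),
    n_parameters = n_group_parameters(x$K, x$J, x$C),
    logLik = tryCatch(group_loglik_hat(x), error = function(e) NA_real_),
    AIC = if (is.null(x$AIC)) NA_real_ else x$AIC,
    n_draws = dim(x$draws$transition)[1L],
    n_chains = max(x$draws$chain))
}

#' Trace-based convergence diagnostics
#'
#' Split-chain potential-scale-reduction factors and crude effective sample
#' sizes for every group-level transition and emission probability, plus a
#' summary of Metropolis acceptance rates. Thresholds are reported, not
#' enforced.
#'
#' @param fit an `mhmm_fit`.
#' @return list with `parameters` (tibble: parameter, rhat, ess), and
#'   `acceptance` (tibble of mean acceptance rates per block type).
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mhmm_fit"))
  K <- fit$K; J <- fit$J; C <- fit$C
  params <- list()
  for (i in seq_len(K)) for (j in seq_len(K))
    params[[sprintf("transition[%d,%d]", i, j)]] <- fit$draws$transition[, i, j]
  for (k in seq_len(K)) for (j in seq_len(J))
    params[[sprintf("emission[%d,%d,1]", k, j)]] <- fit$draws$emission[, k, j, 1]
  tab <- purrr::imap_dfr(params, function(v, nm) {
    tibble::tibble(parameter = nm, rhat = split_rhat(v, fit$draws$chain),
                   ess = ess_acf(v))
  })
  acc <- purrr::imap_dfr(fit$acceptance, function(a, ch) tibble::tibble(
    chain = ch,
    block = c("transition", "emission"),
    mean_acceptance = c(mean(a$transition), mean(a$emission))))
  flags <- c(
    if (any(is.finite(tab$rhat) & tab$rhat > 1.1))
      paste0("rhat > 1.1 for ",
             sum(is.finite(tab$rhat) & tab$rhat > 1.1), " parameter(s)"),
    if (any(acc$mean_acceptance < 0.05, na.rm = TRUE))
      "near-zero Metropolis acceptance: stuck chain (proposal scale too large?)",
    if (any(acc$mean_acceptance > 0.9, na.rm = TRUE))
      paste0("near-total Metropolis acceptance: stuck or barely moving chain ",
             "(proposal scale too small?)"),
    if (any(tab$ess < 50, na.rm = TRUE))
      paste0("effective sample size < 50 for ",
             sum(tab$ess < 50, na.rm = TRUE), " parameter(s)"))
  list(parameters = tab, acceptance = acc, flags = flags)
}

# split-half potential scale reduction (rank-free, per chain split in two)
split_rhat <- function(v, chain = rep(1L, length(v))) {
  halves <- list()
  for (ch in unique(chain)) {
    x <- v[chain == ch]
    h <- length(x) %/% 2L
    if (h < 2L) return(NA_real_)
    halves <- c(halves, list(x[seq_len(h)], x[h + seq_len(h)]))
  }
  m <- length(halves); n <- length(halves[[1L]])
  means <- purrr::map_dbl(halves, mean)
  vars <- purrr::map_dbl(halves, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude ESS from the initial-positive autocorrelation sum
ess_acf <- function(v, max_lag = min(200L, length(v) %/% 4L)) {
  n <- length(v)
  if (stats::var(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = max_lag, plot = FALSE)$acf[-1L]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}
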