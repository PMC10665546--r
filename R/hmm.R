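#' @keywords internal
"_PACKAGE"

## Single-subject HMM machinery with multivariate categorical emissions.
##
## Observations are a T x J integer matrix of ordinal ratings (levels 1..C),
## NA allowed per cell. `weeks` is a strictly increasing integer vector of
## calendar-week indices; a gap of g skipped weeks between consecutive rows is
## bridged by the (g+1)-step transition matrix, so removed weeks do not distort
## the weekly time base. Missing symptom cells are marginalised out (they
## contribute a factor of 1 to the emission probability).

#' Integer matrix power
#' @noRd
mat_pow <- function(M, n) {
  stopifnot(n >= 1)
  out <- M
  n <- n - 1L
  P <- M
  while (n > 0L) {
    if (n %% 2L == 1L) out <- out %*% P
    P <- P %*% P
    n <- n %/% 2L
  }
  out
}

#' Per-week emission probabilities under every state
#'
#' @param obs T x J integer matrix (levels 1..C, NA = missing).
#' @param emission K x J x C array of categorical emission probabilities.
#' @return T x K matrix; entry (t, k) is prod_j P(obs[t, j] | state k), with
#'   missing cells contributing 1.
#' @noRd
emission_probs <- function(obs, emission) {
  K <- dim(emission)[1]
  J <- dim(emission)[2]
  Tn <- nrow(obs)
  out <- matrix(1, Tn, K)
  jj <- rep(seq_len(J), each = Tn)
  for (k in seq_len(K)) {
    th <- emission[k, , , drop = TRUE]            # J x C
    if (is.null(dim(th))) th <- matrix(th, nrow = J)
    p <- matrix(th[cbind(jj, as.vector(obs))], Tn, J)
    p[is.na(p)] <- 1
    out[, k] <- apply(p, 1L, prod)
  }
  out
}

#' Step transition matrices between consecutive observed weeks
#' @return list of length T-1; element t is Gamma^(weeks[t+1] - weeks[t]).
#' @noRd
step_matrices <- function(Gamma, weeks) {
  Tn <- length(weeks)
  if (Tn < 2L) return(list())
  gaps <- diff(weeks)
  pow_cache <- list(`1` = Gamma)
  lapply(gaps, function(g) {
    key <- as.character(g)
    if (is.null(pow_cache[[key]])) pow_cache[[key]] <<- mat_pow(Gamma, g)
    pow_cache[[key]]
  })
}

check_hmm_inputs <- function(obs, Gamma, emission, init) {
  K <- nrow(Gamma)
  stopifnot(ncol(Gamma) == K, dim(emission)[1] == K)
  if (max(abs(rowSums(Gamma) - 1)) > 1e-8)
    stop("transition matrix rows must sum to 1", call. = FALSE)
  if (abs(sum(init) - 1) > 1e-8)
    stop("initial distribution must sum to 1", call. = FALSE)
  C <- dim(emission)[3]
  vals <- obs[!is.na(obs)]
  if (length(vals) && (any(vals < 1) || any(vals > C)))
    stop("observed ratings outside emission support 1..", C, call. = FALSE)
  invisible(TRUE)
}

#' Forward log-likelihood of an ordinal symptom sequence
#'
#' Scaled forward recursion for a hidden Markov chain with conditionally
#' independent categorical emissions per symptom. Missing symptom cells are
#' marginalised; gaps in the week index are bridged with matrix powers of the
#' transition matrix.
#'
#' @param obs Integer matrix (weeks x symptoms) of ratings in 1..C, NA allowed.
#' @param Gamma K x K row-stochastic transition matrix.
#' @param emission K x J x C array, `emission[k, j, c]` = P(rating c | state k)
#'   for symptom j.
#' @param init Initial state distribution; defaults to the stationary
#'   distribution of `Gamma`.
#' @param weeks Integer week indices, strictly increasing; defaults to
#'   `1:nrow(obs)` (contiguous weeks).
#' @return Log-likelihood (scalar). `-Inf` with a warning if some week has zero
#'   probability under every state.
#' @export
#' @examples
#' Gamma <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' emission <- array(c(.8, .1, .2, .9), c(2, 1, 2))
#' forward_loglik(matrix(c(1, 1, 2), 3, 1), Gamma, emission)
forward_loglik <- function(obs, Gamma, emission, init = NULL,
                           weeks = seq_len(nrow(obs))) {
  obs <- as.matrix(obs)
  if (is.null(init)) init <- stationary_distribution(Gamma)
  check_hmm_inputs(obs, Gamma, emission, init)
  e <- emission_probs(obs, emission)
  steps <- step_matrices(Gamma, weeks)
  Tn <- nrow(obs)
  a <- init * e[1L, ]
  ll <- 0
  for (t in seq_len(Tn)) {
    if (t > 1L) a <- drop(a %*% steps[[t - 1L]]) * e[t, ]
    ct <- sum(a)
    if (ct <= 0) {
      warning("zero-probability observation at position ", t,
              " under all states; log-likelihood is -Inf")
      return(-Inf)
    }
    ll <- ll + log(ct)
    a <- a / ct
  }
  ll
}

#' Smoothed posterior state probabilities (forward-backward)
#'
#' @inheritParams forward_loglik
#' @return T x K matrix of P(state k at observed week t | all observations);
#'   rows sum to 1.
#' @export
posterior_state_probs <- function(obs, Gamma, emission, init = NULL,
                                  weeks = seq_len(nrow(obs))) {
  obs <- as.matrix(obs)
  if (is.null(init)) init <- stationary_distribution(Gamma)
  check_hmm_inputs(obs, Gamma, emission, init)
  e <- emission_probs(obs, emission)
  steps <- step_matrices(Gamma, weeks)
  Tn <- nrow(obs)
  K <- nrow(Gamma)
  alpha <- matrix(0, Tn, K)
  a <- init * e[1L, ]
  for (t in seq_len(Tn)) {
    if (t > 1L) a <- drop(a %*% steps[[t - 1L]]) * e[t, ]
    ct <- sum(a)
    if (ct <= 0) stop("zero-probability observation at position ", t)
    alpha[t, ] <- a / ct
    a <- alpha[t, ]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    b <- drop(steps[[t]] %*% (e[t + 1L, ] * beta[t + 1L, ]))
    beta[t, ] <- b / max(b)
  }
  post <- alpha * beta
  post / rowSums(post)
}

#' Viterbi decoding of the most probable state path
#'
#' Ties are broken toward the lowest state index.
#'
#' @inheritParams forward_loglik
#' @return list with `path` (integer vector of states, one per observed week)
#'   and `log_score` (joint log probability of the returned path and the data).
#' @export
viterbi_decode <- function(obs, Gamma, emission, init = NULL,
                           weeks = seq_len(nrow(obs))) {
  obs <- as.matrix(obs)
  if (is.null(init)) init <- stationary_distribution(Gamma)
  check_hmm_inputs(obs, Gamma, emission, init)
  e <- emission_probs(obs, emission)
  steps <- step_matrices(Gamma, weeks)
  Tn <- nrow(obs)
  K <- nrow(Gamma)
  delta <- matrix(-Inf, Tn, K)
  back <- matrix(1L, Tn, K)
  delta[1L, ] <- log(init) + log(e[1L, ])
  if (Tn > 1L) for (t in 2L:Tn) {
    lG <- log(steps[[t - 1L]])
    for (k in seq_len(K)) {
      cand <- delta[t - 1L, ] + lG[, k]
      back[t, k] <- which.max(cand)             # first max = lowest index
      delta[t, k] <- cand[back[t, k]] + log(e[t, k])
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1L) for (t in (Tn - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  list(path = path, log_score = max(delta[Tn, ]))
}
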