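## Markov-chain dynamics of fitted transition matrices: inertia, stationary
## occupancy, mean first-passage times and recurrence times, per subject and
## averaged over subjects.

#' Communicating-class check for a stochastic matrix
#' @return character vector naming states unreachable from state 1 (empty if
#'   irreducible).
#' @noRd
unreachable_states <- function(Gamma, tol = 1e-12) {
  K <- nrow(Gamma)
  reach <- (Gamma > tol) | diag(K) > 0
  for (i in seq_len(ceiling(log2(max(K, 2))))) reach <- (reach %*% reach) > 0
  mutual <- reach & t(reach)
  which(!mutual[1L, ])
}

assert_irreducible <- function(Gamma) {
  bad <- unreachable_states(Gamma)
  if (length(bad))
    stop("transition matrix is reducible: states {", paste(bad, collapse = ", "),
         "} do not communicate with state 1", call. = FALSE)
  invisible(TRUE)
}

#' Stationary distribution of a transition matrix
#'
#' Solves the balance equations pi = pi Gamma, sum(pi) = 1 as a linear system.
#'
#' @param Gamma K x K row-stochastic matrix of an irreducible chain.
#' @return Numeric vector pi of length K summing to 1.
#' @export
#' @examples
#' stationary_distribution(matrix(c(.9, .1, .2, .8), 2, byrow = TRUE))
stationary_distribution <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  K <- nrow(Gamma)
  if (K == 1L) return(1)
  assert_irreducible(Gamma)
  A <- rbind(t(diag(K) - Gamma), rep(1, K))
  pi <- qr.solve(A, c(rep(0, K), 1))
  pi / sum(pi)
}

#' Mean first-passage times between states
#'
#' Expected number of steps (weeks) to first reach state j starting from
#' state i, for an irreducible chain. For each target j the linear system
#' m_ij = 1 + sum_{k != j} Gamma_ik m_kj is solved over i != j.
#'
#' @inheritParams stationary_distribution
#' @return K x K matrix of passage times in weeks; the diagonal is NA
#'   (recurrence is reported separately, see [recurrence_time()]).
#' @export
mean_first_passage <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  K <- nrow(Gamma)
  assert_irreducible(Gamma)
  m <- matrix(NA_real_, K, K, dimnames = dimnames(Gamma))
  for (j in seq_len(K)) {
    idx <- setdiff(seq_len(K), j)
    A <- diag(length(idx)) - Gamma[idx, idx, drop = FALSE]
    m[idx, j] <- solve(A, rep(1, length(idx)))
  }
  m
}

#' Mean recurrence times of states
#'
#' For an ergodic chain the expected number of weeks for state i to recur is
#' 1 / pi_i, the reciprocal of its stationary probability.
#'
#' @inheritParams stationary_distribution
#' @return Numeric vector of length K, in weeks.
#' @export
recurrence_time <- function(Gamma) {
  1 / stationary_distribution(Gamma)
}

#' Empirical recurrence times of a decoded state path
#'
#' Alternative to the analytic `1/pi` definition: the average number of weeks
#' between successive visits to each state along a decoded path.
#'
#' @param path integer vector of decoded states.
#' @param weeks optional week indices matching `path`.
#' @return named numeric vector (NA for states visited fewer than twice).
#' @export
empirical_recurrence_time <- function(path, weeks = seq_along(path)) {
  K <- max(path)
  vapply(seq_len(K), function(k) {
    at <- weeks[path == k]
    if (length(at) < 2L) return(NA_real_)
    mean(diff(at))
  }, numeric(1))
}

#' Per-subject and group-average Markov dynamics of a fitted model
#'
#' Computes, for every subject, the posterior-mean transition matrix and its
#' inertia (diagonal), stationary distribution, mean first-passage times,
#' recurrence times, and the proportion of weeks spent in each state along the
#' Viterbi-decoded path. Group summaries are unweighted means over subjects;
#' subjects whose posterior-mean matrix is reducible are excluded from the
#' passage/recurrence averages with a warning.
#'
#' @param fit An `mhmm_fit` object from [fit_mhmm()].
#' @return An object of class `mhmm_dynamics`: a list with
#'   \describe{
#'     \item{subjects}{tibble of per-subject quantities, one row per
#'       (subject, state): inertia, stationary probability, recurrence time,
#'       decoded occupancy.}
#'     \item{passage}{tibble of per-subject mean first-passage times, one row
#'       per (subject, from, to) with from != to.}
#'     \item{transitions}{tibble of per-subject transition probabilities
#'       (subject, from, to, prob).}
#'     \item{group}{list with the group-average transition matrix, inertia,
#'       stationary, first-passage matrix, recurrence and occupancy vectors.}
#'     \item{paths}{tibble of Viterbi-decoded states (subject_id, week,
#'       state).}
#'   }
#' @export
summarize_dynamics <- function(fit) {
  stopifnot(inherits(fit, "mhmm_fit"))
  K <- fit$K
  mats <- subject_mean_matrices(fit)
  paths <- decode_states(fit)

  occ <- paths |>
    dplyr::count(.data$subject_id, .data$state) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(occupancy = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(subject_id = names(mats), state = seq_len(K),
                    fill = list(n = 0L, occupancy = 0)) |>
    dplyr::select("subject_id", "state", "occupancy")

  per_subj <- purrr::map(names(mats), function(sid) {
    G <- mats[[sid]]
    red <- length(unreachable_states(G)) > 0
    pi <- if (red) rep(NA_real_, K) else stationary_distribution(G)
    mfp <- if (red) matrix(NA_real_, K, K) else mean_first_passage(G)
    list(
      states = tibble::tibble(
        subject_id = sid, state = seq_len(K), inertia = diag(G),
        stationary = pi,
        recurrence = if (red) rep(NA_real_, K) else 1 / pi,
        reducible = red),
      passage = tibble::tibble(
        subject_id = sid,
        from = rep(seq_len(K), K), to = rep(seq_len(K), each = K),
        weeks = as.vector(mfp)) |> dplyr::filter(.data$from != .data$to),
      trans = tibble::tibble(
        subject_id = sid,
        from = rep(seq_len(K), K), to = rep(seq_len(K), each = K),
        prob = as.vector(G))
    )
  })

  subjects <- purrr::map_dfr(per_subj, "states") |>
    dplyr::left_join(occ, by = c("subject_id", "state"))
  passage <- purrr::map_dfr(per_subj, "passage")
  transitions <- purrr::map_dfr(per_subj, "trans")

  n_red <- sum(purrr::map_lgl(per_subj, ~ .x$states$reducible[1]))
  if (n_red > 0)
    warning(n_red, " subject(s) with reducible posterior-mean transition ",
            "matrices excluded from passage/recurrence averages")

  G_bar <- Reduce(`+`, mats) / length(mats)
  group <- list(
    transition = G_bar,
    inertia = tapply(subjects$inertia, subjects$state, mean, na.rm = TRUE),
    stationary = tapply(subjects$stationary, subjects$state, mean, na.rm = TRUE),
    recurrence = tapply(subjects$recurrence, subjects$state, mean, na.rm = TRUE),
    occupancy = tapply(subjects$occupancy, subjects$state, mean),
    first_passage = {
      fp <- matrix(NA_real_, K, K)
      agg <- stats::aggregate(weeks ~ from + to, data = passage, FUN = mean,
                              na.rm = TRUE, na.action = stats::na.pass)
      fp[cbind(agg$from, agg$to)] <- agg$weeks
      fp
    }
  )

  structure(list(subjects = subjects, passage = passage,
                 transitions = transitions, group = group, paths = paths,
                 K = K, state_labels = fit$state_labels),
            class = "mhmm_dynamics")
}

#' @export
print.mhmm_dynamics <- function(x, ...) {
  cat("Markov dynamics for", length(unique(x$subjects$subject_id)),
      "subjects,", x$K, "states\n")
  cat("Group-average inertia: ",
      paste(sprintf("%.3f", x$group$inertia), collapse = ", "), "\n")
  cat("Group-average recurrence (weeks): ",
      paste(sprintf("%.1f", x$group$recurrence), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.mhmm_dynamics <- function(x, ...) x$subjects
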