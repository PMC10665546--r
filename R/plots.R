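## Figure-style summaries: per-state symptom endorsement profiles and the
## transition/inertia matrix.

#' Per-state symptom endorsement profile table
#'
#' Probability of endorsing each symptom at the subclinical-or-clinical level
#' given each state (posterior means of the group-level emission
#' parameters).
#'
#' @param fit an `mhmm_fit`.
#' @return tibble with `state`, `state_label`, `symptom`, `p_endorse`.
#' @export
emission_profile_table <- function(fit) {
  th <- group_emission_array(fit)
  sym <- if (fit$J == length(DEPRESSION_SYMPTOMS)) DEPRESSION_SYMPTOMS
         else sprintf("symptom_%02d", seq_len(fit$J))
  tibble::tibble(
    state = rep(seq_len(fit$K), each = fit$J),
    state_label = rep(fit$state_labels, each = fit$J),
    symptom = rep(sym, fit$K),
    p_endorse = as.vector(t(1 - th[, , 1L])))
}

#' Transition/inertia matrix report
#'
#' Group-level posterior-mean transition probabilities in long form, with the
#' diagonal flagged as inertia.
#'
#' @param fit an `mhmm_fit`.
#' @return tibble with `from`, `to`, `from_label`, `to_label`, `prob`,
#'   `is_inertia`.
#' @export
transition_report <- function(fit) {
  G <- group_transition_matrix(fit)
  K <- fit$K
  tibble::tibble(
    from = rep(seq_len(K), K), to = rep(seq_len(K), each = K),
    from_label = rep(fit$state_labels, K),
    to_label = rep(fit$state_labels, each = K),
    prob = as.vector(G),
    is_inertia = rep(seq_len(K), K) == rep(seq_len(K), each = K))
}

#' Plot per-state symptom endorsement profiles
#'
#' Bar chart of the probability of endorsing each symptom at subclinical or
#' clinical level, faceted by state.
#'
#' @param fit an `mhmm_fit`.
#' @return a ggplot object.
#' @export
plot_emission_profiles <- function(fit) {
  tab <- emission_profile_table(fit)
  tab$symptom <- factor(tab$symptom, levels = unique(tab$symptom))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$symptom, y = .data$p_endorse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~ state_label, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL,
                  y = "P(subclinical or clinical | state)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the group-level transition matrix
#'
#' Heat-map of transition probabilities; diagonal tiles are the state
#' inertias.
#'
#' @param fit an `mhmm_fit`.
#' @return a ggplot object.
#' @export
plot_transition_matrix <- function(fit) {
  tab <- transition_report(fit)
  tab$from_label <- factor(tab$from_label, levels = fit$state_labels)
  tab$to_label <- factor(tab$to_label, levels = fit$state_labels)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$to_label, y = .data$from_label,
                                    fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$prob)),
                       color = "white") +
    ggplot2::scale_fill_gradient(low = "grey20", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "to state", y = "from state", fill = "probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mhmm_fit <- function(object, ...) plot_emission_profiles(object)

#' Plot per-subject dynamics distributions
#'
#' Violin/jitter plot of subject-level inertias per state.
#'
#' @param dyn an `mhmm_dynamics`.
#' @return a ggplot object.
#' @export
plot_subject_inertias <- function(dyn) {
  d <- dyn$subjects
  d$state_label <- factor(dyn$state_labels[d$state], levels = dyn$state_labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state_label, y = .data$inertia)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "subject-level inertia") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mhmm_dynamics <- function(object, ...) plot_subject_inertias(object)
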