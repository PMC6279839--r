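#' Plot the per-state emission distributions of a fit
#'
#' Poisson probability mass functions of each state, faceted, over a
#' count range covering the bulk of every state's mass.
#'
#' @param object A `poisson_hmm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poisson_hmm <- function(object, ...) {
  lam <- object$params$lambda
  pmf <- purrr::map_dfr(seq_along(lam), function(j) {
    ks <- qpois(0.001, lam[j]):qpois(0.999, lam[j])
    tibble::tibble(
      state = paste0("z", j, " (λ = ", signif(lam[j], 3), ")"),
      count = ks,
      prob = dpois(ks, lam[j])
    )
  })
  ggplot2::ggplot(pmf, ggplot2::aes(x = .data$count, y = .data$prob)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::facet_wrap(~state, scales = "free") +
    ggplot2::labs(
      x = "asynchrony events per window", y = "probability",
      title = "State-conditional emission distributions"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a transition matrix
#'
#' @param params An [hmm_params] object (or a `poisson_hmm` fit).
#' @param digits Digits for the cell labels.
#' @return A ggplot object.
#' @export
plot_transition_matrix <- function(params, digits = 2) {
  if (inherits(params, "poisson_hmm")) params <- params$params
  K <- params$K
  d <- tidyr::expand_grid(from = seq_len(K), to = seq_len(K)) |>
    dplyr::mutate(prob = params$A[cbind(.data$from, .data$to)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from, fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$prob, digits))) +
    ggplot2::scale_y_reverse(breaks = seq_len(K), labels = paste0("z", seq_len(K))) +
    ggplot2::scale_x_continuous(breaks = seq_len(K), labels = paste0("z", seq_len(K)),
                                position = "top") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "state at t + 1", y = "state at t", fill = "probability",
                  title = "Transition probabilities") +
    ggplot2::theme_minimal()
}

#' Plot a decoded count series
#'
#' Window counts coloured by the decoded (Viterbi) risk state.
#'
#' @param fit A `poisson_hmm` fit.
#' @param patient_id Which sequence to show; default the first.
#' @return A ggplot object.
#' @export
plot_decoded_series <- function(fit, patient_id = NULL) {
  aug <- augment(fit)
  if (is.null(patient_id)) patient_id <- aug$patient_id[1]
  d <- dplyr::filter(aug, .data$patient_id == !!patient_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$count)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$.state))) +
    ggplot2::labs(
      x = "window", y = "asynchrony events", colour = "state",
      title = paste("Decoded asynchrony count series -", patient_id)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hmm_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_fold,
    cols = c("rmse_hmm", "rmse_base"),
    names_to = "model", values_to = "rmse", names_prefix = "rmse_"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$rmse)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(x = NULL, y = "per-fold RMSE",
                  title = "Cross-validated one-step-ahead forecast error") +
    ggplot2::theme_minimal()
}
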