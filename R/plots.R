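# ggplot2 views of fitted objects.

#' @describeIn solve_maxent Bar chart of the fitted exit-age pmf with the
#'   survival curve overlaid.
#' @param object An `hl_maxent` object.
#' @export
autoplot.hl_maxent <- function(object, ...) {
  pmf <- object$pmf
  ggplot2::ggplot(pmf, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$phloss), fill = "steelblue",
                      alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lhealth * max(pmf$phloss)),
                       colour = "grey30", linewidth = 0.4) +
    ggplot2::scale_y_continuous(
      "probability of health loss",
      sec.axis = ggplot2::sec_axis(~ . / max(pmf$phloss),
                                   name = "probability still healthy")) +
    ggplot2::labs(x = "age", title = sprintf(
      "Exit-age distribution (mode %d, p = %.3f)",
      object$mode_age, object$mode_prob)) +
    ggplot2::theme_minimal()
}

#' Overlay two exit-age distributions
#'
#' @param pmf1,pmf2 Pmf tibbles (or `hl_maxent` fits); labelled via
#'   `labels`.
#' @param labels Length-2 character labels (default `c("pop 1", "pop 2")`).
#' @return A ggplot object.
#' @export
plot_comparison <- function(pmf1, pmf2, labels = c("pop 1", "pop 2")) {
  get_pmf <- function(x) if (inherits(x, "hl_maxent")) x$pmf else tibble::as_tibble(x)
  d <- dplyr::bind_rows(
    dplyr::mutate(get_pmf(pmf1), population = labels[1]),
    dplyr::mutate(get_pmf(pmf2), population = labels[2]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$phloss,
                                  fill = .data$population)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "age", y = "probability of health loss") +
    ggplot2::theme_minimal()
}

#' @describeIn bootstrap_pipeline Interval plot of the bootstrap CIs for
#'   the scalar summaries.
#' @param object An `hl_bootstrap` object.
#' @export
autoplot.hl_bootstrap <- function(object, ...) {
  ci <- tidy(object)
  ci <- ci[is.na(match(ci$quantity, "phloss")), , drop = FALSE]
  grp_cols <- intersect(object$by, names(ci))
  ci$group <- if (length(grp_cols) > 0) {
    do.call(paste, c(ci[grp_cols], sep = "/"))
  } else "all"
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$group, y = .data$replicate_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "bootstrap replicate mean (95% CI)") +
    ggplot2::theme_minimal()
}
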