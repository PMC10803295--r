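#' @export
autoplot.psychometric_fit <- function(object, n_curve = 200, ...) {
  agg <- object$data
  xs <- seq(min(agg$x), max(agg$x), length.out = n_curve)
  curve <- tibble::tibble(x = xs, p = predict(object, xs))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$k / .data$n,
                                     size = .data$n), alpha = 0.6) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p)) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "stimulus strength", y = "P(choose R)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.history_psychometric <- function(object, n_curve = 200, ...) {
  layer_of <- function(fit, lab) {
    agg <- fit$data
    xs <- seq(min(agg$x), max(agg$x), length.out = n_curve)
    list(points = dplyr::mutate(agg, condition = lab),
         curve = tibble::tibble(x = xs, p = predict(fit, xs),
                                condition = lab))
  }
  pieces <- list(layer_of(object$prev_rw, "prev R win"),
                 layer_of(object$prev_lw, "prev L win"))
  pts <- dplyr::bind_rows(lapply(pieces, `[[`, "points"))
  cvs <- dplyr::bind_rows(lapply(pieces, `[[`, "curve"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, colour = .data$condition)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$k / .data$n), alpha = 0.5) +
    ggplot2::geom_line(data = cvs, ggplot2::aes(y = .data$p)) +
    ggplot2::scale_colour_manual(values = c("prev R win" = "#4477aa",
                                            "prev L win" = "#cc6688")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "stimulus strength", y = "P(choose R)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Reaction-time signatures of history-dependent initial states
#'
#' Summarizes a reaction-time session into the three diagnostic patterns
#' that initial-state variability produces: (i) error trials faster than
#' correct trials, (ii) after a rightward win, faster responses when the
#' stimulus favors the right (and conversely after leftward wins), and
#' (iii) a repetition bias (same choice as the previous win) concentrated
#' in the fastest reaction-time quantiles.
#'
#' @param tbl A reaction-time session tibble.
#' @param n_quantiles Number of RT bins for the repetition panel.
#' @return A list of class `rt_signatures` with `outcome_rt`,
#'   `consistency_rt`, and `repetition_by_rt` tibbles.
#' @export
rt_signatures <- function(tbl, n_quantiles = 5) {
  valid <- tbl[!tbl$violation & !is.na(tbl$rt_s), , drop = FALSE]
  outcome_rt <- valid |>
    dplyr::group_by(outcome = .data$outcome) |>
    dplyr::summarise(mean_rt = mean(.data$rt_s), n = dplyr::n(),
                     .groups = "drop")
  pairs <- choice_outcome_pair(tbl$choice, tbl$outcome)
  prev <- rep(NA_character_, nrow(tbl))
  last <- NA_character_
  for (i in seq_len(nrow(tbl))) {
    prev[i] <- last
    if (!is.na(pairs[i])) last <- pairs[i]
  }
  stim_side <- ifelse(lengths(tbl$right_clicks) >= lengths(tbl$left_clicks),
                      "R", "L")
  keep <- !tbl$violation & !is.na(tbl$rt_s) & prev %in% c("Rw", "Lw")
  consistency_rt <- tibble::tibble(
    rt = tbl$rt_s[keep],
    consistent = (prev[keep] == "Rw" & stim_side[keep] == "R") |
      (prev[keep] == "Lw" & stim_side[keep] == "L")
  ) |>
    dplyr::group_by(consistent = .data$consistent) |>
    dplyr::summarise(mean_rt = mean(.data$rt), n = dplyr::n(),
                     .groups = "drop")
  rep_tbl <- tibble::tibble(
    rt = tbl$rt_s[keep],
    repeat_choice = tbl$choice[keep] == substr(prev[keep], 1, 1)
  )
  rep_tbl$quantile <- dplyr::ntile(rep_tbl$rt, n_quantiles)
  repetition_by_rt <- rep_tbl |>
    dplyr::group_by(quantile = .data$quantile) |>
    dplyr::summarise(p_repeat = mean(.data$repeat_choice), n = dplyr::n(),
                     .groups = "drop")
  structure(list(outcome_rt = outcome_rt, consistency_rt = consistency_rt,
                 repetition_by_rt = repetition_by_rt),
            class = "rt_signatures")
}

#' @export
autoplot.rt_signatures <- function(object, ...) {
  rep_df <- dplyr::mutate(object$repetition_by_rt,
                          quantile = factor(.data$quantile))
  ggplot2::ggplot(rep_df, ggplot2::aes(x = .data$quantile,
                                       y = .data$p_repeat, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "RT quantile (fast to slow)",
                  y = "P(repeat previous rewarded choice)") +
    ggplot2::theme_minimal()
}

#' First-passage density plot
#'
#' @param fpd Tibble from [first_passage_density()].
#' @return A ggplot showing the per-bin absorbed mass at each bound.
#' @export
plot_first_passage <- function(fpd) {
  long <- tidyr::pivot_longer(fpd, c("mass_upper", "mass_lower"),
                              names_to = "bound", values_to = "mass")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$mass,
                                     colour = .data$bound)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "absorbed mass per bin") +
    ggplot2::theme_minimal()
}
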