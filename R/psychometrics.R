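#' Fit a 4-parameter logistic psychometric function
#'
#' Maximizes the Binomial log likelihood of rightward choices as a function
#' of stimulus strength under
#' \deqn{P(R) = \kappa_0 + \kappa_1 / (1 + e^{-b (x - x_0)}),}
#' with `kappa0, kappa1` constrained to `[0, 1]`. `kappa0` is the left
#' asymptote (left lapse rate), `1 - (kappa0 + kappa1)` the right lapse
#' rate, `x0` the threshold (inflection-point abscissa) and `b` the
#' sensitivity. Lapse rates are always read from these fits, never from
#' error rates at extreme stimulus strengths. Optimization is box-
#' constrained (L-BFGS-B) from several deterministic starts, including a
#' logistic-regression warm start; the best optimum is kept. Degenerate
#' data (all one choice) produce a boundary fit, flagged but returned.
#'
#' @param stimulus Numeric stimulus strength per trial (at least 4 distinct
#'   values).
#' @param choice_right Logical (or 0/1): rightward choice per trial.
#' @param n_starts Number of optimization starts.
#' @return An object of class `psychometric_fit`: list with `params`
#'   (named vector `kappa0, kappa1, x0, b`), `loglik`, `n`, `data`
#'   (aggregated counts), `boundary` flag and `convergence` code.
#' @export
fit_psychometric <- function(stimulus, choice_right, n_starts = 5) {
  y <- as.logical(choice_right)
  keep <- !is.na(stimulus) & !is.na(y)
  stimulus <- stimulus[keep]
  y <- y[keep]
  ux <- sort(unique(stimulus))
  if (length(ux) < 4) abort("need at least 4 distinct stimulus strengths")
  agg <- tibble::tibble(x = stimulus, y = as.numeric(y)) |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$y), .groups = "drop")
  xr <- diff(range(agg$x))
  nll <- function(par) {
    p <- par[1] + par[2] * stats::plogis(par[4] * (agg$x - par[3]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }
  lower <- c(0, 0, min(agg$x) - xr, 1e-4)
  upper <- c(1, 1, max(agg$x) + xr, 1e3)
  # deterministic starts: glm warm start plus lapse-rate/threshold spread
  glm_b <- tryCatch({
    fit <- stats::glm(cbind(agg$k, agg$n - agg$k) ~ agg$x, family = stats::binomial())
    cf <- stats::coef(fit)
    c(x0 = unname(-cf[1] / cf[2]), b = unname(cf[2]))
  }, error = function(e) c(x0 = 0, b = 1))
  b0 <- min(max(abs(glm_b["b"]), 1e-3), 1e2)
  x00 <- min(max(glm_b["x0"], lower[3]), upper[3])
  starts <- list(
    c(0.01, 0.98, x00, b0),
    c(0.05, 0.90, x00, b0),
    c(0.10, 0.80, 0, b0 / 2),
    c(0.01, 0.98, x00, b0 * 2),
    c(0.20, 0.60, x00, b0)
  )[seq_len(max(1, min(n_starts, 5)))]
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("psychometric optimization failed from all starts")
  par <- setNames(best$par, c("kappa0", "kappa1", "x0", "b"))
  tol <- 1e-5
  boundary <- par["kappa0"] <= tol || par["kappa0"] >= 1 - tol ||
    par["kappa1"] <= tol || par["kappa1"] >= 1 - tol ||
    all(agg$k == agg$n) || all(agg$k == 0)
  structure(list(params = par, loglik = -best$value, n = sum(agg$n),
                 data = agg, boundary = unname(boundary),
                 convergence = best$convergence),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("4-parameter logistic psychometric fit (", x$n, " trials)\n", sep = "")
  print(round(x$params, 4))
  cat("left lapse =", round(x$params[["kappa0"]], 4),
      "; right lapse =", round(1 - x$params[["kappa0"]] - x$params[["kappa1"]], 4),
      if (x$boundary) "; boundary fit" else "", "\n")
  invisible(x)
}

#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  p <- object$params
  unname(p["kappa0"] + p["kappa1"] * stats::plogis(p["b"] * (x - p["x0"])))
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, boundary = x$boundary,
                 convergence = x$convergence)
}

#' Subset trials by previous-trial history
#'
#' Returns the non-violation trials whose most recent non-violation
#' predecessor matches the conditioner: previous rightward win, leftward
#' win, any win, or any loss. Trials with no valid predecessor are dropped.
#' The `prev_Rw` and `prev_Lw` subsets (together with the loss-predecessor
#' trials) partition the valid trials from the second onward.
#'
#' @param tbl Session tibble ordered by `trial_index`.
#' @param conditioner One of `"prev_Rw"`, `"prev_Lw"`, `"prev_win"`,
#'   `"prev_loss"`.
#' @return The matching subset of `tbl`.
#' @export
condition_on_history <- function(tbl, conditioner = c("prev_Rw", "prev_Lw",
                                                      "prev_win", "prev_loss")) {
  conditioner <- match.arg(conditioner)
  pairs <- choice_outcome_pair(tbl$choice, tbl$outcome)
  # most recent non-violation pair strictly before each trial
  last_valid <- rep(NA_character_, length(pairs))
  prev <- NA_character_
  for (i in seq_along(pairs)) {
    last_valid[i] <- prev
    if (!is.na(pairs[i])) prev <- pairs[i]
  }
  match_ok <- switch(conditioner,
    prev_Rw = last_valid == "Rw",
    prev_Lw = last_valid == "Lw",
    prev_win = last_valid %in% c("Rw", "Lw"),
    prev_loss = last_valid %in% c("Rl", "Ll")
  )
  keep <- !is.na(match_ok) & match_ok & !tbl$violation
  tbl[keep, , drop = FALSE]
}

#' Stimulus strength of each trial
#'
#' The signed stimulus value used as the psychometric x-axis: the click
#' count difference `#R - #L` (natural for the fixed-duration, count-
#' rewarded task) or the smoothed log count ratio
#' `log((#R + 1/2) / (#L + 1/2))` (a rate-ratio proxy for the reaction-time
#' task, where durations vary across trials).
#'
#' @param tbl Session tibble.
#' @param axis `"click_diff"` or `"log_click_ratio"`.
#' @return Numeric vector, one value per trial.
#' @export
stimulus_strength <- function(tbl, axis = c("click_diff", "log_click_ratio")) {
  axis <- match.arg(axis)
  nr <- lengths(tbl$right_clicks)
  nl <- lengths(tbl$left_clicks)
  switch(axis,
         click_diff = nr - nl,
         log_click_ratio = log((nr + 0.5) / (nl + 0.5)))
}

#' History modulation of psychometric parameters
#'
#' Summarizes how trial history shifts the psychometric function, from
#' separate fits to choices following rightward wins and leftward wins.
#' The threshold modulation is `x0^Rw - x0^Lw`; the lapse-rate modulation
#' adds the shifts of both asymptotes,
#' `2 (kappa0^Rw - kappa0^Lw) + (kappa1^Rw - kappa1^Lw)`. With a win-stay
#' agent the threshold modulation is negative (the curve shifts toward the
#' previously rewarded side) while the lapse modulation is positive.
#'
#' @param params_rw,params_lw Named parameter vectors (or
#'   `psychometric_fit` objects) from the post-rightward-win and
#'   post-leftward-win fits.
#' @return A tibble with columns `threshold_mod` and `lapse_mod`.
#' @export
modulation_metrics <- function(params_rw, params_lw) {
  pr <- if (inherits(params_rw, "psychometric_fit")) params_rw$params else params_rw
  pl <- if (inherits(params_lw, "psychometric_fit")) params_lw$params else params_lw
  tibble::tibble(
    threshold_mod = unname(pr["x0"] - pl["x0"]),
    lapse_mod = unname(2 * (pr["kappa0"] - pl["kappa0"]) +
                         (pr["kappa1"] - pl["kappa1"]))
  )
}

#' Percentile bootstrap confidence intervals for a fit statistic
#'
#' Resamples trials (rows) with replacement, applies `fit_fun` to each
#' resample, and returns percentile intervals for every statistic the
#' function reports. Deterministic given `seed`.
#'
#' @param fit_fun Function mapping a session tibble to a named numeric
#'   vector of statistics.
#' @param tbl Session tibble (rows are resampled).
#' @param n_boot Number of bootstrap replicates (>= 200 recommended).
#' @param seed Integer seed.
#' @param level Coverage level (default 0.95).
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`. The point estimate is `fit_fun` applied to the original
#'   table, and always lies within the interval columns' range by
#'   construction of the percentile method on the resamples.
#' @export
bootstrap_ci <- function(fit_fun, tbl, n_boot = 200, seed = 1, level = 0.95) {
  est <- fit_fun(tbl)
  with_local_seed(seed, {
    reps <- matrix(NA_real_, nrow = n_boot, ncol = length(est))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(tbl), replace = TRUE)
      r <- tryCatch(fit_fun(tbl[idx, , drop = FALSE]),
                    error = function(e) rep(NA_real_, length(est)))
      reps[b, ] <- r
    }
    alpha <- (1 - level) / 2
    tibble::tibble(
      term = names(est),
      estimate = unname(est),
      conf.low = apply(reps, 2, quantile, probs = alpha, na.rm = TRUE),
      conf.high = apply(reps, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
    )
  })
}

#' History-conditioned psychometric analysis of a session
#'
#' Convenience wrapper: computes the stimulus axis, fits the pooled
#' psychometric curve and the post-rightward-win / post-leftward-win
#' conditioned curves, and summarizes their modulation.
#'
#' @param tbl Session tibble.
#' @param axis Stimulus axis passed to [stimulus_strength()].
#' @param n_starts Starts for each logistic fit.
#' @return A list of class `history_psychometric` with elements `pooled`,
#'   `prev_rw`, `prev_lw` (fits) and `modulation`.
#' @export
history_psychometric <- function(tbl, axis = c("click_diff",
                                               "log_click_ratio"),
                                 n_starts = 5) {
  axis <- match.arg(axis)
  valid <- tbl[!tbl$violation, , drop = FALSE]
  pooled <- fit_psychometric(stimulus_strength(valid, axis),
                             valid$choice == "R", n_starts)
  sub_rw <- condition_on_history(tbl, "prev_Rw")
  sub_lw <- condition_on_history(tbl, "prev_Lw")
  fit_rw <- fit_psychometric(stimulus_strength(sub_rw, axis),
                             sub_rw$choice == "R", n_starts)
  fit_lw <- fit_psychometric(stimulus_strength(sub_lw, axis),
                             sub_lw$choice == "R", n_starts)
  structure(list(pooled = pooled, prev_rw = fit_rw, prev_lw = fit_lw,
                 modulation = modulation_metrics(fit_rw, fit_lw),
                 axis = axis),
            class = "history_psychometric")
}
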