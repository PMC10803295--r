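#' Assemble and validate a session table
#'
#' A session table is a tibble with one row per trial of a single behavioral
#' session: click trains on both sides (list-columns of click times, in
#' seconds from stimulus onset), the stimulus duration, the subject's choice
#' and outcome, an optional reaction time, and a violation flag (broken
#' fixation: no choice, no outcome). `session_table()` builds one from
#' vectors; `validate_session_table()` checks the invariants and errors with
#' an informative message on the first breach.
#'
#' @param session_id Character scalar identifying the session.
#' @param duration_s Stimulus duration per trial (seconds, > 0).
#' @param left_clicks,right_clicks Lists of numeric vectors: click times in
#'   seconds, ascending, within `[0, duration_s]`.
#' @param choice Character, `"L"`, `"R"`, or `NA` (violation).
#' @param outcome Character, `"win"`, `"loss"`, or `NA` (violation).
#' @param rt_s Reaction time in seconds (> 0) or `NA`; present only for
#'   reaction-time sessions.
#' @param violation Logical; `TRUE` iff choice and outcome are absent.
#' @param trial_index Integer trial numbers, strictly increasing; defaults
#'   to `1:n`.
#' @return A tibble of class `tbl_df` with the columns above.
#' @examples
#' tbl <- session_table(
#'   session_id = "demo", duration_s = rep(0.5, 2),
#'   left_clicks = list(c(0.1, 0.3), 0.2), right_clicks = list(0.05, numeric(0)),
#'   choice = c("L", "R"), outcome = c("win", "loss"),
#'   rt_s = c(NA, NA), violation = c(FALSE, FALSE)
#' )
#' validate_session_table(tbl)
#' @export
session_table <- function(session_id, duration_s, left_clicks, right_clicks,
                          choice, outcome, rt_s = NA_real_, violation = FALSE,
                          trial_index = NULL) {
  n <- length(duration_s)
  tbl <- tibble::tibble(
    session_id = rep_len(as.character(session_id), n),
    trial_index = if (is.null(trial_index)) seq_len(n) else as.integer(trial_index),
    duration_s = as.numeric(duration_s),
    left_clicks = as.list(left_clicks),
    right_clicks = as.list(right_clicks),
    choice = as.character(choice),
    outcome = as.character(outcome),
    rt_s = rep_len(as.numeric(rt_s), n),
    violation = rep_len(as.logical(violation), n)
  )
  validate_session_table(tbl)
}

#' @rdname session_table
#' @param tbl A session table tibble.
#' @param max_rt Largest admissible reaction time in seconds.
#' @export
validate_session_table <- function(tbl, max_rt = Inf) {
  need <- c("session_id", "trial_index", "duration_s", "left_clicks",
            "right_clicks", "choice", "outcome", "rt_s", "violation")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("session table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(unique(tbl$session_id)) > 1) {
    abort("session table must contain a single session_id")
  }
  if (nrow(tbl) > 1 && any(diff(tbl$trial_index) <= 0)) {
    abort("trial_index must be strictly increasing")
  }
  if (any(!is.na(tbl$duration_s) & tbl$duration_s <= 0)) {
    abort("duration_s must be positive")
  }
  bad_choice <- !tbl$choice %in% c("L", "R") & !is.na(tbl$choice)
  if (any(bad_choice)) {
    abort(sprintf("invalid choice in row %d", which(bad_choice)[1]))
  }
  bad_outcome <- !tbl$outcome %in% c("win", "loss") & !is.na(tbl$outcome)
  if (any(bad_outcome)) {
    abort(sprintf("invalid outcome in row %d", which(bad_outcome)[1]))
  }
  # violation <=> no choice <=> no outcome
  viol_ok <- (tbl$violation & is.na(tbl$choice) & is.na(tbl$outcome)) |
    (!tbl$violation & !is.na(tbl$choice) & !is.na(tbl$outcome))
  if (any(!viol_ok)) {
    abort(sprintf(
      "row %d violates: violation = TRUE <=> choice is NA <=> outcome is NA",
      which(!viol_ok)[1]
    ))
  }
  if (any(!is.na(tbl$rt_s) & tbl$rt_s <= 0)) {
    abort("rt_s must be positive where present")
  }
  if (any(!is.na(tbl$rt_s) & tbl$rt_s > max_rt)) {
    abort(sprintf("rt_s exceeds the configured maximum (%g s)", max_rt))
  }
  for (i in seq_len(nrow(tbl))) {
    for (side in c("left_clicks", "right_clicks")) {
      ck <- tbl[[side]][[i]]
      if (length(ck) == 0) next
      if (is.unsorted(ck) || any(ck < 0) || any(ck > tbl$duration_s[i] + 1e-9)) {
        abort(sprintf(
          "row %d: %s must be ascending within [0, duration_s]", i, side
        ))
      }
    }
  }
  tbl
}

#' Read or write a session table
#'
#' Sessions are stored as delimited text (CSV, or TSV for files ending in
#' `.tsv`) with one row per trial and click trains encoded as
#' semicolon-delimited second offsets, e.g. `"0.012;0.104;0.471"`. Columns:
#' `session_id, trial_index, duration_s, left_clicks, right_clicks, choice
#' {L,R,NA}, outcome {win,loss,NA}, rt_s, violation {0,1}`.
#'
#' @param path File to read or write.
#' @param task_mode `"fixed_duration"` or `"reaction_time"`; reaction times
#'   are only admitted in reaction-time mode.
#' @param max_rt Largest admissible reaction time (seconds).
#' @return `read_session_table()` returns a validated session tibble;
#'   `write_session_table()` returns `path` invisibly. Reading a written
#'   table reproduces it (round-trip identity).
#' @export
read_session_table <- function(path, task_mode = c("fixed_duration", "reaction_time"),
                               max_rt = Inf) {
  task_mode <- match.arg(task_mode)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      session_id = readr::col_character(),
      trial_index = readr::col_integer(),
      duration_s = readr::col_double(),
      left_clicks = readr::col_character(),
      right_clicks = readr::col_character(),
      choice = readr::col_character(),
      outcome = readr::col_character(),
      rt_s = readr::col_double(),
      violation = readr::col_integer()
    )
  )
  parse_clicks <- function(strings, col) {
    purrr::imap(strings, function(s, i) {
      if (is.na(s) || s == "") return(numeric(0))
      out <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
      if (anyNA(out)) {
        abort(sprintf("malformed %s in row %d: %s", col, i, s))
      }
      out
    })
  }
  tbl <- raw |>
    dplyr::mutate(
      left_clicks = parse_clicks(.data$left_clicks, "left_clicks"),
      right_clicks = parse_clicks(.data$right_clicks, "right_clicks"),
      violation = as.logical(.data$violation)
    )
  if (task_mode == "fixed_duration" && any(!is.na(tbl$rt_s))) {
    abort("rt_s present in a fixed-duration session")
  }
  attr(tbl, "task_mode") <- task_mode
  validate_session_table(tbl, max_rt = max_rt)
}

#' @rdname read_session_table
#' @param tbl A validated session tibble.
#' @export
write_session_table <- function(tbl, path) {
  validate_session_table(tbl)
  fmt_clicks <- function(lst) {
    vapply(lst, function(x) paste(formatC(x, format = "fg", digits = 15),
                                  collapse = ";"), character(1))
  }
  out <- tbl |>
    dplyr::mutate(
      left_clicks = fmt_clicks(.data$left_clicks),
      right_clicks = fmt_clicks(.data$right_clicks),
      violation = as.integer(.data$violation)
    )
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Session-level quality filters
#'
#' Applies the session inclusion rules used for the rat datasets: sessions
#' with fewer than `min_trials` trials, or with accuracy below
#' `min_side_accuracy` for either side, are rejected; in the reaction-time
#' task the first `omit_first` trials of a session are dropped before any
#' other check (performance early in a session is systematically worse).
#' Accuracy is computed per *correct* side over non-violation trials: among
#' trials whose rewarded side was L (resp. R), the fraction won. Set
#' `accuracy_by = "chosen_side"` for the alternative reading (fraction of
#' wins among trials where the subject chose that side).
#'
#' Rejection is a value, not an error: a rejected session is returned as an
#' object of class `session_rejection` carrying the reason. The function is
#' idempotent: a table it has already trimmed passes through unchanged.
#'
#' @param tbl Session tibble.
#' @param min_trials Minimum trial count (default 300).
#' @param min_side_accuracy Minimum per-side accuracy (default 0.60).
#' @param omit_first Number of leading trials to drop; defaults to 50 for
#'   reaction-time sessions and 0 otherwise.
#' @param task_mode Task mode, used only for the `omit_first` default.
#' @param accuracy_by `"correct_side"` (default) or `"chosen_side"`.
#' @return The trimmed session tibble, or a `session_rejection`.
#' @seealso [is_rejected()]
#' @export
apply_session_filters <- function(tbl, min_trials = 300, min_side_accuracy = 0.60,
                                  omit_first = NULL,
                                  task_mode = c("fixed_duration", "reaction_time"),
                                  accuracy_by = c("correct_side", "chosen_side")) {
  task_mode <- match.arg(task_mode)
  accuracy_by <- match.arg(accuracy_by)
  if (isTRUE(attr(tbl, "qc_applied"))) return(tbl)
  if (is.null(omit_first)) {
    omit_first <- if (task_mode == "reaction_time") 50L else 0L
  }
  if (omit_first > 0 && nrow(tbl) > omit_first) {
    tbl <- tbl[-seq_len(omit_first), , drop = FALSE]
  } else if (omit_first >= nrow(tbl)) {
    return(reject_session("min_trials",
                          sprintf("%d trials, all omitted", nrow(tbl))))
  }
  if (nrow(tbl) < min_trials) {
    return(reject_session("min_trials",
                          sprintf("%d < %d trials", nrow(tbl), min_trials)))
  }
  valid <- tbl[!tbl$violation, , drop = FALSE]
  side_col <- if (accuracy_by == "correct_side") {
    correct_side(valid$choice, valid$outcome)
  } else {
    valid$choice
  }
  for (s in c("L", "R")) {
    idx <- which(side_col == s)
    if (length(idx) == 0) next
    acc <- mean(valid$outcome[idx] == "win")
    if (acc < min_side_accuracy) {
      return(reject_session(
        "min_side_accuracy",
        sprintf("accuracy %.3f < %.2f on %s-%s trials", acc,
                min_side_accuracy, s,
                if (accuracy_by == "correct_side") "correct" else "chosen")
      ))
    }
  }
  attr(tbl, "qc_applied") <- TRUE
  tbl
}

reject_session <- function(reason, detail) {
  structure(list(reason = reason, detail = detail),
            class = "session_rejection")
}

#' @rdname apply_session_filters
#' @param x Object returned by `apply_session_filters()`.
#' @export
is_rejected <- function(x) inherits(x, "session_rejection")

#' @export
print.session_rejection <- function(x, ...) {
  cat("session rejected [", x$reason, "]: ", x$detail, "\n", sep = "")
  invisible(x)
}

# Rewarded side implied by choice and outcome (NA on violations).
correct_side <- function(choice, outcome) {
  dplyr::case_when(
    outcome == "win" ~ choice,
    outcome == "loss" & choice == "L" ~ "R",
    outcome == "loss" & choice == "R" ~ "L",
    TRUE ~ NA_character_
  )
}

# Choice-outcome pair labels ("Rw", "Lw", "Rl", "Ll"; NA on violations).
choice_outcome_pair <- function(choice, outcome) {
  out <- rep(NA_character_, length(choice))
  ok <- !is.na(choice) & !is.na(outcome)
  out[ok] <- paste0(choice[ok], ifelse(outcome[ok] == "win", "w", "l"))
  out
}
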