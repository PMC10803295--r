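#' Pipeline orchestration
#'
#' Thin, config-driven wrappers tying the package's stages together for
#' scripted use: simulate a synthetic session to disk, fit a model variant
#' to a session file, and produce a psychometric/modulation report.
#' Configurations are YAML files (or equivalent named lists); outputs are
#' the same CSV session format read by [read_session_table()], a JSON
#' ground-truth sidecar the fitting stage must not read, and JSON fit and
#' report files. Identical config and seed reproduce identical outputs.
#'
#' Config keys for `pipeline_simulate()`: `task` (fields of
#' [task_config()]), optional `agent` (named parameter values as in
#' [make_cohort()] ranges, scalar), `seed`.
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory (created if missing).
#' @return `pipeline_simulate()`: invisible named list of file paths.
#' @name pipeline
NULL

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  config
}

require_keys <- function(config, keys, where = "config") {
  missing <- setdiff(keys, names(config))
  if (length(missing) > 0) {
    abort(paste0("missing required ", where, " key: ",
                 paste(missing, collapse = ", ")))
  }
}

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  config <- read_config(config)
  require_keys(config, c("task", "seed"))
  require_keys(config$task, "n_trials", where = "task")
  cfg <- do.call(task_config, config$task)
  agent <- default_agent(cfg)
  if (!is.null(config$agent)) {
    agent <- modify_agent(agent, unlist(config$agent))
  }
  sim <- simulate_agent_session(cfg, agent, seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  session_path <- file.path(out_dir, "session.csv")
  truth_path <- file.path(out_dir, "truth.json")
  write_session_table(sim$session, session_path)
  jsonlite::write_json(
    list(truth = sim$truth,
         agent = list(history = lapply(agent$history[c("eta", "beta")],
                                       as.list),
                      acc = unclass(agent$acc),
                      lapse = unclass(agent$lapse)[c("kappa", "rho",
                                                     "variant")],
                      ndt = if (!is.null(agent$ndt)) unclass(agent$ndt)),
         meta = list(seed = config$seed, task_mode = cfg$task_mode)),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(session = session_path, truth = truth_path))
}

#' @rdname pipeline
#' @param data Path to a session CSV.
#' @param model One of `"hist_motor"`, `"nohist_motor"`,
#'   `"hist_inattention"`, `"hist_hybrid"`.
#' @param out Output path of the fit JSON.
#' @param seed Integer seed for the optimizer.
#' @param grid An [fp_grid()] used for fitting.
#' @export
pipeline_fit <- function(config = list(), data, model = "hist_motor",
                         out = NULL, seed = 1, grid = fp_grid(61, 0.005)) {
  config <- read_config(config)
  task_mode <- config$task_mode %||% "fixed_duration"
  tbl <- read_session_table(data, task_mode)
  qc <- apply_session_filters(tbl,
                              min_trials = config$min_trials %||% 300,
                              task_mode = task_mode)
  if (is_rejected(qc)) abort(paste0("session failed QC: ", qc$reason))
  spec <- model_from_label(model, task_mode, config)
  fit <- fit_mle(qc, spec, grid = grid, seed = seed,
                 n_starts = config$n_starts %||% 5)
  if (!is.null(out)) write_fit_json(fit, out)
  fit
}

model_from_label <- function(model, task_mode, config = list()) {
  known <- c("hist_motor", "nohist_motor", "hist_inattention", "hist_hybrid")
  if (!model %in% known) {
    abort(paste0("unknown model label: ", model, " (expected one of ",
                 paste(known, collapse = ", "), ")"))
  }
  with_hist <- grepl("^hist", model)
  variant <- sub("^(no)?hist_", "", model)
  free <- config$free %||% {
    base <- c("bound", "kappa", "rho")
    if (with_hist) c("eta_Rw", "eta_Lw", "beta_w", base) else base
  }
  model_spec(with_hist = with_hist, lapse_variant = variant,
             task_mode = task_mode, free = free,
             fixed = unlist(config$fixed %||% list()), label = model)
}

#' Serialize or load a fit
#'
#' Fit results are stored as JSON with blocks `history`, `accumulator`,
#' `lapse`, `ndt`, and `meta` (seed, optimizer diagnostics, grid
#' settings, log likelihood, per-trial BIC).
#'
#' @param fit A `histddm_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  p <- as.list(fit$best_params)
  out <- list(
    model = fit$spec$label,
    history = list(eta_Rw = p$eta_Rw, eta_Lw = p$eta_Lw,
                   eta_loss = p$eta_loss, beta_win = p$beta_w,
                   beta_loss = p$beta_loss),
    accumulator = p[c("lambda", "sigma2_a", "sigma2_s", "bound", "phi",
                      "tau_phi", "bias", "drift")],
    lapse = c(p[c("kappa", "rho")],
              if (fit$spec$lapse_variant == "hybrid")
                list(match_slope = p$match_slope),
              list(variant = fit$spec$lapse_variant)),
    ndt = if (fit$spec$task_mode == "reaction_time")
      p[c("omega_L", "omega_R", "nu_L", "nu_R", "alpha", "gamma_o")],
    meta = list(seed = fit$seed, n_trials = fit$n_trials, k = fit$k,
                loglik = fit$loglik, per_trial_bic = fit$per_trial_bic,
                grid = unclass(fit$grid),
                diagnostics = fit$diagnostics)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline
#' @param session Path to the session CSV the fits describe.
#' @param fits List of `histddm_fit` objects (or paths written by
#'   [write_fit_json()] are not re-loaded; pass fit objects).
#' @param task_mode Task mode of the session.
#' @export
pipeline_report <- function(session, fits = list(), out_dir,
                            task_mode = "fixed_duration") {
  tbl <- read_session_table(session, task_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  axis <- if (task_mode == "reaction_time") "log_click_ratio" else
    "click_diff"
  hp <- history_psychometric(tbl, axis = axis)
  report <- list(
    pooled = as.list(hp$pooled$params),
    prev_rw = as.list(hp$prev_rw$params),
    prev_lw = as.list(hp$prev_lw$params),
    modulation = as.list(hp$modulation),
    models = lapply(fits, function(f) list(label = f$spec$label,
                                           per_trial_bic = f$per_trial_bic,
                                           loglik = f$loglik))
  )
  if (task_mode == "reaction_time") {
    sig <- rt_signatures(tbl)
    report$rt_signatures <- lapply(unclass(sig), function(x) x)
    ggplot2::ggsave(file.path(out_dir, "rt_signatures.pdf"), autoplot(sig),
                    width = 5, height = 4)
  }
  ggplot2::ggsave(file.path(out_dir, "psychometric.pdf"), autoplot(hp),
                  width = 5, height = 4)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(json_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
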