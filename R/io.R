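#' Read and write session tables
#'
#' Sessions are serialized as plain CSV with header columns `mouse_id,
#' session_id, trial, block, high_side, choice, rewarded, t_CE, t_CX,
#' t_SE, t_FL, t_SX` (times in seconds, 6 decimal places; `rewarded` as
#' 0/1; a missing first lick written as an empty field). A file may hold
#' several sessions, distinguished by (`mouse_id`, `session_id`).
#'
#' Reading validates every session with [validate_session()] and reports
#' the offending trial on failure.
#'
#' @param path CSV file path.
#' @param sessions A `session_table` or list of them (for writing).
#' @return `read_sessions()`: a named list of `session_table`s.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rewarded <- as.logical(df$rewarded)
  keys <- paste(df$mouse_id, df$session_id, sep = "_")
  out <- lapply(split(df, factor(keys, levels = unique(keys))), function(s) {
    rownames(s) <- NULL
    class(s) <- c("session_table", "data.frame")
    validate_session(s)
    s
  })
  out
}

#' @rdname read_sessions
#' @export
write_sessions <- function(sessions, path) {
  sessions <- as_session_list(sessions)
  df <- do.call(rbind, lapply(sessions, as.data.frame))
  for (col in c("t_CE", "t_CX", "t_SE", "t_FL", "t_SX"))
    df[[col]] <- sprintf("%.6f", df[[col]])
  df$t_FL[df$t_FL == "NA"] <- ""
  df$rewarded <- as.integer(df$rewarded)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write raw photometry as CSV
#'
#' Small-fixture text format: commented metadata lines (`# fs=...`,
#' `# carriers=...`) followed by a single `value` column of detector
#' samples.
#'
#' @param raw A [raw_photometry()] (for writing).
#' @param path CSV file path.
#' @return `read_photometry_csv()`: a `raw_photometry`.
#' @export
write_photometry_csv <- function(raw, path) {
  stopifnot(inherits(raw, "raw_photometry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%g", raw$fs),
               sprintf("# carriers=%s", paste(raw$carriers, collapse = ",")),
               "value"), con)
  writeLines(sprintf("%.8g", raw$samples), con)
  invisible(path)
}

#' @rdname write_photometry_csv
#' @export
read_photometry_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# fs=", "", hdr[1], fixed = TRUE))
  carriers <- as.numeric(strsplit(sub("# carriers=", "", hdr[2],
                                      fixed = TRUE), ",")[[1]])
  vals <- utils::read.csv(path, comment.char = "#")$value
  raw_photometry(vals, fs = fs, carriers = carriers)
}

#' Write an RFLR fit as JSON
#'
#' @param fit An `rflr_fit` from [fit_rflr()].
#' @param path Output path.
#' @export
write_rflr_json <- function(fit, path) {
  jsonlite::write_json(
    list(alpha = fit$params$alpha, beta = fit$params$beta,
         tau = fit$params$tau, nll = fit$nll, n_trials = fit$n_trials),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, then runs every analysis stage:
#' session summaries, transition curves with exponential fits,
#' history-conditioned switch probabilities, the RFLR fit, photometry
#' demodulation, the kernel GLM with grouped cross-validation, and the
#' variable-omission analysis. Artifacts are written as CSV/JSON under
#' `out_dir`. Deterministic under the config's seeds.
#'
#' @param config Named list; recognized entries (all optional):
#'   `spec` (a [truth_spec()]), `sessions` (path to a session CSV to use
#'   instead of simulating), `n_mice`, `sessions_per_mouse`,
#'   `rflr_epochs`, `glm_alpha`, `cv_folds`, `omission_folds`, `seed`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return List of all stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(
    list(spec = truth_spec(), n_mice = 3, sessions_per_mouse = 2,
         rflr_epochs = 100, glm_alpha = 1, cv_folds = 10,
         omission_folds = 5, seed = 1),
    config)
  if (!is.null(cfg[["sessions"]])) {
    sessions <- read_sessions(cfg[["sessions"]])
    cohort <- NULL
  } else {
    cohort <- generate_cohort(cfg$spec, cfg$n_mice, cfg$sessions_per_mouse,
                              photometry = "first")
    sessions <- cohort$sessions
  }

  summaries <- session_summaries(sessions)
  curves <- list(p_high = p_high_port_curve(sessions),
                 p_switch = p_switch_curve(sessions))
  tau <- fit_tau(curves$p_high)
  cond <- conditional_switch(sessions)
  rflr <- fit_rflr(sessions, epochs = cfg$rflr_epochs, seed = cfg$seed)

  glm_res <- NULL
  if (!is.null(cohort) && length(cohort$photometry)) {
    designs <- lapply(cohort$photometry, function(ph) {
      sig <- demodulate(ph$raw, cohort$spec$carriers[["signal"]],
                        detrend_raw = TRUE)
      pr <- build_predictors(cohort$sessions[[ph$session_key]], sig,
                             hemisphere = cohort$spec$hemisphere)
      build_design(pr, sig)
    })
    design <- stack_designs(designs)
    glm_res <- list(fit = fit_ridge(design, alpha = cfg$glm_alpha),
                    cv = cross_validate(design, alpha = cfg$glm_alpha,
                                        n_folds = cfg$cv_folds,
                                        seed = cfg$seed),
                    omission = omission_analysis(design,
                                                 n_folds = cfg$omission_folds,
                                                 alpha = cfg$glm_alpha,
                                                 seed = cfg$seed))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sessions(sessions, file.path(out_dir, "sessions.csv"))
    utils::write.csv(summaries, file.path(out_dir, "session_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(curves$p_high, file.path(out_dir, "p_high_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(curves$p_switch, file.path(out_dir, "p_switch_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(cond, file.path(out_dir, "conditional_switch.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(tau = tau$tau, asymptote = tau$asymptote,
                              amplitude = tau$amplitude),
                         file.path(out_dir, "tau_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    write_rflr_json(rflr, file.path(out_dir, "rflr_params.json"))
    if (!is.null(glm_res)) {
      km <- data.frame(lag_s = glm_res$fit$lag_s, glm_res$fit$kernels,
                       check.names = FALSE)
      utils::write.csv(km, file.path(out_dir, "glm_kernels.csv"),
                       row.names = FALSE)
      utils::write.csv(glm_res$cv, file.path(out_dir, "glm_cv.csv"),
                       row.names = FALSE)
      utils::write.csv(glm_res$omission, file.path(out_dir, "glm_omission.csv"),
                       row.names = FALSE)
    }
  }
  list(sessions = sessions, summaries = summaries, curves = curves,
       tau = tau, conditional_switch = cond, rflr = rflr, glm = glm_res)
}
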