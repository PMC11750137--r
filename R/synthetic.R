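#' Ground-truth specification for synthetic datasets
#'
#' Bundles every parameter of the synthetic behavior + photometry
#' generator so that a whole cohort is reproducible from `(spec, seed)`
#' and every downstream estimate can be compared against known truth.
#'
#' Kernels are difference-of-exponentials transients
#' `amp * (exp(-t/decay) - exp(-t/rise))`, peak-normalized to `amp`
#' (z-units), with 100 ms rise and 400 ms decay by default so their
#' support fits inside the GLM's 41-lag window. Default amplitudes mimic
#' the qualitative response pattern of the recorded population: a large
#' positive transient after ipsilateral center entry, a negative
#' transient after rewarded side entry, and a positive one after
#' unrewarded side entry. Frame-level noise is AR(1) (coefficient 0.8,
#' sd 0.5 z-units), approximating the slow autocorrelation of calcium
#' signals; an exponential bleaching drift multiplies the envelope
#' before modulation to exercise the rolling z-score detrending path.
#'
#' @param agent_params [rflr_params()] of the generating agent.
#' @param task [task_config()] of each session.
#' @param latency Latency parameters, see [latency_defaults()].
#' @param kernels Named list (over [predictor_names()]) of lists with
#'   `amp`, `rise`, `decay` (seconds).
#' @param noise List with `ar` (AR(1) coefficient) and `sd` (z-units).
#' @param drift List with `amp` (relative bleach depth) and `tau_s`.
#' @param carriers Named vector, signal and control carrier Hz; the two
#'   bands must not overlap (|f1 - f2| >= 8 Hz).
#' @param modulation List with `baseline` (envelope DC), `gain`
#'   (envelope units per z-unit of fluorescence) and `control_level`.
#' @param hemisphere Recording hemisphere for direction labels.
#' @param seed Base seed for the cohort.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(agent_params = rflr_params(1.0, 2.0, 1.4),
                       task = task_config(0.9, 0.1, n_trials = 500),
                       latency = latency_defaults(),
                       kernels = default_kernels(),
                       noise = list(ar = 0.8, sd = 0.5),
                       drift = list(amp = 0.3, tau_s = 1200),
                       carriers = c(signal = 167, control = 223),
                       modulation = list(baseline = 1, gain = 0.05,
                                         control_level = 0.8),
                       hemisphere = "left",
                       seed = 7) {
  if (abs(carriers[1] - carriers[2]) < 8)
    stop("carrier bands overlap: |f1 - f2| must be >= 8 Hz", call. = FALSE)
  stopifnot(noise$sd >= 0, drift$tau_s > 0)
  structure(list(agent_params = agent_params, task = task,
                 latency = latency, kernels = kernels, noise = noise,
                 drift = drift, carriers = carriers,
                 modulation = modulation, hemisphere = hemisphere,
                 seed = seed),
            class = "truth_spec")
}

#' @rdname truth_spec
#' @param amp_scale Multiplier applied to all default amplitudes.
#' @export
default_kernels <- function(amp_scale = 1) {
  amps <- c(CE_ipsi = 1.5, CE_contra = 0.5, CX_ipsi = 0.6, CX_contra = 0.5,
            SE_ipsi = 0.6, SE_contra = 0.5, SX_ipsi = 0.5, SX_contra = 0.5,
            Rew = -1.5, Unrew = 1.2)
  lapply(amps, function(a)
    list(amp = a * amp_scale, rise = 0.1, decay = 0.4))
}

# Kernel sampled on the frame grid at lags 0..n_lag-1 (causal),
# peak-normalized to amp.
kernel_frames <- function(kern, period = 0.054, n_lag = 21) {
  t <- (seq_len(n_lag) - 1) * period
  shape <- exp(-t / kern$decay) - exp(-t / kern$rise)
  if (max(abs(shape)) < 1e-12) return(rep(0, n_lag))
  kern$amp * shape / max(abs(shape))
}

#' Truth kernels on the 41-lag axis
#'
#' Evaluates the generating kernels of a [truth_spec()] on the same
#' -T..T frame-lag axis the GLM fits, zero at negative lags.
#'
#' @param spec A `truth_spec`.
#' @param T Number of lags each way (default 20).
#' @param period Frame period in seconds.
#' @return Matrix (2T+1 lags x 10 predictors).
#' @export
truth_kernel_matrix <- function(spec, T = 20, period = 0.054) {
  K <- vapply(spec$kernels[predictor_names()], function(k)
    c(rep(0, T), kernel_frames(k, period, T + 1)), numeric(2 * T + 1))
  rownames(K) <- -T:T
  K
}

# Render one session's photometry: frame-level truth envelope, 2 kHz
# modulated samples (signal + static control carrier), and truth record.
render_photometry <- function(session, spec) {
  period <- 0.054
  fs <- 2000
  t_end <- max(session$t_SX) + 2
  nf <- ceiling(t_end / period)
  env <- numeric(nf)
  dir <- ifelse(session$choice == spec$hemisphere, "ipsi", "contra")
  add_events <- function(env, times, kern_name) {
    kf <- kernel_frames(spec$kernels[[kern_name]], period)
    times <- times[!is.na(times)]
    for (te in times) {
      k <- nearest_frame(te, period)
      idx <- k + seq_along(kf) - 1
      ok <- idx >= 1 & idx <= nf
      env[idx[ok]] <- env[idx[ok]] + kf[ok]
    }
    env
  }
  for (ev in c("CE", "CX", "SE", "SX"))
    for (d in c("ipsi", "contra")) {
      nm <- paste0(ev, "_", d)
      env <- add_events(env, session[[paste0("t_", ev)]][dir == d], nm)
    }
  t_out <- ifelse(is.na(session$t_FL), session$t_SE, session$t_FL)
  env <- add_events(env, t_out[session$rewarded], "Rew")
  env <- add_events(env, t_out[!session$rewarded], "Unrew")

  noise <- if (spec$noise$sd > 0)
    as.numeric(stats::filter(stats::rnorm(nf, 0, spec$noise$sd *
                                            sqrt(1 - spec$noise$ar^2)),
                             spec$noise$ar, method = "recursive"))
  else numeric(nf)
  fluor <- env + noise

  # piecewise-linear envelope at 2 kHz through the frame-center values,
  # so Hamming-windowed band power tracks the frame series faithfully
  n_samp <- nf * 108
  ts <- (seq_len(n_samp) - 0.5) / fs
  tf <- seq_len(nf) * period
  fl_s <- stats::approx(tf, fluor, xout = ts, rule = 2)$y
  bleach <- 1 - spec$drift$amp * (1 - exp(-ts / spec$drift$tau_s))
  m <- spec$modulation
  amp_sig <- pmax(m$baseline + m$gain * fl_s, 0.05) * bleach
  amp_ctl <- m$control_level * bleach
  samples <- amp_sig * 0.5 * (1 + sin(2 * pi * spec$carriers[["signal"]] * ts)) +
    amp_ctl * 0.5 * (1 + sin(2 * pi * spec$carriers[["control"]] * ts))

  list(raw = raw_photometry(samples, fs, spec$carriers),
       truth = list(envelope_frames = env, fluor_frames = fluor,
                    period = period, n_frames = nf))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates behavioral sessions for `n_mice` mice under the spec's RFLR
#' agent and task, and renders raw modulated photometry (signal carrier
#' tracking kernel-generated fluorescence plus AR(1) noise and bleaching;
#' static control carrier) for selected sessions. Byte-identical under
#' the same `(spec, seed)`.
#'
#' @param spec A [truth_spec()].
#' @param n_mice Number of mice (default 6).
#' @param sessions_per_mouse Sessions per mouse (default 5).
#' @param photometry Which sessions get rendered photometry: `"first"`
#'   (first session of each mouse, default), `"all"`, or `"none"`.
#' @return A `synthetic_cohort`: list with `sessions` (list of
#'   `session_table`), `photometry` (named list of
#'   `list(raw, truth, session_key)`), and `spec`.
#' @export
generate_cohort <- function(spec = truth_spec(), n_mice = 6,
                            sessions_per_mouse = 5,
                            photometry = c("first", "all", "none")) {
  photometry <- match.arg(photometry)
  stopifnot(inherits(spec, "truth_spec"))
  sessions <- list()
  phot <- list()
  for (mi in seq_len(n_mice)) {
    for (si in seq_len(sessions_per_mouse)) {
      seed <- (spec$seed * 1000L + mi * 100L + si) %% .Machine$integer.max
      ag <- agent_rflr(spec$agent_params$alpha, spec$agent_params$beta,
                       spec$agent_params$tau)
      s <- simulate_session(ag, spec$task, seed = seed,
                            mouse_id = paste0("m", mi),
                            session_id = paste0("s", si),
                            latency = spec$latency)
      key <- paste0("m", mi, "_s", si)
      sessions[[key]] <- s
      if (photometry == "all" || (photometry == "first" && si == 1)) {
        set.seed((seed + 500000L) %% .Machine$integer.max)
        ph <- render_photometry(s, spec)
        ph$session_key <- key
        phot[[key]] <- ph
      }
    }
  }
  structure(list(sessions = sessions, photometry = phot, spec = spec),
            class = "synthetic_cohort")
}

#' Truth-versus-estimate recovery report
#'
#' Runs the full analysis stack on a synthetic cohort -- [fit_rflr()] on
#' the choice data, [p_high_port_curve()] + [fit_tau()] on the
#' block-transition dynamics, and demodulation + [fit_ridge()] on the
#' rendered photometry -- and tabulates estimates against the generating
#' truth. The behavioral time constant has no closed-form truth (it is a
#' derived property of the agent), so only its estimate is reported.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param rflr_epochs SGD epochs for the RFLR fit.
#' @param glm_alpha Ridge penalty for the kernel fit.
#' @return List with `params` (data.frame: truth, estimate, rel_error for
#'   alpha/beta/tau), `tau_p_high_port` (estimate), `kernel_cor` (named
#'   per-predictor correlation between fitted and truth kernels), and the
#'   underlying `rflr_fit`/`glm_fit` objects.
#' @export
recovery_report <- function(cohort, rflr_epochs = 200, glm_alpha = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  spec <- cohort$spec
  fit <- fit_rflr(cohort$sessions, epochs = rflr_epochs, seed = 1)
  truth <- c(alpha = spec$agent_params$alpha, beta = spec$agent_params$beta,
             tau = spec$agent_params$tau)
  est <- c(fit$params$alpha, fit$params$beta, fit$params$tau)
  params <- data.frame(parameter = names(truth), truth = unname(truth),
                       estimate = est,
                       rel_error = (est - unname(truth)) / unname(truth))

  tau_hat <- fit_tau(p_high_port_curve(cohort$sessions))$tau

  kernel_cor <- NULL; glm_fit <- NULL
  if (length(cohort$photometry)) {
    designs <- lapply(cohort$photometry, function(ph) {
      sig <- demodulate(ph$raw, spec$carriers[["signal"]], detrend_raw = TRUE)
      s <- cohort$sessions[[ph$session_key]]
      pr <- build_predictors(s, sig, hemisphere = spec$hemisphere)
      build_design(pr, sig)
    })
    design <- stack_designs(designs)
    glm_fit <- fit_ridge(design, alpha = glm_alpha)
    Ktruth <- truth_kernel_matrix(spec)
    kernel_cor <- vapply(colnames(Ktruth), function(nm)
      stats::cor(glm_fit$kernels[, nm], Ktruth[, nm]), 0)
  }
  list(params = params, tau_p_high_port = tau_hat,
       kernel_cor = kernel_cor, rflr_fit = fit, glm_fit = glm_fit)
}
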