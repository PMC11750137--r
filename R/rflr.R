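#' RFLR parameters
#'
#' The recursively formulated logistic regression (RFLR) describes choice
#' with three parameters: `alpha`, the weight on the most recent choice
#' (perseveration); `beta`, the weight on accumulated action-outcome
#' evidence; and `tau` (> 0, in trials), the time constant over which
#' that evidence decays.
#'
#' @param alpha,beta Finite real weights.
#' @param tau Positive decay time constant in trials.
#' @return A list of class `rflr_params`.
#' @export
rflr_params <- function(alpha, beta, tau) {
  if (!all(is.finite(c(alpha, beta, tau))))
    stop("alpha, beta, tau must be finite", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, tau = tau),
            class = "rflr_params")
}

#' One RFLR update
#'
#' Given the evidence accumulator `phi` and the trial just completed
#' (signed choice `c_t`, +1 left / -1 right; outcome `r_t`, 0/1), the
#' next-state equations are
#' `phi' = c_t * r_t + exp(-1/tau) * phi` and
#' `psi' = alpha * c_t + beta * phi'`,
#' with `P(next choice = left) = plogis(psi')`.
#'
#' @param phi Current evidence accumulator.
#' @param c_t Signed choice, +1 (left) or -1 (right).
#' @param r_t Outcome, 0 or 1.
#' @param params An [rflr_params()].
#' @return List with `phi`, `psi`, and `p_left`.
#' @examples
#' rflr_step(0, +1, 1, rflr_params(0, 1, 1e6))$psi  # ~1
#' @export
rflr_step <- function(phi, c_t, r_t, params) {
  stopifnot(inherits(params, "rflr_params"))
  phi2 <- c_t * r_t + exp(-1 / params$tau) * phi
  psi2 <- params$alpha * c_t + params$beta * phi2
  list(phi = phi2, psi = psi2, p_left = stats::plogis(psi2))
}

# Teacher-forced latent states for one session.
# Returns phi[t] (evidence after trial t, phi_0 = 0) and psi[t], the
# log-odds for the choice on trial t+1.
rflr_states <- function(c_t, r_t, params) {
  gamma <- exp(-1 / params$tau)
  phi <- as.numeric(stats::filter(c_t * r_t, gamma, method = "recursive"))
  psi <- params$alpha * c_t + params$beta * phi
  list(phi = phi, psi = psi)
}

session_cr <- function(session) {
  list(c = side_sign(session$choice), r = as.numeric(session$rewarded))
}

#' Mean negative log-likelihood of the RFLR on sessions
#'
#' Evidence starts at 0 at the beginning of each session and the first
#' trial, for which no prediction exists, is excluded from the mean.
#' Predicted probabilities are clamped away from 0/1 by 1e-12.
#'
#' @param sessions A `session_table` or list of them.
#' @param params An [rflr_params()].
#' @return Mean NLL per predicted trial (scalar); attribute `n_predicted`
#'   gives the number of predicted trials.
#' @export
rflr_nll <- function(sessions, params) {
  sessions <- as_session_list(sessions)
  tot <- 0; n <- 0
  for (s in sessions) {
    cr <- session_cr(s)
    st <- rflr_states(cr$c, cr$r, params)
    m <- length(cr$c)
    if (m < 2) next
    p <- stats::plogis(st$psi[-m])          # prediction for trials 2..m
    y <- (cr$c[-1] + 1) / 2                 # 1 = left
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    tot <- tot + sum(-(y * log(p) + (1 - y) * log(1 - p)))
    n <- n + (m - 1)
  }
  if (n == 0) stop("need at least one session with >= 2 trials", call. = FALSE)
  structure(tot / n, n_predicted = n)
}

# Mean NLL and its analytic gradient in (alpha, beta, theta = log tau)
# for one session's (c, r) vectors.
rflr_nll_grad <- function(c_t, r_t, alpha, beta, theta) {
  tau <- exp(theta)
  gamma <- exp(-1 / tau)
  m <- length(c_t)
  phi <- as.numeric(stats::filter(c_t * r_t, gamma, method = "recursive"))
  # dphi/dgamma: g[t] = phi[t-1] + gamma * g[t-1], g[1] = 0
  g <- as.numeric(stats::filter(c(0, phi[-m]), gamma, method = "recursive"))
  psi <- alpha * c_t + beta * phi
  p <- stats::plogis(psi[-m])
  y <- (c_t[-1] + 1) / 2
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  nll <- mean(-(y * log(pc) + (1 - y) * log(1 - pc)))
  d_psi <- (p - y) / (m - 1)                # d(mean NLL)/d(psi_t), t = 1..m-1
  d_alpha <- sum(d_psi * c_t[-m])
  d_beta <- sum(d_psi * phi[-m])
  d_gamma <- sum(d_psi * beta * g[-m])
  d_theta <- d_gamma * gamma / tau          # via gamma = exp(-exp(-theta))
  list(nll = nll, grad = c(alpha = d_alpha, beta = d_beta, theta = d_theta))
}

#' Fit the RFLR by stochastic gradient descent
#'
#' Maximum-likelihood estimation of (alpha, beta, tau) by SGD on the mean
#' per-trial negative log-likelihood with analytic gradients. One
#' mini-batch is one session; tau is fitted as log(tau) to keep it
#' positive; the learning rate decays as `1/sqrt(epoch)`. Classical
#' momentum (default 0.9) accelerates convergence along the narrow
#' beta/tau valley of the likelihood, where these two parameters trade
#' off against each other; set `momentum = 0` for plain SGD.
#' Deterministic under a fixed seed.
#'
#' @param sessions A `session_table` or list of them.
#' @param init Initial [rflr_params()] (default alpha 0, beta 0, tau 1).
#' @param learning_rate Base learning rate (default 0.05).
#' @param epochs Number of passes over the sessions (default 200).
#' @param momentum Classical momentum coefficient in `[0, 1)`.
#' @param seed Integer seed for the session shuffling.
#' @return An `rflr_fit` list: `params` ([rflr_params()]), `nll` (final
#'   mean NLL over all sessions), `n_trials`, and `trace` (per-epoch NLL).
#' @examples
#' ss <- lapply(1:4, function(i)
#'   simulate_session(agent_rflr(1, 2, 1.4),
#'                    task_config(0.9, 0.1, n_trials = 300), seed = i))
#' fit <- fit_rflr(ss, epochs = 50, seed = 1)
#' @export
fit_rflr <- function(sessions, init = rflr_params(0, 0, 1),
                     learning_rate = 0.05, epochs = 200, momentum = 0.9,
                     seed = 1) {
  sessions <- as_session_list(sessions)
  dat <- lapply(sessions, session_cr)
  dat <- dat[vapply(dat, function(d) length(d$c) >= 2, TRUE)]
  if (!length(dat)) stop("no session with >= 2 trials", call. = FALSE)
  par <- c(alpha = init$alpha, beta = init$beta, theta = log(init$tau))
  vel <- par * 0
  set.seed(seed)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lr <- learning_rate / sqrt(e)
    ord <- sample.int(length(dat))
    nlls <- numeric(length(dat))
    for (k in seq_along(ord)) {
      d <- dat[[ord[k]]]
      gr <- rflr_nll_grad(d$c, d$r, par["alpha"], par["beta"], par["theta"])
      if (!is.finite(gr$nll))
        stop("NLL diverged; reduce the learning rate", call. = FALSE)
      vel <- momentum * vel - lr * gr$grad
      par <- par + vel
      nlls[k] <- gr$nll
    }
    trace[e] <- mean(nlls)
  }
  params <- rflr_params(unname(par["alpha"]), unname(par["beta"]),
                        exp(unname(par["theta"])))
  nll <- rflr_nll(sessions, params)
  structure(list(params = params, nll = as.numeric(nll),
                 n_trials = sum(vapply(dat, function(d) length(d$c), 0L)),
                 trace = trace),
            class = "rflr_fit")
}

#' @export
print.rflr_fit <- function(x, ...) {
  cat(sprintf("<rflr_fit> alpha = %.3f, beta = %.3f, tau = %.3f; mean NLL = %.4f (%d trials)\n",
              x$params$alpha, x$params$beta, x$params$tau, x$nll, x$n_trials))
  invisible(x)
}

#' Per-trial RFLR predictions for a session
#'
#' Teacher-forced mode uses the animal's actual choice/outcome history to
#' compute the log-odds `psi` for every trial and one-step-ahead choice
#' predictions. Simulate-forward mode instead runs an [agent_rflr()]
#' through the task generatively (via [simulate_session()]) so that
#' model-implied transition curves can be compared with the data's.
#'
#' @param params An [rflr_params()].
#' @param session A `session_table` (teacher-forced mode).
#' @param mode `"teacher"` or `"simulate"`.
#' @param config,seed Task configuration and seed for simulate mode;
#'   `config` defaults to the session's own attached config.
#' @return Teacher mode: data.frame with `trial`, `psi` (log-odds for
#'   this trial's choice, NA on trial 1), `p_left`, `predicted` and
#'   `choice`. Simulate mode: a new `session_table`.
#' @export
predict_session <- function(params, session, mode = c("teacher", "simulate"),
                            config = attr(session, "config"), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(config)) stop("simulate mode needs a task_config", call. = FALSE)
    return(simulate_session(agent_rflr(params$alpha, params$beta, params$tau),
                            config, seed = seed,
                            mouse_id = session$mouse_id[1],
                            session_id = paste0(session$session_id[1], "_sim")))
  }
  cr <- session_cr(session)
  st <- rflr_states(cr$c, cr$r, params)
  m <- length(cr$c)
  psi <- c(NA, st$psi[-m])
  p_left <- stats::plogis(psi)
  data.frame(trial = session$trial, psi = psi, p_left = p_left,
             predicted = ifelse(is.na(psi), NA,
                                ifelse(psi > 0, "left", "right")),
             choice = session$choice, stringsAsFactors = FALSE)
}

#' Psychometric curve from RFLR log-odds
#'
#' Groups teacher-forced log-odds into `n_bins` equal-count (quantile)
#' bins, computes the observed probability of choosing left per bin, and
#' fits a logistic `p = 1 / (1 + exp(-(psi - m) / s))` with free midpoint
#' `m` and slope `s` by least squares (smaller `s` = steeper curve).
#'
#' @param sessions A `session_table` or list of them.
#' @param params An [rflr_params()].
#' @param n_bins Number of bins (default 13).
#' @return A `psychometric_curve`: data.frame with `bin_center` (mean psi
#'   per bin), `p_left_observed`, `n`; attributes `midpoint`, `slope`,
#'   `sse`. Degenerate (empty) bins are merged with a warning.
#' @export
psychometric <- function(sessions, params, n_bins = 13) {
  sessions <- as_session_list(sessions)
  psi <- numeric(0); y <- numeric(0)
  for (s in sessions) {
    cr <- session_cr(s)
    if (length(cr$c) < 2) next
    st <- rflr_states(cr$c, cr$r, params)
    m <- length(cr$c)
    psi <- c(psi, st$psi[-m])
    y <- c(y, (cr$c[-1] + 1) / 2)
  }
  if (length(unique(psi)) < n_bins)
    stop("need at least ", n_bins, " distinct log-odds values", call. = FALSE)
  br <- unique(stats::quantile(psi, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < n_bins + 1)
    warning("duplicate quantiles: ", n_bins + 1 - length(br),
            " degenerate bin(s) merged")
  bins <- cut(psi, breaks = br, include.lowest = TRUE)
  bc <- tapply(psi, bins, mean)
  po <- tapply(y, bins, mean)
  nn <- tapply(y, bins, length)
  out <- data.frame(bin_center = as.numeric(bc),
                    p_left_observed = as.numeric(po),
                    n = as.integer(nn), row.names = NULL)
  fit <- fit_logistic(out$bin_center, out$p_left_observed)
  attr(out, "midpoint") <- fit$midpoint
  attr(out, "slope") <- fit$slope
  attr(out, "sse") <- fit$sse
  class(out) <- c("psychometric_curve", "data.frame")
  out
}

fit_logistic <- function(x, p, start = NULL) {
  if (is.null(start)) {
    # start from a logit-scale linear regression on the interior points
    pc <- pmin(pmax(p, 0.01), 0.99)
    cf <- stats::coef(stats::lm(stats::qlogis(pc) ~ x))
    s0 <- if (is.finite(cf[2]) && abs(cf[2]) > 1e-6) 1 / cf[2] else 1
    s0 <- min(max(abs(unname(s0)), 1e-3), 100)
    m0 <- if (is.finite(cf[1])) -unname(cf[1]) * s0 else 0
    start <- list(m = m0, s = s0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ 1 / (1 + exp(-(x - m) / s)),
                      start = start, lower = c(-Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(list(midpoint = unname(cf["m"]), slope = unname(cf["s"]),
                sse = sum(stats::resid(fit)^2)))
  }
  # tiny or exactly-fitting inputs can defeat the LM gradient check;
  # fall back to direct minimization of the same sum of squares
  sse_fn <- function(th)
    sum((p - 1 / (1 + exp(-(x - th[1]) / max(th[2], 1e-6))))^2)
  o <- stats::optim(c(start$m, start$s), sse_fn)
  o <- stats::optim(o$par, sse_fn)   # polish
  list(midpoint = o$par[1], slope = max(o$par[2], 1e-6), sse = o$value)
}

#' Extra sum-of-squares comparison of psychometric curves
#'
#' Tests whether several psychometric curves are better described by one
#' shared logistic or by separate logistics per curve:
#' `F = ((SSE_shared - SSE_sep) / (df_shared - df_sep)) / (SSE_sep / df_sep)`
#' with p-value from the F distribution.
#'
#' @param curves A list of `psychometric_curve` objects.
#' @return List with `F`, `p_value`, `df1`, `df2`, `sse_shared`,
#'   `sse_separate`.
#' @export
compare_psychometrics <- function(curves) {
  if (length(curves) < 2) stop("need at least 2 curves", call. = FALSE)
  x <- unlist(lapply(curves, function(cu) cu$bin_center))
  p <- unlist(lapply(curves, function(cu) cu$p_left_observed))
  n_pts <- length(x)
  k <- length(curves)
  df_sep <- n_pts - 2 * k
  df_sh <- n_pts - 2
  if (df_sep <= 0) stop("too few points for separate fits", call. = FALSE)
  sse_sep <- sum(vapply(curves, function(cu) attr(cu, "sse"), 0))
  sse_sh <- fit_logistic(x, p)$sse
  Fstat <- max(0, ((sse_sh - sse_sep) / (df_sh - df_sep)) / (sse_sep / df_sep))
  list(F = Fstat, p_value = stats::pf(Fstat, df_sh - df_sep, df_sep,
                                      lower.tail = FALSE),
       df1 = df_sh - df_sep, df2 = df_sep,
       sse_shared = sse_sh, sse_separate = sse_sep)
}
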