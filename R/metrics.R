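#' Transition-aligned behavioral curves
#'
#' Aligns a per-trial indicator to block transitions and averages it,
#' first within each mouse (across all transitions in all of that mouse's
#' sessions) and then across mice. Offset 0 is the first trial after the
#' reward probabilities flip; negative offsets index pre-transition
#' trials. Transitions close to a session edge contribute whatever
#' offsets exist.
#'
#' `p_high_port_curve()` tracks the probability of choosing the currently
#' highly rewarded port; `p_switch_curve()` tracks the probability that
#' the choice differs from the previous trial's choice (the first trial
#' of a session has no switch value and is skipped).
#'
#' @param sessions A `session_table` or list of them.
#' @param pre Number of pre-transition trials (offsets `-pre .. -1`).
#' @param post Number of post-transition trials (offsets `0 .. post-1`).
#' @return A `transition_curve`: data.frame with columns `offset`, `mean`,
#'   `sem`, `n_mice`, plus attribute `per_mouse` (mice x offsets matrix).
#'   For `p_switch_curve()` the attribute `max_p_switch` holds, per mouse,
#'   the maximum of the curve over the first 20 post-transition trials.
#' @examples
#' ss <- lapply(1:3, function(i)
#'   simulate_session(agent_rflr(1, 2, 1.4),
#'                    task_config(0.9, 0.1, n_trials = 400), seed = i,
#'                    mouse_id = paste0("m", i)))
#' pc <- p_high_port_curve(ss)
#' @export
p_high_port_curve <- function(sessions, pre = 10, post = 20) {
  transition_curve(sessions, pre, post,
                   value_fun = function(s) as.numeric(s$choice == s$high_side))
}

#' @rdname p_high_port_curve
#' @export
p_switch_curve <- function(sessions, pre = 10, post = 20) {
  cur <- transition_curve(sessions, pre, post,
                          value_fun = function(s) {
                            sw <- c(NA, s$choice[-1] != s$choice[-nrow(s)])
                            as.numeric(sw)
                          })
  pm <- attr(cur, "per_mouse")
  post_cols <- as.character(0:min(19, post - 1))
  attr(cur, "max_p_switch") <-
    apply(pm[, post_cols, drop = FALSE], 1, max, na.rm = TRUE)
  cur
}

transition_curve <- function(sessions, pre, post, value_fun) {
  sessions <- as_session_list(sessions)
  offsets <- seq(-pre, post - 1)
  acc <- list()  # per mouse: sum and count per offset
  for (s in sessions) {
    v <- value_fun(s)
    trans <- which(diff(s$block) > 0) + 1L  # first trial of each new block
    if (!length(trans)) next
    m <- s$mouse_id[1]
    if (is.null(acc[[m]]))
      acc[[m]] <- list(sum = numeric(length(offsets)),
                       n = numeric(length(offsets)))
    for (tr in trans) {
      idx <- tr + offsets
      ok <- idx >= 1 & idx <= nrow(s)
      ok[ok] <- !is.na(v[idx[ok]])
      acc[[m]]$sum[ok] <- acc[[m]]$sum[ok] + v[idx[ok]]
      acc[[m]]$n[ok] <- acc[[m]]$n[ok] + 1
    }
  }
  if (!length(acc))
    stop("no completed block transitions in the input sessions",
         call. = FALSE)
  per_mouse <- t(vapply(acc, function(a) a$sum / pmax(a$n, 1),
                        numeric(length(offsets))))
  per_mouse[t(vapply(acc, function(a) a$n == 0, logical(length(offsets))))] <- NA
  colnames(per_mouse) <- as.character(offsets)
  mu <- colMeans(per_mouse, na.rm = TRUE)
  nm <- colSums(!is.na(per_mouse))
  sem <- apply(per_mouse, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nm, 1))
  sem[nm < 2] <- NA
  out <- data.frame(offset = offsets, mean = mu, sem = sem, n_mice = nm,
                    row.names = NULL)
  attr(out, "per_mouse") <- per_mouse
  class(out) <- c("transition_curve", "data.frame")
  out
}

#' Exponential fit to a post-transition recovery curve
#'
#' Least-squares fit of `p(t) = A - B * exp(-t / tau)` to the first 20
#' trials following a block transition (offsets 0..19 mapped to t =
#' 1..20, t in trials). `tau` is the recovery time constant of p(high
#' port) after a reversal; smaller values mean faster re-tracking of the
#' new high port.
#'
#' @param curve A `transition_curve` (from [p_high_port_curve()]) or a
#'   numeric vector of 20 post-transition values.
#' @param n_fit Number of post-transition trials used (default 20).
#' @return A `tau_fit` list: `tau`, `asymptote` (A), `amplitude` (B),
#'   `sse`, `converged`, and `degenerate` (TRUE when the series is flat
#'   and tau is unidentifiable, in which case `tau` is `NA`).
#' @examples
#' p <- 0.8 - 0.7 * exp(-(1:20) / 3)
#' fit_tau(p)$tau
#' @export
fit_tau <- function(curve, n_fit = 20) {
  if (inherits(curve, "transition_curve")) {
    post <- curve$mean[curve$offset >= 0]
    if (length(post) < n_fit)
      stop("need at least ", n_fit, " post-transition offsets", call. = FALSE)
    y <- post[seq_len(n_fit)]
  } else {
    y <- as.numeric(curve)
    if (length(y) < n_fit)
      stop("need at least ", n_fit, " values", call. = FALSE)
    y <- y[seq_len(n_fit)]
  }
  t <- seq_len(n_fit)
  # endpoint-based initialization
  A0 <- mean(y[(n_fit - 4):n_fit])
  B0 <- A0 - y[1]
  if (abs(B0) < 1e-8 || stats::sd(y) < 1e-10) {
    return(structure(list(tau = NA_real_, asymptote = mean(y),
                          amplitude = 0, sse = sum((y - mean(y))^2),
                          converged = TRUE, degenerate = TRUE),
                     class = "tau_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A - B * exp(-t / tau),
                      start = list(A = A0, B = B0, tau = 3),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("exponential fit failed to converge: ", conditionMessage(fit),
         call. = FALSE)
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]), asymptote = unname(cf["A"]),
                 amplitude = unname(cf["B"]),
                 sse = sum(stats::resid(fit)^2),
                 converged = TRUE, degenerate = FALSE),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  if (x$degenerate)
    cat("<tau_fit> flat series, tau unidentifiable\n")
  else
    cat(sprintf("<tau_fit> tau = %.3f trials (A = %.3f, B = %.3f, sse = %.2e)\n",
                x$tau, x$asymptote, x$amplitude, x$sse))
  invisible(x)
}

#' History-conditioned switch probabilities
#'
#' Conditions p(switch) on the combination of choices and outcomes of the
#' previous `depth` trials. Histories are encoded as words over
#' \{A, a, B, b\}: the letter for a past trial is A/a if it used the same
#' side as the reference trial (the most recent trial of the history) and
#' B/b otherwise; upper case means rewarded. The word reads oldest trial
#' first, so the final letter is always A (same side as itself, rewarded)
#' or a (unrewarded). p(switch) is the probability that the trial
#' following the history chooses the other side than the reference trial.
#'
#' The frequency-weighted mean of p(switch) over words equals the overall
#' p(switch) restricted to trials with a full history (law of total
#' probability; exact identity, used as a self-check).
#'
#' @param sessions A `session_table` or list of them.
#' @param depth Number of history trials (default 2).
#' @return A data.frame with columns `word`, `n`, `p_switch`, sorted by
#'   word; attribute `overall` holds the overall p(switch) over the same
#'   trials.
#' @export
conditional_switch <- function(sessions, depth = 2) {
  sessions <- as_session_list(sessions)
  words <- character(0); switches <- logical(0)
  for (s in sessions) {
    n <- nrow(s)
    if (n < depth + 1) next
    ch <- side_sign(s$choice)
    rw <- s$rewarded
    for (i in seq(depth, n - 1)) {        # i = reference trial
      hist_idx <- (i - depth + 1):i
      same <- ch[hist_idx] == ch[i]
      letters_ <- ifelse(same, "a", "b")
      letters_[rw[hist_idx]] <- toupper(letters_[rw[hist_idx]])
      words <- c(words, paste(letters_, collapse = ""))
      switches <- c(switches, ch[i + 1] != ch[i])
    }
  }
  if (!length(words))
    stop("sessions too short for the requested history depth", call. = FALSE)
  tab <- tapply(switches, words, function(z) c(n = length(z), p = mean(z)))
  out <- data.frame(word = names(tab),
                    n = vapply(tab, `[`, numeric(1), "n"),
                    p_switch = vapply(tab, `[`, numeric(1), "p"),
                    row.names = NULL)
  out <- out[order(out$word), ]
  attr(out, "overall") <- mean(switches)
  out
}

#' Per-session behavioral summaries
#'
#' Scalar performance measures for each session: probability of reward,
#' of choosing the high port, of choosing left, of switching sides
#' (first trial excluded from the denominator), trial counts, mean trial
#' duration (CE to SX), mean inter-trial interval, and the lengths (in
#' trials) of completed blocks.
#'
#' @param sessions A `session_table` or list of them.
#' @return A data.frame with one row per session; attribute
#'   `block_lengths` holds the pooled completed-block lengths.
#' @export
session_summaries <- function(sessions) {
  sessions <- as_session_list(sessions)
  if (!length(sessions) || all(vapply(sessions, nrow, 0L) == 0)) {
    out <- data.frame(mouse_id = character(0), session_id = character(0),
                      n_trials = integer(0), p_reward = numeric(0),
                      p_high_port = numeric(0), p_left = numeric(0),
                      p_switch = numeric(0), mean_trial_duration = numeric(0),
                      mean_iti = numeric(0))
    attr(out, "block_lengths") <- integer(0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  rows <- lapply(sessions, function(s) {
    n <- nrow(s)
    sw <- if (n > 1) mean(s$choice[-1] != s$choice[-n]) else NA_real_
    iti <- if (n > 1) mean(s$t_CE[-1] - s$t_SX[-n]) else NA_real_
    data.frame(mouse_id = s$mouse_id[1], session_id = s$session_id[1],
               n_trials = n, p_reward = mean(s$rewarded),
               p_high_port = mean(s$choice == s$high_side),
               p_left = mean(s$choice == "left"), p_switch = sw,
               mean_trial_duration = mean(s$t_SX - s$t_CE),
               mean_iti = iti, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bl <- unlist(lapply(sessions, function(s) {
    tb <- table(s$block)
    nb <- max(s$block)
    if (nb > 1) as.integer(tb[seq_len(nb - 1)]) else integer(0)
  }))
  attr(out, "block_lengths") <- bl
  out
}

#' Across-mouse summary of session measures
#'
#' Averages [session_summaries()] output per mouse and reports mean and
#' SEM across mice for each measure.
#'
#' @param summaries Output of [session_summaries()].
#' @return A data.frame with one row per measure: `mean`, `sem`, `n_mice`.
#' @export
cohort_summary <- function(summaries) {
  meas <- c("n_trials", "p_reward", "p_high_port", "p_left", "p_switch",
            "mean_trial_duration", "mean_iti")
  per_mouse <- stats::aggregate(summaries[meas],
                                by = list(mouse_id = summaries$mouse_id),
                                FUN = mean, na.rm = TRUE)
  mu <- colMeans(per_mouse[meas], na.rm = TRUE)
  n <- nrow(per_mouse)
  sem <- apply(per_mouse[meas], 2, stats::sd) / sqrt(n)
  data.frame(measure = meas, mean = unname(mu),
             sem = if (n > 1) unname(sem) else NA_real_, n_mice = n)
}

#' Pre-manipulation performance criteria
#'
#' Applies the four expert-performance criteria to exactly five
#' consecutive sessions: across the five sessions, (1) mean p(high port)
#' >= 0.80 with variance < 0.003; (2) mean p(switch) <= 0.15 with
#' variance < 0.001; (3) mean p(left) within [0.45, 0.55] with variance
#' < 0.005; (4) every session has at least 200 trials. Mean/inclusive
#' thresholds are inclusive, variance thresholds strict; variances are
#' population variances over the five sessions.
#'
#' @param sessions A list of exactly 5 `session_table`s.
#' @return A list with `pass` (logical) and `reasons` (character vector
#'   of failed criteria, empty when passing), plus the computed measures.
#' @export
criteria_check <- function(sessions) {
  sessions <- as_session_list(sessions)
  if (length(sessions) != 5)
    stop("criteria are defined over exactly 5 consecutive sessions",
         call. = FALSE)
  sm <- session_summaries(sessions)
  popvar <- function(x) mean((x - mean(x))^2)
  reasons <- character(0)
  if (!(mean(sm$p_high_port) >= 0.80))
    reasons <- c(reasons, "mean p(high port) < 0.80")
  if (!(popvar(sm$p_high_port) < 0.003))
    reasons <- c(reasons, "var p(high port) >= 0.003")
  if (!(mean(sm$p_switch) <= 0.15))
    reasons <- c(reasons, "mean p(switch) > 0.15")
  if (!(popvar(sm$p_switch) < 0.001))
    reasons <- c(reasons, "var p(switch) >= 0.001")
  if (!(mean(sm$p_left) >= 0.45 && mean(sm$p_left) <= 0.55))
    reasons <- c(reasons, "mean p(left) outside [0.45, 0.55]")
  if (!(popvar(sm$p_left) < 0.005))
    reasons <- c(reasons, "var p(left) >= 0.005")
  if (!all(sm$n_trials >= 200))
    reasons <- c(reasons, "fewer than 200 trials in a session")
  list(pass = length(reasons) == 0, reasons = reasons, measures = sm)
}
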