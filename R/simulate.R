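#' Simulate one session of the probabilistic switching task
#'
#' Runs a choice agent through the block-structured task. Each trial the
#' agent chooses a side port; reward is drawn Bernoulli with the chosen
#' port's current probability (per-port, independent, no baiting). After
#' the trial on which the `rewards_per_block`-th reward of the block is
#' delivered, the high side flips and the block index increments. Event
#' timestamps within and between trials are drawn by
#' [sample_trial_timing()], honoring the minimum inter-trial interval.
#'
#' @param agent A [bandit_agent][agents]; it is `reset()` at session start.
#' @param config A [task_config()].
#' @param seed Integer seed; the session is bit-identical under the same
#'   (agent, config, seed).
#' @param mouse_id,session_id Identifiers stored with the session.
#' @param latency Latency parameters, see [latency_defaults()].
#' @return A `session_table`: a data.frame with one row per trial and
#'   columns `mouse_id`, `session_id`, `trial`, `block`, `high_side`,
#'   `choice`, `rewarded`, `t_CE`, `t_CX`, `t_SE`, `t_FL`, `t_SX`
#'   (timestamps in seconds from session start), with the `task_config`
#'   attached as attribute `config`.
#' @examples
#' s <- simulate_session(agent_rflr(1, 2, 1.4),
#'                       task_config(0.9, 0.1, n_trials = 200), seed = 1)
#' head(s)
#' @export
simulate_session <- function(agent, config, seed = NULL,
                             mouse_id = "m1", session_id = "s1",
                             latency = latency_defaults()) {
  stopifnot(inherits(agent, "bandit_agent"), inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  agent$reset()

  n <- config$n_trials
  high_side <- character(n); choice <- character(n)
  rewarded <- logical(n); block <- integer(n)
  tt <- matrix(NA_real_, n, 5,
               dimnames = list(NULL, c("t_CE", "t_CX", "t_SE", "t_FL", "t_SX")))

  cur_high <- config$initial_high_side
  cur_block <- 1L
  block_rewards <- 0L
  t_now <- config$min_iti   # session clock starts one ITI before trial 1
  for (i in seq_len(n)) {
    ch <- agent$choose()
    p <- if (ch == cur_high) config$p_high else config$p_low
    rw <- stats::runif(1) < p
    agent$observe(ch, rw)

    high_side[i] <- cur_high; choice[i] <- ch
    rewarded[i] <- rw; block[i] <- cur_block
    tim <- sample_trial_timing(rw, latency)
    tt[i, ] <- t_now + tim
    t_now <- tt[i, "t_SX"] +
      config$min_iti + rlnorm_capped(1, latency$iti_extra)

    if (rw) {
      block_rewards <- block_rewards + 1L
      if (block_rewards >= config$rewards_per_block) {
        cur_block <- cur_block + 1L
        cur_high <- other_side(cur_high)
        block_rewards <- 0L
      }
    }
  }

  out <- data.frame(mouse_id = mouse_id, session_id = session_id,
                    trial = seq_len(n), block = block,
                    high_side = high_side, choice = choice,
                    rewarded = rewarded, tt,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("session_table", "data.frame")
  out
}

#' Validate a session table
#'
#' Checks the structural invariants of a `session_table`: required
#' columns, ordered event times within each trial (`t_CE < t_CX <= t_SE <
#' t_SX`, with `t_FL` in `[t_SE, t_SX]` when present), and consecutive
#' trials separated by at least the configured minimum inter-trial
#' interval when a config is attached. A missing `t_FL` is accepted only
#' on unrewarded trials.
#'
#' @param session A `session_table` or equivalent data.frame.
#' @return The session, invisibly; errors name the first offending trial.
#' @export
validate_session <- function(session) {
  need <- c("mouse_id", "session_id", "trial", "block", "high_side",
            "choice", "rewarded", "t_CE", "t_CX", "t_SE", "t_FL", "t_SX")
  miss <- setdiff(need, names(session))
  if (length(miss))
    stop("session is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_side <- !session$choice %in% c("left", "right") |
    !session$high_side %in% c("left", "right")
  if (any(bad_side))
    stop("trial ", session$trial[which(bad_side)[1]],
         ": choice/high_side must be 'left' or 'right'", call. = FALSE)
  ord <- with(session, t_CE < t_CX & t_CX <= t_SE & t_SE < t_SX)
  if (any(!ord))
    stop("trial ", session$trial[which(!ord)[1]],
         ": event times must satisfy t_CE < t_CX <= t_SE < t_SX",
         call. = FALSE)
  fl_ok <- is.na(session$t_FL) |
    (session$t_FL >= session$t_SE & session$t_FL <= session$t_SX)
  if (any(!fl_ok))
    stop("trial ", session$trial[which(!fl_ok)[1]],
         ": t_FL must lie in [t_SE, t_SX]", call. = FALSE)
  fl_missing_rewarded <- is.na(session$t_FL) & session$rewarded
  if (any(fl_missing_rewarded))
    stop("trial ", session$trial[which(fl_missing_rewarded)[1]],
         ": rewarded trial lacks t_FL", call. = FALSE)
  cfg <- attr(session, "config")
  if (!is.null(cfg) && nrow(session) > 1) {
    gap <- session$t_CE[-1] - session$t_SX[-nrow(session)]
    if (any(gap < cfg$min_iti - 1e-9))
      stop("trial ", session$trial[which(gap < cfg$min_iti - 1e-9)[1] + 1],
           ": inter-trial interval below the configured minimum",
           call. = FALSE)
  }
  invisible(session)
}

#' @export
print.session_table <- function(x, ...) {
  cat(sprintf("<session_table> %s/%s: %d trials, %d blocks, p(reward)=%.3f\n",
              x$mouse_id[1], x$session_id[1], nrow(x), max(x$block),
              mean(x$rewarded)))
  NextMethod()
}

# Coerce a session or list of sessions into a plain list of sessions.
as_session_list <- function(sessions) {
  if (inherits(sessions, "session_table") || is.data.frame(sessions))
    return(list(sessions))
  if (is.list(sessions)) return(sessions)
  stop("expected a session_table or a list of them", call. = FALSE)
}
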