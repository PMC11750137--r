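#' Task configuration for the two-port probabilistic switching task
#'
#' Describes one session of the task: two side ports deliver water with
#' fixed but unequal probabilities, and once `rewards_per_block` rewards
#' have been earned the probabilities swap sides (a "block transition").
#' `p_high` and `p_low` are per-port probabilities and need not sum to 1
#' (90/10 means 0.9 and 0.1).
#'
#' @param p_high Reward probability at the currently high port, in (0.5, 1].
#' @param p_low Reward probability at the low port, in [0, 0.5).
#' @param n_trials Number of trials to simulate.
#' @param rewards_per_block Rewards earned before the sides swap (default 50).
#' @param min_iti Enforced minimum inter-trial interval, seconds.
#' @param side_poke_deadline Maximum side-poke latency, seconds; the latency
#'   generator's support stays below it so trials never time out.
#' @param initial_high_side `"left"` or `"right"`.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config(0.9, 0.1, n_trials = 500)
#' @export
task_config <- function(p_high, p_low, n_trials,
                        rewards_per_block = 50L,
                        min_iti = 1.0,
                        side_poke_deadline = 8.0,
                        initial_high_side = c("left", "right")) {
  initial_high_side <- match.arg(initial_high_side)
  if (!is.numeric(p_high) || !is.numeric(p_low) ||
      p_high < 0 || p_high > 1 || p_low < 0 || p_low > 1)
    stop("p_high and p_low must be probabilities in [0, 1]", call. = FALSE)
  if (p_high <= p_low)
    stop("p_high must exceed p_low", call. = FALSE)
  if (rewards_per_block < 1)
    stop("rewards_per_block must be >= 1", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  structure(
    list(p_high = p_high, p_low = p_low,
         n_trials = as.integer(n_trials),
         rewards_per_block = as.integer(rewards_per_block),
         min_iti = min_iti, side_poke_deadline = side_poke_deadline,
         initial_high_side = initial_high_side),
    class = "task_config")
}

#' Default within-trial latency parameters
#'
#' Log-normal `(meanlog, sdlog)` pairs for each latency in a trial, chosen
#' so that rewarded trials last 2-3 s in total, rewarded side-port
#' occupancy (licking and consuming, ~1 s) exceeds the quick exit after an
#' unrewarded poke, and all draws stay well below the 8 s side-poke
#' deadline. All values can be overridden through [truth_spec()].
#'
#' @return Named list of latency parameter pairs (seconds):
#'   `center_dwell` (CE to CX), `side_approach` (CX to SE), `lick_latency`
#'   (SE to FL), `consume` (FL to SX, rewarded trials), `quick_exit`
#'   (FL to SX, unrewarded trials), `iti_extra` (added to `min_iti`).
#' @export
latency_defaults <- function() {
  list(center_dwell  = c(meanlog = log(0.25), sdlog = 0.35),
       side_approach = c(meanlog = log(0.50), sdlog = 0.35),
       lick_latency  = c(meanlog = log(0.30), sdlog = 0.30),
       consume       = c(meanlog = log(1.20), sdlog = 0.25),
       quick_exit    = c(meanlog = log(0.20), sdlog = 0.40),
       iti_extra     = c(meanlog = log(0.30), sdlog = 0.50))
}

rlnorm_capped <- function(n, par, cap = 6) {
  pmin(stats::rlnorm(n, par[["meanlog"]], par[["sdlog"]]), cap)
}

#' Draw within-trial event timing
#'
#' Draws the latencies separating the five trial events -- center entry
#' (CE), center exit (CX), side entry (SE), first lick (FL), and side
#' exit (SX) -- from log-normal distributions. On rewarded trials the
#' animal stays at the spout to consume the reward (~1 s); on unrewarded
#' trials it withdraws quickly.
#'
#' @param rewarded Logical, whether the trial is rewarded.
#' @param latency Latency parameter list as from [latency_defaults()].
#' @return Named numeric vector of event times in seconds relative to CE:
#'   `t_CE` (0), `t_CX`, `t_SE`, `t_FL`, `t_SX`.
#' @export
sample_trial_timing <- function(rewarded, latency = latency_defaults()) {
  cx <- rlnorm_capped(1, latency$center_dwell)
  se <- cx + rlnorm_capped(1, latency$side_approach)
  fl <- se + rlnorm_capped(1, latency$lick_latency)
  sx <- fl + if (rewarded) rlnorm_capped(1, latency$consume)
             else rlnorm_capped(1, latency$quick_exit)
  c(t_CE = 0, t_CX = cx, t_SE = se, t_FL = fl, t_SX = sx)
}

side_sign <- function(side) ifelse(side == "left", 1, -1)
other_side <- function(side) ifelse(side == "left", "right", "left")
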