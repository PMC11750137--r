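# Shared fixtures, built once per test run.

# Hand-constructed session with a fixed 4 s trial cadence; times are
# valid for validate_session and event-to-frame mapping.
make_session <- function(choice, rewarded,
                         high_side = rep("left", length(choice)),
                         mouse_id = "m1", session_id = "s1",
                         fl_na_unrewarded = FALSE) {
  n <- length(choice)
  t_CE <- 2 + 4 * (seq_len(n) - 1)
  t_FL <- t_CE + 1.1
  if (fl_na_unrewarded) t_FL[!rewarded] <- NA
  s <- data.frame(mouse_id = mouse_id, session_id = session_id,
                  trial = seq_len(n), block = 1L,
                  high_side = high_side, choice = choice,
                  rewarded = rewarded,
                  t_CE = t_CE, t_CX = t_CE + 0.3, t_SE = t_CE + 0.8,
                  t_FL = t_FL, t_SX = t_CE + 2.2,
                  stringsAsFactors = FALSE)
  class(s) <- c("session_table", "data.frame")
  s
}

# Small cohort of RFLR-agent sessions, reused across behavioral tests.
rflr_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(1:4, function(i)
        simulate_session(agent_rflr(1, 2, 1.4),
                         task_config(0.9, 0.1, n_trials = 600),
                         seed = 100 + i, mouse_id = paste0("m", i)))
    cache
  }
})

# Minimal demod_signal on a given number of frames (period 54 ms).
make_signal <- function(values) {
  structure(list(values = values,
                 t = seq_along(values) * 0.054,
                 period = 0.054, carrier = 167),
            class = "demod_signal")
}

# Flip all left/right labels in a session.
flip_session <- function(s) {
  flip <- function(x) ifelse(x == "left", "right", "left")
  s$choice <- flip(s$choice)
  s$high_side <- flip(s$high_side)
  s
}
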