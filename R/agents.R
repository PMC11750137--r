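#' Choice agents
#'
#' Agents are closures over mutable internal state implementing the
#' contract `choose()` (returns `"left"` or `"right"`, drawing from the
#' agent's current choice distribution), `observe(choice, rewarded)`
#' (updates internal state after a trial), and `reset()` (returns to the
#' naive state). All randomness comes from R's global RNG, so a session
#' simulated under [simulate_session()] with a fixed seed is fully
#' reproducible.
#'
#' @section Provided agents:
#' * `agent_rflr(alpha, beta, tau)` -- the recursively formulated logistic
#'   regression agent: its log-odds of choosing left on the next trial are
#'   `psi = alpha * c + beta * phi` where `c` is the signed previous choice
#'   (+1 left, -1 right) and `phi` is reward evidence decaying with time
#'   constant `tau` (see [rflr_step()]).
#' * `agent_random(p_left)` -- chooses left with fixed probability.
#' * `agent_wsls()` -- deterministic win-stay/lose-shift.
#' * `agent_constant(side)` -- always chooses `side`.
#'
#' @param alpha,beta,tau RFLR parameters (see [rflr_params()]).
#' @param p_left Probability of choosing left for the random agent.
#' @param side Fixed side for the constant agent.
#' @return An object of class `bandit_agent`: a list with functions
#'   `choose`, `observe`, `reset` and a `label`.
#' @examples
#' ag <- agent_rflr(1, 2, 1.4)
#' set.seed(1)
#' ag$choose()
#' @name agents
NULL

new_agent <- function(choose, observe, reset, label) {
  structure(list(choose = choose, observe = observe, reset = reset,
                 label = label),
            class = "bandit_agent")
}

#' @rdname agents
#' @export
agent_rflr <- function(alpha, beta, tau) {
  params <- rflr_params(alpha, beta, tau)
  gamma <- exp(-1 / params$tau)
  phi <- 0
  last_c <- NA_real_
  new_agent(
    choose = function() {
      p_left <- if (is.na(last_c)) 0.5 else
        stats::plogis(params$alpha * last_c + params$beta * phi)
      if (stats::runif(1) < p_left) "left" else "right"
    },
    observe = function(choice, rewarded) {
      c_t <- side_sign(choice)
      phi <<- c_t * as.numeric(rewarded) + gamma * phi
      last_c <<- c_t
    },
    reset = function() { phi <<- 0; last_c <<- NA_real_ },
    label = sprintf("rflr(%g,%g,%g)", alpha, beta, tau))
}

#' @rdname agents
#' @export
agent_random <- function(p_left = 0.5) {
  new_agent(
    choose = function() if (stats::runif(1) < p_left) "left" else "right",
    observe = function(choice, rewarded) invisible(NULL),
    reset = function() invisible(NULL),
    label = sprintf("random(%g)", p_left))
}

#' @rdname agents
#' @export
agent_wsls <- function() {
  nxt <- NULL
  new_agent(
    choose = function() {
      if (is.null(nxt)) {
        if (stats::runif(1) < 0.5) "left" else "right"
      } else nxt
    },
    observe = function(choice, rewarded) {
      nxt <<- if (rewarded) choice else other_side(choice)
    },
    reset = function() nxt <<- NULL,
    label = "wsls")
}

#' @rdname agents
#' @export
agent_constant <- function(side = "left") {
  side <- match.arg(side, c("left", "right"))
  new_agent(
    choose = function() side,
    observe = function(choice, rewarded) invisible(NULL),
    reset = function() invisible(NULL),
    label = paste0("constant(", side, ")"))
}

#' @export
print.bandit_agent <- function(x, ...) {
  cat("<bandit_agent>", x$label, "\n")
  invisible(x)
}
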