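#' Joint-task configuration
#'
#' The shared human-robot task: `n_subtasks` subtask types, of which the
#' human silently chooses `n_human` as their own; episodes are sequences of
#' `episode_length` subtask demands.
#'
#' @param n_subtasks total number of subtask types `n`.
#' @param n_human number `m` of subtasks the human claims, `1 <= m < n`.
#' @param episode_length trials `o` per episode.
#' @return object of class `task_config`.
#' @export
task_config <- function(n_subtasks = 4, n_human = 2, episode_length = 10) {
  stopifnot(n_human >= 1, n_human < n_subtasks, episode_length >= 1)
  structure(list(n_subtasks = n_subtasks, n_human = n_human,
                 episode_length = episode_length),
            class = "task_config")
}

#' Sample the human's hidden subtask choice
#'
#' Uniform random `m`-subset of the `n` subtasks, drawn without replacement;
#' the robot is responsible for the complement.
#'
#' @param config a [task_config()].
#' @return object of class `assignment`: list with `human_set` (sorted ids)
#'   and `n_subtasks`.
#' @export
sample_assignment <- function(config) {
  stopifnot(inherits(config, "task_config"))
  structure(list(human_set = sort(sample.int(config$n_subtasks, config$n_human)),
                 n_subtasks = config$n_subtasks),
            class = "assignment")
}

#' Sample one episode of subtask demands
#'
#' `o` independent uniform draws with replacement from the subtask ids, so a
#' subtask can recur within an episode.
#'
#' @param config a [task_config()].
#' @return integer vector of length `episode_length` with ids in `1..n`.
#' @export
sample_episode <- function(config) {
  stopifnot(inherits(config, "task_config"))
  sample.int(config$n_subtasks, config$episode_length, replace = TRUE)
}

#' Truly responsible agent for a subtask
#'
#' @param subtask subtask id(s) in `1..n` (vectorized).
#' @param assignment an [sample_assignment()] result.
#' @return character vector, `"H"` for human-claimed subtasks, `"R"` otherwise.
#' @export
true_actor <- function(subtask, assignment) {
  stopifnot(inherits(assignment, "assignment"))
  if (any(subtask < 1 | subtask > assignment$n_subtasks | subtask != round(subtask))) {
    stop("unknown subtask id; valid ids are 1..", assignment$n_subtasks)
  }
  ifelse(subtask %in% assignment$human_set, "H", "R")
}

#' Per-context accuracies of the simulated anticipation decoder
#'
#' The four correct-classification rates of a single-trial anticipation
#' decoder, one per consecutive-trial context: `tnr_hh` (human continues),
#' `tpr_hr` (robot takes over from human), `tnr_rr` (robot continues) and
#' `tpr_rh` (human takes over from robot), in percent.
#'
#' @param tnr_hh,tpr_hr,tnr_rr,tpr_rh rates in percent, each in `[0, 100]`.
#' @return object of class `decoder_rates`.
#' @seealso [empirical_decoder_rates()], [uniform_decoder_rates()]
#' @export
decoder_rates <- function(tnr_hh, tpr_hr, tnr_rr, tpr_rh) {
  r <- c(tnr_hh = tnr_hh, tpr_hr = tpr_hr, tnr_rr = tnr_rr, tpr_rh = tpr_rh)
  if (any(r < 0 | r > 100)) stop("decoder rates must lie in [0, 100] percent")
  structure(as.list(r), class = "decoder_rates")
}

#' Empirically grounded decoder rates
#'
#' The mean single-trial decoding accuracies measured during intermittent
#' human-robot collaboration, which the feasibility simulations use as the
#' realistic operating point: TNR_HH = 51.5, TPR_HR = 51.4, TNR_RR = 57.9,
#' TPR_RH = 56.1 percent. Only the robot-continuation versus human-takeover
#' contrast is meaningfully above chance, which is what makes learning from
#' such a weak signal the interesting regime.
#'
#' @return a [decoder_rates()] object.
#' @export
empirical_decoder_rates <- function() {
  decoder_rates(tnr_hh = 51.5, tpr_hr = 51.4, tnr_rr = 57.9, tpr_rh = 56.1)
}

#' All-equal decoder rates
#'
#' Convenience constructor setting all four context rates to one value, used
#' for hypothetical decoder-quality sweeps (50, 60, 70, 80 percent).
#'
#' @param rate percent in `[0, 100]`.
#' @return a [decoder_rates()] object.
#' @export
uniform_decoder_rates <- function(rate) {
  decoder_rates(rate, rate, rate, rate)
}

#' @export
print.decoder_rates <- function(x, ...) {
  cat(sprintf("<decoder_rates> TNR_HH=%g TPR_HR=%g TNR_RR=%g TPR_RH=%g (%%)\n",
              x$tnr_hh, x$tpr_hr, x$tnr_rr, x$tpr_rh))
  invisible(x)
}

#' Simulate one decoded anticipation of the next actor
#'
#' Stochastic stand-in for a single-trial ERP decoder observing the
#' anticipation of the upcoming trial: a sample \eqn{\epsilon \sim U(0,100)}
#' is compared with the context rate selected by the true consecutive-trial
#' pair (`a_prev`, `a_next`). A draw at or below the rate yields the correct
#' next actor; a draw above it yields the opposite (misclassified) actor.
#'
#' @param a_prev,a_next true actors (`"H"` or `"R"`) of the previous and the
#'   upcoming trial.
#' @param rates a [decoder_rates()] object.
#' @return the decoded actor, `"H"` or `"R"`.
#' @export
simulate_decoded_anticipation <- function(a_prev, a_next, rates) {
  stopifnot(inherits(rates, "decoder_rates"),
            a_prev %in% c("H", "R"), a_next %in% c("H", "R"))
  rate <- if (a_prev == "H") {
    if (a_next == "H") rates$tnr_hh else rates$tpr_hr
  } else {
    if (a_next == "R") rates$tnr_rr else rates$tpr_rh
  }
  eps <- stats::runif(1, 0, 100)
  if (eps <= rate) a_next else setdiff(c("H", "R"), a_next)
}

#' Minimum-jerk motion profile
#'
#' Normalized progress of a point-to-point movement of duration `t_f` that
#' minimizes jerk (the time derivative of acceleration):
#' \eqn{s(t) = 6u^5 - 15u^4 + 10u^3} with \eqn{u = t/t_f}. The profile starts
#' and ends with zero velocity and acceleration and is the standard model for
#' smooth, human-like robot end-effector motion; a position trajectory is
#' `x(t) = x_i + s(t) (x_f - x_i)`.
#'
#' @param t time(s) in seconds, each in `[0, t_f]`.
#' @param t_f movement duration in seconds (> 0); realistic tile-to-tile
#'   movements use `t_f` in 0.6-1.2 s.
#' @return unitless progress in `[0, 1]`, vectorized over `t`.
#' @export
#' @examples
#' minimum_jerk_profile(c(0, 0.5, 1), t_f = 1)
minimum_jerk_profile <- function(t, t_f) {
  stopifnot(t_f > 0)
  if (any(t < 0 | t > t_f)) stop("t must lie within [0, t_f]")
  u <- t / t_f
  6 * u^5 - 15 * u^4 + 10 * u^3
}
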