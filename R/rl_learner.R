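#' Learner parameters
#'
#' Parameters of the bandit-style assignment learner: per-trial learning rate
#' `alpha`, softmax temperature `tau`, and the constant reward credited to
#' the decoded action. The defaults `alpha = 0.05`, `tau = 0.1`,
#' `reward = 1` give a good trade-off between learning speed and robustness
#' (steep yet smooth learning curves) and are used unchanged in all bundled
#' simulations.
#'
#' @param alpha learning rate (> 0).
#' @param tau softmax temperature (> 0); small values sharpen the policy.
#' @param reward constant reward per decoded trial.
#' @return object of class `learner_config`.
#' @export
learner_config <- function(alpha = 0.05, tau = 0.1, reward = 1) {
  stopifnot(alpha > 0, tau > 0)
  structure(list(alpha = alpha, tau = tau, reward = reward),
            class = "learner_config")
}

#' Initialize the assignment memory
#'
#' A `n x 2` value matrix `q(s, a)` over subtasks and the two actions
#' (column `"H"`: leave the subtask to the human; column `"R"`: execute it),
#' initialized uniformly at zero so the initial policy is indifferent.
#'
#' @param n_subtasks number of subtasks.
#' @return numeric `n x 2` matrix of zeros with columns `H`, `R`.
#' @export
init_memory <- function(n_subtasks) {
  stopifnot(n_subtasks >= 1)
  matrix(0, n_subtasks, 2, dimnames = list(NULL, c("H", "R")))
}

#' Credit one decoded trial to the memory
#'
#' Adds `alpha * reward` to the single cell `q(subtask, action)`; every
#' other entry is untouched. The action is the *decoded* anticipation, so an
#' imperfect decoder credits the wrong cell at its misclassification rate,
#' and learning rests on the correct cell accumulating faster on average.
#'
#' @param q memory matrix from [init_memory()].
#' @param subtask subtask id of the trial being anticipated.
#' @param action decoded actor, `"H"` or `"R"` (or column index 1/2).
#' @param config a [learner_config()].
#' @return the updated memory.
#' @export
update_memory <- function(q, subtask, action, config = learner_config()) {
  stopifnot(is.matrix(q), ncol(q) == 2,
            subtask >= 1, subtask <= nrow(q), subtask == round(subtask))
  q[subtask, action] <- q[subtask, action] + config$alpha * config$reward
  q
}

#' Standardize the memory to zero mean and unit spread
#'
#' Applied after every trial update: `q' = (q - mean(q)) / SD(q)` over all
#' `2 n` entries, with the population SD (divide by `2 n`). Standardization
#' stops the values from growing without bound, which would otherwise let
#' the divergence between the two actions of a subtask deflate relative to
#' the softmax temperature. It is a strictly increasing affine map, so the
#' action preferences it encodes are unchanged. A memory with zero spread
#' (all entries equal, e.g. freshly initialized) is returned unchanged.
#'
#' @param q memory matrix.
#' @return standardized memory.
#' @export
standardize_memory <- function(q) {
  m <- mean(q)
  s <- sqrt(mean((q - m)^2))
  if (s == 0) return(q)
  (q - m) / s
}

#' Softmax policy of a memory
#'
#' Row-wise softmax at temperature `tau`:
#' \eqn{p(a_j \mid s_i) = e^{q(s_i,a_j)/\tau} / \sum_j e^{q(s_i,a_j)/\tau}}.
#' The row maximum is subtracted before exponentiation, so the policy is
#' finite for any finite memory and invariant to adding a constant to a row.
#'
#' @param q memory matrix.
#' @param tau softmax temperature (> 0).
#' @return `n x 2` matrix of probabilities; rows sum to 1.
#' @export
policy_from_memory <- function(q, tau = 0.1) {
  stopifnot(tau > 0)
  z <- q / tau
  z <- z - apply(z, 1, max)
  p <- exp(z)
  p / rowSums(p)
}

#' Choice accuracy of a policy against the true assignment
#'
#' The probability mass the policy places on the truly responsible agent,
#' averaged uniformly over all subtasks. A fresh (uniform) policy scores
#' exactly 0.5; a policy saturated on the correct actor for every subtask
#' scores 1. Set `argmax = TRUE` for the harder fraction-of-subtasks-argmax
#' variant (ties count 0.5).
#'
#' @param policy `n x 2` probability matrix from [policy_from_memory()].
#' @param assignment an [sample_assignment()] result over the same subtasks.
#' @param argmax use the argmax fraction instead of the probability mass.
#' @return accuracy in `[0, 1]`.
#' @export
choice_accuracy <- function(policy, assignment, argmax = FALSE) {
  stopifnot(inherits(assignment, "assignment"),
            nrow(policy) == assignment$n_subtasks)
  truth <- ifelse(seq_len(nrow(policy)) %in% assignment$human_set, 1L, 2L)
  p_true <- policy[cbind(seq_len(nrow(policy)), truth)]
  if (!argmax) return(mean(p_true))
  mean(ifelse(p_true > 0.5, 1, ifelse(p_true == 0.5, 0.5, 0)))
}
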