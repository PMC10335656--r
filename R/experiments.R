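#' Specification of one simulated collaboration study
#'
#' Bundles the task, learner, decoder operating point and run lengths of a
#' feasibility simulation. The defaults are the realistic baseline study:
#' 4 subtasks of which the human claims 2, episodes of 10 trials, the
#' empirical decoder rates, 200 episodes and 100 independent repetitions.
#'
#' @param task a [task_config()].
#' @param learner a [learner_config()].
#' @param rates a [decoder_rates()] object.
#' @param n_episodes episodes per repetition.
#' @param n_repetitions independent repetitions to average over.
#' @param reassignment_every if set, the human redraws their subtask choice
#'   every this many episodes (the learner is not told); `NULL` disables
#'   re-assignment.
#' @param seed master seed; per-repetition seeds are derived from it so the
#'   averaged curve is reproducible and repetitions are exchangeable.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(task = task_config(),
                     learner = learner_config(),
                     rates = empirical_decoder_rates(),
                     n_episodes = 200,
                     n_repetitions = 100,
                     reassignment_every = NULL,
                     seed = NULL) {
  stopifnot(inherits(task, "task_config"), inherits(learner, "learner_config"),
            inherits(rates, "decoder_rates"),
            n_episodes >= 1, n_repetitions >= 1)
  if (!is.null(reassignment_every)) {
    stopifnot(reassignment_every >= 1, reassignment_every < n_episodes)
  }
  structure(
    list(task = task, learner = learner, rates = rates,
         n_episodes = n_episodes, n_repetitions = n_repetitions,
         reassignment_every = reassignment_every, seed = seed),
    class = "sim_spec")
}

#' Run one repetition of a simulated collaboration
#'
#' One complete learning run from a fresh memory and a fresh hidden
#' assignment, using the current RNG state. Episodes are freshly sampled
#' sequences of subtask demands; within a repetition the running
#' previous-trial actor carries across episode boundaries, since the
#' collaboration is one long trial sequence. Per trial the learner pipeline
#' is: observe the true (previous, next) actor pair, sample the decoded
#' anticipation at the context rate, credit `alpha * reward` to the decoded
#' cell of the demanded subtask, standardize the memory, and record the
#' choice accuracy of the softmax policy against the current assignment.
#' The very first trial has no predecessor, so it is recorded at the fresh
#' uniform policy (accuracy exactly 0.5) without a decoder sample or update.
#' If `reassignment_every` is set, the human's subtask choice is redrawn at
#' each boundary while the memory is left untouched, and accuracy is always
#' scored against the current assignment.
#'
#' @param spec a [sim_spec()].
#' @return numeric vector of per-trial choice accuracies, length
#'   `n_episodes * episode_length`.
#' @export
run_repetition <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$task$n_subtasks
  o <- spec$task$episode_length
  alpha <- spec$learner$alpha
  tau <- spec$learner$tau
  reward <- spec$learner$reward
  # context rate lookup as fractions, indexed [a_prev, a_next] with 1=H, 2=R
  rate <- matrix(c(spec$rates$tnr_hh, spec$rates$tpr_rh,
                   spec$rates$tpr_hr, spec$rates$tnr_rr) / 100, 2, 2)

  assignment <- sample_assignment(spec$task)
  truth <- ifelse(seq_len(n) %in% assignment$human_set, 1L, 2L)
  q <- init_memory(n)
  acc <- numeric(spec$n_episodes * o)
  prev <- NA_integer_
  tr <- 0L
  rows <- seq_len(n)
  for (ep in seq_len(spec$n_episodes)) {
    if (!is.null(spec$reassignment_every) && ep > 1 &&
        (ep - 1) %% spec$reassignment_every == 0) {
      assignment <- sample_assignment(spec$task)
      truth <- ifelse(rows %in% assignment$human_set, 1L, 2L)
    }
    eseq <- sample_episode(spec$task)
    for (k in seq_len(o)) {
      tr <- tr + 1L
      s <- eseq[k]
      a_next <- truth[s]
      if (!is.na(prev)) {
        a_hat <- if (stats::runif(1) <= rate[prev, a_next]) a_next else 3L - a_next
        q[s, a_hat] <- q[s, a_hat] + alpha * reward
        q <- standardize_memory(q)
      }
      prev <- a_next
      p <- policy_from_memory(q, tau)
      acc[tr] <- mean(p[cbind(rows, truth)])
    }
  }
  acc
}

#' Run a simulation and average its learning curve over repetitions
#'
#' Executes `n_repetitions` independent [run_repetition()] runs, each from
#' its own derived seed, and aggregates the per-trial choice-accuracy traces
#' into a repetition-averaged learning curve, reported both per trial and
#' per episode (mean over each episode's trials).
#'
#' @param spec a [sim_spec()].
#' @return An object of class `learning_curve`: list with `mean_trial`,
#'   `sd_trial` (across repetitions), `mean_episode`, `sd_episode`, the raw
#'   `traces` matrix (trials x repetitions) and the `spec`.
#' @export
#' @examples
#' spec <- sim_spec(n_episodes = 20, n_repetitions = 5, seed = 1)
#' curve <- run_sim(spec)
#' head(curve$mean_episode)
run_sim <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(spec$seed)
  }
  rep_seeds <- sample.int(.Machine$integer.max, spec$n_repetitions)
  o <- spec$task$episode_length
  traces <- matrix(0, spec$n_episodes * o, spec$n_repetitions)
  for (r in seq_len(spec$n_repetitions)) {
    set.seed(rep_seeds[r])
    traces[, r] <- run_repetition(spec)
  }
  mean_trial <- rowMeans(traces)
  sd_trial <- apply(traces, 1, stats::sd)
  ep_of <- rep(seq_len(spec$n_episodes), each = o)
  structure(
    list(mean_trial = mean_trial,
         sd_trial = sd_trial,
         mean_episode = as.vector(tapply(mean_trial, ep_of, mean)),
         sd_episode = as.vector(tapply(sd_trial, ep_of, mean)),
         traces = traces,
         spec = spec),
    class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  ne <- x$spec$n_episodes
  cat(sprintf("<learning_curve> %d reps x %d episodes x %d trials\n",
              x$spec$n_repetitions, ne, x$spec$task$episode_length))
  cat(sprintf("  accuracy: episode 1 %.3f -> episode %d %.3f; 0.70 first crossed at episode %s\n",
              x$mean_episode[1], ne, x$mean_episode[ne],
              ifelse(is.na(episodes_to_threshold(x)), "never",
                     episodes_to_threshold(x))))
  invisible(x)
}

#' @export
plot.learning_curve <- function(x, ..., col = "steelblue") {
  ep <- seq_along(x$mean_episode)
  graphics::plot(ep, x$mean_episode, type = "l", lwd = 2, col = col,
                 ylim = c(0.4, 1), xlab = "episode",
                 ylab = "mean choice accuracy", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' First episode at which the mean curve reaches a threshold
#'
#' @param curve a [run_sim()] result.
#' @param threshold accuracy threshold in `[0, 1]`.
#' @return episode index of the first crossing, or `NA` if never reached.
#' @export
episodes_to_threshold <- function(curve, threshold = 0.7) {
  stopifnot(inherits(curve, "learning_curve"))
  idx <- which(curve$mean_episode >= threshold)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Scalability suite over task sizes and assignment balance
#'
#' Runs the baseline task (n = 4, m = 2) and three variants (n = 6 / m = 3,
#' n = 10 / m = 5, n = 10 / m = 2) under one shared configuration, and
#' summarizes learning speed as episodes to reach 70% choice accuracy.
#'
#' @param rates a [decoder_rates()] object.
#' @param learner a [learner_config()].
#' @param n_episodes,n_repetitions run lengths shared by all variants.
#' @param seed master seed; variant seeds are derived from it.
#' @return list with `curves` (named list of [run_sim()] results) and
#'   `summary` (data.frame: n_subtasks, n_human, episodes_to_70,
#'   final_accuracy).
#' @export
run_scalability_suite <- function(rates = empirical_decoder_rates(),
                                  learner = learner_config(),
                                  n_episodes = 200, n_repetitions = 100,
                                  seed = NULL) {
  variants <- list(n4_m2 = c(4, 2), n6_m3 = c(6, 3),
                   n10_m5 = c(10, 5), n10_m2 = c(10, 2))
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(variants))
  } else {
    as.list(seed + seq_along(variants))
  }
  curves <- Map(function(v, s) {
    run_sim(sim_spec(task = task_config(v[1], v[2]), learner = learner,
                     rates = rates, n_episodes = n_episodes,
                     n_repetitions = n_repetitions, seed = s))
  }, variants, seeds)
  summary <- data.frame(
    variant = names(variants),
    n_subtasks = vapply(variants, `[`, numeric(1), 1),
    n_human = vapply(variants, `[`, numeric(1), 2),
    episodes_to_70 = vapply(curves, function(cv) {
      as.numeric(episodes_to_threshold(cv, 0.7))
    }, numeric(1)),
    final_accuracy = vapply(curves, function(cv) {
      mean(cv$mean_episode[max(1, n_episodes - 49):n_episodes])
    }, numeric(1)),
    row.names = NULL)
  list(curves = curves, summary = summary)
}

#' Write a learning curve to CSV with a JSON spec snapshot
#'
#' Writes one row per trial (`trial`, `episode`, `mean_accuracy`,
#' `sd_accuracy`) to `path`, plus a JSON sidecar `<path>.json` capturing the
#' generating specification including the seed, so the exact run can be
#' reproduced.
#'
#' @param curve a [run_sim()] result.
#' @param path CSV output path.
#' @return invisibly, the paths written.
#' @export
write_results <- function(curve, path) {
  stopifnot(inherits(curve, "learning_curve"))
  o <- curve$spec$task$episode_length
  df <- data.frame(
    trial = seq_along(curve$mean_trial),
    episode = rep(seq_len(curve$spec$n_episodes), each = o),
    mean_accuracy = curve$mean_trial,
    sd_accuracy = curve$sd_trial)
  utils::write.csv(df, path, row.names = FALSE)
  spec <- curve$spec
  snapshot <- list(
    task = unclass(spec$task), learner = unclass(spec$learner),
    rates = unclass(spec$rates), n_episodes = spec$n_episodes,
    n_repetitions = spec$n_repetitions,
    reassignment_every = spec$reassignment_every, seed = spec$seed)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(snapshot, json_path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(c(csv = path, json = json_path))
}

#' Read back a learning curve written by [write_results()]
#'
#' @param path the CSV path given to [write_results()].
#' @return data.frame with columns `trial`, `episode`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
read_results <- function(path) {
  utils::read.csv(path)
}
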