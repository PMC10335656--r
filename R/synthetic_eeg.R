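#' Configuration for the synthetic ERP epoch generator
#'
#' Describes a simulated recording session: how many trials of each condition
#' to draw, and the shape of the class-dependent event-related component that
#' is superimposed on 1/f background noise for the conditions named in
#' `effect_classes`.
#'
#' Defaults emulate a single subject of an intermittent human-robot
#' collaboration session: 530 trials of robot continuation (`RR_pre`) versus
#' 212 trials of anticipated human takeover (`RH_pre`), a positive deflection
#' peaking 500 ms after robot-movement onset over fronto-central channels in
#' the takeover class only, and pink-noise background at realistic single-trial
#' amplitude.
#'
#' @param n_trials_per_class named integer vector mapping condition codes to
#'   trial counts; names must be a subset of [takeover_conditions()].
#' @param effect_amplitude peak amplitude of the class-dependent component
#'   (microvolts).
#' @param effect_latency peak latency of the component in ms after event onset.
#' @param effect_width temporal SD of the Gaussian component in ms.
#' @param effect_channels channels carrying the component; the remaining
#'   channels receive none.
#' @param effect_classes condition codes whose trials carry the component.
#' @param noise_scale per-channel SD of the 1/f background noise (microvolts).
#' @param alpha_amplitude amplitude of an optional 10 Hz oscillation with
#'   random phase per trial and channel (microvolts); 0 disables it.
#' @param srate sampling rate in samples/s.
#' @param t_start,t_end epoch window in ms relative to event onset.
#' @param channel_names channel labels; defaults to the 27-channel scalp
#'   montage of [default_montage()].
#' @param seed integer seed making the generated epochs bitwise reproducible;
#'   `NULL` uses the current RNG state.
#'
#' @return An object of class `erp_gen_config`.
#' @export
erp_gen_config <- function(n_trials_per_class = c(RR_pre = 530, RH_pre = 212),
                           effect_amplitude = 3,
                           effect_latency = 500,
                           effect_width = 60,
                           effect_channels = c("FP1", "FP2", "F3", "F4", "Fz",
                                               "FC1", "FC2", "Cz"),
                           effect_classes = "RH_pre",
                           noise_scale = 8,
                           alpha_amplitude = 2,
                           srate = 512,
                           t_start = -200,
                           t_end = 1200,
                           channel_names = default_montage(),
                           seed = NULL) {
  if (is.null(names(n_trials_per_class)) ||
      !all(names(n_trials_per_class) %in% takeover_conditions())) {
    stop("n_trials_per_class must be named by condition codes; see takeover_conditions()")
  }
  stopifnot(all(n_trials_per_class >= 1),
            effect_amplitude >= 0, noise_scale >= 0, alpha_amplitude >= 0,
            effect_width > 0, srate > 0, t_end > t_start)
  if (effect_latency < t_start || effect_latency > t_end) {
    stop("effect_latency (", effect_latency, " ms) lies outside the epoch window ",
         t_start, "..", t_end, " ms")
  }
  if (!all(effect_channels %in% channel_names)) {
    stop("effect_channels not in channel_names: ",
         paste(setdiff(effect_channels, channel_names), collapse = ", "))
  }
  structure(
    list(n_trials_per_class = n_trials_per_class,
         effect_amplitude = effect_amplitude,
         effect_latency = effect_latency,
         effect_width = effect_width,
         effect_channels = effect_channels,
         effect_classes = effect_classes,
         noise_scale = noise_scale,
         alpha_amplitude = alpha_amplitude,
         srate = srate, t_start = t_start, t_end = t_end,
         channel_names = channel_names,
         seed = seed),
    class = "erp_gen_config")
}

# Pink (1/f amplitude) noise, one column per series, unit SD per column.
# White noise is shaped in the frequency domain by 1/sqrt(f) and transformed
# back; the DC bin is zeroed.
pink_noise <- function(n_samples, n_series) {
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  f <- stats::mvfft(w)
  freq <- c(0, seq_len(n_samples - 1))
  freq <- pmin(freq, n_samples - freq)  # two-sided spectrum
  scale <- ifelse(freq == 0, 0, 1 / sqrt(freq))
  x <- Re(stats::mvfft(f * scale, inverse = TRUE)) / n_samples
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(x, 2, sds, "/")
}

#' Generate labelled synthetic ERP epochs
#'
#' Draws an [epoch_set] according to an [erp_gen_config()]: every trial is
#' 1/f ("pink") background noise, independent across channels, plus an
#' optional 10 Hz oscillation with uniformly random phase; trials of the
#' conditions in `effect_classes` additionally carry a Gaussian-in-time
#' positive deflection peaking at `effect_latency` on `effect_channels`.
#' With `effect_amplitude = 0` all conditions are exchangeable and a
#' downstream decoder can only perform at chance.
#'
#' @param config an [erp_gen_config()].
#' @return an [epoch_set] with `sum(n_trials_per_class)` trials in
#'   class-blocked order.
#' @export
#' @examples
#' cfg <- erp_gen_config(n_trials_per_class = c(RR_pre = 20, RH_pre = 10),
#'                       seed = 1)
#' ep <- generate_epochs(cfg)
#' dim(ep$data)
generate_epochs <- function(config) {
  stopifnot(inherits(config, "erp_gen_config"))
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(config$seed)
  }
  t_ms <- with(config, t_start + (0:floor((t_end - t_start) / 1000 * srate)) / srate * 1000)
  n_samp <- length(t_ms)
  n_chan <- length(config$channel_names)
  labels <- rep(names(config$n_trials_per_class), config$n_trials_per_class)
  n_trials <- length(labels)

  data <- array(0, dim = c(n_trials, n_chan, n_samp))
  bump <- config$effect_amplitude *
    exp(-(t_ms - config$effect_latency)^2 / (2 * config$effect_width^2))
  has_effect <- labels %in% config$effect_classes
  eff_chan <- config$channel_names %in% config$effect_channels

  for (ch in seq_len(n_chan)) {
    x <- t(pink_noise(n_samp, n_trials)) * config$noise_scale  # trials x samples
    if (config$alpha_amplitude > 0) {
      phase <- stats::runif(n_trials, 0, 2 * pi)
      x <- x + config$alpha_amplitude *
        sin(outer(phase, 2 * pi * 10 * t_ms / 1000, "+"))
    }
    if (eff_chan[ch] && any(has_effect)) {
      x[has_effect, ] <- x[has_effect, ] + rep(bump, each = sum(has_effect))
    }
    data[, ch, ] <- x
  }
  epoch_set(data, config$srate, config$t_start, labels, config$channel_names)
}
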