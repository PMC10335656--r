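#' Time-window specification for anticipation decoding
#'
#' The fifteen per-channel feature windows: four contiguous 50 ms windows
#' covering 400-600 ms (fine-grained coverage of the anticipatory component
#' near 500 ms) followed by eleven overlapping 100 ms windows with a 50 ms hop
#' covering 0-600 ms (coarse coverage of the whole ERP time course). Windows
#' are half-open `[start, end)` on the epoch's sample grid.
#'
#' @return data.frame with columns `start`, `end` (ms) and 15 rows.
#' @export
decoding_windows <- function() {
  short <- data.frame(start = seq(400, 550, by = 50))
  short$end <- short$start + 50
  long <- data.frame(start = seq(0, 500, by = 50))
  long$end <- long$start + 100
  rbind(short, long)
}

#' Extract windowed time-domain features from epochs
#'
#' Per trial and channel, the time series is first baseline-normalized by
#' subtracting its mean over 0-800 ms (removing DC fluctuations), then
#' averaged within each of the fifteen windows of [decoding_windows()].
#' Features are concatenated channel-major: all 15 windows of channel 1, then
#' channel 2, and so on; with 27 channels this yields the 405-dimensional
#' feature vector used by the anticipation decoder. No sample at or after
#' 600 ms enters any window average, so information from a following trial
#' (inter-trial intervals can be as short as 600 ms) cannot leak into the
#' features.
#'
#' @param epochs an [epoch_set] whose window covers at least 0-800 ms.
#' @param windows window table as from [decoding_windows()].
#' @param baseline two-element numeric, the normalization period in ms.
#'
#' @return An object of class `feature_matrix`: list with `values`
#'   (`trials x (channels * windows)` matrix), `window_spec`, `channel_names`
#'   and `labels` carried over from the epochs.
#' @export
#' @examples
#' cfg <- erp_gen_config(n_trials_per_class = c(RR_pre = 8, RH_pre = 8), seed = 1)
#' fm <- extract_features(generate_epochs(cfg))
#' dim(fm$values)  # 16 x 405
extract_features <- function(epochs, windows = decoding_windows(),
                             baseline = c(0, 800)) {
  stopifnot(inherits(epochs, "epoch_set"))
  t_ms <- epoch_times(epochs)
  if (t_ms[1] > 0 || t_ms[length(t_ms)] < baseline[2]) {
    stop("epoch window (", t_ms[1], "..", t_ms[length(t_ms)],
         " ms) must cover the baseline period ", baseline[1], "-", baseline[2], " ms")
  }
  bad <- which(apply(epochs$data, 2, function(ch) any(!is.finite(ch))))
  if (length(bad) > 0) {
    stop("non-finite values in channel(s): ",
         paste(epochs$channel_names[bad], collapse = ", "))
  }
  n_trials <- dim(epochs$data)[1]
  n_chan <- dim(epochs$data)[2]
  n_win <- nrow(windows)

  base_idx <- which(t_ms >= baseline[1] & t_ms < baseline[2])
  win_idx <- lapply(seq_len(n_win), function(w) {
    idx <- which(t_ms >= windows$start[w] & t_ms < windows$end[w])
    if (length(idx) == 0) {
      stop("window ", windows$start[w], "-", windows$end[w],
           " ms contains no samples at srate ", epochs$srate)
    }
    idx
  })

  values <- matrix(0, n_trials, n_chan * n_win)
  for (ch in seq_len(n_chan)) {
    x <- epochs$data[, ch, , drop = TRUE]
    if (n_trials == 1) x <- matrix(x, nrow = 1)
    x <- x - rowMeans(x[, base_idx, drop = FALSE])
    for (w in seq_len(n_win)) {
      values[, (ch - 1) * n_win + w] <- rowMeans(x[, win_idx[[w]], drop = FALSE])
    }
  }
  colnames(values) <- paste(rep(epochs$channel_names, each = n_win),
                            rep(paste0(windows$start, "-", windows$end), n_chan),
                            sep = ".")
  structure(
    list(values = values, window_spec = windows,
         channel_names = epochs$channel_names, labels = epochs$labels),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%d channels x %d windows)\n",
              nrow(x$values), ncol(x$values), length(x$channel_names),
              nrow(x$window_spec)))
  invisible(x)
}
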