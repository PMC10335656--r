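#' Condition codes for takeover situations
#'
#' The eight condition labels arising from crossing the four takeover
#' situations (HH, HR, RR, RH: previous actor followed by next actor,
#' H = human, R = robot) with the epoch position relative to the situation
#' (`pre` = the trial before the possible takeover, `post` = the trial after).
#'
#' @return Character vector of the eight condition codes.
#' @export
#' @examples
#' takeover_conditions()
takeover_conditions <- function() {
  as.vector(outer(c("HH", "HR", "RR", "RH"), c("pre", "post"), paste, sep = "_"))
}

#' Default 27-channel scalp montage
#'
#' Scalp electrode labels of an extended 10-20 montage after removing the
#' three EOG leads and the two mastoid reference electrodes (TP9/TP10),
#' leaving the 27 channels that enter feature extraction.
#'
#' @return Character vector of 27 channel labels.
#' @export
default_montage <- function() {
  c("FP1", "FP2", "F3", "F4", "F7", "F8", "Fz",
    "FC1", "FC2", "FC5", "FC6",
    "C3", "C4", "Cz", "T7", "T8",
    "CP1", "CP2", "CP5", "CP6",
    "P3", "P4", "P7", "P8", "Pz",
    "O1", "O2")
}

#' Construct a set of EEG epochs
#'
#' Container for epoched multichannel EEG-like data: a `trials x channels x
#' samples` amplitude array (in microvolts) together with its sampling rate,
#' the epoch start time relative to event onset, per-trial condition labels,
#' and channel names.
#'
#' The sample grid convention is `t_k = t_start + k / srate * 1000` ms for
#' `k = 0, 1, ...`, including the sample at `t_start` and every sample with
#' `t_k <= t_end`. A window of -200..1200 ms at 512 Hz therefore holds
#' `floor(1400 / 1000 * 512) + 1 = 717` samples.
#'
#' @param data numeric array `trials x channels x samples` (microvolts).
#' @param srate sampling rate in samples/s.
#' @param t_start epoch start in ms relative to event onset (negative for
#'   pre-event baseline).
#' @param labels character vector of per-trial condition codes, each one of
#'   [takeover_conditions()].
#' @param channel_names character vector of channel labels, one per channel.
#'
#' @return An object of class `epoch_set` with elements `data`, `srate`,
#'   `t_start`, `labels`, `channel_names`.
#' @seealso [epoch_times()], [generate_epochs()], [extract_features()]
#' @export
epoch_set <- function(data, srate, t_start, labels, channel_names) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(labels) != dim(data)[1]) {
    stop("length(labels) [", length(labels), "] must equal the number of trials [",
         dim(data)[1], "]")
  }
  if (length(channel_names) != dim(data)[2]) {
    stop("length(channel_names) must equal the number of channels")
  }
  bad <- setdiff(unique(labels), takeover_conditions())
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(data = data, srate = srate, t_start = t_start,
         labels = as.character(labels),
         channel_names = as.character(channel_names)),
    class = "epoch_set")
}

#' Time axis of an epoch set
#'
#' @param x an `epoch_set`.
#' @return numeric vector of sample times in ms relative to event onset.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  n <- dim(x$data)[3]
  x$t_start + (seq_len(n) - 1) / x$srate * 1000
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  t <- epoch_times(x)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples\n", d[1], d[2], d[3]))
  cat(sprintf("  window %g..%g ms @ %g Hz\n", t[1], t[length(t)], x$srate))
  tab <- table(x$labels)
  cat("  trials per condition: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset trials of an epoch set
#'
#' @param x an `epoch_set`.
#' @param i trial index (logical or integer).
#' @param ... unused.
#' @return an `epoch_set` with the selected trials.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[i, , , drop = FALSE], x$srate, x$t_start,
            x$labels[i], x$channel_names)
}

#' Write/read an epoch set as a single container file
#'
#' Serializes the named fields (`data`, `srate`, `t_start`, `labels`,
#' `channel_names`) to one file using R's native serialization, so a set of
#' epochs round-trips bitwise.
#'
#' @param x an `epoch_set`.
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   `epoch_set`.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  saveRDS(unclass(x), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  epoch_set(obj$data, obj$srate, obj$t_start, obj$labels, obj$channel_names)
}
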