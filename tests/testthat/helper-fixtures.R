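# Shared fixtures, all built in code at test time.

# Epoch set with fully controlled sample values: `fill` is a function
# (trial, channel, t_ms) -> amplitude, evaluated on the package's time grid.
make_epochs <- function(n_trials = 2, channel_names = c("Fz", "Cz"),
                        srate = 100, t_start = -200, t_end = 1000,
                        labels = rep("RR_pre", n_trials),
                        fill = function(trial, channel, t) 0 * t) {
  n_samp <- floor((t_end - t_start) / 1000 * srate) + 1
  t_ms <- t_start + (seq_len(n_samp) - 1) / srate * 1000
  data <- array(0, c(n_trials, length(channel_names), n_samp))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_along(channel_names)) {
      data[tr, ch, ] <- fill(tr, ch, t_ms)
    }
  }
  epoch_set(data, srate, t_start, labels, channel_names)
}

# Two-class Gaussian feature sample with shared diagonal covariance.
make_gaussian_classes <- function(n1, n2, mu1, mu2, sd = 1) {
  p <- length(mu1)
  x <- rbind(
    matrix(stats::rnorm(n1 * p, sd = sd), n1, p, byrow = TRUE) +
      matrix(mu1, n1, p, byrow = TRUE),
    matrix(stats::rnorm(n2 * p, sd = sd), n2, p, byrow = TRUE) +
      matrix(mu2, n2, p, byrow = TRUE))
  list(x = x, y = rep(c("a", "b"), c(n1, n2)))
}

# The symmetric identity-covariance textbook case: lambda = 1 forces
# pooled covariance 2I, means (1,0) vs (-1,0) give w = (1, 0), b = 0.
symmetric_rlda_fit <- function() {
  x <- rbind(c(2, 1), c(0, -1), c(1, 2), c(1, -2),   # class a, mean (1, 0)
             c(-2, 1), c(0, 1), c(-1, -2), c(-1, 0)) # class b, mean (-1, 0)
  y <- rep(c("a", "b"), each = 4)
  stopifnot(all(colMeans(x[1:4, ]) == c(1, 0)),
            all(colMeans(x[5:8, ]) == c(-1, 0)))
  fit_rlda(x, y, lambda = 1)
}
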