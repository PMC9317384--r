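#' Difference-of-gammas evoked-response kernel
#'
#' Canonical pattern-onset VEP waveform model: a positive gamma pulse peaking
#' at \code{peak_latency} followed by a weighted negative gamma lobe, rescaled
#' so the kernel maximum is exactly 1. The kernel is identically zero for
#' \code{t <= 0}, so a pre-stimulus baseline window is signal-free by
#' construction.
#'
#' Each lobe is the unit-peak gamma pulse
#' \deqn{g(t; t_p, p) = (t/t_p)^p \exp\{-p\,(t/t_p - 1)\},}
#' which attains its maximum 1 at \eqn{t = t_p}; the shape exponent \eqn{p}
#' controls the width.
#'
#' @param t numeric vector of times in seconds (may include negative values).
#' @param peak_latency time of the positive peak, seconds.
#' @param shape1,shape2 gamma shape exponents of the positive and negative lobe.
#' @param undershoot_latency peak time of the negative lobe, seconds.
#' @param undershoot_weight weight of the negative lobe relative to the
#'   positive one, in \[0, 1).
#' @return numeric vector of kernel values, unit peak amplitude (unitless;
#'   multiply by an amplitude in µV to obtain a response).
#' @examples
#' t <- seq(-0.2, 0.4, by = 0.002)
#' k <- vep_kernel(t)
#' max(k)            # 1
#' all(k[t <= 0] == 0)
#' @export
vep_kernel <- function(t, peak_latency = 0.10, shape1 = 8,
                       undershoot_latency = 0.22, shape2 = 12,
                       undershoot_weight = 0.35) {
  stopifnot(peak_latency > 0, undershoot_latency > peak_latency,
            undershoot_weight >= 0, undershoot_weight < 1)
  raw <- function(x) {
    pos <- ifelse(x > 0, (x / peak_latency)^shape1 *
                    exp(-shape1 * (x / peak_latency - 1)), 0)
    neg <- ifelse(x > 0, (x / undershoot_latency)^shape2 *
                    exp(-shape2 * (x / undershoot_latency - 1)), 0)
    pos - undershoot_weight * neg
  }
  # unit-peak normalization; the peak sits near (slightly before) peak_latency
  pk <- stats::optimize(raw, c(0, undershoot_latency), maximum = TRUE)$maximum
  raw(t) / raw(pk)
}

#' White Gaussian noise matrix
#'
#' @param n_samples samples per column.
#' @param n_series number of independent series (columns).
#' @param sd standard deviation, µV.
#' @return \code{n_samples x n_series} matrix.
#' @keywords internal
noise_white <- function(n_samples, n_series, sd = 1) {
  matrix(stats::rnorm(n_samples * n_series, sd = sd), n_samples, n_series)
}

#' 1/f + white noise by spectral shaping
#'
#' Shapes white Gaussian noise in the frequency domain with the amplitude
#' response \eqn{\sqrt{f_{knee}/f + 1}} (power \eqn{\propto f_{knee}/f + 1}:
#' pink below the knee, flat above; DC removed), with independent random
#' phase per series, then rescales every series to the requested standard
#' deviation. Columns are independent.
#'
#' @inheritParams noise_white
#' @param sample_rate sampling rate in Hz (sets the frequency axis of the
#'   spectral shaping).
#' @param knee frequency (Hz) below which the 1/f component dominates.
#' @return \code{n_samples x n_series} matrix with per-column sd \code{sd}.
#' @keywords internal
noise_one_over_f_plus_white <- function(n_samples, n_series, sd = 1,
                                        sample_rate = 500, knee = 10) {
  spec <- stats::mvfft(noise_white(n_samples, n_series))
  f <- seq_len(n_samples) - 1
  f <- pmin(f, n_samples - f) * sample_rate / n_samples
  amp <- ifelse(f > 0, sqrt(knee / f + 1), 0)
  out <- Re(stats::mvfft(spec * amp, inverse = TRUE)) / n_samples
  cm <- colMeans(out)
  col_sd <- sqrt(pmax((colSums(out * out) - n_samples * cm * cm) /
                        (n_samples - 1), 0))
  out * rep(sd / col_sd, each = n_samples)
}
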