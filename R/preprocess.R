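#' Epoch a continuous recording around stimulus onsets
#'
#' Cuts a continuous multichannel record into trials aligned to stimulus
#' onsets. Sample indexing is half-open \code{[start, end)} and the sample at
#' \code{t = 0} is onset sample itself. Onsets whose full window does not fit
#' inside the record are dropped with a warning.
#'
#' @param x a \code{vep_continuous} object, or a channels x samples matrix
#'   (then \code{sample_rate}, \code{channels}, \code{eye} must be given).
#' @param onsets stimulus onset times, seconds from record start.
#' @param window epoch limits in seconds relative to onset, default
#'   \code{c(-0.2, 0.4)}.
#' @param sample_rate,channels,eye,subject_id metadata when \code{x} is a
#'   bare matrix.
#' @return a \code{\link{vep_epochs}} object.
#' @export
epoch <- function(x, onsets = NULL, window = c(-0.2, 0.4),
                  sample_rate = NULL, channels = NULL, eye = "OS",
                  subject_id = "anon") {
  if (inherits(x, "vep_continuous")) {
    if (is.null(onsets)) onsets <- x$onsets
    sample_rate <- x$sample_rate; channels <- x$channels; eye <- x$eye
    x <- x$signal
  }
  stopifnot(is.matrix(x), !is.null(sample_rate), !is.null(onsets))
  if (is.null(channels)) channels <- rownames(x)
  n_samp <- round((window[2] - window[1]) * sample_rate)
  rel0 <- round(window[1] * sample_rate)
  n_total <- ncol(x)
  starts <- round(onsets * sample_rate) + 1L + rel0  # 1-based first sample
  ok <- starts >= 1L & (starts + n_samp - 1L) <= n_total
  if (any(!ok))
    warning(sum(!ok), " onset(s) too close to the record edge; trial(s) dropped")
  if (!any(ok)) stop("no usable trials: every onset window falls outside the record")
  starts <- starts[ok]
  dat <- array(NA_real_, dim = c(length(starts), nrow(x), n_samp))
  for (i in seq_along(starts))
    dat[i, , ] <- x[, starts[i]:(starts[i] + n_samp - 1L)]
  vep_epochs(subject_id, eye, sample_rate, window, dat, channels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window (closed interval on the sample grid).
#'
#' @param epochs a \code{\link{vep_epochs}}.
#' @param baseline baseline window in seconds, default \code{c(-0.05, 0)}.
#' @return baseline-corrected \code{\link{vep_epochs}}.
#' @export
baseline_correct <- function(epochs, baseline = c(-0.05, 0)) {
  stopifnot(inherits(epochs, "vep_epochs"))
  idx <- which(epochs$times >= baseline[1] & epochs$times <= baseline[2])
  if (length(idx) == 0)
    stop("baseline window contains no samples of the epoch window")
  bl <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

# Blackman-windowed sinc low-pass kernel; odd length, unit DC gain
blackman_sinc_kernel <- function(cutoff, sample_rate, transition) {
  m <- ceiling(5.5 * sample_rate / transition)      # Blackman transition width
  if (m %% 2 == 0) m <- m + 1
  n <- seq_len(m) - 1
  mid <- (m - 1) / 2
  x <- n - mid
  h <- ifelse(x == 0, 2 * cutoff / sample_rate,
              sin(2 * pi * cutoff / sample_rate * x) / (pi * x))
  w <- 0.42 - 0.5 * cos(2 * pi * n / (m - 1)) + 0.08 * cos(4 * pi * n / (m - 1))
  h <- h * w
  h / sum(h)
}

#' High-pass filter a continuous recording
#'
#' Blackman-windowed sinc FIR high-pass (spectral inversion of the low-pass
#' kernel), applied zero-phase: the kernel is symmetric and the group delay is
#' compensated exactly. Used to remove slow drifts before epoching.
#'
#' @param x a \code{vep_continuous}, or a channels x samples matrix plus
#'   \code{sample_rate}.
#' @param cutoff -6 dB cutoff, Hz (default 0.1).
#' @param transition transition bandwidth, Hz (default 0.2; sets the kernel
#'   length, about \code{5.5 * sample_rate / transition} samples).
#' @param sample_rate Hz, when \code{x} is a matrix.
#' @return filtered object of the same shape as the input.
#' @export
highpass_filter <- function(x, cutoff = 0.1, transition = 0.2,
                            sample_rate = NULL) {
  if (inherits(x, "vep_continuous")) {
    x$signal <- highpass_filter(x$signal, cutoff, transition, x$sample_rate)
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(sample_rate))
  h <- blackman_sinc_kernel(cutoff, sample_rate, transition)
  if (ncol(x) <= length(h))
    stop("record (", ncol(x), " samples) is shorter than the filter kernel (",
         length(h), " samples); lengthen the record or widen 'transition'")
  half <- (length(h) - 1) / 2
  out <- x
  for (ch in seq_len(nrow(x))) {
    # high-pass = identity minus zero-phase low-pass
    lp <- stats::convolve(x[ch, ], rev(h), type = "open")
    out[ch, ] <- x[ch, ] - lp[(half + 1):(half + ncol(x))]
  }
  out
}

#' Low-pass filter a VEP waveform
#'
#' Butterworth IIR low-pass (default 4th order) applied zero-phase
#' (forward-backward, \code{signal::filtfilt}), the standard smoothing step
#' before reading off evoked components.
#'
#' @param x a \code{\link{vep_waveform}}, a \code{\link{vep_epochs}} (filtered
#'   trial by trial), or a channels x samples matrix plus \code{sample_rate}.
#' @param cutoff cutoff frequency, Hz (default 35). Must be below Nyquist.
#' @param order filter order (default 4).
#' @param sample_rate Hz, when \code{x} is a matrix.
#' @return filtered object of the same class as the input.
#' @export
lowpass_filter <- function(x, cutoff = 35, order = 4, sample_rate = NULL) {
  if (inherits(x, "vep_waveform")) {
    x$data <- lowpass_filter(x$data, cutoff, order, x$sample_rate)
    return(x)
  }
  if (inherits(x, "vep_epochs")) {
    for (tr in seq_len(dim(x$data)[1]))
      x$data[tr, , ] <- lowpass_filter(matrix(x$data[tr, , ],
                                              dim(x$data)[2]),
                                       cutoff, order, x$sample_rate)
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(sample_rate))
  if (cutoff >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency ", sample_rate / 2, " Hz")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
}

#' Average epochs into a VEP waveform
#'
#' @param epochs a \code{\link{vep_epochs}}.
#' @return a \code{\link{vep_waveform}} (arithmetic mean across trials).
#' @export
average_trials <- function(epochs) {
  stopifnot(inherits(epochs, "vep_epochs"))
  m <- colMeans(epochs$data, dims = 1)
  vep_waveform(epochs$subject_id, epochs$eye, epochs$sample_rate,
               epochs$window, m, epochs$channels,
               n_trials = dim(epochs$data)[1])
}

#' Re-reference EEG data
#'
#' The downstream differential activity (left minus right electrode means
#' over equal-sized sets) is invariant to any common reference, so
#' re-referencing is optional; it is offered for completeness and for
#' inspecting single-channel waveforms.
#'
#' @param x \code{\link{vep_epochs}} or \code{\link{vep_waveform}}.
#' @param reference \code{"none"}, \code{"average"} (common average) or a
#'   channel label (e.g. \code{"CZ"}).
#' @return re-referenced object of the same class.
#' @export
rereference <- function(x, reference = "none") {
  if (identical(reference, "none")) return(x)
  if (inherits(x, "vep_waveform")) {
    ref <- if (identical(reference, "average")) colMeans(x$data)
           else {
             i <- match(reference, x$channels)
             if (is.na(i)) stop("reference channel '", reference, "' not found")
             x$data[i, ]
           }
    x$data <- sweep(x$data, 2, ref)
    return(x)
  }
  stopifnot(inherits(x, "vep_epochs"))
  for (tr in seq_len(dim(x$data)[1])) {
    sl <- matrix(x$data[tr, , ], dim(x$data)[2])
    ref <- if (identical(reference, "average")) colMeans(sl)
           else {
             i <- match(reference, x$channels)
             if (is.na(i)) stop("reference channel '", reference, "' not found")
             sl[i, ]
           }
    x$data[tr, , ] <- sweep(sl, 2, ref)
  }
  x
}

#' Standard epoch-to-waveform preprocessing
#'
#' Baseline correction, trial averaging, then zero-phase 35 Hz low-pass —
#' the default path from raw epochs to the per-eye VEP used by the
#' misrouting statistics. The low-pass is applied after averaging by
#' default; set \code{lowpass_before_average = TRUE} to filter single trials
#' instead (both orders commute for this linear chain up to edge effects).
#'
#' @param epochs a \code{\link{vep_epochs}}.
#' @param baseline baseline window, seconds.
#' @param lowpass low-pass cutoff in Hz, or \code{NA} to skip.
#' @param reference see \code{\link{rereference}}.
#' @param lowpass_before_average filter trials before averaging.
#' @return a \code{\link{vep_waveform}}.
#' @export
preprocess_epochs <- function(epochs, baseline = c(-0.05, 0), lowpass = 35,
                              reference = "none",
                              lowpass_before_average = FALSE) {
  x <- rereference(epochs, reference)
  x <- baseline_correct(x, baseline)
  if (lowpass_before_average && !is.na(lowpass))
    x <- lowpass_filter(x, cutoff = lowpass)
  w <- average_trials(x)
  if (!lowpass_before_average && !is.na(lowpass))
    w <- lowpass_filter(w, cutoff = lowpass)
  w
}
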