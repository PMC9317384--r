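#' Epoched VEP recording
#'
#' Container for per-eye, per-trial EEG epochs. Sample times follow the
#' half-open convention \code{[start, end)}: the number of samples is
#' \code{round((end - start) * sample_rate)} and the sample at \code{t = 0}
#' (stimulus onset) belongs to the epoch.
#'
#' @param subject_id subject identifier.
#' @param eye \code{"OS"} (left) or \code{"OD"} (right).
#' @param sample_rate Hz.
#' @param window epoch limits, seconds, \code{c(start, end)}.
#' @param data numeric array trials x channels x samples, µV.
#' @param channels character vector of unique channel labels.
#' @return object of class \code{vep_epochs}.
#' @export
vep_epochs <- function(subject_id, eye, sample_rate, window, data, channels) {
  eye <- match.arg(eye, c("OS", "OD"))
  if (length(dim(data)) != 3)
    stop("'data' must be a trials x channels x samples array")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (dim(data)[2] != length(channels))
    stop("channel dimension does not match 'channels'")
  n_expect <- round((window[2] - window[1]) * sample_rate)
  if (dim(data)[3] != n_expect)
    stop(sprintf("expected %d samples for window [%g, %g) at %g Hz, got %d",
                 n_expect, window[1], window[2], sample_rate, dim(data)[3]))
  if (dim(data)[1] < 1) stop("at least one trial required")
  structure(list(subject_id = subject_id, eye = eye,
                 sample_rate = sample_rate, window = window,
                 data = data, channels = channels,
                 times = epoch_times(window, sample_rate)),
            class = "vep_epochs")
}

# half-open [start, end) sample-time axis; t = 0 is on the grid
epoch_times <- function(window, sample_rate) {
  n <- round((window[2] - window[1]) * sample_rate)
  (round(window[1] * sample_rate) + seq_len(n) - 1) / sample_rate
}

#' @export
print.vep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VEP epochs: %s %s, %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              x$subject_id, x$eye, d[1], d[2], d[3], x$sample_rate,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Trial-averaged VEP waveform
#'
#' @inheritParams vep_epochs
#' @param data channels x samples matrix, µV.
#' @param n_trials number of trials averaged.
#' @return object of class \code{vep_waveform}.
#' @export
vep_waveform <- function(subject_id, eye, sample_rate, window, data, channels,
                         n_trials = NA_integer_) {
  if (!is.matrix(data) || nrow(data) != length(channels))
    stop("'data' must be a channels x samples matrix")
  structure(list(subject_id = subject_id, eye = eye,
                 sample_rate = sample_rate, window = window,
                 data = data, channels = channels,
                 times = epoch_times(window, sample_rate),
                 n_trials = n_trials),
            class = "vep_waveform")
}

#' @export
print.vep_waveform <- function(x, ...) {
  cat(sprintf("VEP waveform: %s %s, %d channels x %d samples @ %g Hz (mean of %s trials)\n",
              x$subject_id, x$eye, nrow(x$data), ncol(x$data), x$sample_rate,
              x$n_trials))
  invisible(x)
}

#' Occipital electrode montage
#'
#' Two disjoint, equally sized sets of electrodes of interest over the left
#' (OL) and right (OR) occipital pole, used to form the interhemispheric
#' differential activity OL - OR.
#'
#' @param left_set,right_set character vectors of channel labels.
#' @return object of class \code{vep_montage}.
#' @export
vep_montage <- function(left_set, right_set) {
  if (length(left_set) != length(right_set))
    stop("left and right electrode sets must have equal size")
  if (length(intersect(left_set, right_set)) > 0)
    stop("left and right electrode sets must be disjoint")
  if (anyDuplicated(left_set) || anyDuplicated(right_set))
    stop("electrode sets must not contain duplicates")
  structure(list(left_set = left_set, right_set = right_set),
            class = "vep_montage")
}

#' @export
print.vep_montage <- function(x, ...) {
  cat("Montage: OL =", paste(x$left_set, collapse = " "), "\n")
  cat("         OR =", paste(x$right_set, collapse = " "), "\n")
  invisible(x)
}

#' Read / write a montage as YAML
#'
#' The file holds two lists, \code{left_set} and \code{right_set}.
#'
#' @param path file path.
#' @return \code{read_montage}: a \code{\link{vep_montage}}.
#' @export
read_montage <- function(path) {
  y <- yaml::read_yaml(path)
  vep_montage(unlist(y$left_set), unlist(y$right_set))
}

#' @rdname read_montage
#' @param montage a \code{\link{vep_montage}}.
#' @export
write_montage <- function(montage, path) {
  yaml::write_yaml(list(left_set = as.list(montage$left_set),
                        right_set = as.list(montage$right_set)), path)
  invisible(path)
}
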