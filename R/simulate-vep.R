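#' Configuration for the lateralized VEP simulator
#'
#' Describes a cohort of monocular pattern-onset VEP recordings with known
#' routing ground truth. Under misrouting (the albinism situation, where most
#' fibers of each eye cross at the chiasm) the hemisphere contralateral to the
#' stimulated eye receives the larger share of the evoked response; under
#' normal routing both hemispheres respond equally.
#'
#' The per-trial model for eye \eqn{e} and channel in hemisphere \eqn{h} is
#' \deqn{x(t) = A\, w(e,h)\, k(t) + \epsilon(t),}
#' with \eqn{k} the unit-peak kernel of \code{\link{vep_kernel}},
#' \eqn{w = (1 \pm a)/2} for misrouted routing (\eqn{+} contralateral,
#' \eqn{-} ipsilateral, laterality flipping between eyes) and \eqn{w = 1/2}
#' for both hemispheres under normal routing.
#'
#' @param n_subjects number of subjects.
#' @param routing \code{"misrouted"} or \code{"normal"}.
#' @param asymmetry lateralization index \eqn{a} in \[0, 1\]; 0 means no
#'   interhemispheric difference.
#' @param evoked_amplitude peak evoked amplitude \eqn{A}, µV.
#' @param noise_sd per-trial, per-channel noise standard deviation, µV.
#' @param noise_model \code{"one_over_f_plus_white"} (default) or
#'   \code{"white"}.
#' @param n_trials_mean,n_trials_sd mean and SD of the per-eye trial count;
#'   counts are drawn from a normal, rounded and floored at 1.
#' @param sample_rate sampling rate, Hz.
#' @param epoch_window epoch limits in seconds relative to stimulus onset,
#'   half-open \code{[start, end)}. Must contain the baseline window
#'   \code{[-0.05, 0]} and the analysis windows \code{[0.07, 0.1]} and
#'   \code{[0.07, 0.3]}.
#' @param peak_latency kernel peak latency, seconds.
#' @param n_channels_per_hemi electrodes per hemisphere (labels
#'   \code{OL1..}, \code{OR1..}).
#' @param seed integer seed; the cohort RNG is seeded once and per-subject
#'   substreams are derived deterministically from it.
#' @return a list of class \code{vep_sim_config}.
#' @export
vep_sim_config <- function(n_subjects = 8,
                           routing = c("misrouted", "normal"),
                           asymmetry = 0.5,
                           evoked_amplitude = 5,
                           noise_sd = 20,
                           noise_model = c("one_over_f_plus_white", "white"),
                           n_trials_mean = 498,
                           n_trials_sd = 51,
                           sample_rate = 500,
                           epoch_window = c(-0.2, 0.4),
                           peak_latency = 0.10,
                           n_channels_per_hemi = 9,
                           seed = 1L) {
  routing <- match.arg(routing)
  noise_model <- match.arg(noise_model)
  if (!is.numeric(asymmetry) || length(asymmetry) != 1 ||
      asymmetry < 0 || asymmetry > 1)
    stop("'asymmetry' must be a single number in [0, 1]")
  if (length(epoch_window) != 2 || epoch_window[1] >= epoch_window[2])
    stop("'epoch_window' must be increasing [start, end)")
  if (epoch_window[1] > -0.05 || epoch_window[2] <= 0.3)
    stop("epoch window must contain the baseline window [-0.05, 0] and the ",
         "analysis windows [0.07, 0.1] and [0.07, 0.3]")
  structure(list(
    n_subjects = as.integer(n_subjects), routing = routing,
    asymmetry = asymmetry, evoked_amplitude = evoked_amplitude,
    noise_sd = noise_sd, noise_model = noise_model,
    n_trials_mean = n_trials_mean, n_trials_sd = n_trials_sd,
    sample_rate = sample_rate, epoch_window = epoch_window,
    peak_latency = peak_latency,
    n_channels_per_hemi = as.integer(n_channels_per_hemi),
    seed = as.integer(seed)), class = "vep_sim_config")
}

#' @export
print.vep_sim_config <- function(x, ...) {
  cat("VEP simulation config:", x$n_subjects, "subjects,", x$routing,
      sprintf("(asymmetry %.2f), amplitude %.1f uV, noise %.1f uV (%s)\n",
              x$asymmetry, x$evoked_amplitude, x$noise_sd, x$noise_model))
  invisible(x)
}

# normal(mean, sd) trial counts, rounded, floored at 1
draw_trial_counts <- function(n, mean, sd) {
  pmax(1L, as.integer(round(stats::rnorm(n, mean, sd))))
}

hemi_weights <- function(routing, asymmetry, eye) {
  if (routing == "normal") return(c(left = 0.5, right = 0.5))
  # misrouted: contralateral hemisphere dominates, laterality flips with eye
  contra <- (1 + asymmetry) / 2
  ipsi <- (1 - asymmetry) / 2
  if (eye == "OS") c(left = ipsi, right = contra)   # left eye -> right hemi
  else             c(left = contra, right = ipsi)   # right eye -> left hemi
}

#' Simulate a cohort of epoched monocular VEP recordings
#'
#' Generates one \code{\link{vep_epochs}} object per subject per eye (OS then
#' OD), plus a ground-truth table. Reproducible bit-for-bit given
#' \code{cfg$seed}: the cohort RNG is seeded once, then an independent
#' substream seed is drawn per subject.
#'
#' @param cfg a \code{\link{vep_sim_config}}.
#' @return list of class \code{vep_cohort} with elements
#'   \code{recordings} (named list, \code{"<subject>_<eye>"}),
#'   \code{truth} (data.frame: subject_id, routing, asymmetry, trial counts),
#'   \code{montage} (\code{\link{vep_montage}}) and \code{config}.
#' @examples
#' cfg <- vep_sim_config(n_subjects = 1, noise_sd = 0, n_trials_mean = 4,
#'                       n_trials_sd = 0, seed = 7)
#' coh <- simulate_vep_cohort(cfg)
#' names(coh$recordings)
#' @export
simulate_vep_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "vep_sim_config"))
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max, cfg$n_subjects)
  nc <- cfg$n_channels_per_hemi
  channels <- c(paste0("OL", seq_len(nc)), paste0("OR", seq_len(nc)))
  hemi <- rep(c("left", "right"), each = nc)
  times <- epoch_times(cfg$epoch_window, cfg$sample_rate)
  k <- vep_kernel(times, peak_latency = cfg$peak_latency)
  n_samp <- length(times)

  recordings <- list()
  truth <- data.frame(subject_id = sprintf("S%02d", seq_len(cfg$n_subjects)),
                      routing = cfg$routing, asymmetry = cfg$asymmetry,
                      n_trials_OS = NA_integer_, n_trials_OD = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_subjects)) {
    set.seed(sub_seeds[i])
    sid <- truth$subject_id[i]
    n_tr <- draw_trial_counts(2L, cfg$n_trials_mean, cfg$n_trials_sd)
    truth$n_trials_OS[i] <- n_tr[1]; truth$n_trials_OD[i] <- n_tr[2]
    for (ei in 1:2) {
      eye <- c("OS", "OD")[ei]
      w <- hemi_weights(cfg$routing, cfg$asymmetry, eye)
      mean_resp <- outer(k, cfg$evoked_amplitude * unname(w[hemi])) # S x C
      nt <- n_tr[ei]
      if (cfg$noise_sd > 0) {
        noise <- switch(cfg$noise_model,
          white = noise_white(n_samp, nt * 2 * nc, sd = cfg$noise_sd),
          one_over_f_plus_white = noise_one_over_f_plus_white(
            n_samp, nt * 2 * nc, sd = cfg$noise_sd,
            sample_rate = cfg$sample_rate))
      } else noise <- matrix(0, n_samp, nt * 2 * nc)
      # S x (C*T) -> T x C x S, trials vary fastest across column blocks
      dat <- array(noise, dim = c(n_samp, 2 * nc, nt)) +
        array(mean_resp, dim = c(n_samp, 2 * nc, nt))
      dat <- aperm(dat, c(3, 2, 1))
      recordings[[paste(sid, eye, sep = "_")]] <-
        vep_epochs(sid, eye, cfg$sample_rate, cfg$epoch_window, dat, channels)
    }
  }
  structure(list(recordings = recordings, truth = truth,
                 montage = vep_montage(channels[hemi == "left"],
                                       channels[hemi == "right"]),
                 config = cfg),
            class = "vep_cohort")
}

#' @export
print.vep_cohort <- function(x, ...) {
  cat("VEP cohort:", nrow(x$truth), "subjects x 2 eyes,",
      x$config$routing, "routing\n")
  invisible(x)
}

#' Simulate a continuous monocular VEP recording
#'
#' One subject, one eye, as a continuous multichannel record with stimulus
#' onsets spaced regularly (default 0.48 s: the 40 ms ON / 440 ms OFF
#' pattern-onset cycle), suitable for \code{\link{epoch}} and for EDF export.
#'
#' @inheritParams simulate_vep_cohort
#' @param eye \code{"OS"} or \code{"OD"}.
#' @param n_onsets number of stimulations.
#' @param onset_spacing seconds between consecutive onsets.
#' @param lead_in seconds of signal before the first onset.
#' @return list of class \code{vep_continuous}: \code{signal}
#'   (channels x samples matrix, µV), \code{sample_rate}, \code{onsets}
#'   (seconds), \code{channels}, \code{eye}.
#' @export
simulate_vep_continuous <- function(cfg, eye = "OS", n_onsets = 20,
                                    onset_spacing = 0.48, lead_in = 1) {
  stopifnot(inherits(cfg, "vep_sim_config"))
  set.seed(cfg$seed)
  nc <- cfg$n_channels_per_hemi
  channels <- c(paste0("OL", seq_len(nc)), paste0("OR", seq_len(nc)))
  hemi <- rep(c("left", "right"), each = nc)
  fs <- cfg$sample_rate
  onsets <- lead_in + onset_spacing * (seq_len(n_onsets) - 1)
  total <- ceiling((max(onsets) + 1) * fs)
  t_axis <- (seq_len(total) - 1) / fs
  w <- hemi_weights(cfg$routing, cfg$asymmetry, eye)
  resp <- numeric(total)
  for (on in onsets) {
    idx <- which(t_axis >= on & t_axis < on + 0.4)
    resp[idx] <- resp[idx] + vep_kernel(t_axis[idx] - on,
                                        peak_latency = cfg$peak_latency)
  }
  sig <- outer(cfg$evoked_amplitude * unname(w[hemi]), resp)  # C x N
  if (cfg$noise_sd > 0)
    sig <- sig + t(switch(cfg$noise_model,
      white = noise_white(total, 2 * nc, sd = cfg$noise_sd),
      one_over_f_plus_white = noise_one_over_f_plus_white(
        total, 2 * nc, sd = cfg$noise_sd, sample_rate = fs)))
  rownames(sig) <- channels
  structure(list(signal = sig, sample_rate = fs, onsets = onsets,
                 channels = channels, eye = eye),
            class = "vep_continuous")
}
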