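toy_continuous <- function(fun, n_sec = 10, fs = 500, n_ch = 2) {
  t_axis <- (seq_len(n_sec * fs) - 1) / fs
  sig <- matrix(rep(fun(t_axis), each = n_ch), n_ch, byrow = FALSE)
  rownames(sig) <- paste0("C", seq_len(n_ch))
  list(signal = sig, t = t_axis, fs = fs)
}

test_that("epoching the stated window at 500 Hz yields 300 samples", {
  x <- toy_continuous(function(t) rep(1, length(t)))
  ep <- epoch(x$signal, onsets = c(1, 2, 3), sample_rate = x$fs)
  expect_equal(dim(ep$data)[3], 300)
  expect_equal(ep$times[1], -0.2)
  expect_true(0 %in% ep$times)          # t = 0 belongs to the epoch
  expect_false(0.4 %in% ep$times)       # half-open at the right edge
  expect_true(all(ep$data == 1))        # constant signal -> constant epochs
})

test_that("onsets too close to the record edge are dropped with a warning", {
  x <- toy_continuous(function(t) sin(t))
  onsets <- c(0.05, 0.1, seq(1, 8, length.out = 8))   # first two lack baseline room
  expect_warning(ep <- epoch(x$signal, onsets = onsets, sample_rate = x$fs),
                 "dropped")
  expect_equal(dim(ep$data)[1], 8)
  expect_error(suppressWarnings(epoch(x$signal, onsets = c(0.01),
                                      sample_rate = x$fs)),
               "no usable trials")
})

test_that("baseline correction zeroes the baseline mean, with ramp closed form", {
  fs <- 500
  times <- ocadx:::epoch_times(c(-0.2, 0.4), fs)
  a <- 3.7
  ramp <- a * times
  dat <- array(rep(ramp, each = 2), dim = c(1, 2, length(times)))
  ep <- vep_epochs("T", "OS", fs, c(-0.2, 0.4), dat, c("L", "R"))
  bc <- baseline_correct(ep)
  bl_idx <- times >= -0.05 & times <= 0
  expect_equal(mean(bc$data[1, 1, bl_idx]), 0, tolerance = 1e-12)
  expect_equal(bc$data[1, 1, ], ramp - a * mean(times[bl_idx]),
               tolerance = 1e-12)
  # constant signal -> all zeros; signal vanishing on baseline -> unchanged
  const <- ep; const$data[] <- 5
  expect_equal(max(abs(baseline_correct(const)$data)), 0)
  k <- vep_kernel(times)
  kep <- ep; kep$data <- array(rep(k, each = 2), dim = dim(ep$data))
  expect_equal(baseline_correct(kep)$data, kep$data, tolerance = 1e-12)
})

test_that("high-pass removes drift and keeps the passband, per the designed response", {
  # frequency-response oracle evaluated on the designed kernel (default
  # 0.1 Hz cutoff, 0.2 Hz transition)
  h <- ocadx:::blackman_sinc_kernel(0.1, 500, 0.2)
  mid <- (length(h) - 1) / 2
  lp_gain <- function(f) sum(h * cos(2 * pi * f / 500 * (seq_along(h) - 1 - mid)))
  hp_gain <- function(f) 1 - lp_gain(f)          # zero-phase, real response
  expect_lt(abs(hp_gain(0.01)), 0.1)             # 0.01 Hz: >90% attenuated
  expect_lt(abs(hp_gain(0)), 1e-9)               # DC fully removed
  expect_equal(hp_gain(10), 1, tolerance = 0.01) # 10 Hz preserved

  # time-domain check with a shorter kernel (1 Hz cutoff, 2 Hz transition)
  x <- toy_continuous(function(t) 2 + sin(2 * pi * 10 * t), n_sec = 10)
  y <- highpass_filter(x$signal, cutoff = 1, transition = 2,
                       sample_rate = x$fs)
  mid <- 2000:3000
  expect_lt(max(abs(y[1, mid] - sin(2 * pi * 10 * x$t[mid]))), 0.02)
  expect_error(highpass_filter(x$signal[, 1:100, drop = FALSE], cutoff = 1,
                               transition = 2, sample_rate = x$fs),
               "shorter than the filter kernel")
})

test_that("low-pass preserves 5 Hz, attenuates 60 Hz per the Butterworth response, zero phase", {
  fs <- 500
  t_axis <- (seq_len(4 * fs) - 1) / fs
  mid <- 500:1500
  for (freq in c(5, 60)) {
    x <- matrix(sin(2 * pi * freq * t_axis), 1)
    y <- lowpass_filter(x, cutoff = 35, sample_rate = fs)
    gain <- max(abs(y[1, mid]))
    # forward-backward application squares the magnitude response
    expected <- (1 / sqrt(1 + (freq / 35)^(2 * 4)))^2
    expect_equal(gain, expected, tolerance = 0.02)
  }
  expect_error(lowpass_filter(matrix(0, 1, 100), cutoff = 300,
                              sample_rate = fs), "Nyquist")
  # impulse at the center comes out time-symmetric
  imp <- matrix(0, 1, 301); imp[1, 151] <- 1
  y <- lowpass_filter(imp, cutoff = 35, sample_rate = fs)
  expect_equal(y[1, ], rev(y[1, ]), tolerance = 1e-9)
})

test_that("trial averaging is exact for identical trials and converges for noise", {
  fs <- 500
  times <- ocadx:::epoch_times(c(-0.2, 0.4), fs)
  k <- vep_kernel(times)
  dat <- aperm(array(rep(k, 3 * 2), dim = c(length(times), 2, 3)), c(3, 2, 1))
  ep <- vep_epochs("T", "OS", fs, c(-0.2, 0.4), dat, c("L", "R"))
  avg <- average_trials(ep)
  expect_equal(avg$data[1, ], k, tolerance = 1e-12)
  expect_equal(avg$n_trials, 3L)
  single <- vep_epochs("T", "OS", fs, c(-0.2, 0.4),
                       dat[1, , , drop = FALSE], c("L", "R"))
  expect_equal(average_trials(single)$data,
               matrix(dat[1, , ], 2), tolerance = 1e-15)
  # CLT: mean of n noisy trials approaches the kernel at ~sd/sqrt(n)
  set.seed(8)
  n <- 400; sd_n <- 2
  noisy <- dat[rep(1, n), , , drop = FALSE] +
    array(rnorm(n * 2 * length(times), sd = sd_n), c(n, 2, length(times)))
  ep_n <- vep_epochs("T", "OS", fs, c(-0.2, 0.4), noisy, c("L", "R"))
  err <- average_trials(ep_n)$data[1, ] - k
  expect_lt(sqrt(mean(err^2)), 3 * sd_n / sqrt(n))
})

test_that("the preprocessing chain is linear and its idempotent stages are idempotent", {
  fs <- 500
  times <- ocadx:::epoch_times(c(-0.2, 0.4), fs)
  set.seed(3)
  mk <- function() {
    dat <- array(rnorm(4 * 2 * length(times)), c(4, 2, length(times)))
    vep_epochs("T", "OS", fs, c(-0.2, 0.4), dat, c("L", "R"))
  }
  x <- mk(); y <- mk(); a <- 2.5; b <- -1.25
  z <- x; z$data <- a * x$data + b * y$data
  pz <- preprocess_epochs(z)
  px <- preprocess_epochs(x); py <- preprocess_epochs(y)
  expect_equal(pz$data, a * px$data + b * py$data, tolerance = 1e-9)
  # baseline correction is idempotent
  bc1 <- baseline_correct(x); bc2 <- baseline_correct(bc1)
  expect_equal(bc1$data, bc2$data, tolerance = 1e-12)
  # averaging a single-trial epoch set is the identity
  s <- vep_epochs("T", "OS", fs, c(-0.2, 0.4), x$data[1, , , drop = FALSE],
                  c("L", "R"))
  expect_equal(average_trials(s)$data, matrix(x$data[1, , ], 2),
               tolerance = 1e-15)
})

test_that("re-referencing changes channels but not the differential activity", {
  cfg <- vep_sim_config(n_subjects = 1, noise_sd = 2, noise_model = "white",
                        n_trials_mean = 4, n_trials_sd = 0, seed = 6)
  coh <- simulate_vep_cohort(cfg)
  ep <- coh$recordings$S01_OS
  w_none <- preprocess_epochs(ep, lowpass = NA)
  w_avg <- preprocess_epochs(ep, lowpass = NA, reference = "average")
  expect_false(isTRUE(all.equal(w_none$data, w_avg$data)))
  d1 <- differential_activity(w_none, coh$montage)
  d2 <- differential_activity(w_avg, coh$montage)
  expect_equal(d1$d, d2$d, tolerance = 1e-10)
  expect_error(rereference(w_none, "CZ"), "not found")
})
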