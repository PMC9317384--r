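toy_waveform <- function(mat, channels, eye = "OS", fs = 500,
                         window = c(-0.2, 0.4)) {
  vep_waveform("T", eye, fs, window, mat, channels)
}

test_that("differential activity is the left-set mean minus the right-set mean", {
  fs <- 500
  n <- 300
  k <- vep_kernel(ocadx:::epoch_times(c(-0.2, 0.4), fs))
  mont <- vep_montage(c("L1", "L2"), c("R1", "R2"))
  # hemispherically symmetric -> identically zero
  sym <- toy_waveform(rbind(k, k, k, k), c("L1", "L2", "R1", "R2"))
  expect_equal(max(abs(differential_activity(sym, mont)$d)), 0)
  # left carries c(t), right zero -> D = c(t)
  left_only <- toy_waveform(rbind(k, k, 0 * k, 0 * k),
                            c("L1", "L2", "R1", "R2"))
  expect_equal(differential_activity(left_only, mont)$d, k)
  # absent montage channels are reported by name
  expect_error(differential_activity(sym, vep_montage("L1", "XX")), "XX")
})

test_that("chiasm coefficient: identity, antisymmetry under eye swap, window errors", {
  times <- ocadx:::epoch_times(c(-0.2, 0.4), 500)
  set.seed(2)
  d1 <- make_da(rnorm(300), "OS", times)
  d2 <- make_da(rnorm(300), "OD", times)
  expect_equal(chiasm_coefficient(d1, d1), 0)
  cc <- chiasm_coefficient(d1, d2)
  expect_equal(chiasm_coefficient(d2, d1), -cc, tolerance = 1e-15)
  expect_error(chiasm_coefficient(d1, d2, window = c(10, 11)), "window")
  # normalized-product variant is negative iff the window means share a sign
  expect_lt(chiasm_coefficient(make_da(rep(1, 300), "OS", times),
                               make_da(rep(2, 300), "OD", times),
                               method = "normalized_product"), 0)
})

test_that("interocular correlation matches the direct formula and flags degeneracy", {
  x <- c(0.3, -1.2, 2.2, 0.7, -0.4, 1.9, -2.1, 0.2, 1.1, -0.8)
  y <- c(1.0, 0.4, -1.7, -0.2, 0.6, -1.1, 1.8, 0.3, -0.9, 0.5)
  dx <- make_da(x, "OS"); dy <- make_da(y, "OD")
  ic <- interocular_correlation(dx, dy, window = range(dx$times),
                                df_method = "nominal")
  expect_equal(ic$r, pearson_oracle(x, y), tolerance = 1e-12)
  ct <- cor.test(x, y)                       # independent cross-check
  expect_equal(ic$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(ic$p_value, ct$p.value, tolerance = 1e-12)
  expect_identical(ic$p_value, ic$p_nominal)
  # perfect anticorrelation and affine invariance
  expect_equal(interocular_correlation(dx, make_da(-x, "OD"),
                                       range(dx$times))$r, -1)
  expect_equal(interocular_correlation(dx, make_da(2 * x + 3, "OD"),
                                       range(dx$times))$r, 1)
  # zero variance is flagged, not silently zero
  flat <- make_da(rep(1, 10), "OD")
  expect_identical(interocular_correlation(dx, flat, range(dx$times))$status,
                   "undefined")
})

test_that("misrouting classification is the stated conjunction", {
  mk <- function(r, p, cc, status = "ok")
    list(pearson_r = r, p_value = p, chiasm_coefficient = cc,
         correlation_status = status)
  expect_identical(classify_misrouting(mk(-0.9, 1e-5, -1.2)), "misrouted")
  expect_identical(classify_misrouting(mk(-0.9, 1e-5, +0.3)), "not_misrouted")
  expect_identical(classify_misrouting(mk(-0.9, 0.2, -1.2)), "not_misrouted")
  expect_identical(classify_misrouting(mk(+0.9, 1e-5, -1.2)), "not_misrouted")
  expect_identical(classify_misrouting(mk(NA, NA, -1, "undefined")),
                   "indeterminate")
})

test_that("group test matches the hand paired-t formula, t.test, and df convention", {
  os <- c(-2.1, -1.7, -2.8, -0.9, -1.4, -2.2, -1.1, -1.9)
  od <- c(1.8, 1.2, 2.5, 0.7, 1.9, 1.4, 0.8, 2.0)
  g <- group_chiasm_ttest(os, od)
  expect_equal(g$t_statistic, paired_t_oracle(os, od), tolerance = 1e-12)
  tt <- t.test(os, od, paired = TRUE)        # independent cross-check
  expect_equal(g$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(g$p_value, tt$p.value, tolerance = 1e-12)
  expect_identical(g$df, 7L)                 # n = 8 -> df = 7
  # identical pairs -> t = 0, p = 1
  same <- group_chiasm_ttest(od, od)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_chiasm_ttest(1, 1), "at least 2")
})

test_that("both indexes are invariant to a common reference shift", {
  cfg <- vep_sim_config(n_subjects = 1, asymmetry = 0.5, noise_sd = 3,
                        noise_model = "white", n_trials_mean = 5,
                        n_trials_sd = 0, seed = 21)
  coh <- simulate_vep_cohort(cfg)
  w_os <- preprocess_epochs(coh$recordings$S01_OS)
  w_od <- preprocess_epochs(coh$recordings$S01_OD)
  base <- assess_misrouting(w_os, w_od, coh$montage)
  common <- sin(2 * pi * 7 * w_os$times) + 4          # arbitrary common signal
  w_os2 <- w_os; w_os2$data <- sweep(w_os$data, 2, common, "+")
  w_od2 <- w_od; w_od2$data <- sweep(w_od$data, 2, common, "+")
  shifted <- assess_misrouting(w_os2, w_od2, coh$montage)
  expect_equal(shifted$chiasm_coefficient, base$chiasm_coefficient,
               tolerance = 1e-9)
  expect_equal(shifted$pearson_r, base$pearson_r, tolerance = 1e-9)
})

test_that("swapping the montage hemispheres negates D and the coefficient, keeps |r|", {
  cfg <- vep_sim_config(n_subjects = 1, asymmetry = 0.4, noise_sd = 2,
                        noise_model = "white", n_trials_mean = 5,
                        n_trials_sd = 0, seed = 22)
  coh <- simulate_vep_cohort(cfg)
  w_os <- preprocess_epochs(coh$recordings$S01_OS)
  w_od <- preprocess_epochs(coh$recordings$S01_OD)
  m1 <- coh$montage
  m2 <- vep_montage(m1$right_set, m1$left_set)
  a <- assess_misrouting(w_os, w_od, m1)
  b <- assess_misrouting(w_os, w_od, m2)
  expect_equal(b$d_os$d, -a$d_os$d, tolerance = 1e-12)
  expect_equal(b$chiasm_coefficient, -a$chiasm_coefficient, tolerance = 1e-12)
  expect_equal(abs(b$pearson_r), abs(a$pearson_r), tolerance = 1e-12)
})

test_that("a high-SNR misrouted cohort is detected end to end", {
  cfg <- vep_sim_config(n_subjects = 3, asymmetry = 0.5, noise_sd = 4.9,
                        n_trials_mean = 30, n_trials_sd = 3, seed = 33)
  res <- misrouting_cohort(simulate_vep_cohort(cfg))
  expect_identical(unique(res$table$misrouted), "misrouted")
  expect_true(all(res$table$chiasm_coefficient < 0))
  expect_identical(res$group$df, 2L)
  expect_lt(res$group$t_statistic, 0)
})
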