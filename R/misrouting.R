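#' Interhemispheric differential activity (OL - OR)
#'
#' For one eye's trial-averaged VEP, the mean over the left occipital
#' electrode set minus the mean over the right set, per sample. Under
#' chiasmal misrouting the differential flips sign between eyes; under
#' normal routing it is flat (up to noise). Being a difference of two
#' equal-sized channel means, it is invariant to any signal common to all
#' channels (reference shifts).
#'
#' @param vep a \code{\link{vep_waveform}}.
#' @param montage a \code{\link{vep_montage}}; all its channels must be
#'   present in the waveform.
#' @return list of class \code{differential_activity}: \code{eye},
#'   \code{times} (s), \code{d} (µV), \code{subject_id}.
#' @export
differential_activity <- function(vep, montage) {
  stopifnot(inherits(vep, "vep_waveform"), inherits(montage, "vep_montage"))
  missing <- setdiff(c(montage$left_set, montage$right_set), vep$channels)
  if (length(missing) > 0)
    stop("montage channels absent from waveform: ",
         paste(missing, collapse = ", "))
  li <- match(montage$left_set, vep$channels)
  ri <- match(montage$right_set, vep$channels)
  d <- colMeans(vep$data[li, , drop = FALSE]) -
       colMeans(vep$data[ri, , drop = FALSE])
  structure(list(subject_id = vep$subject_id, eye = vep$eye,
                 times = vep$times, d = d),
            class = "differential_activity")
}

window_idx <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0)
    stop(sprintf("window [%g, %g] s lies outside the epoch time axis",
                 window[1], window[2]))
  idx
}

#' Chiasm coefficient
#'
#' Scalar misrouting index: the mean differential activity of the left eye
#' minus that of the right eye within an early window (default
#' \code{[0.07, 0.1]} s, closed on the sample grid). Negative values are
#' consistent with misrouting (contralateral dominance flipping between
#' eyes). An alternative normalized-product form
#' \code{-mean(D_OS) * mean(D_OD) / (|mean(D_OS)| + |mean(D_OD)|)} is
#' available behind \code{method = "normalized_product"}.
#'
#' @param d_os,d_od \code{\link{differential_activity}} for the left (OS)
#'   and right (OD) eye; must share a time axis covering \code{window}.
#' @param window analysis window, seconds.
#' @param method \code{"difference"} (default) or \code{"normalized_product"}.
#' @return scalar, µV.
#' @export
chiasm_coefficient <- function(d_os, d_od, window = c(0.07, 0.1),
                               method = c("difference", "normalized_product")) {
  method <- match.arg(method)
  stopifnot(inherits(d_os, "differential_activity"),
            inherits(d_od, "differential_activity"))
  if (!isTRUE(all.equal(d_os$times, d_od$times)))
    stop("the two differential activities must share one time axis")
  idx <- window_idx(d_os$times, window)
  m_os <- mean(d_os$d[idx]); m_od <- mean(d_od$d[idx])
  if (method == "difference") m_os - m_od
  else if (m_os == 0 && m_od == 0) 0
  else -(m_os * m_od) / (abs(m_os) + abs(m_od))
}

#' Interocular correlation of differential activity
#'
#' Pearson correlation between the OS and OD differential waveforms across
#' time samples in a window (default \code{[0.07, 0.3]} s), with a
#' two-tailed p-value from the t distribution. A strongly negative
#' correlation indicates mirror-image hemispheric lateralization between
#' the eyes, i.e. misrouting.
#'
#' Filtered EEG samples are serially correlated, so treating the window's
#' samples as independent (\code{df_method = "nominal"}: \code{n - 2}
#' degrees of freedom, the convention used when comparing against published
#' per-subject p-values) overstates significance. The default
#' (\code{"effective"}) replaces \code{n} by the Pyper-Peterman effective
#' sample size
#' \deqn{n_{eff} = n / (1 + 2 \sum_k \rho_x(k)\rho_y(k)),}
#' summing sample autocorrelations up to lag \code{n/4}, which keeps the
#' false-positive rate of the downstream misrouting classifier near its
#' nominal level. Both p-values are returned.
#'
#' @inheritParams chiasm_coefficient
#' @param window analysis window, seconds.
#' @param df_method \code{"effective"} (autocorrelation-corrected, default)
#'   or \code{"nominal"}.
#' @return list: \code{r}, \code{p_value} (per \code{df_method}),
#'   \code{p_nominal}, \code{n} (samples), \code{n_eff},
#'   \code{status} (\code{"ok"} or \code{"undefined"} when either series
#'   has zero variance in the window).
#' @export
interocular_correlation <- function(d_os, d_od, window = c(0.07, 0.3),
                                    df_method = c("effective", "nominal")) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(d_os, "differential_activity"),
            inherits(d_od, "differential_activity"))
  if (!isTRUE(all.equal(d_os$times, d_od$times)))
    stop("the two differential activities must share one time axis")
  idx <- window_idx(d_os$times, window)
  x <- d_os$d[idx]; y <- d_od$d[idx]
  n <- length(x)
  if (n < 3) stop("need at least 3 samples in the correlation window")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, p_nominal = NA_real_,
                n = n, n_eff = NA_real_, status = "undefined"))
  r <- stats::cor(x, y)
  n_eff <- effective_sample_size(x, y)
  p_for <- function(m) {
    if (abs(r) >= 1) return(0)
    tt <- r * sqrt((m - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = m - 2)
  }
  p_nom <- p_for(n)
  p_eff <- p_for(n_eff)
  list(r = r,
       p_value = if (df_method == "effective") p_eff else p_nom,
       p_nominal = p_nom, n = n, n_eff = n_eff, status = "ok")
}

# Pyper-Peterman effective sample size for the correlation of two
# autocorrelated series; lags truncated at n/4, result clamped to [3, n]
effective_sample_size <- function(x, y) {
  n <- length(x)
  max_lag <- max(1L, floor(n / 4))
  acf_x <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  acf_y <- stats::acf(y, lag.max = max_lag, plot = FALSE)$acf[-1]
  n_eff <- n / (1 + 2 * sum(acf_x * acf_y))
  min(max(n_eff, 3), n)
}

#' Classify a subject as misrouted
#'
#' Conjunction rule: misrouted iff the interocular correlation is negative
#' and significant at \code{alpha} and the chiasm coefficient is negative.
#' An undefined correlation (zero variance) yields \code{"indeterminate"}.
#'
#' @param result a \code{\link{misrouting_result}} (or any list with
#'   \code{pearson_r}, \code{p_value}, \code{chiasm_coefficient},
#'   \code{correlation_status}).
#' @param alpha significance level (default 0.05, two-tailed).
#' @return \code{"misrouted"}, \code{"not_misrouted"} or
#'   \code{"indeterminate"}.
#' @export
classify_misrouting <- function(result, alpha = 0.05) {
  if (identical(result$correlation_status, "undefined")) return("indeterminate")
  if (result$pearson_r < 0 && result$p_value <= alpha &&
      result$chiasm_coefficient < 0) "misrouted" else "not_misrouted"
}

#' Per-subject misrouting assessment
#'
#' Computes the differential activity for both eyes, the chiasm coefficient
#' (window \code{cc_window}), the interocular Pearson correlation (window
#' \code{cor_window}) and the misrouting classification.
#'
#' @param vep_os,vep_od trial-averaged \code{\link{vep_waveform}}s for OS
#'   and OD.
#' @param montage a \code{\link{vep_montage}}.
#' @param cc_window,cor_window analysis windows, seconds.
#' @param alpha significance level for the classification.
#' @param df_method p-value convention for the correlation, see
#'   \code{\link{interocular_correlation}}.
#' @return object of class \code{misrouting_result}: subject_id,
#'   chiasm_coefficient (µV), pearson_r, p_value (per \code{df_method}),
#'   p_nominal, n_eff, correlation_status, misrouted (classification
#'   string), mean_D_OS, mean_D_OD (µV over \code{cc_window}), and the two
#'   differential activities.
#' @export
assess_misrouting <- function(vep_os, vep_od, montage,
                              cc_window = c(0.07, 0.1),
                              cor_window = c(0.07, 0.3), alpha = 0.05,
                              df_method = c("effective", "nominal")) {
  stopifnot(vep_os$eye == "OS", vep_od$eye == "OD")
  d_os <- differential_activity(vep_os, montage)
  d_od <- differential_activity(vep_od, montage)
  idx <- window_idx(d_os$times, cc_window)
  cc <- chiasm_coefficient(d_os, d_od, cc_window)
  ic <- interocular_correlation(d_os, d_od, cor_window,
                                df_method = df_method)
  res <- structure(list(subject_id = vep_os$subject_id,
                        chiasm_coefficient = cc,
                        pearson_r = ic$r, p_value = ic$p_value,
                        p_nominal = ic$p_nominal, n_eff = ic$n_eff,
                        correlation_status = ic$status,
                        mean_D_OS = mean(d_os$d[idx]),
                        mean_D_OD = mean(d_od$d[idx]),
                        alpha = alpha, d_os = d_os, d_od = d_od),
                   class = "misrouting_result")
  res$misrouted <- classify_misrouting(res, alpha)
  res
}

#' @export
print.misrouting_result <- function(x, ...) {
  cat(sprintf("Misrouting assessment for %s\n", x$subject_id))
  cat(sprintf("  chiasm coefficient : %8.4f uV  [0.07, 0.1] s\n",
              x$chiasm_coefficient))
  if (x$correlation_status == "ok")
    cat(sprintf("  interocular r      : %8.4f (p = %.3g)  [0.07, 0.3] s\n",
                x$pearson_r, x$p_value))
  else
    cat("  interocular r      : undefined (zero variance)\n")
  cat("  classification     :", x$misrouted, "\n")
  invisible(x)
}

#' Plot the differential activity of a misrouting assessment
#'
#' OS and OD interhemispheric differential waveforms with the two analysis
#' windows shaded.
#'
#' @param x a \code{\link{misrouting_result}} (from
#'   \code{\link{assess_misrouting}}).
#' @param ... passed to \code{matplot}.
#' @export
plot.misrouting_result <- function(x, ...) {
  graphics::matplot(x$d_os$times, cbind(x$d_os$d, x$d_od$d), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "time from stimulus onset (s)",
                    ylab = expression(paste("OL - OR (", mu, "V)")),
                    main = paste("Differential activity,", x$subject_id), ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::rect(0.07, graphics::par("usr")[3], 0.1,
                 graphics::par("usr")[4], col = grDevices::adjustcolor("grey", 0.3),
                 border = NA)
  graphics::legend("topright", c("OS", "OD"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Group-level paired t-test on the chiasm coefficient
#'
#' Two-tailed paired t-test of the per-subject mean differential activity of
#' OS against OD within the chiasm-coefficient window — equivalently a
#' one-sample t-test of the per-subject chiasm coefficients against zero.
#' Degrees of freedom are \code{n - 1}.
#'
#' @param mean_d_os,mean_d_od numeric vectors of per-subject window means,
#'   µV, paired by subject.
#' @return object of class \code{misrouting_group}: \code{t_statistic},
#'   \code{df}, \code{p_value}, \code{coefficients} (per-subject differences),
#'   \code{n}.
#' @export
group_chiasm_ttest <- function(mean_d_os, mean_d_od) {
  if (length(mean_d_os) != length(mean_d_od))
    stop("paired vectors must have equal length")
  n <- length(mean_d_os)
  if (n < 2) stop("need at least 2 subjects for the group test")
  d <- mean_d_os - mean_d_od
  s <- stats::sd(d)
  if (s == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else t_stat <- mean(d) / (s / sqrt(n))
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df = n - 1)
  structure(list(t_statistic = t_stat, df = n - 1L, p_value = p,
                 coefficients = d, n = n),
            class = "misrouting_group")
}

#' @export
print.misrouting_group <- function(x, ...) {
  cat(sprintf("Group chiasm-coefficient test: t(%d) = %.4f, p = %.4g (n = %d)\n",
              x$df, x$t_statistic, x$p_value, x$n))
  invisible(x)
}

#' Misrouting analysis of a whole cohort
#'
#' Runs the preprocessing chain and \code{\link{assess_misrouting}} on every
#' subject of a \code{vep_cohort} (or any named list of \code{vep_epochs}
#' keyed \code{"<subject>_<eye>"}), then the group t-test.
#'
#' @param cohort a \code{vep_cohort} from \code{\link{simulate_vep_cohort}}.
#' @param montage a \code{\link{vep_montage}}; defaults to the cohort's own.
#' @param lowpass low-pass cutoff (Hz) for preprocessing, \code{NA} to skip.
#' @param alpha per-subject significance level.
#' @return list of class \code{misrouting_cohort}: \code{subjects} (named
#'   list of \code{misrouting_result}), \code{table} (per-subject data.frame),
#'   \code{group} (\code{\link{group_chiasm_ttest}} result).
#' @export
misrouting_cohort <- function(cohort, montage = NULL, lowpass = 35,
                              alpha = 0.05) {
  if (is.null(montage)) montage <- cohort$montage
  ids <- unique(sub("_(OS|OD)$", "", names(cohort$recordings)))
  subjects <- list()
  for (sid in ids) {
    w_os <- preprocess_epochs(cohort$recordings[[paste0(sid, "_OS")]],
                              lowpass = lowpass)
    w_od <- preprocess_epochs(cohort$recordings[[paste0(sid, "_OD")]],
                              lowpass = lowpass)
    subjects[[sid]] <- assess_misrouting(w_os, w_od, montage, alpha = alpha)
  }
  tab <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id,
               chiasm_coefficient = s$chiasm_coefficient,
               pearson_r = s$pearson_r, p_value = s$p_value,
               mean_D_OS = s$mean_D_OS, mean_D_OD = s$mean_D_OD,
               misrouted = s$misrouted, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  grp <- if (nrow(tab) >= 2)
    group_chiasm_ttest(tab$mean_D_OS, tab$mean_D_OD) else NULL
  structure(list(subjects = subjects, table = tab, group = grp),
            class = "misrouting_cohort")
}

#' @export
print.misrouting_cohort <- function(x, ...) {
  cat("Misrouting analysis,", nrow(x$table), "subjects\n")
  print(x$table, digits = 4)
  if (!is.null(x$group)) print(x$group)
  invisible(x)
}
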