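#' Monte-Carlo operating characteristics of the misrouting indexes
#'
#' Simulates replicate cohorts with the full generation-preprocessing-
#' statistics chain and summarizes per-subject detection and group-test
#' behavior. With \code{routing = "misrouted"} this estimates power; with
#' \code{routing = "normal"} (asymmetry 0) the per-subject false-positive
#' rate of the conjunction classifier.
#'
#' The default simulation size scales the acquisition down for replicate
#' studies: 30 trials/eye at 4.9 µV noise preserves the per-average
#' differential SNR of the full-size default configuration (498 trials at
#' 20 µV), about 5.9 before low-pass filtering (peak signal \eqn{aA} over
#' noise \eqn{\sigma\sqrt{2/9}/\sqrt{n_{trials}}}); see the methods
#' vignette.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param routing,asymmetry,noise_sd,noise_model,n_trials_mean,n_trials_sd
#'   passed to \code{\link{vep_sim_config}}.
#' @param alpha_subject per-subject significance level.
#' @param alpha_group group-test significance level.
#' @param seed master seed; per-cohort seeds are derived from it.
#' @return list: \code{subject_detection_rate} (fraction of subjects
#'   classified misrouted), \code{cc_negative_rate},
#'   \code{correlation_negative_significant_rate},
#'   \code{group_rejection_rate} (fraction of cohorts with group p below
#'   \code{alpha_group} and negative t), \code{dfs} (per-cohort degrees of
#'   freedom), \code{n_subjects_total}, \code{group_t} (per-cohort t
#'   statistics).
#' @export
misrouting_power_study <- function(n_cohorts = 200, n_subjects = 8,
                                   routing = c("misrouted", "normal"),
                                   asymmetry = 0.5, noise_sd = 4.9,
                                   noise_model = "one_over_f_plus_white",
                                   n_trials_mean = 30, n_trials_sd = 5,
                                   alpha_subject = 0.05,
                                   alpha_group = 0.001, seed = 1) {
  routing <- match.arg(routing)
  if (routing == "normal") asymmetry <- 0
  set.seed(seed)
  cohort_seeds <- sample.int(.Machine$integer.max, n_cohorts)
  detected <- cc_neg <- cor_neg <- logical(0)
  group_p <- group_t <- numeric(n_cohorts)
  dfs <- integer(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cfg <- vep_sim_config(n_subjects = n_subjects, routing = routing,
                          asymmetry = asymmetry, noise_sd = noise_sd,
                          noise_model = noise_model,
                          n_trials_mean = n_trials_mean,
                          n_trials_sd = n_trials_sd,
                          seed = cohort_seeds[i])
    res <- misrouting_cohort(simulate_vep_cohort(cfg),
                             alpha = alpha_subject)
    detected <- c(detected, res$table$misrouted == "misrouted")
    cc_neg <- c(cc_neg, res$table$chiasm_coefficient < 0)
    cor_neg <- c(cor_neg, res$table$pearson_r < 0 &
                   res$table$p_value <= alpha_subject)
    group_p[i] <- res$group$p_value
    group_t[i] <- res$group$t_statistic
    dfs[i] <- res$group$df
  }
  list(subject_detection_rate = mean(detected),
       cc_negative_rate = mean(cc_neg),
       correlation_negative_significant_rate = mean(cor_neg),
       group_rejection_rate = mean(group_p <= alpha_group & group_t < 0),
       dfs = dfs, group_t = group_t,
       n_subjects_total = length(detected))
}
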