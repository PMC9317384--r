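#' Write an epoch container as TSV + JSON sidecar
#'
#' The data file (\code{<base>.tsv}) has one row per trial-channel pair
#' (columns \code{trial}, \code{channel}, then one column per sample); the
#' sidecar (\code{<base>.json}) holds subject, eye, sample rate, window and
#' channel labels. Round-trips losslessly with \code{\link{read_epochs}} up
#' to the 15-significant-digit text representation.
#'
#' @param epochs a \code{\link{vep_epochs}}.
#' @param base path prefix (without extension).
#' @return \code{base}, invisibly.
#' @export
write_epochs <- function(epochs, base) {
  stopifnot(inherits(epochs, "vep_epochs"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(epochs$channels, d[1]),
                   signif(flat, 15))
  names(df)[-(1:2)] <- paste0("s", seq_len(d[3]))
  utils::write.table(df, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = epochs$subject_id, eye = epochs$eye,
         sample_rate = epochs$sample_rate, window = epochs$window,
         channels = epochs$channels, n_trials = d[1]),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read an epoch container written by \code{\link{write_epochs}}
#'
#' @param base path prefix (without extension).
#' @return a \code{\link{vep_epochs}}.
#' @export
read_epochs <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(paste0(base, ".tsv"), stringsAsFactors = FALSE)
  n_tr <- meta$n_trials
  n_ch <- length(meta$channels)
  n_s <- ncol(df) - 2
  flat <- as.matrix(df[, -(1:2)])
  dat <- aperm(array(flat, dim = c(n_ch, n_tr, n_s)), c(2, 1, 3))
  vep_epochs(meta$subject_id, meta$eye, meta$sample_rate, meta$window,
             dat, meta$channels)
}
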