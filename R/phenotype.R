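#' Read a phenotype table
#'
#' Tab-separated table with one row per patient and columns
#' \code{patient_id}, \code{sex} (M/F), \code{age_years}, \code{fh_grade}
#' (Thomas foveal-hypoplasia grade 1-4), \code{bcva_re}, \code{bcva_le}
#' (LogMAR per eye), \code{iris_transillumination}, \code{nystagmus},
#' \code{misrouting}, \code{strabismus} (Y/N), \code{fundus_grade}
#' (hypopigmentation grade 0-3), \code{skin_hair_hypopigmentation} (Y/N).
#'
#' @param path TSV path.
#' @return data.frame with logical flag columns.
#' @export
read_phenotype_table <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("iris_transillumination", "nystagmus", "misrouting",
                "strabismus", "skin_hair_hypopigmentation"))
    if (!is.logical(p[[col]]))
      p[[col]] <- toupper(p[[col]]) %in% c("Y", "YES", "TRUE", "1")
  validate_phenotype(p)
  p
}

validate_phenotype <- function(p) {
  if (!all(p$fh_grade %in% 1:4))
    stop("fh_grade must be an integer 1-4 (Thomas classification)")
  if (!all(p$fundus_grade %in% 0:3))
    stop("fundus_grade must be an integer 0-3")
  if (any(c(p$bcva_re, p$bcva_le) < -0.3, na.rm = TRUE))
    stop("BCVA below -0.3 LogMAR is not plausible")
  invisible(p)
}

kruijt_fields <- function() c("fh_grade", "misrouting",
                              "iris_transillumination", "fundus_grade",
                              "nystagmus", "skin_hair_hypopigmentation")

#' Assess the Kruijt major/minor albinism criteria for one patient
#'
#' Major criteria: foveal hypoplasia of grade 2 or higher; optic-pathway
#' misrouting; ocular hypopigmentation (read here as iris transillumination
#' OR fundus hypopigmentation of grade 2 or higher). Minor criteria:
#' nystagmus; skin/hair hypopigmentation; grade 1 fundus hypopigmentation;
#' grade 1 foveal hypoplasia. Clinical diagnosis requires three major, or
#' two major plus two minor criteria; with a molecular diagnosis one major
#' or two minor criteria suffice.
#'
#' @param record one-row data.frame (or list) with the phenotype fields of
#'   \code{\link{read_phenotype_table}}.
#' @param has_molecular_dx logical: is a molecular diagnosis established?
#' @return object of class \code{kruijt_assessment}: \code{major_met},
#'   \code{minor_met} (character vectors), \code{n_major}, \code{n_minor},
#'   \code{diagnostic_clinical}, \code{diagnostic_with_molecular},
#'   \code{status} (\code{"ok"} or \code{"unassessable"} with
#'   \code{missing_fields}).
#' @export
assess_kruijt <- function(record, has_molecular_dx = FALSE) {
  need <- kruijt_fields()
  vals <- lapply(need, function(f) record[[f]])
  names(vals) <- need
  miss <- need[vapply(vals, function(v) is.null(v) || is.na(v), logical(1))]
  if (length(miss) > 0)
    return(structure(list(status = "unassessable", missing_fields = miss,
                          major_met = character(0), minor_met = character(0),
                          n_major = NA_integer_, n_minor = NA_integer_,
                          diagnostic_clinical = NA,
                          diagnostic_with_molecular = NA,
                          has_molecular_dx = has_molecular_dx),
                     class = "kruijt_assessment"))
  major <- c(fh_grade_ge2 = vals$fh_grade >= 2,
             misrouting = isTRUE(vals$misrouting),
             ocular_hypopigmentation = isTRUE(vals$iris_transillumination) ||
               vals$fundus_grade >= 2)
  minor <- c(nystagmus = isTRUE(vals$nystagmus),
             skin_hair_hypopigmentation =
               isTRUE(vals$skin_hair_hypopigmentation),
             fundus_grade_1 = vals$fundus_grade == 1,
             fh_grade_1 = vals$fh_grade == 1)
  n_major <- sum(major); n_minor <- sum(minor)
  structure(list(status = "ok", missing_fields = character(0),
                 major_met = names(major)[major],
                 minor_met = names(minor)[minor],
                 n_major = n_major, n_minor = n_minor,
                 diagnostic_clinical = n_major >= 3 ||
                   (n_major >= 2 && n_minor >= 2),
                 diagnostic_with_molecular = has_molecular_dx &&
                   (n_major >= 1 || n_minor >= 2),
                 has_molecular_dx = has_molecular_dx),
            class = "kruijt_assessment")
}

#' @export
print.kruijt_assessment <- function(x, ...) {
  if (x$status != "ok") {
    cat("Kruijt assessment: unassessable; missing fields:",
        paste(x$missing_fields, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(sprintf("Kruijt criteria: %d major (%s), %d minor (%s)\n",
              x$n_major, paste(x$major_met, collapse = ", "),
              x$n_minor, paste(x$minor_met, collapse = ", ")))
  cat("  clinical diagnosis          :",
      if (x$diagnostic_clinical) "met" else "not met", "\n")
  cat("  with molecular diagnosis    :",
      if (isTRUE(x$diagnostic_with_molecular)) "met"
      else if (x$has_molecular_dx) "not met" else "no molecular dx", "\n")
  invisible(x)
}

#' Cohort phenotype summary
#'
#' Mean and range of BCVA (pooled over all eyes by default, with the
#' per-patient-average variant also reported), and counts/percentages for
#' the categorical features. Percentages are \code{100 * count / n}.
#'
#' @param records phenotype data.frame (see
#'   \code{\link{read_phenotype_table}}).
#' @return object of class \code{oca_cohort_summary}.
#' @export
summarize_cohort <- function(records) {
  stopifnot(nrow(records) >= 1)
  validate_phenotype(records)
  eyes <- c(records$bcva_re, records$bcva_le)
  per_patient <- (records$bcva_re + records$bcva_le) / 2
  n <- nrow(records)
  count_pct <- function(x, levels) {
    cnt <- vapply(levels, function(l) sum(x == l), integer(1))
    data.frame(level = as.character(levels), count = cnt,
               pct = 100 * cnt / n, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  structure(list(
    n = n,
    mean_age = mean(records$age_years),
    age_range = range(records$age_years),
    mean_bcva = mean(eyes),
    bcva_range = range(eyes),
    mean_bcva_per_patient = mean(per_patient),
    fh_grade = count_pct(records$fh_grade, sort(unique(records$fh_grade))),
    fundus_grade = count_pct(records$fundus_grade,
                             sort(unique(records$fundus_grade))),
    strabismus_count = sum(records$strabismus),
    strabismus_pct = 100 * mean(records$strabismus),
    nystagmus_count = sum(records$nystagmus),
    nystagmus_pct = 100 * mean(records$nystagmus),
    iris_transillumination_count = sum(records$iris_transillumination),
    iris_transillumination_pct = 100 * mean(records$iris_transillumination)),
    class = "oca_cohort_summary")
}

#' @export
print.oca_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (mean age %.1f y, range %g-%g)\n",
              x$n, x$mean_age, x$age_range[1], x$age_range[2]))
  cat(sprintf("  mean BCVA %.2f LogMAR (range %g-%g; per-patient mean %.2f)\n",
              x$mean_bcva, x$bcva_range[1], x$bcva_range[2],
              x$mean_bcva_per_patient))
  cat("  foveal hypoplasia grades:\n")
  for (i in seq_len(nrow(x$fh_grade)))
    cat(sprintf("    grade %s: %d/%d (%.1f%%)\n", x$fh_grade$level[i],
                x$fh_grade$count[i], x$n, x$fh_grade$pct[i]))
  cat("  fundus hypopigmentation grades:\n")
  for (i in seq_len(nrow(x$fundus_grade)))
    cat(sprintf("    grade %s: %d/%d (%.1f%%)\n", x$fundus_grade$level[i],
                x$fundus_grade$count[i], x$n, x$fundus_grade$pct[i]))
  cat(sprintf("  strabismus %d/%d (%.1f%%), nystagmus %d/%d (%.1f%%), iris transillumination %d/%d (%.1f%%)\n",
              x$strabismus_count, x$n, x$strabismus_pct,
              x$nystagmus_count, x$n, x$nystagmus_pct,
              x$iris_transillumination_count, x$n,
              x$iris_transillumination_pct))
  invisible(x)
}
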