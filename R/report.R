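#' Run the integrated diagnostic pipeline
#'
#' Orchestrates the three evidence streams into one dossier per patient:
#' phenotype (Kruijt criteria), genotype (trio prioritization with optional
#' microsatellite phase resolution) and VEP misrouting (measured epochs or
#' a simulated cohort). Per-patient stage failures are recorded in the
#' dossier, not propagated; the run is deterministic given the
#' configuration and seed.
#'
#' @param config a list, or the path of a YAML file, with entries:
#'   \describe{
#'     \item{phenotype_table}{path to the phenotype TSV (required).}
#'     \item{vcf, ped, annotations}{paths for the genetics stage (optional;
#'       omit to skip genotype classification).}
#'     \item{str_table, str_ids}{optional STR TSV and a list/vector with
#'       \code{father}, \code{mother}, \code{sib1}, \code{sib2} ids; when
#'       present and the siblings are haplo-identical, ambiguous
#'       polymorphism phases are resolved.}
#'     \item{vep}{either \code{list(simulate = TRUE, ...)} with
#'       \code{\link{vep_sim_config}} fields (a cohort matching the patient
#'       list is simulated), or omitted (misrouting "not assessed").}
#'     \item{seed}{integer seed for any simulation (default 1).}
#'   }
#' @return object of class \code{oca_report}: \code{dossiers} (one per
#'   patient), \code{summary} (classification counts, cohort phenotype
#'   summary, group misrouting test), \code{provenance}.
#' @examples
#' cfg <- list(phenotype_table = oca_fixture("table1_phenotypes.tsv"),
#'             vcf = oca_fixture("table2_trios.vcf"),
#'             ped = oca_fixture("table2_trios.ped"),
#'             annotations = oca_fixture("table2_annotations.tsv"),
#'             str_table = oca_fixture("str_family45_synthetic.tsv"),
#'             str_ids = list(father = "F4_fa", mother = "F4_mo",
#'                            sib1 = "P4", sib2 = "P5"))
#' rep <- run_pipeline(cfg)
#' rep$summary$classification_counts
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  phen <- read_phenotype_table(config$phenotype_table)
  patients <- phen$patient_id

  # genetics stage
  genetics <- NULL
  phase_res <- NULL
  haplo <- NULL
  if (!is.null(config$vcf)) {
    genotypes <- read_trio_vcf(config$vcf)
    ped <- read_ped(config$ped)
    ann <- read_variant_annotations(config$annotations)
    if (!is.null(config$str_table)) {
      ids <- config$str_ids
      str <- read_str_genotypes(config$str_table)
      haplo <- haplo_identity(str, ids$sib1, ids$sib2, ids$father,
                              ids$mother)
      pre <- prioritize_cohort(genotypes, ped, ann)
      sibs <- c(ids$sib1, ids$sib2)
      phased_sibs <- Filter(Negate(is.null),
                            lapply(pre$individuals[sibs], `[[`, "phased"))
      phase_res <- str_phase_resolution(haplo, phased_sibs)
    }
    genetics <- prioritize_cohort(genotypes, ped, ann,
                                  phase_resolution = phase_res)
  }

  # VEP stage
  misrouting <- NULL
  if (isTRUE(config$vep$simulate)) {
    vep_cfg_args <- config$vep[setdiff(names(config$vep), "simulate")]
    vep_cfg_args$n_subjects <- length(patients)
    vep_cfg_args$seed <- seed
    cfg_vep <- do.call(vep_sim_config, vep_cfg_args)
    cohort <- simulate_vep_cohort(cfg_vep)
    # align simulated subjects with the patient list, in order
    names(cohort$recordings) <- unlist(lapply(seq_along(patients), function(i)
      paste(patients[i], c("OS", "OD"), sep = "_")))
    misrouting <- misrouting_cohort(cohort)
  }

  dossiers <- lapply(seq_along(patients), function(i) {
    pid <- patients[i]
    cls <- if (!is.null(genetics) && pid %in% names(genetics$individuals))
      genetics$individuals[[pid]]$classification else NULL
    has_mol <- !is.null(cls) &&
      cls$class %in% c("biallelic_pathogenic", "pathogenic_trans_hypomorphic")
    mis <- if (!is.null(misrouting) && pid %in% names(misrouting$subjects))
      misrouting$subjects[[pid]] else "not assessed"
    structure(list(
      patient_id = pid,
      phenotype = phen[i, ],
      misrouting = mis,
      classification = if (is.null(cls)) "not assessed" else cls,
      kruijt_clinical = assess_kruijt(phen[i, ], has_molecular_dx = FALSE),
      kruijt_with_molecular = assess_kruijt(phen[i, ],
                                            has_molecular_dx = has_mol)),
      class = "oca_dossier")
  })
  names(dossiers) <- patients

  summary <- list(
    phenotype = summarize_cohort(phen),
    classification_counts = if (is.null(genetics)) NULL else genetics$counts,
    haplo_identity = haplo,
    group_misrouting = if (is.null(misrouting)) NULL else misrouting$group,
    n_diagnostic_with_molecular = sum(vapply(dossiers, function(d)
      isTRUE(d$kruijt_with_molecular$diagnostic_with_molecular), logical(1))))

  structure(list(dossiers = dossiers, summary = summary,
                 genetics = genetics, misrouting = misrouting,
                 provenance = list(
                   inputs = config[intersect(names(config),
                                             c("phenotype_table", "vcf", "ped",
                                               "annotations", "str_table"))],
                   seed = seed,
                   config_hash = config_hash(config))),
            class = "oca_report")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.oca_dossier <- function(x, ...) {
  cat("== Dossier", x$patient_id, "==\n")
  cat("Genotype class:",
      if (is.character(x$classification)) x$classification
      else x$classification$class, "\n")
  if (inherits(x$misrouting, "misrouting_result")) print(x$misrouting)
  else cat("Misrouting: not assessed\n")
  print(x$kruijt_with_molecular)
  invisible(x)
}

#' @export
print.oca_report <- function(x, ...) {
  cat("Integrated diagnostic report,", length(x$dossiers), "patients\n\n")
  print(x$summary$phenotype)
  if (!is.null(x$summary$classification_counts)) {
    cat("\nGenotype classification counts:\n")
    print(x$summary$classification_counts)
  }
  if (!is.null(x$summary$haplo_identity)) print(x$summary$haplo_identity)
  if (!is.null(x$summary$group_misrouting)) print(x$summary$group_misrouting)
  cat("Kruijt-diagnostic with molecular dx:",
      x$summary$n_diagnostic_with_molecular, "of", length(x$dossiers), "\n")
  invisible(x)
}
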