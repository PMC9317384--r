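#' Trio prioritization and diagnostic classification of a cohort
#'
#' End-to-end segregation analysis: applies the variant retention cascade
#' (\code{\link{filter_variants}}), phases every affected individual's
#' retained variants by trio segregation (\code{\link{phase_trio}}), and
#' classifies the phased genotype (\code{\link{classify_genotype}}).
#' Affected individuals without genotyped parents are phased through a
#' phased offspring where possible (\code{\link{phase_from_offspring}} —
#' the cascade-diagnosis situation of an affected parent). An external
#' phase resolution (e.g. from microsatellite haplo-identity,
#' \code{\link{str_phase_resolution}}) can upgrade families whose
#' polymorphism phase is ambiguous. Per-individual failures are recorded,
#' not propagated.
#'
#' @param genotypes data.frame: \code{variant} column plus one genotype
#'   column per individual (\code{WT}/\code{Het}/\code{Hom}/NA).
#' @param ped pedigree data.frame (\code{family_id}, \code{id},
#'   \code{father_id}, \code{mother_id}, \code{affected}).
#' @param annotations annotation data.frame (one row per variant,
#'   \code{hgvs_p} matching \code{genotypes$variant}); see
#'   \code{\link{filter_variants}}.
#' @param panel gene panel (see \code{\link{default_gene_panel}}).
#' @param phase_resolution optional named list: individual id -> named
#'   character vector (variant -> \code{"paternal"}/\code{"maternal"}).
#' @return object of class \code{prioritization_report}: \code{individuals}
#'   (list with phased genotype, classification, status per affected id),
#'   \code{table} (per-individual summary), \code{counts} (classification
#'   counts), \code{filter} (the retention audit).
#' @export
prioritize_cohort <- function(genotypes, ped, annotations,
                              panel = default_gene_panel(),
                              phase_resolution = NULL) {
  flt <- filter_variants(annotations, panel)
  retained <- flt$retained
  keep <- genotypes$variant %in% retained$hgvs_p
  geno <- genotypes[keep, , drop = FALSE]
  pathogenic_set <- retained$hgvs_p[retained$acmg_class %in% c("P", "LP") &
                                      !is_hypomorphic(retained$gene,
                                                      retained$hgvs_p)]
  affected <- ped$id[ped$affected]
  individuals <- list()
  deferred <- character(0)
  phase_one <- function(ind) {
    row <- ped[ped$id == ind, ]
    fa <- row$father_id; mo <- row$mother_id
    if (fa %in% names(geno) && mo %in% names(geno)) {
      trios <- data.frame(variant = geno$variant,
                          proband = geno[[ind]],
                          father = geno[[fa]],
                          mother = geno[[mo]],
                          stringsAsFactors = FALSE)
      trios <- trios[!(trios$proband == "WT" & trios$father == "WT" &
                         trios$mother == "WT"), , drop = FALSE]
      return(phase_trio(trios, individual = ind))
    }
    # cascade case: phase through a fully phased offspring
    children <- ped$id[ped$father_id == ind | ped$mother_id == ind]
    for (ch in children) {
      chp <- individuals[[ch]]$phased
      if (is.null(chp) || chp$phase_status != "resolved") next
      role <- if (any(ped$father_id == ind & ped$id == ch)) "father"
              else "mother"
      transmitted <- if (role == "father") chp$paternal else chp$maternal
      gts <- geno[[ind]]
      names(gts) <- geno$variant
      gts <- gts[!is.na(gts)]
      return(phase_from_offspring(as.list(gts), transmitted, role = role,
                                  individual = ind))
    }
    stop("no genotyped parents and no phased offspring for ", ind)
  }
  # two passes so offspring get phased before their affected parents
  order_ids <- c(
    affected[vapply(affected, function(i) {
      r <- ped[ped$id == i, ]
      r$father_id %in% names(geno) && r$mother_id %in% names(geno)
    }, logical(1))],
    setdiff(affected, affected[vapply(affected, function(i) {
      r <- ped[ped$id == i, ]
      r$father_id %in% names(geno) && r$mother_id %in% names(geno)
    }, logical(1))]))
  for (ind in order_ids) {
    rec <- tryCatch({
      phased <- phase_one(ind)
      if (!is.null(phase_resolution[[ind]]))
        phased <- resolve_phase(phased, phase_resolution[[ind]])
      cls <- classify_genotype(phased, pathogenic_set)
      list(individual = ind, phased = phased, classification = cls,
           status = "ok")
    }, error = function(e)
      list(individual = ind, phased = NULL, classification = NULL,
           status = paste("error:", conditionMessage(e))))
    individuals[[ind]] <- rec
  }
  if (length(individuals) == 0) {
    tab <- data.frame(individual = character(0), family = character(0),
                      class = character(0), phase_status = character(0),
                      status = character(0), stringsAsFactors = FALSE)
    counts <- table(factor(character(0),
                           levels = c("biallelic_pathogenic",
                                      "pathogenic_trans_hypomorphic",
                                      "ambiguous_requires_haplotyping",
                                      "carrier_only", "none")))
    return(structure(list(individuals = individuals, table = tab,
                          counts = counts, filter = flt$audit),
                     class = "prioritization_report"))
  }
  tab <- do.call(rbind, lapply(individuals, function(r) data.frame(
    individual = r$individual,
    family = ped$family_id[match(r$individual, ped$id)],
    class = if (is.null(r$classification)) NA_character_
            else r$classification$class,
    phase_status = if (is.null(r$phased)) NA_character_
                   else r$phased$phase_status,
    status = r$status, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  counts <- table(factor(tab$class,
                         levels = c("biallelic_pathogenic",
                                    "pathogenic_trans_hypomorphic",
                                    "ambiguous_requires_haplotyping",
                                    "carrier_only", "none")))
  structure(list(individuals = individuals, table = tab,
                 counts = counts, filter = flt$audit),
            class = "prioritization_report")
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat("Trio prioritization,", nrow(x$table), "affected individuals\n")
  print(x$table)
  cat("\nClassification counts:\n")
  print(x$counts)
  invisible(x)
}
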