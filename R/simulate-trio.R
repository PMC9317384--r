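#' Trio genotype configuration
#'
#' Describes one family's genotypes over a set of variants, for the trio
#' simulator. Members are the proband, father, mother and optional
#' additional children (siblings) of the same parents.
#'
#' @param family_id family identifier.
#' @param proband,father,mother individual identifiers.
#' @param genotypes data.frame with a \code{variant} column (identifier) and
#'   one column per individual id, values \code{WT}/\code{Het}/\code{Hom}.
#' @param siblings character vector of additional child ids (columns of
#'   \code{genotypes}).
#' @param true_phase optional named list: child id -> named character vector
#'   variant -> \code{"paternal"}/\code{"maternal"} (ground-truth phase of
#'   heterozygous variants), checked for consistency with the genotypes.
#' @return object of class \code{trio_config}.
#' @export
trio_config <- function(family_id, proband, father, mother, genotypes,
                        siblings = character(0), true_phase = NULL) {
  need <- c(proband, father, mother, siblings)
  missing_cols <- setdiff(need, names(genotypes))
  if (length(missing_cols) > 0)
    stop("genotype columns missing for: ", paste(missing_cols, collapse = ", "))
  structure(list(family_id = family_id, proband = proband, father = father,
                 mother = mother, siblings = siblings,
                 genotypes = genotypes, true_phase = true_phase),
            class = "trio_config")
}

#' Emit a family's trio genotypes, validating Mendelian consistency
#'
#' Every child's genotype at every variant must be producible from one
#' paternal plus one maternal transmitted allele; any configured true phase
#' must be consistent with the genotypes (a variant phased to a parent must
#' be transmissible by that parent). Inconsistent configurations are
#' rejected with an error.
#'
#' @param cfg a \code{\link{trio_config}}.
#' @return the validated genotype data.frame (variant x individuals), with
#'   the family structure attached as attributes \code{family_id},
#'   \code{proband}, \code{father}, \code{mother}, \code{siblings}.
#' @export
simulate_trio <- function(cfg) {
  stopifnot(inherits(cfg, "trio_config"))
  g <- cfg$genotypes
  for (child in c(cfg$proband, cfg$siblings)) {
    for (i in seq_len(nrow(g))) {
      mc <- check_mendelian(g[[child]][i], g[[cfg$father]][i],
                            g[[cfg$mother]][i])
      if (mc != "consistent")
        stop("family ", cfg$family_id, ": ", mc, " trio at variant ",
             g$variant[i], " for child ", child)
    }
    ph <- cfg$true_phase[[child]]
    if (!is.null(ph)) {
      for (v in names(ph)) {
        i <- match(v, g$variant)
        parent <- if (ph[[v]] == "paternal") cfg$father else cfg$mother
        if (g[[child]][i] == "WT" || g[[parent]][i] == "WT")
          stop("family ", cfg$family_id, ": configured phase of ", v,
               " for ", child, " is inconsistent with the genotypes")
      }
    }
  }
  structure(g, family_id = cfg$family_id, proband = cfg$proband,
            father = cfg$father, mother = cfg$mother,
            siblings = cfg$siblings)
}

#' Catalogue of the TYR variants of the study cohort
#'
#' Coding-level labels, consequences and GRCh37 coordinates for the
#' hypomorphic polymorphism pair and the six family-specific pathogenic
#' variants. The two polymorphisms sit at their dbSNP loci; pathogenic
#' variant positions are reconstructed from the cDNA offsets within the TYR
#' locus (synthetic but internally consistent — the coordinates serve as
#' identifiers for the fixture VCF, not for annotation lookups).
#'
#' @return data.frame: \code{hgvs_p}, \code{hgvs_c}, \code{gene},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{consequence},
#'   \code{pathogenic}.
#' @export
tyr_variant_catalogue <- function() {
  data.frame(
    hgvs_p = c("p.(Ser192Tyr)", "p.(Arg402Gln)", "p.(Arg77Gln)",
               "p.(Cys247Arg)", "p.(Met96Asnfs*73)", "p.(Gly109Arg)",
               "p.(Gly47Asp)", "p.(Met1Val)", "p.(Pro152Arg)"),
    hgvs_c = c("c.575C>A", "c.1205G>A", "c.230G>A", "c.739T>C",
               "c.286dupA", "c.325G>A", "c.140G>A", "c.1A>G", "c.455C>G"),
    gene = "TYR", chrom = "11",
    pos = c(88911696L, 89017961L, 88911351L, 88924200L, 88911407L,
            88911446L, 88911261L, 88911122L, 88911576L),
    ref = c("C", "G", "G", "T", "A", "G", "G", "A", "C"),
    alt = c("A", "A", "A", "C", "AA", "A", "A", "G", "G"),
    consequence = c("missense", "missense", "missense", "missense",
                    "frameshift", "missense", "missense", "start_loss",
                    "missense"),
    pathogenic = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' The study cohort's six family genotype configurations
#'
#' Eight affected individuals in six families: five trio probands, one
#' affected sibling pair with their parents, and one affected parent
#' (cascade diagnosis) of a trio proband. Genotypes cover the two
#' hypomorphic polymorphisms and each family's pathogenic variant(s).
#'
#' @return list: \code{families} (list of \code{\link{trio_config}}),
#'   \code{patients} (data.frame patient -> family, individual id),
#'   \code{catalogue} (\code{\link{tyr_variant_catalogue}}).
#' @export
study_cohort_trios <- function() {
  S <- "p.(Ser192Tyr)"; R <- "p.(Arg402Gln)"
  gdf <- function(variants, ...) {
    cols <- list(...)
    do.call(data.frame, c(list(variant = variants, stringsAsFactors = FALSE),
                          cols))
  }
  fams <- list(
    trio_config("F1", "P1", "F1_fa", "F1_mo",
      gdf(c(R, S, "p.(Arg77Gln)"),
          P1 = c("Het", "Hom", "Het"),
          F1_fa = c("WT", "Hom", "Het"),
          F1_mo = c("Hom", "Het", "WT"))),
    trio_config("F2", "P2", "F2_fa", "F2_mo",
      gdf(c(R, S, "p.(Cys247Arg)"),
          P2 = c("Hom", "Het", "Het"),
          F2_fa = c("Hom", "Het", "WT"),
          F2_mo = c("Het", "WT", "Het"))),
    trio_config("F3", "P3", "F3_fa", "F3_mo",
      gdf(c(R, S, "p.(Met96Asnfs*73)", "p.(Gly109Arg)"),
          P3 = c("WT", "WT", "Het", "Het"),
          F3_fa = c("WT", "WT", "WT", "Het"),
          F3_mo = c("WT", "WT", "Het", "WT"))),
    trio_config("F4", "P4", "F4_fa", "F4_mo",
      gdf(c(R, S, "p.(Gly47Asp)"),
          P4 = c("Het", "Het", "Het"),
          P5 = c("Het", "Het", "Het"),
          F4_fa = c("Het", "Hom", "WT"),
          F4_mo = c("Het", "WT", "Het")),
      siblings = "P5",
      true_phase = list(
        P4 = c("p.(Arg402Gln)" = "paternal", "p.(Ser192Tyr)" = "paternal",
               "p.(Gly47Asp)" = "maternal"),
        P5 = c("p.(Arg402Gln)" = "paternal", "p.(Ser192Tyr)" = "paternal",
               "p.(Gly47Asp)" = "maternal"))),
    trio_config("F5", "P7", "P8", "F5_mo",
      gdf(c(R, S, "p.(Pro152Arg)"),
          P7 = c("Hom", "Het", "Het"),
          P8 = c("Hom", "Het", "Het"),
          F5_mo = c("Het", "Hom", "WT"))),
    trio_config("F6", "P6", "F6_fa", "F6_mo",
      gdf(c(R, S, "p.(Met1Val)"),
          P6 = c("Hom", "Het", "Het"),
          F6_fa = c("Het", "Hom", "WT"),
          F6_mo = c("Het", "Het", "Het"))))
  names(fams) <- vapply(fams, `[[`, character(1), "family_id")
  patients <- data.frame(
    patient = paste0("P", 1:8),
    family = c("F1", "F2", "F3", "F4", "F4", "F6", "F5", "F5"),
    individual = paste0("P", 1:8),
    stringsAsFactors = FALSE)
  list(families = fams, patients = patients,
       catalogue = tyr_variant_catalogue())
}

#' Flatten a set of family configurations into one genotype table + pedigree
#'
#' @param families list of \code{\link{trio_config}}.
#' @param affected character vector of affected individual ids.
#' @return list: \code{genotypes} (data.frame variant x individuals; WT where
#'   a family does not segregate a variant), \code{ped} (data.frame:
#'   family_id, id, father_id, mother_id, sex, affected).
#' @export
flatten_families <- function(families, affected = character(0)) {
  all_vars <- unique(unlist(lapply(families, function(f) f$genotypes$variant)))
  geno <- data.frame(variant = all_vars, stringsAsFactors = FALSE)
  ped <- NULL
  for (f in families) {
    g <- simulate_trio(f)
    members <- c(f$proband, f$siblings, f$father, f$mother)
    for (m in members) {
      col <- rep("WT", length(all_vars))
      i <- match(g$variant, all_vars)
      col[i] <- g[[m]]
      geno[[m]] <- col
    }
    ped <- rbind(ped, data.frame(
      family_id = f$family_id, id = members,
      father_id = c(rep(f$father, 1 + length(f$siblings)), "0", "0"),
      mother_id = c(rep(f$mother, 1 + length(f$siblings)), "0", "0"),
      sex = c(rep(0L, 1 + length(f$siblings)), 1L, 2L),
      affected = members %in% affected,
      stringsAsFactors = FALSE))
  }
  list(genotypes = geno, ped = ped)
}
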