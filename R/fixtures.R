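#' Path to a packaged fixture file
#'
#' Packaged fixtures: \code{table1_phenotypes.tsv} (the study cohort's
#' phenotype table), \code{table2_trios.vcf} / \code{table2_trios.ped}
#' (the six families' TYR genotypes and pedigree),
#' \code{table2_annotations.tsv} (annotation sidecar for the nine cohort
#' variants), \code{montage_occipital.yaml} (9+9 occipital electrode sets),
#' \code{str_family45_synthetic.tsv} (synthetic 9-marker STR pedigree for
#' the sibling family, constructed to be haplo-identical).
#'
#' @param name fixture file name; with no argument, lists available
#'   fixtures.
#' @return file path (or a character vector of names).
#' @export
oca_fixture <- function(name = NULL) {
  if (is.null(name))
    return(list.files(system.file("extdata", package = "ocadx")))
  path <- system.file("extdata", name, package = "ocadx")
  if (path == "") stop("no packaged fixture named '", name, "'")
  path
}

#' Load all packaged study fixtures
#'
#' @return list: \code{phenotypes}, \code{genotypes}, \code{ped},
#'   \code{annotations}, \code{montage}, \code{str}.
#' @export
load_study_fixtures <- function() {
  list(phenotypes = read_phenotype_table(oca_fixture("table1_phenotypes.tsv")),
       genotypes = read_trio_vcf(oca_fixture("table2_trios.vcf")),
       ped = read_ped(oca_fixture("table2_trios.ped")),
       annotations = read_variant_annotations(
         oca_fixture("table2_annotations.tsv")),
       montage = read_montage(oca_fixture("montage_occipital.yaml")),
       str = read_str_genotypes(oca_fixture("str_family45_synthetic.tsv")))
}
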