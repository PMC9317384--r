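#' Default gene panel for foveal hypoplasia / albinism
#'
#' Genes with their inheritance mode: the non-syndromic oculocutaneous
#' albinism genes (autosomal recessive), PAX6 (autosomal dominant) and the
#' X-linked ocular albinism gene GPR143. Editable: pass your own data.frame
#' with columns \code{gene} and \code{inheritance} (\code{AR}, \code{AD},
#' \code{XL}) anywhere a panel is accepted.
#'
#' @return data.frame with columns \code{gene}, \code{inheritance}.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("TYR", "OCA2", "TYRP1", "SLC45A2", "SLC38A8", "DCT",
             "PAX6", "GPR143"),
    inheritance = c(rep("AR", 6), "AD", "XL"),
    stringsAsFactors = FALSE)
}

#' Names of the hypomorphic TYR polymorphism pair
#' @return character vector \code{c("Ser192Tyr", "Arg402Gln")}.
#' @export
hypomorphic_pair <- function() c("Ser192Tyr", "Arg402Gln")

is_hypomorphic <- function(gene, hgvs_p,
                           pair = hypomorphic_pair()) {
  gene == "TYR" & vapply(hgvs_p, function(h)
    any(vapply(pair, grepl, logical(1), x = h, fixed = TRUE)), logical(1))
}

predictor_tools <- function() c("sift", "polyphen2", "mutation_taster",
                                "mutation_assessor", "fathmm", "fathmm_mkl")

admissible_consequences <- function() c("missense", "frameshift",
                                        "inframe_indel", "nonsense",
                                        "synonymous", "splice_site_20bp",
                                        "start_loss")

#' Variant retention cascade
#'
#' Applies the exome prioritization filter to an annotated variant table.
#' A variant is retained iff all of the following hold:
#' \enumerate{
#'   \item consequence in the admissible set (non-synonymous, short indel,
#'     synonymous or splice-site within 20 bp);
#'   \item gene is on the panel;
#'   \item maximum minor allele frequency across the four population sources
#'     (1000G, EVS, dbSNP, in-house; missing treated as 0 = absent) is
#'     at most 0.01 for AR genes and 0.001 for AD genes (XL follows the AR
#'     threshold);
#'   \item no homozygous/hemizygous carriers in gnomAD;
#'   \item known pathogenic in ClinVar/HGMD, or called damaging by at least
#'     3 of the 6 in silico predictors; synonymous and splice variants
#'     additionally require a damaging splice prediction;
#'   \item ACMG class P, LP or VUS.
#' }
#' Override: the TYR polymorphisms Ser192Tyr and Arg402Gln are always
#' retained and tagged \code{"manual-inspection"}, bypassing rules 3-6 —
#' they are common (allele frequencies about 25\% and 18\%) and individually
#' benign, but diagnostic when both lie in trans with a pathogenic variant.
#'
#' @param variants data.frame with columns \code{gene}, \code{hgvs_p},
#'   \code{consequence}, \code{maf_1000g}, \code{maf_evs}, \code{maf_dbsnp},
#'   \code{maf_inhouse}, \code{gnomad_hom_or_hemi},
#'   \code{pred_sift} \dots \code{pred_fathmm_mkl} (values \code{damaging},
#'   \code{benign}, \code{missing}), \code{in_clinvar_or_hgmd},
#'   \code{splice_predicted_damaging}, \code{acmg_class}.
#' @param panel gene panel data.frame (see \code{\link{default_gene_panel}}).
#' @param maf_ar,maf_ad MAF thresholds for recessive / dominant genes.
#' @return list: \code{retained} (subset of \code{variants} with an added
#'   logical column \code{manual_inspection}), \code{audit} (one row per
#'   input variant: retained flag, override flag, failed rules).
#' @export
filter_variants <- function(variants, panel = default_gene_panel(),
                            maf_ar = 0.01, maf_ad = 0.001) {
  if (nrow(variants) == 0)
    return(list(retained = cbind(variants, manual_inspection = logical(0)),
                audit = data.frame(hgvs_p = character(0),
                                   retained = logical(0),
                                   override = logical(0),
                                   failed_rules = character(0))))
  pv <- as.matrix(variants[, paste0("pred_", predictor_tools())])
  n_damaging <- rowSums(pv == "damaging")
  mafs <- as.matrix(variants[, c("maf_1000g", "maf_evs", "maf_dbsnp",
                                 "maf_inhouse")])
  mafs[is.na(mafs)] <- 0   # absent from a database counts as rare
  max_maf <- apply(mafs, 1, max)
  inh <- panel$inheritance[match(variants$gene, panel$gene)]
  maf_thr <- ifelse(is.na(inh), NA, ifelse(inh == "AD", maf_ad, maf_ar))
  needs_splice <- variants$consequence %in% c("synonymous", "splice_site_20bp")

  fails <- list(
    consequence = !(variants$consequence %in% admissible_consequences()),
    panel = is.na(inh),
    maf = !is.na(maf_thr) & max_maf > maf_thr,
    gnomad_hom = variants$gnomad_hom_or_hemi > 0,
    evidence = !(variants$in_clinvar_or_hgmd | n_damaging >= 3) |
      (needs_splice & !variants$splice_predicted_damaging),
    acmg = !(variants$acmg_class %in% c("P", "LP", "VUS")))
  fail_mat <- do.call(cbind, fails)
  override <- is_hypomorphic(variants$gene, variants$hgvs_p)
  # override bypasses rules 3-6 but not consequence/panel admissibility
  hard_fail <- fails$consequence | fails$panel
  retained <- ifelse(override, !hard_fail, rowSums(fail_mat) == 0)
  failed_rules <- apply(fail_mat, 1, function(f)
    paste(colnames(fail_mat)[f], collapse = ";"))
  audit <- data.frame(hgvs_p = variants$hgvs_p, gene = variants$gene,
                      retained = retained, override = override,
                      failed_rules = failed_rules,
                      stringsAsFactors = FALSE)
  out <- variants[retained, , drop = FALSE]
  out$manual_inspection <- override[retained]
  list(retained = out, audit = audit)
}

# alleles a parent with genotype g can transmit (count of alt alleles)
transmissible <- function(g) switch(g, WT = 0L, Het = 0:1, Hom = 1L,
                                    stop("unknown genotype '", g, "'"))

gt_count <- function(g) switch(g, WT = 0L, Het = 1L, Hom = 2L,
                               stop("unknown genotype '", g, "'"))

#' Mendelian consistency of a trio genotype
#'
#' A trio is consistent at a variant iff the proband's allele count can be
#' written as one paternal plus one maternal transmitted allele.
#'
#' @param proband,father,mother genotypes, each \code{"WT"}, \code{"Het"},
#'   \code{"Hom"} or \code{NA}.
#' @return \code{"consistent"}, \code{"inconsistent"} or \code{"untestable"}
#'   (missing genotype).
#' @export
check_mendelian <- function(proband, father, mother) {
  if (any(is.na(c(proband, father, mother)))) return("untestable")
  cnt <- gt_count(proband)
  ok <- any(outer(transmissible(father), transmissible(mother), "+") == cnt)
  if (ok) "consistent" else "inconsistent"
}

new_phased_genotype <- function(paternal, maternal, ambiguous,
                                individual = NA_character_) {
  structure(list(individual = individual,
                 paternal = sort(paternal), maternal = sort(maternal),
                 ambiguous = sort(ambiguous),
                 phase_status = if (length(ambiguous) == 0) "resolved"
                                else "ambiguous"),
            class = "phased_genotype")
}

#' @export
print.phased_genotype <- function(x, ...) {
  fmt <- function(v) if (length(v) == 0) "-" else paste(v, collapse = ", ")
  cat("Phased genotype", if (!is.na(x$individual)) paste0("(", x$individual, ")"),
      "-", x$phase_status, "\n")
  cat("  paternal :", fmt(x$paternal), "\n")
  cat("  maternal :", fmt(x$maternal), "\n")
  if (length(x$ambiguous) > 0)
    cat("  ambiguous:", fmt(x$ambiguous), "\n")
  invisible(x)
}

#' Phase a proband's variants by trio segregation
#'
#' For each variant carried by the proband: homozygous variants sit on both
#' alleles; a heterozygous variant is placed on the paternal (maternal)
#' allele when the father (mother) is the only carrier parent, or when that
#' parent is homozygous (a homozygous parent necessarily transmits the
#' variant, so the other transmitted allele must be wild type); when both
#' parents are heterozygous carriers the phase is ambiguous.
#'
#' @param trios data.frame with columns \code{variant} (identifier, e.g. the
#'   protein-level HGVS label), \code{proband}, \code{father}, \code{mother}
#'   (genotypes \code{WT}/\code{Het}/\code{Hom}); one row per variant of one
#'   gene in one family.
#' @param individual optional proband identifier carried into the result.
#' @return a \code{phased_genotype}: character vectors \code{paternal},
#'   \code{maternal}, \code{ambiguous} and \code{phase_status}
#'   (\code{"resolved"} iff no variant is ambiguous).
#' @export
phase_trio <- function(trios, individual = NA_character_) {
  pat <- mat <- amb <- character(0)
  for (i in seq_len(nrow(trios))) {
    v <- trios$variant[i]
    mc <- check_mendelian(trios$proband[i], trios$father[i], trios$mother[i])
    if (mc == "inconsistent")
      stop("Mendelian inconsistency at variant ", v)
    if (mc == "untestable")
      stop("missing genotype at variant ", v)
    g <- trios$proband[i]
    if (g == "WT") next
    if (g == "Hom") { pat <- c(pat, v); mat <- c(mat, v); next }
    fa <- trios$father[i]; mo <- trios$mother[i]
    if (fa == "Hom")      pat <- c(pat, v)   # father must transmit it
    else if (mo == "Hom") mat <- c(mat, v)
    else if (fa == "Het" && mo == "WT") pat <- c(pat, v)
    else if (mo == "Het" && fa == "WT") mat <- c(mat, v)
    else amb <- c(amb, v)                    # both parents Het
  }
  new_phased_genotype(pat, mat, amb, individual)
}

#' Phase a parent through a phased offspring
#'
#' Segregation in reverse: when an affected parent's own parents are not
#' available, but the allele this parent transmitted to a phased child is
#' fully resolved, the parent's two alleles are the transmitted set and its
#' complement (homozygous variants on both).
#'
#' @param genotypes named character vector of the parent's genotypes
#'   (\code{WT}/\code{Het}/\code{Hom}), names = variant identifiers.
#' @param transmitted character vector of variant identifiers on the allele
#'   the parent transmitted to the child.
#' @param individual optional identifier.
#' @return a \code{phased_genotype} (transmitted allele reported as
#'   \code{paternal} when \code{role = "father"}, else \code{maternal}).
#' @param role \code{"father"} or \code{"mother"} (decides the labelling of
#'   the transmitted allele in the result; classification is label-symmetric).
#' @export
phase_from_offspring <- function(genotypes, transmitted,
                                 role = c("father", "mother"),
                                 individual = NA_character_) {
  role <- match.arg(role)
  a1 <- a2 <- character(0)   # a1 = transmitted allele
  for (v in names(genotypes)) {
    g <- genotypes[[v]]
    if (g == "WT") {
      if (v %in% transmitted)
        stop("variant ", v, " reported transmitted but parent is WT")
      next
    }
    if (g == "Hom") { a1 <- c(a1, v); a2 <- c(a2, v); next }
    if (v %in% transmitted) a1 <- c(a1, v) else a2 <- c(a2, v)
  }
  extra <- setdiff(transmitted, names(genotypes))
  if (length(extra) > 0)
    stop("transmitted variant(s) not in parent's genotypes: ",
         paste(extra, collapse = ", "))
  if (role == "father") new_phased_genotype(a1, a2, character(0), individual)
  else new_phased_genotype(a2, a1, character(0), individual)
}

classify_resolved <- function(allele_a, allele_b, pathogenic_set,
                              pair = hypomorphic_pair()) {
  has_path <- function(x) any(x %in% pathogenic_set)
  has_pair <- function(x) all(vapply(pair, function(p)
    any(grepl(p, x, fixed = TRUE)), logical(1)))
  # diagnostically complete content: a pathogenic variant or the full
  # hypomorphic pair (a lone polymorphism is not a carrier haplotype)
  content <- function(x) has_path(x) || has_pair(x)
  if (has_path(allele_a) && has_path(allele_b)) return("biallelic_pathogenic")
  if ((has_path(allele_a) && has_pair(allele_b)) ||
      (has_path(allele_b) && has_pair(allele_a)))
    return("pathogenic_trans_hypomorphic")
  if (xor(content(allele_a), content(allele_b))) return("carrier_only")
  "none"
}

#' Diagnostic classification of a phased genotype
#'
#' Classes, in order of precedence:
#' \code{biallelic_pathogenic} (each allele carries a pathogenic variant),
#' \code{pathogenic_trans_hypomorphic} (one allele pathogenic, the other
#' carrying \emph{both} members of the hypomorphic pair Ser192Tyr +
#' Arg402Gln), \code{carrier_only} (relevant content on exactly one allele),
#' \code{none}. If the phase of some variants is unresolved, all consistent
#' assignments of the ambiguous variants to the two alleles are enumerated;
#' when they do not agree on the class the verdict is
#' \code{ambiguous_requires_haplotyping}.
#'
#' @param phased a \code{phased_genotype}.
#' @param pathogenic_set character vector of variant identifiers considered
#'   pathogenic.
#' @param pair the hypomorphic polymorphism pair (default
#'   \code{\link{hypomorphic_pair}}).
#' @return list of class \code{diagnostic_classification}: \code{class},
#'   \code{supporting} (variants on the phased alleles), \code{candidates}
#'   (classes over the ambiguity envelope).
#' @export
classify_genotype <- function(phased, pathogenic_set,
                              pair = hypomorphic_pair()) {
  stopifnot(inherits(phased, "phased_genotype"))
  amb <- phased$ambiguous
  k <- length(amb)
  classes <- character(0)
  for (mask in 0:(2^k - 1)) {
    to_pat <- if (k > 0) amb[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0] else character(0)
    classes <- c(classes, classify_resolved(
      c(phased$paternal, to_pat),
      c(phased$maternal, setdiff(amb, to_pat)),
      pathogenic_set, pair))
  }
  classes <- unique(classes)
  cls <- if (length(classes) == 1) classes else "ambiguous_requires_haplotyping"
  structure(list(class = cls,
                 supporting = sort(unique(c(phased$paternal, phased$maternal,
                                            phased$ambiguous))),
                 candidates = classes),
            class = "diagnostic_classification")
}

#' @export
print.diagnostic_classification <- function(x, ...) {
  cat("Diagnostic class:", x$class, "\n")
  if (length(x$supporting) > 0)
    cat("  variants:", paste(x$supporting, collapse = ", "), "\n")
  if (length(x$candidates) > 1)
    cat("  candidate classes:", paste(x$candidates, collapse = " | "), "\n")
  invisible(x)
}

#' Resolve ambiguous phase with external evidence
#'
#' Applies an assignment (e.g. derived from microsatellite haplo-identity of
#' siblings) of ambiguous variants to parental alleles.
#'
#' @param phased a \code{phased_genotype}.
#' @param assignments named character vector: variant identifier ->
#'   \code{"paternal"} or \code{"maternal"}.
#' @return the updated \code{phased_genotype}.
#' @export
resolve_phase <- function(phased, assignments) {
  stopifnot(inherits(phased, "phased_genotype"))
  for (v in names(assignments)) {
    if (!(v %in% phased$ambiguous)) next
    side <- match.arg(assignments[[v]], c("paternal", "maternal"))
    phased[[side]] <- sort(c(phased[[side]], v))
    phased$ambiguous <- setdiff(phased$ambiguous, v)
  }
  phased$phase_status <- if (length(phased$ambiguous) == 0) "resolved"
                         else "ambiguous"
  phased
}
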