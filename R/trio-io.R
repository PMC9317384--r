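#' Write trio genotypes as a VCF v4.2 file
#'
#' One sample column per individual; genotypes are unphased GT calls
#' (\code{0/0}, \code{0/1}, \code{1/1}, \code{./.}). Variant identity,
#' gene and protein/cDNA labels travel in the INFO field
#' (\code{GENE}, \code{HGVSP}, \code{HGVSC}).
#'
#' @param genotypes data.frame: \code{variant} column (hgvs_p identifiers)
#'   plus one column per individual with \code{WT}/\code{Het}/\code{Hom}/NA.
#' @param catalogue variant catalogue with \code{hgvs_p}, \code{hgvs_c},
#'   \code{gene}, \code{chrom}, \code{pos}, \code{ref}, \code{alt}
#'   (see \code{\link{tyr_variant_catalogue}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trio_vcf <- function(genotypes, catalogue, path) {
  idx <- match(genotypes$variant, catalogue$hgvs_p)
  if (anyNA(idx))
    stop("variants missing from catalogue: ",
         paste(genotypes$variant[is.na(idx)], collapse = ", "))
  cat_rows <- catalogue[idx, ]
  samples <- setdiff(names(genotypes), "variant")
  ord <- order(cat_rows$chrom, cat_rows$pos)
  gt_code <- function(g) ifelse(is.na(g), "./.",
                                c(WT = "0/0", Het = "0/1", Hom = "1/1")[g])
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=HGVSP,Number=1,Type=String,Description="Protein-level HGVS">',
    '##INFO=<ID=HGVSC,Number=1,Type=String,Description="cDNA-level HGVS">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(ord, function(i) {
    gts <- vapply(samples, function(s) gt_code(genotypes[[s]][i]),
                  character(1))
    paste(c(cat_rows$chrom[i], cat_rows$pos[i], ".", cat_rows$ref[i],
            cat_rows$alt[i], ".", "PASS",
            sprintf("GENE=%s;HGVSP=%s;HGVSC=%s", cat_rows$gene[i],
                    genotypes$variant[i], cat_rows$hgvs_c[i]),
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trio VCF back into a genotype table
#'
#' Inverse of \code{\link{write_trio_vcf}}; variants are identified by the
#' \code{HGVSP} INFO key.
#'
#' @param path VCF file path.
#' @return data.frame with columns \code{variant}, \code{gene}, and one
#'   genotype column (\code{WT}/\code{Het}/\code{Hom}/NA) per sample.
#' @export
read_trio_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  info <- v@fix[, "INFO"]
  grab <- function(key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", info)
  gt <- vcfR::extract.gt(v, element = "GT")
  to_state <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_character_, length(g))
    out[g %in% "0/0"] <- "WT"
    out[g %in% c("0/1", "1/0")] <- "Het"
    out[g %in% "1/1"] <- "Hom"
    out
  }
  res <- data.frame(variant = unname(grab("HGVSP")),
                    gene = unname(grab("GENE")),
                    stringsAsFactors = FALSE)
  for (s in colnames(gt)) res[[s]] <- to_state(gt[, s])
  res
}

#' Write / read a 6-column PED pedigree file
#'
#' Columns: family, individual, father (0 = founder), mother, sex
#' (1 male, 2 female, 0 unknown), phenotype (2 affected, 1 unaffected).
#'
#' @param ped data.frame with columns \code{family_id}, \code{id},
#'   \code{father_id}, \code{mother_id}, \code{sex}, \code{affected}
#'   (logical).
#' @param path file path.
#' @return \code{write_ped}: \code{path} invisibly; \code{read_ped}: the
#'   pedigree data.frame.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(ped$family_id, ped$id, ped$father_id, ped$mother_id,
                    ped$sex, ifelse(ped$affected, 2L, 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  p <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "character", "integer", "integer"))
  names(p) <- c("family_id", "id", "father_id", "mother_id", "sex",
                "phenotype")
  p$affected <- p$phenotype == 2L
  p$phenotype <- NULL
  p
}

#' Read an annotation sidecar table
#'
#' Tab-separated annotation table keyed by \code{hgvs_p}, carrying the
#' columns consumed by \code{\link{filter_variants}} (population
#' frequencies, predictor calls, ClinVar/HGMD flag, splice prediction,
#' ACMG class). Predictor calls must already be normalized to
#' \code{damaging}/\code{benign}/\code{missing}.
#'
#' @param path TSV path.
#' @return annotation data.frame.
#' @export
read_variant_annotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("in_clinvar_or_hgmd", "splice_predicted_damaging"))
    if (!is.logical(a[[col]])) a[[col]] <- a[[col]] %in% c("TRUE", "Y", "yes", "1")
  a
}
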