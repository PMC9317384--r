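#' Configuration for the STR pedigree simulator
#'
#' Parental haplotypes across an ordered set of microsatellite markers
#' (integer repeat sizes) plus a per-sibling transmission pattern. The
#' marker interval is treated as a single non-recombinant linkage block, so
#' each child receives one whole haplotype per parent.
#'
#' @param markers character vector of marker names (default: nine synthetic
#'   D11S-style markers flanking the TYR locus).
#' @param paternal_haps,maternal_haps 2 x n_markers integer matrices; row =
#'   haplotype, column = marker.
#' @param transmissions named list: child id -> integer vector
#'   \code{c(paternal = 1 or 2, maternal = 1 or 2)}.
#' @param father,mother individual ids.
#' @return object of class \code{str_pedigree_config}.
#' @export
str_pedigree_config <- function(markers, paternal_haps, maternal_haps,
                                transmissions, father = "father",
                                mother = "mother") {
  stopifnot(ncol(paternal_haps) == length(markers),
            ncol(maternal_haps) == length(markers),
            nrow(paternal_haps) == 2, nrow(maternal_haps) == 2)
  if (any(paternal_haps <= 0) || any(maternal_haps <= 0))
    stop("allele repeat sizes must be positive integers")
  storage.mode(paternal_haps) <- "integer"
  storage.mode(maternal_haps) <- "integer"
  for (tr in transmissions)
    stopifnot(tr[["paternal"]] %in% 1:2, tr[["maternal"]] %in% 1:2)
  structure(list(markers = markers, paternal_haps = paternal_haps,
                 maternal_haps = maternal_haps,
                 transmissions = transmissions,
                 father = father, mother = mother),
            class = "str_pedigree_config")
}

#' Simulate Mendelian STR genotypes for a nuclear family
#'
#' Parents' genotypes are their two haplotypes; each child receives the
#' configured paternal and maternal haplotype at every marker (no
#' recombination within the block).
#'
#' @param cfg a \code{\link{str_pedigree_config}}.
#' @return data.frame: \code{individual}, \code{marker}, \code{allele1},
#'   \code{allele2} (unordered pair, reported sorted).
#' @export
simulate_str_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "str_pedigree_config"))
  rows <- list()
  add <- function(id, a1, a2) {
    rows[[length(rows) + 1]] <<- data.frame(
      individual = id, marker = cfg$markers,
      allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
      stringsAsFactors = FALSE)
  }
  add(cfg$father, cfg$paternal_haps[1, ], cfg$paternal_haps[2, ])
  add(cfg$mother, cfg$maternal_haps[1, ], cfg$maternal_haps[2, ])
  for (child in names(cfg$transmissions)) {
    tr <- cfg$transmissions[[child]]
    add(child, cfg$paternal_haps[tr[["paternal"]], ],
        cfg$maternal_haps[tr[["maternal"]], ])
  }
  do.call(rbind, rows)
}

#' Write / read STR genotype tables (TSV)
#'
#' Columns: individual, marker, allele1, allele2.
#'
#' @param str STR genotype data.frame.
#' @param path file path.
#' @export
write_str_genotypes <- function(str, path) {
  utils::write.table(str, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_str_genotypes
#' @export
read_str_genotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Infer which parental alleles a child received at one marker
#'
#' Enumerates all haplotype-level decompositions of the child's unordered
#' allele pair into one paternal plus one maternal allele. Each parent's
#' transmission is \code{resolved} when every decomposition uses the same
#' haplotype of that parent (a homozygous parent's transmission is
#' therefore ambiguous at the haplotype level even though the transmitted
#' value is known). The overall status is \code{resolved} when both sides
#' are, \code{inconsistent} when no decomposition exists, \code{ambiguous}
#' otherwise.
#'
#' @param child,father,mother length-2 integer vectors (unordered allele
#'   pairs).
#' @return list: \code{status} (\code{resolved}/\code{ambiguous}/
#'   \code{inconsistent}), \code{paternal_status}, \code{maternal_status},
#'   \code{paternal}, \code{maternal} (transmitted allele values, NA unless
#'   the corresponding side is resolved).
#' @export
infer_transmission <- function(child, father, mother) {
  sols <- NULL
  for (pi in 1:2) for (mi in 1:2)
    if (setequal_multiset(c(father[pi], mother[mi]), child))
      sols <- rbind(sols, c(pi, mi))
  if (is.null(sols))
    return(list(status = "inconsistent", paternal_status = "inconsistent",
                maternal_status = "inconsistent",
                paternal = NA, maternal = NA))
  pat_ok <- length(unique(sols[, 1])) == 1
  mat_ok <- length(unique(sols[, 2])) == 1
  list(status = if (pat_ok && mat_ok) "resolved" else "ambiguous",
       paternal_status = if (pat_ok) "resolved" else "ambiguous",
       maternal_status = if (mat_ok) "resolved" else "ambiguous",
       paternal = if (pat_ok) father[sols[1, 1]] else NA,
       maternal = if (mat_ok) mother[sols[1, 2]] else NA)
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

#' Sibling haplo-identity across an STR marker block
#'
#' Decides whether two siblings inherited the same parental haplotypes
#' across the marker interval (treated as one non-recombinant block). Per
#' marker: \code{concordant} when both siblings' transmissions are resolved,
#' at least one parent is heterozygous (informative) and every informative
#' parent transmitted the same allele to both siblings; \code{discordant}
#' when an informative parent transmitted different alleles;
#' \code{uninformative} when transmissions are ambiguous or no parent is
#' heterozygous; \code{inconsistent} markers (impossible genotypes) are
#' flagged and excluded from the verdict. Verdict: \code{non_identical} iff
#' at least one discordant marker; \code{identical} iff at least one
#' concordant and no discordant marker; otherwise \code{uninformative}.
#'
#' @param str STR genotype data.frame (individual, marker, allele1, allele2).
#' @param sib1,sib2,father,mother individual ids in \code{str}.
#' @return object of class \code{haplo_identity_result}: \code{verdict},
#'   \code{per_marker} (data.frame marker/status), \code{n_concordant},
#'   \code{n_discordant}.
#' @export
haplo_identity <- function(str, sib1, sib2, father, mother) {
  get <- function(id, m) {
    r <- str[str$individual == id & str$marker == m, ]
    if (nrow(r) != 1) stop("expected one genotype row for ", id, " at ", m)
    c(r$allele1, r$allele2)
  }
  markers <- unique(str$marker)
  status <- character(length(markers))
  for (i in seq_along(markers)) {
    m <- markers[i]
    fa <- get(father, m); mo <- get(mother, m)
    t1 <- infer_transmission(get(sib1, m), fa, mo)
    t2 <- infer_transmission(get(sib2, m), fa, mo)
    if (t1$status == "inconsistent" || t2$status == "inconsistent") {
      status[i] <- "inconsistent"; next
    }
    # a parent contributes identity information only when heterozygous and
    # resolvable for both siblings
    informative <- c(
      paternal = fa[1] != fa[2] && t1$paternal_status == "resolved" &&
        t2$paternal_status == "resolved",
      maternal = mo[1] != mo[2] && t1$maternal_status == "resolved" &&
        t2$maternal_status == "resolved")
    if (!any(informative)) { status[i] <- "uninformative"; next }
    same <- c(paternal = isTRUE(t1$paternal == t2$paternal),
              maternal = isTRUE(t1$maternal == t2$maternal))
    status[i] <- if (any(informative & !same)) "discordant" else "concordant"
  }
  verdict <- if (any(status == "discordant")) "non_identical"
             else if (any(status == "concordant")) "identical"
             else "uninformative"
  structure(list(verdict = verdict,
                 per_marker = data.frame(marker = markers, status = status,
                                         stringsAsFactors = FALSE),
                 n_concordant = sum(status == "concordant"),
                 n_discordant = sum(status == "discordant")),
            class = "haplo_identity_result")
}

#' @export
print.haplo_identity_result <- function(x, ...) {
  cat("Sibling haplo-identity verdict:", x$verdict,
      sprintf("(%d concordant, %d discordant of %d markers)\n",
              x$n_concordant, x$n_discordant, nrow(x$per_marker)))
  invisible(x)
}

#' Derive a phase resolution from sibling haplo-identity
#'
#' When two affected siblings sharing the same genotype configuration are
#' haplo-identical across the block containing the gene, an ambiguous
#' polymorphism is inferred to travel in cis with its resolved partner
#' polymorphism (single shared parental origin), and is assigned to the
#' partner's allele.
#'
#' @param haplo a \code{\link{haplo_identity_result}}.
#' @param phased_list named list of \code{phased_genotype} objects (the
#'   siblings).
#' @param pair the hypomorphic polymorphism pair.
#' @return named list: individual -> named character vector
#'   (variant -> \code{"paternal"}/\code{"maternal"}); empty when the
#'   siblings are not haplo-identical or nothing can be resolved.
#' @export
str_phase_resolution <- function(haplo, phased_list,
                                 pair = hypomorphic_pair()) {
  if (haplo$verdict != "identical") return(list())
  out <- list()
  for (ind in names(phased_list)) {
    ph <- phased_list[[ind]]
    assignments <- character(0)
    for (v in ph$ambiguous) {
      member <- pair[vapply(pair, grepl, logical(1), x = v, fixed = TRUE)]
      if (length(member) != 1) next
      partner <- setdiff(pair, member)
      on_pat <- any(grepl(partner, ph$paternal, fixed = TRUE))
      on_mat <- any(grepl(partner, ph$maternal, fixed = TRUE))
      if (xor(on_pat, on_mat))
        assignments[v] <- if (on_pat) "paternal" else "maternal"
    }
    if (length(assignments) > 0) out[[ind]] <- assignments
  }
  out
}
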