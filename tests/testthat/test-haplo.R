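test_that("transmission inference: unique, ambiguous and impossible decompositions", {
  r1 <- infer_transmission(c(150, 158), c(150, 154), c(158, 162))
  expect_identical(r1$status, "resolved")
  expect_identical(r1$paternal, 150)
  expect_identical(r1$maternal, 158)
  expect_identical(infer_transmission(c(150, 150), c(150, 150),
                                      c(150, 150))$status, "ambiguous")
  expect_identical(infer_transmission(c(166, 170), c(150, 154),
                                      c(158, 162))$status, "inconsistent")
})

test_that("forced transmission patterns yield the expected verdicts", {
  markers <- paste0("M", 1:9)
  pat <- rbind(seq(150, 182, 4), seq(152, 184, 4))
  mat <- rbind(seq(250, 282, 4), seq(252, 284, 4))
  same <- str_pedigree_config(markers, pat, mat,
                              list(s1 = c(paternal = 1, maternal = 1),
                                   s2 = c(paternal = 1, maternal = 1)))
  res <- haplo_identity(simulate_str_pedigree(same), "s1", "s2",
                        "father", "mother")
  expect_identical(res$verdict, "identical")
  expect_identical(res$n_concordant, 9L)
  diff_pat <- str_pedigree_config(markers, pat, mat,
                                  list(s1 = c(paternal = 1, maternal = 1),
                                       s2 = c(paternal = 2, maternal = 1)))
  res2 <- haplo_identity(simulate_str_pedigree(diff_pat), "s1", "s2",
                         "father", "mother")
  expect_identical(res2$verdict, "non_identical")
  expect_gte(res2$n_discordant, 1L)
  # all four parental haplotypes identical at every marker
  flat <- matrix(150, 2, 9)
  unin <- str_pedigree_config(markers, flat, flat,
                              list(s1 = c(paternal = 1, maternal = 1),
                                   s2 = c(paternal = 2, maternal = 2)))
  res3 <- haplo_identity(simulate_str_pedigree(unin), "s1", "s2",
                         "father", "mother")
  expect_identical(res3$verdict, "uninformative")
  expect_true(all(res3$per_marker$status == "uninformative"))
})

test_that("every simulated sibling allele traces to a parental haplotype", {
  set.seed(31)
  for (i in 1:25) {
    ped <- random_str_pedigree()
    str <- ped$str
    for (sib in c("sib1", "sib2")) for (m in unique(str$marker)) {
      kid <- str[str$individual == sib & str$marker == m, ]
      tr <- ped$trans[[sib]]
      mi <- match(m, ped$cfg$markers)
      expected <- sort(c(ped$cfg$paternal_haps[tr[["paternal"]], mi],
                         ped$cfg$maternal_haps[tr[["maternal"]], mi]))
      expect_identical(c(kid$allele1, kid$allele2), expected)
    }
  }
})

test_that("the verdict is sibling-swap invariant", {
  set.seed(17)
  for (i in 1:50) {
    str <- random_str_pedigree()$str
    a <- haplo_identity(str, "sib1", "sib2", "father", "mother")
    b <- haplo_identity(str, "sib2", "sib1", "father", "mother")
    expect_identical(a$verdict, b$verdict)
  }
})

test_that("with a fully informative marker the verdict recovers the truth", {
  set.seed(53)
  n_checked <- 0
  for (i in 1:500) {
    ped <- random_str_pedigree()
    # fully informative marker: four pairwise-distinct parental alleles
    fully <- vapply(seq_along(ped$cfg$markers), function(mi) {
      al <- c(ped$cfg$paternal_haps[, mi], ped$cfg$maternal_haps[, mi])
      length(unique(al)) == 4
    }, logical(1))
    if (!any(fully)) next
    n_checked <- n_checked + 1
    truth_same <- identical(ped$trans$sib1, ped$trans$sib2)
    v <- haplo_identity(ped$str, "sib1", "sib2", "father", "mother")$verdict
    expect_identical(v, if (truth_same) "identical" else "non_identical")
  }
  expect_gt(n_checked, 100)   # the property was actually exercised
})

test_that("an impossible marker is flagged and excluded from the verdict", {
  markers <- paste0("M", 1:2)
  cfg <- str_pedigree_config(markers, rbind(c(150, 150), c(154, 154)),
                             rbind(c(158, 158), c(162, 162)),
                             list(s1 = c(paternal = 1, maternal = 1),
                                  s2 = c(paternal = 1, maternal = 1)))
  str <- simulate_str_pedigree(cfg)
  str$allele1[str$individual == "s1" & str$marker == "M2"] <- 999
  res <- haplo_identity(str, "s1", "s2", "father", "mother")
  expect_identical(res$per_marker$status[res$per_marker$marker == "M2"],
                   "inconsistent")
  expect_identical(res$verdict, "identical")   # M1 still concordant
})

test_that("haplo-identity of the sibling fixture resolves the polymorphism phase", {
  fx <- load_study_fixtures()
  haplo <- haplo_identity(fx$str, "P4", "P5", "F4_fa", "F4_mo")
  expect_identical(haplo$verdict, "identical")
  coh <- study_cohort_trios()
  g <- coh$families$F4$genotypes
  phased <- list(
    P4 = phase_trio(data.frame(variant = g$variant, proband = g$P4,
                               father = g$F4_fa, mother = g$F4_mo),
                    individual = "P4"),
    P5 = phase_trio(data.frame(variant = g$variant, proband = g$P5,
                               father = g$F4_fa, mother = g$F4_mo),
                    individual = "P5"))
  res <- str_phase_resolution(haplo, phased)
  expect_identical(res$P4, c("p.(Arg402Gln)" = "paternal"))
  expect_identical(res$P5, c("p.(Arg402Gln)" = "paternal"))
  # a non-identical verdict resolves nothing
  not_id <- haplo; not_id$verdict <- "non_identical"
  expect_length(str_phase_resolution(not_id, phased), 0)
})
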