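fam_trio <- function(fam) {
  g <- fam$genotypes
  data.frame(variant = g$variant, proband = g[[fam$proband]],
             father = g[[fam$father]], mother = g[[fam$mother]],
             stringsAsFactors = FALSE)
}

pathogenic_ids <- function() {
  cat <- tyr_variant_catalogue()
  cat$hgvs_p[cat$pathogenic]
}

test_that("trio segregation phases the first family onto the expected alleles", {
  coh <- study_cohort_trios()
  ph <- phase_trio(fam_trio(coh$families$F1), individual = "P1")
  expect_identical(ph$paternal, c("p.(Arg77Gln)", "p.(Ser192Tyr)"))
  expect_identical(ph$maternal, c("p.(Arg402Gln)", "p.(Ser192Tyr)"))
  expect_identical(ph$phase_status, "resolved")
})

test_that("a polymorphism heterozygous in child and both parents stays ambiguous", {
  coh <- study_cohort_trios()
  ph <- phase_trio(fam_trio(coh$families$F4), individual = "P4")
  expect_identical(ph$ambiguous, "p.(Arg402Gln)")
  expect_identical(ph$phase_status, "ambiguous")
  expect_identical(ph$paternal, "p.(Ser192Tyr)")   # father Hom forces this
  expect_identical(ph$maternal, "p.(Gly47Asp)")
})

test_that("homozygous variants are placed on both alleles", {
  trios <- data.frame(variant = "p.(V)", proband = "Hom", father = "Het",
                      mother = "Het", stringsAsFactors = FALSE)
  ph <- phase_trio(trios)
  expect_identical(ph$paternal, "p.(V)")
  expect_identical(ph$maternal, "p.(V)")
  expect_identical(ph$phase_status, "resolved")
  expect_error(phase_trio(data.frame(variant = "v", proband = "Hom",
                                     father = "WT", mother = "Het")),
               "inconsistency")
})

test_that("phase_trio agrees with brute-force allele-assignment enumeration", {
  set.seed(99)
  for (i in 1:300) {
    trio <- random_trio(sample(1:4, 1))
    oracle <- brute_force_phase(trio)
    ph <- phase_trio(trio)
    expect_identical(ph$paternal, oracle$paternal, info = paste("case", i))
    expect_identical(ph$maternal, oracle$maternal, info = paste("case", i))
    expect_identical(ph$ambiguous, oracle$ambiguous, info = paste("case", i))
  }
})

test_that("diagnostic classification reproduces the cohort's genotype classes", {
  coh <- study_cohort_trios()
  # compound heterozygote without hypomorphic alleles
  ph3 <- phase_trio(fam_trio(coh$families$F3), individual = "P3")
  expect_identical(classify_genotype(ph3, pathogenic_ids())$class,
                   "biallelic_pathogenic")
  # pathogenic in trans with the complete hypomorphic haplotype
  ph7 <- phase_trio(fam_trio(coh$families$F5), individual = "P7")
  expect_identical(ph7$paternal, c("p.(Arg402Gln)", "p.(Pro152Arg)"))
  expect_identical(ph7$maternal, c("p.(Arg402Gln)", "p.(Ser192Tyr)"))
  expect_identical(classify_genotype(ph7, pathogenic_ids())$class,
                   "pathogenic_trans_hypomorphic")
  # unresolved polymorphism spanning diagnostic and non-diagnostic phases
  ph4 <- phase_trio(fam_trio(coh$families$F4))
  expect_identical(classify_genotype(ph4, pathogenic_ids())$class,
                   "ambiguous_requires_haplotyping")
  # a lone polymorphism opposite a pathogenic variant is carrier-only
  trios <- data.frame(variant = c("p.(Bad)", "p.(Ser192Tyr)"),
                      proband = c("Het", "Het"),
                      father = c("Het", "WT"), mother = c("WT", "Het"),
                      stringsAsFactors = FALSE)
  expect_identical(classify_genotype(phase_trio(trios), "p.(Bad)")$class,
                   "carrier_only")
})

test_that("classification is symmetric under swapping the parental labels", {
  set.seed(7)
  ids <- c("p.(Ser192Tyr)", "p.(Arg402Gln)", "p.(Bad1)", "p.(Bad2)")
  for (i in 1:60) {
    pat <- sample(ids, sample(0:3, 1))
    mat <- sample(ids, sample(0:3, 1))
    a <- ocadx:::new_phased_genotype(pat, mat, character(0))
    b <- ocadx:::new_phased_genotype(mat, pat, character(0))
    expect_identical(classify_genotype(a, c("p.(Bad1)", "p.(Bad2)"))$class,
                     classify_genotype(b, c("p.(Bad1)", "p.(Bad2)"))$class)
  }
})

test_that("an affected parent is phased through the transmitted allele", {
  coh <- study_cohort_trios()
  g <- coh$families$F5$genotypes
  gts <- stats::setNames(g$P8, g$variant)
  ph7 <- phase_trio(fam_trio(coh$families$F5))
  ph8 <- phase_from_offspring(as.list(gts), transmitted = ph7$paternal,
                              role = "father", individual = "P8")
  expect_identical(ph8$phase_status, "resolved")
  expect_identical(classify_genotype(ph8, pathogenic_ids())$class,
                   "pathogenic_trans_hypomorphic")
  expect_error(phase_from_offspring(list("p.(V)" = "WT"),
                                    transmitted = "p.(V)"),
               "WT")
})

test_that("external phase resolution upgrades an ambiguous genotype", {
  coh <- study_cohort_trios()
  ph4 <- phase_trio(fam_trio(coh$families$F4))
  fixed <- resolve_phase(ph4, c("p.(Arg402Gln)" = "paternal"))
  expect_identical(fixed$phase_status, "resolved")
  expect_identical(classify_genotype(fixed, pathogenic_ids())$class,
                   "pathogenic_trans_hypomorphic")
})

test_that("cohort prioritization matches the study with and without STR resolution", {
  fx <- load_study_fixtures()
  rep0 <- prioritize_cohort(fx$genotypes, fx$ped, fx$annotations)
  tab0 <- rep0$table
  expect_identical(sort(tab0$individual[tab0$class ==
                                          "ambiguous_requires_haplotyping"]),
                   c("P4", "P5"))
  expect_identical(tab0$class[tab0$individual == "P3"],
                   "biallelic_pathogenic")
  haplo <- haplo_identity(fx$str, "P4", "P5", "F4_fa", "F4_mo")
  res <- str_phase_resolution(haplo, lapply(rep0$individuals[c("P4", "P5")],
                                            `[[`, "phased"))
  rep1 <- prioritize_cohort(fx$genotypes, fx$ped, fx$annotations,
                            phase_resolution = res)
  counts <- rep1$counts
  expect_identical(unname(counts["pathogenic_trans_hypomorphic"]), 7L)
  expect_identical(unname(counts["biallelic_pathogenic"]), 1L)
  expect_true(all(rep1$table$status == "ok"))
  # empty cohort degrades to an empty report
  ped_none <- fx$ped; ped_none$affected <- FALSE
  rep_empty <- prioritize_cohort(fx$genotypes, ped_none, fx$annotations)
  expect_identical(nrow(rep_empty$table), 0L)
})
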