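---
title: "Methods: VEP misrouting, TYR trio phasing and clinical criteria in ultra-mild albinism"
author: "ocadx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VEP misrouting, TYR trio phasing and clinical criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocadx)
```

## The diagnostic problem

Oculocutaneous albinism (OCA) is usually recognized from overt
hypopigmentation, nystagmus and severely reduced acuity. At the mild end of
the spectrum, however, patients may present only with bilateral foveal
hypoplasia and a modest acuity deficit — a picture easily labelled
"isolated foveal hypoplasia". Two observations can still secure an albinism
diagnosis in such patients:

1. **Optic-pathway misrouting.** In albinism an excessive fraction of
   retinal fibers crosses at the chiasm, so monocular stimulation drives
   the *contralateral* occipital cortex disproportionately, with the
   lateralization flipping between eyes. Pattern-onset visual evoked
   potentials (VEPs) recorded over both occipital hemispheres detect this.
2. **A hypomorphic *TYR* genotype.** The two common tyrosinase
   polymorphisms p.(Ser192Tyr) and p.(Arg402Gln) (population allele
   frequencies ≈ 25% and ≈ 18%) are individually benign, but when both sit
   *in cis* on one chromosome and a pathogenic *TYR* variant sits *in
   trans*, the combination behaves as a mild loss-of-function genotype.

`ocadx` implements the full analysis chain for this diagnosis — VEP
preprocessing and misrouting statistics, trio-based variant prioritization
with cis/trans phasing, microsatellite haplo-identity for families where
trio segregation alone cannot phase the polymorphisms, and the Kruijt
major/minor clinical criteria — together with synthetic-data generators so
that every stage can be exercised against known ground truth.

## VEP misrouting statistics

### Signal model and preprocessing

Epochs span −0.2 to 0.4 s around stimulus onset (half-open sample
convention: 300 samples at 500 Hz, the onset sample included), are
baseline-corrected on \[−0.05, 0\] s, averaged across trials, and the
average is low-pass filtered at 35 Hz (4th-order Butterworth, zero-phase
forward–backward; the order is configurable since only the cutoff is
conventional). Whether the low-pass precedes or follows averaging is
configurable (`lowpass_before_average`); the default filters the average —
for a linear chain the two commute up to edge effects. Continuous records
can first be drift-corrected with a Blackman-windowed sinc FIR high-pass
(0.1 Hz cutoff, 0.2 Hz transition width, zero-phase), and read or written
as EDF with `read_edf()`/`write_edf()`.

Re-referencing (`none`, a channel, or common average) is offered but
immaterial downstream: the misrouting indexes are built from the
*differential activity* `D(t)` — the mean of nine left-occipital
electrodes minus the mean of nine right-occipital electrodes — which
cancels any signal common to all channels. The actual 128-channel
identities behind the two electrode sets are a study-specific detail, so
the montage is user-supplied (a YAML file with `left_set`/`right_set`;
synthetic labels `OL1..OL9`/`OR1..OR9` are used throughout the package).

### The two indexes

With `D_OS(t)` and `D_OD(t)` the differential activities under left- and
right-eye stimulation:

* **Chiasm coefficient** `CC = mean(D_OS) − mean(D_OD)` over
  \[0.07, 0.1\] s (closed window on the sample grid; the 0.07 s sample
  belongs to both windows). Under misrouting, `D_OS` is negative and
  `D_OD` positive in this early window, so `CC < 0`. The published
  description of the coefficient is elliptical; this difference form is
  adopted because it is negative exactly when the per-eye window means
  straddle the equality line the study plots, and because it makes the
  group-level paired t-test on (mean_D_OS, mean_D_OD) identical to a
  one-sample test of `CC` against zero. A normalized-product variant is
  available behind `method = "normalized_product"`.
* **Interocular correlation**: Pearson r between `D_OS(t)` and `D_OD(t)`
  across the samples of \[0.07, 0.3\] s. Mirror-image lateralization
  makes it strongly negative.

A subject is classified *misrouted* by the conjunction
`r < 0 AND p ≤ α AND CC < 0` (α = 0.05, two-tailed, no multiple-testing
correction across subjects). A zero-variance differential (possible only
in noise-free synthetic data) flags the correlation "undefined" and the
classification "indeterminate" rather than silently passing a 0.

### Degrees of freedom for the correlation p-value

Filtered EEG samples are serially dependent: after the 35 Hz low-pass at a
500 Hz sampling rate (and with 1/f noise) the ~116 samples of the
correlation window carry far fewer than 114 independent degrees of
freedom. Treating them as independent inflates significance — on simulated
normal-routing cohorts the conjunction classifier's false-positive rate
rises well above its nominal level. The package therefore defaults
to a Pyper–Peterman effective sample size,
`n_eff = n / (1 + 2 Σ_k ρ_x(k) ρ_y(k))` (lags to n/4, clamped to \[3, n\]),
and computes the t-based p-value on `n_eff − 2` df. The nominal-df p-value
(the convention used in published per-subject values) is always reported
alongside (`p_nominal`), and `df_method = "nominal"` restores it as the
deciding value. With the correction the simulated false-positive rate
stays within its nominal level while power at realistic SNR is essentially
unchanged; both operating characteristics are measured by the shipped
acceptance checks.

### Group statistic

`group_chiasm_ttest()` is the two-tailed paired t-test of the per-subject
window means (df = n − 1; n = 8 subjects gives t(7), matching the study's
df convention). Degenerate inputs are defined explicitly: identical pairs
give t = 0, p = 1; constant non-zero differences give ±Inf, p = 0.

## The synthetic VEP generator

`simulate_vep_cohort()` draws, per subject and eye, trials of
`evoked_amplitude · w(eye, hemisphere) · k(t)` plus noise, where

* `k(t)` is a difference-of-gammas kernel (`vep_kernel()`): unit-peak
  positive lobe at 0.10 s, weighted negative lobe at 0.22 s, identically
  zero for t ≤ 0 (so the baseline window is signal-free). The published
  experiment specifies no waveform model; this family is standard VEP
  morphology and evaluable in closed form, which the oracle tests exploit.
* `w = (1 ± asymmetry)/2` under misrouted routing (`+` contralateral,
  flipping between eyes) and `1/2` everywhere under normal routing. Hence
  noiseless misrouted data give `D_OS(t) = −asymmetry · amplitude · k(t)`
  exactly, and `CC = −2 · asymmetry · amplitude · mean(k)` over the window
  — the closed form the acceptance tests check to 1e−9.
* Noise is white or (default) 1/f + white, generated by spectral shaping
  with amplitude response `sqrt(knee/f + 1)` (knee 10 Hz, DC removed),
  independent phase per trial and channel, rescaled per series to
  `noise_sd`.
* Trial counts are drawn per eye from Normal(498, 51), rounded, floored at
  1 — the acquisition's reported stimulation counts.
* One RNG is seeded per cohort and per-subject substream seeds are derived
  from it, so cohorts are bit-reproducible and subjects independent.

Stimulus timing in the continuous simulator spaces onsets 0.48 s apart
(the 40 ms ON / 440 ms OFF cycle). Since the kernel support is 0.4 s, the
previous response's tail reaches a new epoch's pre-stimulus segment only
before −0.08 s — the baseline window and all post-onset samples are
overlap-free, which is why overlap is simulated rather than avoided.

What the generator does **not** emulate: volume conduction from a real
head model, electrode geometry (labels are synthetic), blinks and movement
artifacts (the study cleaned these with ASR and channel interpolation,
which the package deliberately does not re-implement — inputs are assumed
pre-cleaned), and non-stationary noise. Passing tests therefore validate
the statistical chain, not robustness to real-world artifacts.

### Monte-Carlo problem sizes

Replicate-cohort studies (`misrouting_power_study()`) scale the
acquisition down so hundreds of cohorts run in minutes: 30 trials/eye at
4.9 µV noise, which preserves the per-average differential SNR of the
full-size default (498 trials at 20 µV): peak signal
`asymmetry × amplitude = 2.5 µV` against averaged differential noise
`σ √(2/9) / √n ≈ 0.42 µV`, i.e. SNR ≈ 5.9 before low-pass. At these
conditions the acceptance run over 200 misrouted cohorts of 8 subjects
measures per-subject detection and group-test rejection at α = 0.001 both
above 95%, and a false-positive rate below 5% over 200 normal-routing
subjects.

## Variant prioritization and phasing

### Retention cascade

`filter_variants()` retains a variant iff it (1) has an admissible
consequence (non-synonymous, short indel, synonymous, splice-site within
20 bp), (2) lies in a panel gene (default panel: TYR/OCA2/TYRP1/SLC45A2/
SLC38A8/DCT autosomal recessive, PAX6 dominant, GPR143 X-linked;
editable), (3) has maximum MAF across 1000G/EVS/dbSNP/in-house ≤ 0.01 (AR)
or ≤ 0.001 (AD) — the maximum across sources is used as the stricter
reading, configurable; a missing frequency counts as 0 (absent = rare) and
is an explicit contract, (4) has no homozygous/hemizygous gnomAD carriers,
(5) is known pathogenic (ClinVar/HGMD) or called damaging by ≥ 3 of 6
predictors, with synonymous/splice variants additionally needing a
damaging splice prediction, and (6) has ACMG class P/LP/VUS. Predictor
calls and the ACMG class are consumed as pre-normalized annotation columns
— the package does not re-implement annotation or ACMG scoring.
**Override:** TYR p.(Ser192Tyr) and p.(Arg402Gln) are always retained and
tagged `manual-inspection`, bypassing rules 3–6; they fail the frequency
filters by three orders of magnitude yet are the diagnostic haplotype's
components. Every decision is returned in an audit table.

### Trio phasing

For each variant carried by a proband, `phase_trio()` applies segregation
logic: homozygous → both alleles; heterozygous with a homozygous parent →
that parent's allele (a homozygous parent necessarily transmits it, which
also forces the other transmitted allele to be wild type); heterozygous
with exactly one carrier parent → that parent's allele; heterozygous with
both parents heterozygous → ambiguous. Mendelian violations abort with the
variant named — de novo variants are surfaced as errors rather than
phased, because the logic is segregation-based. X-linked hemizygous male
genotypes are encoded as Hom.

`classify_genotype()` enumerates every assignment of the ambiguous
variants to the two alleles and classifies each completion:
`biallelic_pathogenic` (a pathogenic variant on each allele),
`pathogenic_trans_hypomorphic` (one allele pathogenic, the other carrying
*both* polymorphisms), `carrier_only` (diagnostically complete content —
a pathogenic variant or the full pair — on exactly one allele), else
`none`. If the completions disagree the verdict is
`ambiguous_requires_haplotyping`; this makes "could the unresolved phase
change the diagnosis?" a computed property instead of a heuristic.

An affected *parent* of a proband (cascade diagnosis) has no genotyped
grandparents; `phase_from_offspring()` phases them in reverse from the
fully resolved allele they transmitted to the proband: the transmitted set
is one allele, the complement the other.

### Microsatellite haplo-identity

Where both parents are heterozygous for a polymorphism, trio segregation
cannot place it. For an affected sibling pair, nine microsatellite markers
spanning the ~4.5 Mb around *TYR* (treated as one non-recombinant block — a
documented simplification; intra-block recombination would be
misclassified) decide whether the siblings inherited the same parental
haplotypes. Per marker, `infer_transmission()` enumerates haplotype-level
decompositions of each child's allele pair; a parent is informative when
heterozygous and resolved for both siblings. A marker is concordant/
discordant by comparing transmitted alleles of informative parents;
verdicts: `non_identical` iff any discordant marker, `identical` iff at
least one concordant and none discordant, else `uninformative`;
inconsistent markers are flagged and excluded. If the siblings are
haplo-identical and share the genotype configuration,
`str_phase_resolution()` assigns the ambiguous polymorphism to the allele
carrying its resolved partner (single shared parental origin), and
`prioritize_cohort(phase_resolution = ...)` upgrades the family. The
module reports genetic evidence only; combining it with phenotype
concordance is left to the report layer.

## Kruijt clinical criteria

Major criteria: foveal hypoplasia grade ≥ 2 (Thomas OCT classification),
misrouting, and ocular hypopigmentation — read as *iris transillumination
OR fundus hypopigmentation grade ≥ 2*. The OR-reading resolves a genuine
ambiguity in how the criterion is usually restated (the original grading
separates iris grades and hair colorimetry, which this package does not
reproduce); it is a design choice, recorded here. Minor criteria:
nystagmus, skin/hair hypopigmentation (a boolean input — reported
qualitatively as "lighter than the parents'"), fundus grade 1, foveal
hypoplasia grade 1. Clinical diagnosis: ≥ 3 major, or ≥ 2 major and ≥ 2
minor; with a molecular diagnosis: ≥ 1 major or ≥ 2 minor. Missing fields
yield "unassessable" with the fields named. The diagnosis is monotone in
the criteria (adding a met criterion never revokes it) — note that raising
the fundus grade past 1 *trades* a minor for a major sub-condition and is
only evidence-adding when the ocular major was not already met.

Cohort summaries pool BCVA over all eyes by default (16 values for 8
patients); per-patient averaging is also reported — both give 0.20 LogMAR
on the packaged cohort. The packaged table's ages average 16.5 y, slightly
different from the 16.3 y printed in the source cohort description; the
summary reports the table-derived value.

## Packaged fixtures and the integrated pipeline

`inst/extdata/` ships the study cohort as plain text: the phenotype table,
the six families' trio genotypes as VCF v4.2 + PED (coordinates for the
two polymorphisms are their GRCh37 dbSNP loci; the pathogenic variants'
positions are reconstructed from cDNA offsets and serve as identifiers),
an annotation sidecar, the occipital montage YAML, and a *synthetic* STR
pedigree for the sibling family constructed to be haplo-identical (the
source appendix prints the conclusion, not the genotypes). EEG is not
shipped: epoch bundles are large and fully reproducible from
`simulate_vep_cohort()` seeds, so they are generated at run time.

`run_pipeline()` joins the three evidence streams into per-patient
dossiers; the Kruijt "with molecular diagnosis" rule is fed by the
genotype classification (`biallelic_pathogenic` or
`pathogenic_trans_hypomorphic`). Per-patient failures are recorded in the
dossier rather than aborting the cohort; a missing VEP section degrades to
"not assessed".

```{r pipeline, eval = FALSE}
cfg <- list(
  phenotype_table = oca_fixture("table1_phenotypes.tsv"),
  vcf = oca_fixture("table2_trios.vcf"),
  ped = oca_fixture("table2_trios.ped"),
  annotations = oca_fixture("table2_annotations.tsv"),
  str_table = oca_fixture("str_family45_synthetic.tsv"),
  str_ids = list(father = "F4_fa", mother = "F4_mo",
                 sib1 = "P4", sib2 = "P5"),
  vep = list(simulate = TRUE),
  seed = 1)
report <- run_pipeline(cfg)
report
```

## Numerical choices and known limitations

* Windows are closed intervals on the native sample grid; at 500 Hz the
  chiasm window holds 16 samples, the correlation window 116.
* The Butterworth order (4) and the FIR transition width (0.2 Hz) are
  conventions, exposed as arguments.
* EDF round-trips are exact only to 16-bit quantization (the format's
  intrinsic resolution); per-channel physical ranges are rounded to 4
  significant digits so the header's ASCII fields encode them exactly.
* The brute-force phase oracle (and the classifier's ambiguity
  enumeration) is exponential in the number of ambiguous variants — fine
  for single-gene diagnostic sets (≤ 4 variants), not for genome-wide use.
* Sample sizes used by the shipped tests and the acceptance script: 200
  misrouted cohorts × 8 subjects and 200 normal-routing subjects for the
  operating characteristics; 1000 random trios for the phase oracle; 500
  random pedigrees for the STR property. These are the package's chosen
  study sizes; all are driven by a single seed.
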