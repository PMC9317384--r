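Package: ocadx
Title: Diagnostic Analytics for Ultra-Mild Oculocutaneous Albinism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for the integrated diagnostic work-up of very mild
    oculocutaneous albinism presenting as apparently isolated foveal
    hypoplasia. Implements visual-evoked-potential (VEP) preprocessing and
    interhemispheric misrouting statistics (chiasm coefficient and
    interocular correlation of occipital differential activity), trio-based
    variant prioritization with cis/trans phasing of the hypomorphic TYR
    haplotype p.[Ser192Tyr;Arg402Gln], microsatellite haplo-identity
    analysis for sibling phase resolution, and a rule engine for the
    Kruijt major/minor clinical criteria. Ships synthetic-data generators
    (lateralized evoked responses with 1/f plus white noise, Mendelian
    trio and STR pedigrees, phenotype cohorts) so every stage is testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
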