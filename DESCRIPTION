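Package: amphipept
Title: Discovery of Emulsifier Peptides Embedded in Food Proteins
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exhaustive mining of protein sequences for peptides predicted to
    act as emulsifiers. Candidate peptides of 7-30 residues are scored with
    three conformation-specific amphiphilicity statistics (helical and strand
    hydrophobic moments plus a two-block axial score) on the Kyte-Doolittle
    hydropathy scale, gated on predicted secondary-structure probability, and
    z-normalized per length against Monte-Carlo backgrounds of random peptides
    drawn from Swiss-Prot average composition. Additional modules annotate
    physicochemical properties (average mass, net charge, isoelectric point),
    simulate protease digestion with Keil-style rules to assess whether a
    predicted peptide can be released by hydrolysis, and map peptide abundance
    in protein mixtures via riBAQ label-free quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
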