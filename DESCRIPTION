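Package: phagedyn
Title: Gut Phageome Dynamics After Faecal Filtrate Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementation of a faecal-filtrate-transplant
    (FFT) phageome analysis pipeline operating on the tabular outputs of
    standard upstream metagenomics tools. Covers viral contig triage by a
    four-criteria evidence rule, exact deduplication and greedy
    average-nucleotide-identity (ANI) clustering into viral populations
    (VPs), coverage-breadth-filtered RPKM quantification, phage-host linkage
    via prophage containment and filtered CRISPR-spacer hits,
    donor-engraftment and novel-phage tracking, a Spearman statistic for
    lytic-versus-lysogenic phage-bacterium dynamics, hypergeometric host
    enrichment among differentially abundant VPs, PERMANOVA on compositional
    distances, and the trial's small clinical statistics (Fisher exact
    tests, continuous-glucose-monitor time in range, oral glucose tolerance
    test area under the curve, HOMA-IR). A synthetic-data module generates
    every input table with planted ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
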