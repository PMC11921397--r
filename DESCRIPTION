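Package: qsipr
Title: Quantitative Stable Isotope Probing of Amplicon Density Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-taxon isotope incorporation from DNA stable
    isotope probing (SIP) experiments in which 16S rRNA gene amplicon
    libraries are sequenced across CsCl buoyant-density gradient fractions.
    Implements the quantitative SIP (qSIP) inference chain: taxon-specific
    weighted average densities (WADs), replicate-core bootstrap confidence
    intervals, GC-content and nucleotide molecular-weight conversion, and
    carbon-13 atom fraction excess with active-taxon calling. Includes qPCR
    based absolute-abundance (QSEQ) normalization, prevalence and depth
    filtering, active-community abundance, diversity and overlap summaries,
    a forward gradient simulator with known ground truth, and a pipeline
    orchestrator for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
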