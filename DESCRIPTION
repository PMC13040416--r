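Package: epoScreen
Title: Confounder-Specificity Screening of Candidate rHuEPO Transcriptomic
    Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for screening candidate blood transcriptomic biomarkers of
    recombinant human erythropoietin (rHuEPO) administration against the two
    major physiological confounders of erythropoiesis-targeted doping tests:
    exercise and altitude-induced hypoxia. The package harmonises gene symbols
    to an approved nomenclature via supplied alias tables, screens candidate
    genes for exercise responsiveness with Cohen's d effect sizes computed
    from condition-wise summary statistics (with an explicit rule for
    non-computable Kruskal-Wallis p values), replicates per-study altitude
    differential-expression cut-offs in three table dialects, derives the
    confounder-free candidate panel through a two-step set-overlap framework
    with full Venn-region attribution, and runs hypergeometric
    over-representation analysis with Benjamini-Hochberg adjustment under
    measured or genome background universes. A synthetic-data module generates
    every input with planted ground truth so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, GeneSetEnrichment, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ExpressionSummary.R'
    'GenePanel.R'
    'deg-filter.R'
    'enrichment.R'
    'epoScreen-package.R'
    'harmonise.R'
    'io.R'
    'overlap.R'
    'screen.R'
    'synthetic-data.R'
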