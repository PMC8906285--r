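Package: sulfoprofiler
Title: Untargeted Profiling of the Urinary Sulfate Metabolome from DDA LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted detection and differential analysis of
    sulfate-conjugated metabolites in data-dependent acquisition (DDA)
    LC-MS/MS experiments. Matches the six diagnostic sulfate-derived
    fragment signals (product ions and neutral losses) and seven
    glucuronide transitions in MS/MS spectra, computes per-feature
    intensity-ratio (IR) and maximum-abundance (MA) statistics, classifies
    features into sulfate and non-sulfate groups by seeded k-means
    clustering on eight spectral parameters, corrects injection-order
    signal drift with pooled-QC anchored LOWESS, performs moderated-t
    differential metabolite-level analysis with Benjamini-Hochberg
    correction, and annotates candidate metabolites by enumerating phase-I
    biotransformations of parent compounds followed by conjugation. A
    seeded synthetic-data generator emulates DDA datasets with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
Collate:
    'sulfoprofiler-package.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'chem-masses.R'
    'spectra-io.R'
    'fragment-rules.R'
    'feature-mapping.R'
    'normalize.R'
    'classify.R'
    'differential.R'
    'candidates.R'
    'synth.R'
    'pipeline.R'
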