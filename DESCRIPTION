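Package: repsim
Title: Simulation and Analysis of iNKT T Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for simulating and analysing T cell receptor (TCR)
    repertoires of invariant natural killer T (iNKT) cells. Provides a
    synthetic repertoire generator with tissue-specific presets (log-series
    clone-size model, TRBV/TRBJ usage vectors, a near-invariant canonical
    alpha chain, configurable nonproductive-rearrangement fraction), a
    toy-scale CDR3 junction extraction and productivity-filtering stage with
    clonotype assembly, repertoire statistics (V/J usage, V-J pairing,
    clone-size classes, clonality curves, rare-versus-abundant usage
    contrasts), CDR3 physicochemical profiling (Kyte-Doolittle
    hydrophobicity, EMBOSS-style isoelectric point, residue-class
    frequencies, position frequency matrices with information content), and
    the small-sample comparison statistics used in repertoire studies
    (exact Mann-Whitney, t-tests, one-way ANOVA with Tukey HSD, Pearson
    correlation). Reads and writes AIRR Rearrangement TSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
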