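Package: pgcprot
Title: Quantification of Protrusion Plasticity and Migration of Primordial Germ Cells
Version: 0.1.0
Authors@R:
    person("pgcprot", "developers", email = "pgcprot@example.org", role = c("aut", "cre"))
Description: Image-quantification toolkit for in-vivo studies of amoeboid cell
    migration, built around the phenotypes of zebrafish primordial germ cells
    (PGCs): cortical angular intensity profiling with circular Gaussian fits,
    bleb frequency and size metrics, actin-rich protrusion time fractions,
    track speed and straightness with tissue-drift correction, kymograph-based
    retrograde flow estimation, ratiometric (FRET-style) whole-cell and
    front/back quantification, stain quantification with background
    subtraction, nuclei-density statistics, gel-encounter response scoring,
    and the associated statistical decision rules (D'Agostino-Pearson-gated
    t/Welch/Mann-Whitney, Kolmogorov-Smirnov, Fisher's exact with Bonferroni).
    A synthetic-microscopy generator with machine-readable ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
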