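Package: htatools
Title: Fragment-Size-Resolved MNase-Seq Analysis of Archaeal Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing micrococcal nuclease (MNase) footprinting
    data from archaea whose chromatin is organised by small HU-family
    proteins such as HTa of Thermoplasma acidophilum. Provides
    fragment-size-resolved coverage computation with RPGC and
    replication-bias normalisation, Fourier-filtered footprint (peak)
    calling with empirical height scoring, re-orientation of broad
    footprints by small-fragment dyad asymmetry, positional mono- and
    dinucleotide class profiling with sampled background expectations,
    k-mer LASSO modelling of sequence-encoded occupancy, quantification of
    band-sequencing electrophoretic mobility shift assays (P_slow), and a
    fully seeded synthetic-data generator that emulates the statistical
    structure of such experiments for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
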