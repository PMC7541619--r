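Package: otochron
Title: Otolith Biochronologies and Individual Thermal Plasticity of Fish Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building otolith-increment growth biochronologies with
    crossed random-effects linear mixed models. Implements the full analysis
    protocol for repeated growth measurements of individual fish: filtering and
    transformation of increment series, sliding-window selection of monthly
    climate signals against an intrinsic baseline with a randomization null,
    within-group centering of temperature into within- and among-individual
    components, individual thermal reaction norms via random slopes, BLUP-based
    year and cohort chronologies, and cohort-level analysis of plasticity
    variance. Includes a synthetic-data generator with known truth for
    validation and power analysis, and a dense-matrix likelihood oracle for
    verifying the mixed-model objective.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
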