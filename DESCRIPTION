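Package: pfnavector
Title: Invertible-Vector Analysis of PFNa Population Codes in the Fly Central Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of vector inversion by PFNa neurons in the
    Drosophila central complex. Generates a complete in-silico experiment
    (closed-loop heading behavior, open-loop air-puff protocol, 10 kHz membrane
    potential traces with sodium spikes and 2-6 Hz calcium-spike oscillations,
    and sector-resolved calcium-imaging matrices), implements the signal
    processing used to analyse such recordings (spike detection, band power,
    bump-phase extraction, phase nulling, occupancy-gated tuning curves and
    conjunctive maps), fits sum-of-sinusoids and rectified-quadratic response
    models, and decodes the allocentric airflow direction with an
    invertible-phasor vector sum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
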