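Package: earpipe
Title: Envelope Following Responses, Pupillometry and Speech-in-Noise Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: A tidyverse-native analysis chain for cross-species studies of
    cochlear neural degeneration and listening effort. Extracts envelope
    following response (EFR) amplitudes, noise floors and significance from
    event-marked electrophysiological recordings; preprocesses eye-tracker
    pupil traces (artifact rejection, blink/saccade interpolation,
    downsampling, trial-wise baseline normalization); fits second-order
    orthogonal-polynomial growth-curve mixed models of the pupillary response;
    scores QuickSIN keyword tables into per-SNR accuracies and dB SNR loss;
    and runs the association stage (mixed-design ANOVA with
    Greenhouse-Geisser correction, Tukey-fence-screened Pearson correlations,
    elastic-net regression with cross-validation). A synthetic-cohort
    generator emulates the statistical structure of the human and gerbil
    data so that every stage is verifiable by parameter recovery.
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
    glmnet,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
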