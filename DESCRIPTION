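Package: regrecur
Title: Recurrence-Based Prediction of Noncoding Regulatory Mutations in Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies recurrent noncoding somatic mutations with a windowed
    Poisson significance test of local mutation recurrence, annotates candidate
    regulatory mutations with a 35-feature profile (transcription-factor
    binding-site gain/loss from position weight matrix rescanning, target-gene
    assignment through enhancer-promoter pairs and DNase hypersensitivity
    correlation maps, differential-expression and network-based cancer gene
    scores, and genetic and epigenetic track signals), and trains a random
    forest classifier to predict mutations whose recurrence is likely to emerge
    with additional samples. Includes repeated stratified cross-validation,
    leave-one-sample-out voting, permutation variable importance,
    external-cohort recurrence revalidation, and a synthetic-cohort simulator
    with planted hotspots for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    randomForest,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
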