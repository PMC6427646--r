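Package: spiketempo
Title: Spike-Train Odor Decoding with Tempotron and Voltage-Regulated
    Tempotron Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes stimulus identity from multi-channel spike-train
    recordings with a two-layer spiking neural network. Implements the
    leaky integrate-and-fire postsynaptic-potential kernel, membrane
    voltage evaluation with maximal-voltage search, the classic
    error-driven Tempotron learning rule, and a voltage-regulation
    variant that rescales every weight update by the derivative of a
    softplus voltage-share objective across output groups. Also provides
    binned spike-count features with a roster of conventional
    classifiers (decision tree, k-nearest neighbours, linear
    discriminant analysis, diagonal Gaussian maximum likelihood, and
    support vector machines), a seeded generator of class-structured
    synthetic spike trains with latency-template and firing-rate
    structure, and repeated random-split evaluation protocols with
    hyperparameter selection, bin-size, training-set-size, and
    time-period sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    rlang,
    rpart,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
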