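Package: serialbias
Title: Serial-Dependence Biases in Behavior and Neural Orientation Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of sensory-history biases in continuous-report
    working-memory experiments. Computes circular response errors,
    folded performance-bias curves with a summed-bias index, and
    three-component von Mises mixture fits (target/guess/swap) from
    trial tables; performs spatiotemporal linear-discriminant decoding
    of binned orientation from epoched multichannel recordings with
    sliding-window features, fold-pure PCA, class-evidence tensors,
    cosine-convolved representational-similarity scores, cross-decoding
    of previous-trial targets, and sensor searchlight maps; quantifies
    attractive versus repulsive shifts of the decoded representation
    with CW/CCW asymmetry and neural-bias scores; and provides
    permutation inference via trialwise sign-flip shuffle nulls and
    one-dimensional cluster-based permutation tests. Includes a
    synthetic-data generator with known, injectable behavioral and
    neural bias parameters so every stage has a parameter-recovery
    test surface.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    digest,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
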