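Package: semgfatigue
Title: Muscle-Fatigue Prediction and Detection from Surface EMG
Version: 0.1.0
Authors@R: person("EMG", "Tools", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Detects and predicts localized muscle fatigue in surface
    electromyography recorded during isometric contraction. Each second of a
    trial is labeled Non-Fatigue, Transition-to-Fatigue or Fatigue by a
    six-rule type-1 fuzzy classifier driven by elbow-angle kinematics; a
    family of per-second spectral features is extracted, headlined by the
    composite "1D spectro_std" feature (rolling standard deviation of the
    unified band-power / median-frequency stream); pairwise longitudinal
    Fisher discriminant classification and a Davies-Bouldin-style
    separability index quantify how well the classes are told apart. A
    synthetic fatiguing-contraction generator with ground-truth labels makes
    the whole pipeline testable without access to recorded subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
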