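Package: tinnaerp
Title: Evaluation of Acoustic Tinnitus Therapies with Auditory Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for evaluating sound-based tinnitus
    therapies with auditory event-related potentials (AERPs). Provides a synthetic
    cohort generator with audiograms, tinnitus profiles and THI/HADS questionnaires;
    personalized therapy-sound synthesis (retraining noise bands, auditory
    discrimination oddball trains, enriched acoustic environments, binaural beats,
    and untuned placebo music); a ground-truth EEG simulator (evoked component
    templates, resting alpha, trial-coherence control, artifacts); a six-step
    cleaning chain (baseline, band-pass, notch, artifact subspace reconstruction,
    wavelet-ICA) with epoch segmentation; inter-trial-coherence and individual-
    alpha-frequency weighted AERP estimation with area-under-curve scoring of
    before/after grand-average differences; and the accompanying nonparametric
    statistics (D'Agostino-Pearson omnibus normality, exact Wilcoxon signed-rank,
    Spearman correlation screen).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
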