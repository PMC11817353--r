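Package: coromix
Title: Culprit Coronary Artery Classification from 12-Lead ECG Spectrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying which main coronary
    artery (or combination of arteries) is occluded from 12-lead ECG
    signals in the NSTEMI setting. Each lead is converted into an RGB
    spectrogram image (short-time Fourier transform, viridis colormap),
    a multi-input multi-scale ConvMixer network is trained on the 24
    resulting image streams, a 1000-wide fully connected embedding is
    extracted, feature importances are computed with the ReliefF
    algorithm, and a weighted subspace SVM ensemble combines per-subspace
    predictions by importance-weighted voting. Because the clinical
    dataset the method was developed on is not public, the package ships
    a synthetic 12-lead ECG generator with class-dependent ST-segment
    morphology so that the whole pipeline is testable, plus stratified
    k-fold evaluation with per-class one-vs-rest metrics and a
    four-arm ablation runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
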