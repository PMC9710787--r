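Package: timsDescent
Title: De Novo MS1 Feature Detection in 4-D Ion-Mobility Mass
    Spectrometry Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects peptide precursor features in sparse four-dimensional
    (m/z, ion mobility, retention time, intensity) MS1 point clouds of the
    kind produced by trapped-ion-mobility time-of-flight instruments.
    Candidate regions are found by ranking fixed-size voxels by mean
    intensity; peaks are profiled with Savitzky-Golay smoothed apex and
    valley detection; isotopic envelopes are resolved by intensity descent
    and averagine-model deconvolution; detections are scored for
    identifiability with a small neural classifier, filtered and
    de-duplicated. A synthetic point-cloud generator with ground-truth
    manifests supports end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    signal,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
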