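Package: hsichem
Title: Chemometric Analysis of Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for near-infrared
    hyperspectral imaging of granular food samples: reflectance correction
    of raw cubes against white/dark reference frames, background
    segmentation and connected-component object labeling, pixel-wise
    spectral preprocessing (Daubechies-7 wavelet smoothing followed by
    standard normal variate), effective-wavelength selection from PCA
    loadings or FastICA unmixing weights, SVM / k-NN / RBF-network
    classifiers with representative-pixel selection by k-means, and
    evaluation designs that cross pixel-wise and object-wise calibration
    and prediction, including grade-transfer experiments and per-pixel
    prediction maps. A synthetic-scene generator with ground truth makes
    the full pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
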