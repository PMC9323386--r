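Package: nirclust
Title: Fuzzy Clustering of Near-Infrared Spectra for Storage-Time Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying samples from Fourier-transform near-infrared
    (FT-NIR) diffuse reflectance spectra by storage class. Implements
    multiplicative scatter correction (MSC) against a mean reference spectrum,
    orthogonal linear discriminant analysis (OLDA) for supervised dimension
    reduction valid when the spectral dimension exceeds the sample count, and
    three fuzzy clustering estimators (fuzzy C-means, K-harmonic means, and
    Gustafson-Kessel with adaptive covariance norms) sharing a common partition
    model and convergence contract. A pipeline orchestrates the full protocol
    (stratified split, preprocessing, reduction, chained initialization of the
    clusterers, cluster-to-class matching and evaluation), and a synthetic
    spectra generator emulates the statistical structure of refrigerated-meat
    NIR data so every stage is testable without proprietary measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
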