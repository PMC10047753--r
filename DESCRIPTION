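Package: sdpskin
Title: Sobel Directional Patterns and Stacked Restricted Boltzmann Machines
    for Dermoscopy Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying pigmented skin lesions in
    dermoscopy images: DullRazor-style hair artifact removal, classical lesion
    segmentation (Otsu thresholding, morphology and region growing) behind a
    pluggable mask interface, a colour-texture-edge descriptor built from
    fractional-order Sobel compass masks applied to opponent colour-channel
    pairs (maximum-response code images, Difference-of-Gaussians denoising and
    grid histograms), and a stacked Bernoulli Restricted Boltzmann Machine
    trained with persistent contrastive divergence topped by a multinomial
    logistic layer. Includes a seeded synthetic dermoscopy image generator with
    ground-truth lesion and hair masks, a metric suite (sensitivity,
    specificity, positive predictive rate, F-score, harmonic mean) and a
    stratified k-fold cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    png,
    jpeg,
    nnet,
    class,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
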