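Package: foadpc
Title: Gray-Level Density-Peaks Image Segmentation Tuned by Fruit-Fly Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of 8-bit grayscale images (medical
    CT/MRI and similar) by density-peaks clustering of the gray-level
    histogram. The two free parameters of the clustering -- the cut-off
    distance d_c and the number of cluster centers k -- are selected
    automatically by a random-step fruit-fly optimizer that maximizes the
    Shannon entropy of the segmented image. Includes an exhaustive
    grid-search oracle, weighted one-dimensional k-means and a real-coded
    genetic algorithm as baselines, a between-class-variance (SEC) quality
    metric, a synthetic phantom generator with ground-truth labels, and a
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
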