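Package: grainsplit
Title: Counting Touching Cereal Grains in Images by Concave-Point
    Detection and Elliptical Approximation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and counts wheat grains in digital photographs,
    including grains that touch each other. Images are binarized
    (Gaussian and mean-shift smoothing, HSV conversion, Otsu
    thresholding), closed boundary contours are extracted for every
    connected grain region, and concave contact points between touching
    grains are located with a corner response function evaluated along
    each contour. Compound contours are then split into individual
    grains by enumerating set partitions of the inter-corner boundary
    segments and selecting the partition whose segments are best
    approximated by ellipses, which makes the count robust to spurious
    corners caused by chips and surface irregularities. Includes a
    watershed baseline counter, a count-accuracy metric, and a seeded
    synthetic scene generator with per-grain ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
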