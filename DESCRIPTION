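Package: spamkit
Title: Spatial Arrangement Similarity Norming, Scaling and Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for norming sets of novel object stimuli with the spatial
    arrangement method (SpAM). Generates pair-covering trial designs, turns
    canvas arrangements into dissimilarity matrices, embeds them with metric
    SMACOF multidimensional scaling, selects dimensionality and cluster number
    with the kneedle elbow detector, derives global categories by k-means and
    Ward agglomerative clustering, quantifies their robustness with a
    participant-bootstrap Adjusted Rand Index protocol, scores object novelty
    and naming agreement, and checks for color confounds with CIEDE2000 color
    differences. Includes a synthetic-participant generator so the whole
    pipeline can be exercised and validated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    farver,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
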