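Package: phenoclust
Title: Phenotype Clustering and Balancing of Fermentation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw concentration time series from batch and fed-batch
    fermentations into vectors of biomass-specific rates (specific growth rate
    plus specific consumption and production rates), clusters those vectors
    into reference phenotypes with k-means (squared-Euclidean or cosine
    metric) and DBSCAN, and provides downstream analyses: cluster-number
    selection by silhouette, gap, Davies-Bouldin and Calinski-Harabasz
    criteria, conditionality screening via a log-deviation statistic,
    carbon-recovery and ATP balancing of cluster centroids, and
    superposition decomposition of phenotype time courses into non-negative
    mixtures of reference centroids. Includes a synthetic fermentation
    simulator with planted phenotype archetypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
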