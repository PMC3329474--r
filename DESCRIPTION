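Package: rasffnet
Title: Time-Decayed Network Analysis of Food Safety Notifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, temporally decayed notification networks between
    detector and transgressor countries from food-safety alert logs (RASFF-style
    records), computes normalized Transgressor and Detector Indices with
    weighted PageRank and HITS under contaminant and notification-type filters,
    analyses network structure by modularity community detection and k-core
    decomposition, assembles index trajectories over date grids, and generates
    synthetic notification logs with planted statistical structure for testing
    and method evaluation. Snapshots, indices, partitions and colour-coded
    graphs can be exported as CSV and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
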