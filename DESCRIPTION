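Package: tomatoPheno
Title: Stereo-Geometric Phenotyping, Ripeness Scoring and Yield
    Clustering for Greenhouse Tomatoes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-detection phenotyping for greenhouse tomato imagery.
    Converts detector bounding boxes plus an aligned depth map into metric
    fruit sizes, 3D centroids and volumes through the pinhole camera model;
    scores ripeness from HSV hue, cultivar-calibrated diameter and shape,
    fuses the scores and classifies fruits as immature, ripe or overripe;
    groups fruits into plants by density-based (DBSCAN) clustering of their
    3D positions and estimates per-plant yield. Also provides reference
    numerics for ghost feature-map composition, the learnable AReLU/ELSA
    activation, and EIoU / Focal-EIoU bounding-box regression losses, a
    fully ground-truthed synthetic greenhouse scene generator, PASCAL VOC
    and YOLO annotation I/O, and detection/classification/counting
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    xml2,
    EBImage,
    mclust
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
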