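Package: petrigen
Title: Synthetic Annotated Petri-Dish Image Generation for Colony Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates annotated synthetic images of microbial colonies on
    Petri dishes for training instance-segmentation and counting models.
    Colony clusters are extracted from a small set of annotated dish
    photographs with a classical computer-vision chain (bounding-box
    adjacency clustering, unsharp masking, CIELab dark-artifact removal
    with random-walk inpainting, non-local-means denoising, Chan-Vese
    level-set segmentation, distance-based blending masks), composed onto
    empty-dish backgrounds without overlap under an exponential
    colonies-per-patch law, and optionally restyled with a one-shot
    neural style transfer stage driven by Gram-matrix losses. Includes a
    programmatic fixture generator, COCO-style dataset writers with
    run-length-encoded instance masks, and colony-counting error metrics
    (MAE, sMAPE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
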