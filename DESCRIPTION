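Package: caucseg
Title: Lightweight Concatenated Attention U-Net for Crop and Weed Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a lightweight encoder-decoder
    semantic segmentation network for pixel-wise labelling of crop and weed
    regions in field images. The network combines depth-wise separable
    convolutions inside linearly concatenated blocks, attention-gated skip
    connections, and channel/spatial (CBAM) attention over a multi-scale
    feature-fusion head. The package also provides the parameter-reduction
    calculus for these blocks, a synthetic crop-field image generator, a
    label-palette codec, paired image/mask augmentation with hold-out and
    k-fold resampling, and pixel-wise evaluation metrics. All computation is
    plain R; the small reverse-mode engine behind the network is part of the
    package.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
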