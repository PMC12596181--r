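Package: cryocurate
Title: Quality-Controlled Curation of CryoEM Map-Model Datasets for Deep Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds AI-ready voxel datasets from cryoEM density maps and their
    fitted atomic models. Curates EMDB entry metadata with a Q-score filter and
    two-tier redundancy filtering over UniProtKB/AlphaFold cross-references;
    reads and writes MRC2014 density maps; resamples maps to a uniform voxel
    size and applies adaptive contour-anchored denoising and 0-1 normalization;
    scores global map-model fitness with the Volume Overlap Fraction (mean
    intersection-over-union of binarized 2-D projections over six directions,
    excluding the best); generates voxel-wise structural labels by
    nearest-atom assignment within a labeling radius; partitions map/label
    pairs into cubic subvolumes and splits them into train/validation/test
    sets; and evaluates voxel-wise predictions with accuracy, precision,
    recall and F1. A synthetic map/model/metadata generator makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
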