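Package: stereofish
Title: Stereo-Vision Morphometry and Mass Estimation for Farmed Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-contact estimation of fish body size and mass from
    stereo-camera keypoint detections. Back-projects four anatomical
    keypoints (head, tail, upper width, lower width) to 3D using a
    rectified pinhole stereo model, measures body length and width as
    3D Euclidean distances, and predicts body mass with a natively
    implemented random-forest regression on (length, width). Includes
    the full keypoint-detection evaluation stack (IoU, object keypoint
    similarity, precision-recall, interpolated average precision, mAP,
    and regression error metrics), a ground-truthed synthetic stereo
    scene generator with condition presets for clear/turbid/low-light
    water and low/high stocking density, structural building blocks of
    the underlying keypoint-detection network, readers and writers for
    COCO-keypoint JSON, YOLO-pose labels, PFM depth rasters and
    calibration files, and a packaged validation dataset of measured
    and stereo-estimated sizes and masses for 20 grass carp.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    randomForest,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
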