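Package: recovgait
Title: Recovery of Occluded Gait Keypoints by Unscented Tracking with Gated Initialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing occluded 2D human-gait keypoints in COCO-17
    skeleton sequences and for downstream Parkinsonian gait classification. A
    lightweight gated recurrent network imputes missing coordinates from short
    sliding windows and seeds the initial state and covariance of a per-keypoint
    Unscented Kalman Filter, which refines the imputations by fusing them as
    pseudo-measurements under a constant-velocity motion prior. Includes
    confidence-score based occlusion detection, body-part-level occlusion
    simulation, a synthetic walking-skeleton generator with class-specific gait
    profiles and data augmentation, an LSTM sequence classifier, recovery and
    classification error metrics, and an ablation/sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
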