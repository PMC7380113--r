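Package: lvmeasure
Title: Automatic Fetal Lateral-Ventricle Width Measurement from 2D Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the width of the fetal lateral ventricle (LV) on 2D
    ultrasound images from an LV segmentation mask and the on-screen caliper
    ruler burned into the image. The pixels-per-centimeter (PPC) calibration
    is recovered from the caliper ticks by morphological filtering and three
    prior-knowledge contour rules (small contours, common ruler axis, fixed
    inter-tick spacing), with automatic discrimination of 5-mm and 10-mm tick
    rulers. The LV diameter is located by the minimum-enclosing-rectangle
    method: the mask is rotated so its enclosing rectangle is horizontal and
    the longest vertical chord is taken as the width, then converted to
    millimeters via the PPC. Includes a seedable synthetic phantom generator
    (speckle background, caliper ruler, rotated elliptical LV blob) with full
    ground truth, a naive brightness-based detector so phantoms run end to
    end without a trained segmenter, and the evaluation arithmetic used to
    summarise detection, caliper-type and width-error performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
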