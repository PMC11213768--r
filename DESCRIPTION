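Package: latmseg
Title: Location-Adaptive Threshold Segmentation of Coronary Vessel
    Cross-Sections in CT Attenuation Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lumen and outer-vessel-wall boundary detection on
    cross-sectional planes perpendicular to a coronary centerline in
    contrast-enhanced CT attenuation volumes, using a location-adaptive
    threshold rule: per-plane attenuation limits scale with the local
    inner-point attenuation (145 percent upper limit to exclude
    calcification, 50 percent lower limit in the spirit of full width at
    half maximum), with a calibration-factor override when the inner point
    deviates strongly from a reference attenuation. Includes curved planar
    reformation along arbitrary centerlines with rotation-minimizing
    frames, per-plane area and plaque-burden quantification, volume
    integration (interval sum and composite Simpson), interval-adaptive
    profile matching against a fine-interval reference, method-agreement
    statistics (Bland-Altman limits of agreement, Pearson correlation with
    Fisher confidence intervals, two-way random single-measurement
    absolute-agreement intraclass correlation, Fisher r-to-Z comparison of
    independent coefficients), and a digital vessel-phantom generator with
    analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
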