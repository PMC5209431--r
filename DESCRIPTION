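Package: glottocine
Title: Quantifying Vocal Fold Abduction and Adduction from Axial Cine-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures vocal fold mobility from axial cine-MRI frame series.
    Each frame's glottal airway is split into left and right hemi-glottal
    areas and angles about the line bisecting the anterior and posterior
    commissures; per-period means feed the asymmetry metrics VFPa and VFRa
    (deviation of the left/right hemi-glottal ratio from unity during
    phonation and respiration) and the abduction-potential metric VFAP
    (percentage reduction in total glottal area from respiration to
    phonation), with glottal-angle variants of all three. Includes unpaired
    t-tests (raw and summary-statistics forms), single-measure intraclass
    correlation coefficients with F-based confidence intervals for
    test-retest and inter-reader repeatability, and a seeded synthetic
    cine-frame generator emulating healthy and unilateral-paralysis
    laryngeal kinematics so the full pipeline is testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    ggplot2,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
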