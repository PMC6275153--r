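Package: cephaloframe
Title: Corrected-Reference-Frame Evaluation of Craniofacial Treatment
    Change from Superimposed 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for descriptive three-dimensional treatment evaluation
    from pre- and post-treatment cone-beam CT volumes. Performs masked,
    voxel-wise rigid superimposition on cranial-base anatomy by mutual
    information, constructs a corrected Frankfort Horizontal reference
    frame (asymmetry-corrected Orbitale, constructed Sella, Porion axis,
    corrected midline) from semi-automated landmarks, orients the
    superimposed records in that frame, and reports direction-aware
    linear and angular change measurements obtained by projection onto
    the reference plane and a mid-maxillary auxiliary plane. Includes
    the intraclass-correlation and standard-deviation reliability
    analysis used to validate the reference frame, and a parametric
    skull-like phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
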