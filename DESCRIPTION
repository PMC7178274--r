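Package: rsataper
Title: Radiostereometric Measurement of Implant Migration and Head-Taper Slip
Version: 0.1.0
Authors@R:
    person("RSA", "Maintainers", email = "maintainers@rsataper.org", role = c("aut", "cre"))
Description: Tools for uniplanar Roentgen stereophotogrammetric analysis (RSA)
    of total hip arthroplasty: two-plane calibration-box calibration and stereo
    reconstruction, rigid-body migration kinematics with RSA quality metrics
    (condition number, rigid-body error), pose fitting of elementary geometrical
    shapes (sphere head, cone taper) from silhouette observations, head-taper
    slip measurement in a taper-axis coordinate frame with Hurschler
    reference-point correction, Bland-Altman / t-test / Fisher-Z method
    interchangeability statistics, and a ground-truth-paired synthetic phantom
    generator emulating a long-term follow-up cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
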