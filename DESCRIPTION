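Package: oasense
Title: Ophthalmic Artery as a Non-Invasive Intracranial Pressure Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order pulsatile modeling and analysis tools for two-depth
    transcranial Doppler monitoring of intracranial pressure (ICP) through the
    ophthalmic artery. Implements a one-dimensional compliant-vessel simulator of
    the ophthalmic artery under intracranial and extracranial pressure loading,
    the snapshot balance-point measurement with decomposition of its systematic
    error into intraorbital and Poiseuille-gradient components, the blood flow
    factor (BFF) statistic computed from two-depth Doppler intensity traces with
    artifact filtering, per-subject linear calibration of BFF to ICP for
    continuous monitoring, Bland-Altman and pooled method-comparison statistics,
    and a seeded synthetic patient-cohort generator for end-to-end validation
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
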