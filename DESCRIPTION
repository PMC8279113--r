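Package: odontometry
Title: Trigonometric Measurement of Tooth Rotation, Inclination and
    Angulation on Digital Dental Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal measurement of orthodontic tooth movement from five
    anatomical landmarks per tooth (lingual gingival, mesial, distal, occlusal,
    vestibular gingival) digitised on paired initial and final-planned arch
    models.  Builds an occlusal/median reference frame from a total
    least-squares plane through the lingual gingival landmarks, measures
    per-tooth rotation by the arctangent of the mesiodistal line against the
    anteroposterior axis, resets each tooth's rotation with a rotational
    matrix before reading inclination and angulation as projection angles of
    the gingivo-occlusal crown line, and reports per-tooth angular changes
    (delta rotation, inclination, angulation) between time points.  Includes
    landmark-based rigid best-fit alignment (Kabsch), an IGES point-entity
    reader for coordinates exported from mesh software, a synthetic arch
    generator with known applied movements and digitisation noise, and the
    agreement and reliability statistics used to validate the method
    (Bland-Altman limits of agreement, one-sample t test for systematic
    error, Dahlberg random-error index, and intraclass correlation
    coefficients for single measurements with absolute agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
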