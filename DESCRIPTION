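Package: divecurate
Title: Acquisition, Curation and Management of Underwater Photo-Transect Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A curation pipeline for seafloor image surveys acquired by
    autonomous underwater vehicles and similar camera platforms. Provides a
    machine-readable image naming scheme and metadata schema, camera-versus-
    navigation clock synchronization by cross-anti-correlating image
    brightness with vehicle altitude, outlier and gap repair for navigation
    telemetry, merging of multi-sensor metadata streams by timecode,
    automated image quality control (water-column, dark, black and
    condensation-impaired frames), equidistant fisheye un-distortion to
    virtual perspective views, per-pixel geo-referencing on a flat-seafloor
    model, EXIF metadata fusion, and deterministic folder/archive
    organization with checksum manifests. Includes a synthetic dive
    generator with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jpeg,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
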