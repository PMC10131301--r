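Package: batlas
Title: Acoustic Multilateration of Bat Flight with LiDAR Vegetation Context
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for reconstructing three-dimensional bat flight paths from
    multichannel ultrasonic recordings of echolocation calls made with an
    overdetermined eight-microphone array, and for placing those paths in the
    vegetation context measured by terrestrial laser scanning. Covers call
    detection, time-of-arrival-difference estimation by cross-correlation,
    nonlinear least-squares multilateration with radial/tangential error
    assessment and position filtering, flight-track construction, point-cloud
    deviation filtering and voxelisation, rigid-body co-registration of the
    acoustic and LiDAR coordinate frames from array reference points,
    distance-to-structure analyses, and a synthetic-scene simulator (flight
    paths, FM calls with spherical spreading and trunk occlusion, vegetation
    clouds) that exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    RANN,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
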