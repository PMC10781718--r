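Package: tmjvol
Title: Temporomandibular Joint Space Volumetry from Serial 3D Scans
Version: 0.1.0
Authors@R: person("tmjvol", "developers", role = c("aut", "cre"),
    email = "tmjvol@example.org")
Description: Landmark-based craniofacial reference planes, rigid
    superimposition of serial cranial scans, voxel-based extraction of the
    glenoid-fossa and temporomandibular joint-space volumes with anterior/
    posterior and medial/lateral compartment partitioning, and a
    repeated-measures linear mixed model with unstructured covariance for the
    longitudinal time course of those volumes. Includes a synthetic phantom
    generator (fossa, condyle, landmarks, per-visit scanner pose and condylar
    sagging with partial recovery) and a longitudinal record simulator so the
    whole pipeline is testable without patient imaging.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
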