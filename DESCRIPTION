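Package: vitreflow
Title: Oscillatory Viscoelastic Flow in a Rotating Sphere and PIV-Style
    Post-Processing for Vitreous Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the motion of the vitreous humour (or a
    viscoelastic vitreous substitute) inside a periodically rotating
    spherical chamber. Provides the closed-form small-amplitude solution
    for a linear viscoelastic fluid filling a rigid sphere under
    sinusoidal rotation, rheology containers for the complex modulus
    G* = G' + iG'', a seeded generator of synthetic particle-image-
    velocimetry (PIV) style ensemble velocity fields on the equatorial
    plane, and the post-processing chain used in experimental studies of
    vitreous dynamics: ensemble averaging, polar decomposition and
    nondimensionalization, azimuthal averaging, normalized kinetic energy,
    single-harmonic least-squares fits of the velocity profiles, maximum
    shear-strain profiles, and resonance detection across forcing
    frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
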