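Package: holoscatter
Title: Holographic 3D Imaging of Incoherent Sources Through Scattering Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive holographic reconstruction of spatially incoherent
    (e.g. fluorescent) point sources hidden behind a thin, strongly scattering
    layer. Mutually incoherent scattered fields are recovered from random-mask
    modulated intensity images by mixed-state phase retrieval, demixed into
    per-source fields by Riemannian optimization on the unitary group, and
    coherently fused into a virtual scattering medium -- a phase screen at the
    internal correlation plane that replicates the distortion of the physical
    layer. Numerically propagating the fields through the virtual medium yields
    a diffraction-limited 3D image of the hidden object. A physical-optics
    simulator (band-limited angular-spectrum propagation, phase-screen
    diffusers, SLM mask sets, optional shot noise) generates all inputs, so the
    entire pipeline runs and is tested without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
SystemRequirements: fftw3
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
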