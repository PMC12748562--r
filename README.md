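# holoscatter

Holographic 3D imaging of spatially incoherent sources hidden behind a
scattering layer — for microscopists and computational-imaging researchers
who need to see fluorescent objects through strongly scattering media at
working distances of tens to hundreds of micrometres, where speckle
intensity-correlation methods fail.

## The method

A thin scattering layer multiplies the field of every hidden source n by the
same unknown unit-modulus transmission `S_o(r)`, so the field at the layer is
`E_n(r) = S_o(r) h_n(r)` with `h_n` the free-space field of source n. The
camera records only random-mask modulated sums of intensities,

    I_m = Σ_n | F⁻¹[ Ẽ_n K_m ] |²,

where `K_m` are known SLM phase masks. The package:

1. recovers the mutually incoherent fields `E_n` from `{I_m, K_m}` by
   mixed-state alternating projections (up to an unavoidable unitary mix);
2. finds the internal *correlation plane* — the layer — as the propagation
   distance maximizing the pairwise tilt correlation
   `Γ(r, z) = Σ_{n,m} |F[conj(P_z E_n) · P_z E_m](r)|²` (r = 0 excluded);
3. demixes the unitary ambiguity by maximizing
   `M(U) = Σ_{n≠m} max_{r≠0} |F[conj(E'_n) E'_m](r)|`
   over the unitary group (Riemannian gradient ascent; tile-wise for 3D
   objects);
4. fuses the demixed fields into a **virtual scattering medium**
   `S(r) = exp(i arg[Σ_n E_n e^{iΦ_nm}])`, a phase screen that replicates
   the layer's distortion relative to a reference source m;
5. reconstructs the 3D object by numerically propagating through it:
   `I(r, z) = Σ_n | P_z{ F[conj(E_n) S] }(r) |²`,
   then detects sources, calibrates coordinates against the fixture, and
   scores PSNR/SSIM against the diffraction-limited ground truth.

A physical-optics simulator (band-limited angular-spectrum propagation,
Gaussian phase screens, SLM mask sets, optional shot noise) generates all
inputs, so the full pipeline runs and is tested with no experimental data.

## A worked example

```r
library(holoscatter)

cfg <- study_config("beads2d", seed = 1)   # 5 beads ~100 um behind the layer
res <- run_pipeline(cfg)
```

The run log prints each stage:

```
simulate: 5 sources, 120 masks, focus 100 um (0.5s)
retrieve: 5 states, 11 epochs, residual 2.63e-13 (1.7s)
locate-plane: z_hat 100 um, confidence 66.8 (1.0s)
demix (global): metric 0.071524 (identity 0.03247), 13 iters (1.5s)
build-medium: reference 1, 5 admitted (0.1s)
reconstruct: 11 planes, peak 0.1255 (0.4s)
evaluate: 5 detections, PSNR 45.42 dB, SSIM 0.9983 (0.5s)
```

Reading the result: the measurement residual `2.6e-13` says retrieval
reproduced the noiseless camera data essentially exactly; `z_hat = 100 um`
locates the scattering layer at its true distance from the camera-conjugate
plane; the demixing metric more than doubles over the mixed fields; and the
registered reconstruction of the five beads agrees with the
diffraction-limited ground-truth image to `PSNR 45.4 dB`, `SSIM 0.998`,
with every bead detected:

```r
res$detections              # positions in reconstruction coordinates
res$evaluation$fwhm_um      # lateral spot FWHM, calibrated: 0.77 um
res$calibration             # magnification 1.055, residual RMS 0.37 um
```

The two-depth (`"beads3d"`) and 20-focus spiral (`"spiral"`) scenarios run
the tiled-demixing / stitched-medium route; `run_pipeline(cfg, out_dir =)`
persists every intermediate artifact (TIFF + JSON bundles, detection CSV,
`summary.json`, `run.log`). A thin CLI over the same functions lives at
`inst/scripts/holoscatter` with stages `simulate`, `retrieve`,
`locate-plane`, `demix`, `build-medium`, `reconstruct`, `evaluate`, `run`.

## Layout

- `R/` — grids and Fourier optics, the simulator, phase retrieval, field
  correlation and demixing, virtual-medium construction, reconstruction and
  evaluation, IO, pipeline orchestration.
- `src/` — FFTW-backed centred FFTs and the retrieval/demixing inner loops.
- `vignettes/virtual-medium-method.Rmd` — the model, its assumptions,
  parameter defaults and numerical choices.
- `tests/testthat/` — unit, property and acceptance suites.
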