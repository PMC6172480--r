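---
title: "Simulating and mapping dual-wavelength optoacoustic breast images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and mapping dual-wavelength optoacoustic breast images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatomo)
```

## The problem

Hand-held optoacoustic/ultrasound imaging maps blood in the breast by firing
short near-infrared laser pulses at two wavelengths (757 nm, where
deoxyhemoglobin dominates absorption, and 1064 nm, where oxyhemoglobin
does), recording the resulting wide-band pressure transients on a
128-element linear transducer array, reconstructing per-wavelength images,
and converting the co-registered pair into functional maps of total
hemoglobin \[tHb\] and blood oxygen saturation \[sO2\] displayed as RGBA
color over a grayscale anatomical background. `oatomo` implements that
computational chain in simulation: digital phantoms stand in for the tissue,
a physics-based forward model for the acquisition, and the identical
processing path (conditioning, filtered back-projection, depth
normalization, spectral unmixing, palette rendering) for image formation.

## Models and assumptions

**Optics.** Light transport is a one-dimensional planar fluence model,
$F(z) = \exp(-\mu_\mathrm{eff} z)$ with
$\mu_\mathrm{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}$ from diffusion theory.
With the average breast coefficients ($\mu_a$ = 0.039 / 0.122 cm$^{-1}$ and
$\mu_s'$ = 9.0 / 4.0 cm$^{-1}$ at 757 / 1064 nm) this gives close to a
3-fold fluence loss per centimetre, matching the system-level description.
Lateral structure of the illumination and Monte Carlo transport are out of
scope; the fluence is laterally uniform.

**Initial pressure.** $p_0 = \Gamma\,\mu_a\,F$ per pixel, with the
Grueneisen efficiency $\Gamma$ constant across the scene (relative
brightness convention, $\Gamma \equiv 1$). Blood absorption follows
$\mu_a = \mathrm{tHb}\,[s\,\varepsilon_{HbO_2} + (1-s)\,\varepsilon_{Hb}]$
with tHb = 1 at hematocrit 41% on the relative extinction scale; the
rasterizer converts blood to physical cm$^{-1}$ through the whole-blood
factor $\ln(10) \times 150/64500 \approx 5.4\times10^{-3}$, which puts
whole blood near 8.5 cm$^{-1}$ at 757 nm — the physically sensible contrast
over the 0.039 cm$^{-1}$ background. The bundled extinction table is a
rounded literature compilation; only its spectral ordering (the oxy/deoxy
inversion between 757 and 1064 nm) matters for the self-consistent
simulate-and-unmix studies in this package.

**Acoustics.** Each source voxel radiates the exact retarded field of a
small uniform sphere; traces are the time derivative of the deposited
$1/R$-weighted field, scaled by $1/4\pi c^2$. Amplitude attenuation follows
$u(z) = u_0\,10^{-\alpha f^{1.5} z / 20}$ with $\alpha = 0.32$
dB cm$^{-1}$ MHz$^{-1.5}$, an amplitude-dB convention calibrated so that
10 MHz over 1 cm loses about 3-fold, consistent with the printed summary.
The exponent 1.5 on frequency follows the usual breast-tissue power law;
the attenuation is applied per trace in the frequency domain with the
propagation distance taken as $ct$, interpolated across a small set of
exactly filtered copies. Sound speed defaults to 1.54 mm/µs (soft tissue)
and 1.49 mm/µs for the aqueous bath; heterogeneous speed maps are not
modeled.

**Detection.** The electro-acoustic impulse response (EIR) is a zero-phase
band-pass magnitude with Butterworth skirts placed so the response crosses
-6 dB exactly at 0.1 and 12 MHz. The laser pulse (50 ns at 757 nm, 15 ns at
1064 nm) enters as a rectangular-pulse spectral factor, so the longer pulse
yields the broader axial point-spread function. Element directivity is the
far-field flat-rectangle $\mathrm{sinc}$ at a 6 MHz reference frequency;
element-surface averaging uses 5-point quadrature across the 0.25 mm
element width. Detector noise is white at the noise-equivalent pressure
(1.3 Pa), mapped onto the simulation's relative pressure unit through a
nominal 4000 Pa per unit ($\Gamma = 0.2$ at the 20 mJ/cm$^2$ maximum
permissible surface fluence).

## Numerical choices in the forward model

Discretizing sources on a grid and depositing delta impulses onto a sampled
time axis creates lattice granularity that the tomographic ramp filter
amplifies. Three measures keep the discrete model spectrally faithful:

* each voxel deposits the analytic parabolic kernel of its equal-volume
  sphere, integrated exactly over every sample bin (mass-conserving for any
  sampling rate);
* the kernel radius is inflated by `kernel_scale` (default 2) to smooth
  lattice noise — mass is conserved, at the price of a little extra axial
  smoothing well below the EIR resolution;
* the time derivative is taken spectrally, with the boxcar transfer of the
  per-bin integration divided out, rather than by finite differences
  (which lose ~50% amplitude at the 12 MHz band edge).

With these choices a sphere discretized at 15 µm voxels matches the
closed-form N-wave convolved with the system response to better than 1%
RMS, which is how the simulator is validated.

## Reconstruction

Images are formed by weighted filtered back-projection of the data function
$p(t) - t\,\partial p/\partial t$ (central differences), sampling each
element trace at $t = |r_T - r|/c$ with linear interpolation. Each
contribution is weighted by the element solid angle
$d\Omega = \cos\theta / R^2$ normalized by the per-pixel total aperture
$\Omega_0 = \sum d\Omega$ (limited-view normalization), and by the
regularized inverse element directivity (floor 0.2) — the spatial impulse
response correction, applied in reconstruction coordinates where it acts.
We deliberately use the weight $d\Omega/\Omega_0$ *without* an extra factor
of $R$: the ramp-filtered data function does not decay with distance, so an
$R\,d\Omega/\Omega_0$ weight would make identical absorbers brighten
roughly linearly with depth (we measured a 2.2-fold rise from 13 to 32 mm),
defeating the design goal that relative brightness be comparable across the
image. With $d\Omega/\Omega_0$ the response is depth-neutral to within a
few percent, which the depth-series tests assert.

## Conditioning

Channel gains are divided out and dead elements zeroed. EIR deconvolution
is a frequency-domain Wiener inverse; the regularization is either a scalar
noise-to-signal ratio (default $10^{-3}$, the device's value being
unstated) or `"auto"`, the full Wiener filter with the signal spectrum
estimated from the channel-pooled data and the white-noise floor from the
upper spectral tail. The pipeline estimates one common filter from the
pooled dual-wavelength frame pair so that filtering never treats the two
wavelengths differently — wavelength-asymmetric filtering directly biases
the unmixed saturation. Band-pass filtering is zero-phase (forward-backward
Butterworth, order 4 per section) with the 67 kHz low cutoff (a 100 kHz
variant suppresses beam-edge artifacts harder) and the 12 MHz transducer
edge as high cutoff; traces are odd-reflection padded so the very low
corner's transient stays out of the data.

## Functional mapping

Depth normalization divides every pixel by the average background
brightness of its row (bright objects removed by rowwise-robust
segmentation with morphological closing), which makes the background depth
independent; fully masked or nonpositive rows are interpolated from their
neighbours. On reconstructed simulated data, however, there is nothing to
measure: a perfectly homogeneous background is almost entirely rejected by
band-limited, DC-free tomography, so measured row means are streak noise.
The pipeline therefore divides by the same quantity computed analytically —
the known background $\mu_a F(z)$ profile (`profile` mode) — and multiplies
by the per-wavelength bulk $\mu_a$, returning both wavelengths to one
relative absorption scale. The measured-row-mean mode remains the exact
method in image space and is what the depth-flattening tests exercise.

Because the reconstructed background consists mostly of limited-view
streaks and the illuminated-surface wave — and unmixes to an apparent
saturation above 100% (the 0.039/0.122 background ratio is more
oxyhemoglobin-like than blood) — the pipeline also subtracts the simulated
response of the inclusion-free background scene from each sinogram before
conditioning. This is the simulation-side analogue of the device's
background segmentation/removal step and removes up to +15 percentage
points of sO2 bias in shallow scenes. One consequence is that maps show
absorption *contrast* over background; at very low hematocrit (4%), where
tube absorption is only a few times background, the recovered saturation of
a 50% tube reads low (~36%) — its color class is preserved, which is the
behavior the validation experiments report.

Unmixing solves the exact 2x2 chromophore system per pixel; saturation is
clamped to [0, 1] and marked undefined where tHb falls below 5% of its
99th percentile (the ratio is unstable at low signal). ROI saturations are
reported as the saturation of the ROI-mean chromophore content (ratio of
means over eroded, valid pixels): averaging per-pixel clamped saturations
is biased toward mid-range as soon as pixel SNR drops. Statistical mapping
standardizes a map against a user-selected reference region (default: a
5-15 mm background band).

## Display

Saturation below 85% renders red (magenta below 40%), the closed band
85-90% is transparent so the grayscale anatomy shows through, and values
above 90% render green (cyan above 98%); the magenta/cyan extremes are
package conventions since only the 85/90 boundaries are specified.
Opacity ramps linearly over 3 percentage points on each side of the
transparent band. Total hemoglobin uses a yellow layer colored strictly
above the 90th percentile of the in-image values, so a uniform map shows
nothing. Compositing is standard alpha-over; in combined mode sO2 colors
appear only where the tHb layer is colored. Frame pairing groups
alternating 757/1064 frames at the 5 ms inter-pulse delay into functional
frame pairs (10 frames/s in, 5 pairs/s out).

## Study conditions and problem sizes

The validation scenes mirror the phantom experiments: 2.4 mm blood tubes at
10 or 20 mm depth in breast-mimicking material, 1.5 mm tubes at 13-32 mm in
an aqueous bath index-matched to average breast optics (modeled with breast
bulk optics, water sound speed and negligible acoustic attenuation), blood
at hematocrit 41/27/4% with saturations between 50 and 100%, and tubes
10 mm apart laterally (the separation is not printed; 10 mm keeps the tubes
within the uniformly illuminated core of the aperture). Default grids are
38 x 38 mm at 0.15 mm spacing with 40 MHz sampling; tests use the same
physics on smaller grids where the full field of view is not the point.
Noisy acceptance runs average five frame pairs — one second of the 5 fps
display — because single-pulse estimates at hematocrit 4% sit at the noise
floor (about 3 Pa of signal against the 1.3 Pa NEP) and are honestly
unstable in this chain. When the hematocrit series compares tHb
signal-to-noise across arms, the Wiener regularization is held fixed: the
adaptive filter widens its passband with signal strength and thereby
equalizes SNR between the 41% and 27% arms, so "noise" would not be
commensurable otherwise. The noise level itself is estimated from the map
difference of two independent acquisitions, in which the deterministic
signal and streak structure cancel.

What passing these simulations does *not* show about real data: phantoms
here have homogeneous backgrounds and known optics, so model-based
background handling is exact in a way clinical tissue never is; motion,
heterogeneous sound speed, skin melanin and the bench-measured absolute
resolution figures (0.42-0.47 mm axial, 0.73-0.81 mm lateral) are outside
the simulation — only resolution *orderings* (pulse duration, depth) are
asserted.

## Known limitations

* Fluence is 1D and wavelength-separable; self-shielding inside strong
  absorbers is ignored, so tube interiors are uniformly bright.
* The 2D slab source convention treats tubes as thin cross-sections;
  out-of-plane sensitivity beyond the in-plane directivity model is not
  simulated.
* Absolute image scale is arbitrary (limited-view normalization leaves no
  physical unit); all functional quantities are relative, as in the
  clinical display.
* The aqueous-bath experiments are emulated with breast-average optics;
  the actual emulsion optics of the physical experiment are unpublished.

## A minimal run

```{r, eval = FALSE}
phantom <- make_two_tube_phantom(depth = 20, diameter = 1.5,
                                 so2_left = 1.0, so2_right = 0.5,
                                 hematocrit = 0.27, medium = "aqueous")
manifest <- run_pipeline(list(scene = phantom, out_dir = "run", seed = 1))
sapply(manifest$rois, function(r) r$so2_mean_pct)
```
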