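---
title: "Methods: from heterodyne vSFG interferograms to director maps and domain textures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from heterodyne vSFG interferograms to director maps and domain textures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsfgmap)
```

## The measurement and the model

Phase-resolved (heterodyne) vibrational sum-frequency generation (vSFG)
microscopy records, per camera pixel, the interference of a vibrationally
resonant signal with a local oscillator while the IR-visible delay is
scanned. A Fourier transform of each interferogram yields the complex
second-order susceptibility spectrum of that pixel: its imaginary part has
absorptive, sign-carrying Lorentzian line shapes, and its phase encodes the
*absolute* orientation of the contributing transition dipoles. Because the
process is forbidden in centrosymmetric media, only the ordered interfacial
molecules contribute.

For a P-polarised beam at incidence angle $\vartheta$ the driving field
splits into an in-plane and an out-of-plane part,

$$f_{ip} = \frac{\cos\vartheta}{\cos\vartheta + \sin\vartheta},\qquad
  f_{op} = \frac{\sin\vartheta}{\cos\vartheta + \sin\vartheta},$$

implemented in `field_fractions()`; at the instrument's 36° these are 0.579
and 0.421, so both orientations are probed at once.

To separate them, image stacks are recorded at several sample rotations
$\varphi$ (default six steps of 60°). Out-of-plane responses are invariant
under rotation; in-plane responses are modulated as $\cos(d + \varphi)$,
where $d$ is the lab-frame azimuth of the in-plane transition dipole. After
registering all frames back into the sample frame, the azimuthal discrete
Fourier transform

$$F_n(\omega) = \frac{1}{N}\sum_j S(\omega, \varphi_j)\,e^{-i n \varphi_j}$$

isolates the out-of-plane response in $F_0$ and the in-plane response in
$F_1$, with $|F_1|$ equal to half the cosine amplitude and
$\arg F_1 = d$ (`azimuthal_decompose()`; the normalisation is stated here
because magnitude calibrations depend on it).

The per-pixel molecular direction $\theta$ follows from projecting
$F_1(\omega)$ onto the model in-plane line shape
$P(\omega) = \sum_m a_{ip,m} e^{i\delta_m} L_m(\omega)$, where
$L_m(\omega) = 1/(\omega_m - \omega - i\Gamma_m)$ and $\delta_m$ is each
band's dipole azimuth relative to the molecular direction. The methyl
symmetric stretch dipole points exactly opposite the defined molecular
axis, so CH$_3$ bands carry $\delta = 180°$ and CH$_2$ bands $\delta = 0$;
with this convention $\arg$ of the projection *is* $\theta$, the full 360°
direction. Pixels whose in-plane magnitude falls below a noise floor are
masked, never guessed.

## The spectral model

`default_band_table()` places Lorentzian bands at 2845 (CH$_2$ SS), 2875
(CH$_3$ SS), 2905 (CH$_2$ FR), 2935 (CH$_3$ FR) and 2965 (CH$_3$ AS)
cm$^{-1}$, plus two weak unassigned bands with wide fitting bounds
(2800-2940 cm$^{-1}$) that are excluded from the CH$_2$/CH$_3$ magnitude
images. Symmetric stretches and Fermi resonances have positive amplitudes
and antisymmetric stretches negative ones, reproducing the
positive-SS/negative-AS appearance of upright acyl chains. The denominator
sign convention $(\omega_m - \omega - i\Gamma)$ is chosen so positive
amplitude gives a positive imaginary peak; both conventions circulate in
the SFG literature, so it is fixed and documented here. Half-widths
($\Gamma = 6$-$9$ cm$^{-1}$) and the unassigned band centres are package
conventions, not measured values. Band deconvolution (`fit_bands()`) is a
bounded Levenberg-Marquardt least squares over the joint (Re, Im) residual
with up to three seeded, jittered restarts. It is deliberately
"qualitative-deconvolution" grade: its purpose is the relative CH$_2$ versus
CH$_3$ contributions. At an amplitude signal-to-noise of 20 the fitted
CH$_3$ SS frequency scatters with an RMS well below 1 cm$^{-1}$, while
single-realisation amplitudes trade off against the width and scatter by
roughly 8% RMS; amplitude recovery is therefore assessed as the
(unbiased) Monte-Carlo mean in the test suite.

## The synthetic-data generator

No experimental stacks are distributed, so every stage is verified against
a forward model (`synthetic_scene()`, `synthesize_chi2_series()`,
`synthesize_interferograms()`, `synthesize_reference()`) whose defaults
emulate the experiment's stated conditions:

* circular liquid-condensed domains of radius 5 µm (ca. 10 µm diameters) on
  a 128 x 128 px, 0.5 µm/px field; the liquid-expanded background also
  contributes signal (relative density 0.35 versus 1 inside domains) but
  carries no net in-plane direction ($s = 0$);
* director textures from two parametric families: a boojum family
  $\theta = k\psi + \beta + q r$ (winding $k$, offset $\beta$, pitch $q$ in
  °/µm) and a linear family $\theta = \beta + g\cdot(x, y)$. These
  reproduce the four depicted texture classes: parallel contours (linear),
  radial contours ($k{=}1, q{=}0$, concentric circles of lipids), and
  spirals ($k{=}1, q{\neq}0$, the sign of $q$ giving the spiral sense);
* per-pixel emission $\chi(\omega; p, \varphi) = \chi_{NR} + \sum_m
  L_m(\omega)\rho(p)[f_{op}a_{op,m} + f_{ip} s(p) a_{ip,m}
  \cos(d_m(p) + \varphi)]$, rendered in the *lab* frame (the camera lattice
  is fixed; the sample turns), with the scene evaluated analytically at the
  rotated coordinates so the forward model contains no interpolation;
* heterodyne interferograms as the pure cross-term
  $\mathrm{Re}[\sum_\omega \chi G\,\mathrm{LO}^* e^{-i2\pi c\omega t}]$
  with a Gaussian IR amplitude envelope (FWHM 300 cm$^{-1}$ around
  2899 cm$^{-1}$), 2 fs delay steps from -300 to 3000 fs, and a spectrally
  flat quartz reference on the reduced -300..300 fs axis — homodyne terms
  are omitted because balanced detection isolates the cross-term, which is
  the analysed quantity;
* seeded Gaussian detection noise. "Amplitude-SNR" in the tests means the
  peak in-plane CH$_3$ SS spectral amplitude inside the domains divided by
  the noise standard deviation per quadrature per spectral sample — i.e.
  the SNR of exactly the signal whose phase becomes the director.

What the generator does **not** emulate: camera shot-noise statistics,
paired-pixel balancing residuals, Fresnel/local-field factors and molecular
hyperpolarizability tensors (amplitudes are effective band-level
parameters), scattering backgrounds, drift between rotations, and
non-circular domain morphologies. Passing tests therefore demonstrate the
correctness of the *analysis* under the stated signal model, not robustness
to every instrumental artefact of real data.

## Numerical choices

**Frequency grids.** Interferogram workflows use the grid commensurate with
the delay axis, $\delta\omega = 1/(cN\Delta t) \approx 10.06$ cm$^{-1}$ for
the 3300 fs span (`dft_omega_grid()`), which makes simulate → FFT →
normalise exact to interpolation error; purely spectral workflows default
to 2700-3100 cm$^{-1}$ in 5 cm$^{-1}$ steps.

**Reference normalisation.** The coarse quartz spectrum is interpolated in
polar form (magnitude and unwrapped phase, cubic splines) before the
complex division, avoiding the magnitude dips of linear complex
interpolation; reference magnitudes below 5% of their maximum inside the
roi abort with the offending frequency named.

**Dark counts and baseline.** Dark counts are estimated per pixel as the
median complex offset over the anchor windows (below 2800 and above
3050 cm$^{-1}$, outside every band core), followed by subtraction of a
complex straight line fitted over the anchors. How dark counts are best
estimated (shutter frames versus spectral wings) is instrument-dependent;
this package uses the spectral-wing estimate. The
operation is idempotent and, crucially, the *same* operator is applied to
the in-plane reference shape $P(\omega)$ before the director projection —
otherwise the baseline step would bias every direction by a constant
(about a degree under the default band table).

**Registration.** Back-rotation uses bilinear interpolation with
out-of-footprint pixels marked invalid (zero-filling would corrupt $F_0$);
the common mask is the intersection of all rotated footprints. The rotation
centre is found by maximising the mean correlation of back-rotated
band-integrated magnitude images against the zero-rotation frame on a
coarse-then-fine grid (1 px then 0.25 px), followed by an integer
cross-correlation shift refinement. Pixels within ~1.5 px of a domain
boundary are partial-volume mixtures (their interpolation support straddles
the edge); quantitative per-pixel comparisons and the texture fits
therefore work on masks eroded by 1.5 px (`erode_mask()`), while maps and
images keep every valid pixel.

**Time-domain SVD.** The SVD grouping truncates the spectra to the roi,
returns to real time-domain traces and runs an SVD over (pixels x
rotations) against time, mirroring the instrument-native real
representation. A literal physical-frequency real DFT would need ~1200
time samples;
instead the roi bins are placed at offset $K$ of a $4K$-point real DFT —
an exactly invertible one-sided representation in which signal and
conjugate bins can never alias. The SVD uses LAPACK via `svd()`; retained
component spectra are unit-normalised with their sign fixed so the CH$_3$
SS imaginary part is positive. Director extraction defaults to the
azimuthal projection; the SVD route (`extract_director()` on an
`svd_result`) adds its 180° dipole convention explicitly and serves as a
cross-check mode (and is slightly less noisy, since two components absorb
the whole signal subspace).

**Confidence.** The sinusoidal model of a complex signal occupies azimuthal
orders $\{0, +1, -1\}$; per-pixel confidence is the fraction of azimuthal
power in those orders, and the residual orders ($2 \le n \le N-2$) define
the non-sinusoidal residual. (For real-valued SVD loadings the $\pm1$
orders are conjugates and are counted together.)

**Texture classification.** Both families are fitted by circular least
squares minimising $\sum w\,[1 - \cos(\theta_{obs} - \theta_{model})]$ — a
bounded, wrap-safe loss — with the angular offset solved in closed form
(circular mean) inside every search step. The boojum centre is searched on
a grid extending 1.5 domain diameters beyond the mask, because homochiral
spiral centres fall *outside* their domains ("virtual" boojum), then
refined by Nelder-Mead. Model selection is parsimonious: the boojum family
must beat the linear residual by at least 10% (relative) and $10^{-5}$
(absolute, ≈0.26° RMS), and the free-pitch spiral must beat the pitch-free
radial fit by the same margins. The absolute floor sits well above the
chance improvement one extra parameter buys on pure noise (about
residual/$n_{px}$) and well below any real curvature signal, so flat or
radial fields are never promoted to spirals. Fits whose residual exceeds
0.3 (≈45° RMS) are labelled "unclassified" rather than silently guessed.
Only $k = 1$ boojums are searched: every depicted class, including all
mirrored variants, has $k \in \{0, 1\}$ (mirroring maps $k{=}1 \mapsto
k{=}1$ with $\beta \mapsto -\beta$, $q \mapsto -q$); a hypothetical
$k = -1$ field lands in the rejection path.

**Labels.** Packing curvature is the sign of the magnitude-weighted mean
directional derivative of $\theta$ along the director (negative = CW under
the CCW-positive angle convention). The spiral sign is defined from the
contour winding: '+' if iso-direction contours wind clockwise moving
outward from the fitted centre, which for $\theta = \psi + \beta + qr$
means $q > 0$. A sign could equally be attached to the director winding;
the contour-winding definition is the one adopted and fixed here. A boojum is "real" when the fitted centre lies inside the
domain mask and "virtual" otherwise; the call is invariant under rigid
translations and rotations of the scene.

**Coverage, density, order.** Several defensible estimators exist for
relative composition; the package defines the simplest one that is exactly
invertible under the forward model: relative DPPC density is
the in-domain mean of the band-integrated out-of-plane CH$_3$ magnitude
(taking the out-of-plane response per molecule as orientation-invariant
across samples), and the in-plane order scale is the in-domain mean of
$2|F_1|/|F_0|$ over the CH$_3$ windows. Both are reported only as ratios
between samples (`compare_composition()`), since an absolute
normalisation of "lipid order" across samples would require per-molecule
response factors the measurement does not constrain.

**Mirroring.** `mirror_scene()` reflects about the grid's horizontal
midline (so the mirrored scene stays on the pixel lattice — equivalent to
the $y = 0$ reflection up to a rigid translation) and maps
$\theta \mapsto 360° - \theta$; textures transform as
$\beta \mapsto -\beta$, $q \mapsto -q$ (boojum) and
$g \mapsto (-g_x, g_y)$ with the matching offset (linear). Classifying a
mirrored scene flips CW↔ACW and +↔− and preserves the class.

## Problem sizes used in the test suite

Module tests run on 16-64 px grids. The end-to-end recovery tests use the
default 128 x 128 px field with four domains for director recovery (one
noiseless scene plus twenty noisy seeds at amplitude-SNR 10), sixty
single-domain 64 px scenes for texture classification (ten seeds for each
of six class/handedness configurations, at least twenty per class), twelve
mirrored scenes, two 96 px scene pairs for the composition contrasts at
SNR 20 (injected density ratio 1.21 and order ratio 1.22), fifty
Monte-Carlo seeds for the band fit, and a 16 px field for the full
interferogram round trip on the 1651-sample delay axis. These sizes were
chosen as the smallest at which each property is cleanly exercised.

## Known limitations

* Directors within ~1.5 px of a domain edge are partial-volume estimates;
  treat the rim of the phase maps qualitatively.
* Radial/spiral textures whose defect core lies *inside* the imaged domain
  have an unavoidable interpolation error within a few pixels of the core,
  where the angular gradient diverges as $1/r$; the core pixel itself is
  undefined and masked.
* The in-plane rotation response is modelled as a pure
  $\cos(d+\varphi)$ modulation; full tensor-level rotational responses
  (and chiral tensor elements) are out of scope.
* Only azimuthal orders 0 and 1 are analysed; higher orders appear solely
  in the confidence metric.
* `fit_bands()` amplitudes on single noisy realisations carry the usual
  amplitude-width trade-off of overlapping Lorentzians; use averaged
  spectra (or the Monte-Carlo mean) for quantitative amplitude statements.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1,
                       grid = list(nx = 64, ny = 64),
                       scene = list(n_domains = 1L),
                       noise = list(sigma = 2e-3))
res <- run_pipeline(cfg)
report(res)
arrows <- arrow_map(res$director, block = 6)
contours <- phase_contours(res$director)
```
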