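---
title: "Methods: Monte Carlo optical sampling depth in the spatial frequency domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo optical sampling depth in the spatial frequency domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfddepth)
```

## The question the package answers

Spatial frequency domain (SFD) imaging measures diffuse reflectance under
sinusoidally patterned illumination at spatial frequency $f_x$ (mm$^{-1}$).
Different frequencies interrogate different tissue depths, so any
interpretation of an SFD measurement over layered or heterogeneous tissue
needs a quantitative answer to: *from which depths does the detected light
actually come?*

`sfddepth` answers this with a Monte Carlo simulation of photon-packet
transport that tallies each detected packet directly in the spatial
frequency domain. For each packet the tally is the complex random variable

$$\xi = W\,e^{-2\pi i f_x (x_f - x_0)},$$

where $W$ is the packet weight surviving to detection (discrete absorption
weighting), $x_0$ the surface entry point and $x_f$ the exit point along the
modulation axis. Averaging $\xi$ over all *launched* packets whose
trajectories crossed a horizontal "midway" surface at depth $z$ gives
$P_{V\cap D}(z)$, the joint probability that a packet visits depth $z$ and
is later detected. Its value at $z = 0$ is the diffuse reflectance
$R_d(f_x)$.

Because a packet that reached maximum depth $z_{\max}$ crossed every surface
above $z_{\max}$, the implementation tallies each packet **once**, in the
depth bin containing $z_{\max}$, and obtains $P_{V\cap D}$ as the reverse
cumulative sum of the binned distribution $P_{z\max}(z)$. This is
mathematically identical to scoring every crossed surface but costs O(1) per
packet; a stored-trajectory oracle test enforces the equivalence literally.

From $P_{z\max}$ follow the measurable summaries:
$R_d = \int_0^\infty P_{z\max}\,dz$, the depth-restricted reflectance
$P_{z\max}(z \le d) = \int_0^d P_{z\max}\,dz$, the detected-light fraction
$X(d) = P_{z\max}(z \le d)/R_d$, and the percentile sampling depths $d_X$
with $X(d_X) = X$ for $X \in \{0.10, 0.25, 0.50, 0.75, 0.90\}$.

## Transport model and its assumptions

* **Geometry.** Laterally infinite layered slab; the last layer is
  semi-infinite. Pencil beam at the origin, normal incidence. The oblique
  (15°) projection and finite collection NA of real SFD instruments are
  *not* modeled; every packet crossing the top surface is detected
  regardless of exit angle.
* **Scattering.** Henyey–Greenstein phase function with per-layer
  anisotropy $g$, uniform azimuth. The source work states only $g$; HG is
  the standard choice in this literature and is an assumption of this
  package.
* **Absorption.** Discrete absorption weighting: at each collision
  $W \leftarrow W \mu_s/(\mu_a+\mu_s)$; packets are only killed by Russian
  roulette (default threshold $10^{-4}$, survival probability 0.1,
  unbiased) or by leaving through the top surface.
* **Boundaries.** Unpolarized Fresnel reflection/refraction at the ambient
  interface and at internal index steps, sampled (not split); total internal
  reflection beyond the critical angle. After any boundary interaction the
  remaining optical path is re-drawn — exact for exponential free paths.
* **Specular light.** By default packets start just inside the medium with
  $W = 1$ and the normal-incidence specular reflection is excluded from
  $R_d$, mirroring the crossed-polarizer rejection of specular light in SFD
  instruments. `specular = "fresnel"` instead launches with
  $W = 1 - ((n - n_{amb})/(n + n_{amb}))^2$.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `dz` | 0.01 mm | depth-bin height of the $z_{\max}$ histogram |
| `z_cap` | 40 mm | deepest resolved bin; deeper packets land in an overflow bin that counts toward $R_d$ but makes fractions beyond the cap unattainable (a hard error tells you to raise `z_cap` rather than extrapolate) |
| `fx` | 0–0.3 mm$^{-1}$ in instrument steps | tallied frequencies; all are scored in one run |
| `roulette_threshold`, `roulette_survival` | $10^{-4}$, 0.1 | variance-reduction roulette; unbiased for any values in (0,1) |
| `max_steps` | $10^7$ | per-packet collision cap (below) |

### Numerical choices

* **Reported values are real parts.** The pencil-beam geometry is
  laterally symmetric, so $E[\xi]$ is real; the imaginary component is
  retained in the object with its own 1-σ array and checked against zero.
  Using the modulus instead would bias small values upward by the noise.
* **Per-packet RNG substreams.** Each packet uses an xoshiro256++ stream
  seeded from (seed, packet index), so identical configurations are
  bit-reproducible and a run can be partitioned across calls without
  changing any trajectory.
* **Collision cap.** In a non-absorbing medium the time for the depth
  random walk to return to the surface is heavy-tailed with infinite mean,
  so an uncapped energy-conservation run has unbounded expected runtime.
  Packets exceeding `max_steps` collisions (default $10^7$) are terminated
  and counted in `n_truncated`. At the default cap the truncated fraction
  in the worst case (the $\mu_a = 0$ conservation test) is about
  $2.5\times10^{-4}$; for any realistically absorbing medium it is zero.
  Consequently the energy-conservation test asserts $|R_d - 1| \le 10^{-3}$
  rather than a pure-noise band.
* **Percentile interpolation.** $d_X$ interpolates linearly inside the
  crossing bin; with `dz` = 0.01 mm the choice is sub-bin-level but fixing
  it makes results reproducible to the digit.
* **Two-layer phantom mode.** The extinguishing base defaults to
  $\mu_a = 100$ mm$^{-1}$, $\mu_s = 0$ (first collision kills) with its
  refractive index matched to the top layer, as in a water-based
  liquid-over-gel phantom; the source work does not state the simulated
  index and this is a documented assumption (n = 1.4 throughout).

## The dimensionless lookup table

Scale invariance of the transport equation means scaling $(\mu_a, \mu_s)$
by $k$ and lengths (including $1/f_x$) by $1/k$ leaves the problem
unchanged. The lookup table therefore stores only the dimensionless surface
$d_X/\ell^*$ on axes $(\mu_s'/\mu_a,\ f_x \ell^*)$ at fixed
$\ell^* = 1$ mm, $g = 0.8$, $n = 1.4$, with the 18-value ratio axis spanning
1–1000. A query for arbitrary $(\mu_a, \mu_s')$ computes
$\ell^* = 1/(\mu_a + \mu_s')$, interpolates the stored surface —
**monotone cubic along $f_x\ell^*$, linear in $\ln(\mu_s'/\mu_a)$** —
and rescales by $\ell^*$.

Design notes, made where the published account defers to unavailable
appendix material:

* log-ratio interpolation mirrors the roughly geometric spacing of the
  ratio axis; the $\le 7\%$ validation against direct simulation of eight
  real tissue presets adjudicates the scheme's adequacy.
* along the frequency axis the $d_{50}(f_x\ell^*)$ curve is strongly
  convex, and on the 6-point grid a linear chord overestimates mid-cell
  values by up to $\sim$8%, breaching the 7% bound; the frequency axis
  therefore uses a monotone (Fritsch–Carlson) cubic, which is node-exact,
  continuous and shape-preserving, bringing the worst tissue-validation
  error to about 6%.
* queries outside ratio $\in [1, 1000]$ or the tabulated $f_x\ell^*$ range
  are hard errors — no extrapolation.
* tissues whose $g$ and $n$ differ from the fixed table values rely on
  similarity scaling through $(\mu_a, \mu_s')$ alone; the validation
  quantifies the residual error of that approximation.
* the default `fxl` axis adds midpoints below 0.3, where the
  depth-frequency curve is steepest; the 6-point base grid
  $\{0, 0.05, 0.1, 0.2, 0.3, 0.5\}$ is what the accuracy checks use.

## What the tests do and do not establish

The test suite validates, at reduced packet counts ($10^5$–$10^6$ versus
$10^8$ in the source analysis, with bands widened by the published
rounding plus 3σ of the reduced run):

* closed-form kernels (HG inverse CDF, Fresnel, exponential steps) against
  hand-computed values and moment identities;
* exact conservation, monotonicity and transform-inverse identities of the
  tally;
* bit-level equivalence of the streaming $z_{\max}$ tally with a literal
  stored-trajectory midway-surface implementation (bit-identical where no
  trigonometry is involved; $10^{-12}$ relative otherwise, since R and C
  libm may differ in the last ulp);
* the headline reflectance and depth numbers of the reference medium
  ($\mu_s'/\mu_a = 100$, $\ell^* = 1$ mm), the two-layer phantom twin, the
  eight tissue sweeps, and the lookup-table accuracy bound.

The simulations *are* the model: a green suite establishes internal
consistency and agreement with the published Monte Carlo values, not
agreement with any physical measurement beyond the phantom numbers quoted
from the source experiment. Features of real measurements that are
deliberately out of scope: projector/camera optics, demodulation,
calibration referencing, finite beams, oblique incidence, polarization,
time-resolved transport, and voxelized (non-layered) heterogeneity.

## Known limitations

* Depth distributions bin the *maximum* depth of visitation; they are not
  pathlength-weighted sensitivity maps ("photon hitting density") and do
  not map directly onto absorption sensitivity.
* The $f_x = 0.5$ mm$^{-1}$, $z = 20$ mm tail of $P_{V\cap D}$
  ($\sim 10^{-7}$) needs far more than $10^7$ packets to resolve; desk-scale
  runs resolve the $f_x = 0$ tail ($\sim 5\times10^{-4}$) only.
* Lookup-table accuracy is validated for the eight embedded tissue presets
  ($g \in [0.84, 0.97]$, $n \in [1.40, 1.47]$); media far outside that range
  fall back on the similarity approximation untested.
```{r}
sessionInfo()
```
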