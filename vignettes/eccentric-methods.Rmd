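---
title: "Random eccentric-circle MRSI: trajectory design, simulation and low-rank reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random eccentric-circle MRSI: trajectory design, simulation and low-rank reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the sampling
geometry, the signal model behind the simulator, the inverse problem the
reconstruction solves, and the numerical choices made where the design was
genuinely open. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## 1. Spatial-spectral encoding with random eccentric circles

Spatial-spectral MRSI reads k-space repeatedly during the free induction
decay (FID), so that each excitation encodes both spatial frequencies and
the spectral time axis. This package's trajectory family consists of small
circles of radius $R$ (cycles/m) whose centers $(r_c, \phi_c)$ are drawn
with uniform probability over $r_c \in [0, \max(k_{max}-R, R)]$ and
$\phi_c \in [0, 2\pi)$, on the centered even-$n$ grid with Nyquist distance
$\Delta k = 1/\mathrm{FoV}$ and $k_{max} = n/(2\,\mathrm{FoV})$. One circle
revolution takes one spectral dwell, so the spectral bandwidth equals the
revolution frequency and every revolution revisits the same $m =
\lceil 2\pi R\,\mathrm{FoV}\rceil$ k-space points (Nyquist spacing along
the circumference). All $m$ points of revolution $\tau$ share the time
stamp $t_\tau = \tau/\mathrm{sbw}$; intra-revolution time skew is ignored,
which keeps the encoding separable in (sample, time).

Three rules complete the design:

* **Count.** Full sampling of one partition needs
  $N = \lceil \pi n k_{max} / (2R) \rceil$ circles (202 for $n=64$,
  $R=k_{max}/2$; the rosette special case $R = k_{max}$ gives
  $\lceil \pi n/2\rceil = 101$). Acceleration by AF keeps
  $\max(1, \mathrm{round}(N/\mathrm{AF}))$ circles.
* **Overlap rule.** Consecutive circle centers must be at least
  $\Delta k$ apart. We enforce it between consecutive circles only
  (candidates are redrawn up to 1000 times, then a placement error names
  the offending index); all-pairs enforcement would be far more
  restrictive than the stated constraint and is not used.
* **Rosette core.** A leading subset of
  $\lceil 0.04\,N \rceil$ circles (under the 5% bound) is placed
  deterministically in rosette fashion ($r_c = R$, uniformly spaced
  azimuths), so each passes through the k-space origin and the center of
  k-space is always fully sampled.

The uniform polar draw makes the sampling density fall off as
$1/\lVert k\rVert$ outside the rosette-covered core. The property suite
verifies this by Monte-Carlo: $10^5$ random centers at $R=k_{max}/8$,
binned into annuli over $[2R,\ r_{max}-R]$, match the $1/\lVert k\rVert$
curve within 10% per annulus. The band matters: within $R$ of either end
the density deviates by construction (the core is deliberately
oversampled; near the outer rim fewer circles reach), and at $R=k_{max}/4$
the valid band is empty, so the law is only tested where it can hold.

For 3D, planes are stacked along $k_z$ with either constant in-plane
extent (cylinder) or
$k_{max}(k_z) = k_{max}\sqrt{1 - (k_z/k_z^{max})^2}$ (ellipsoid),
$k_z^{max} = (n_z/2+1)\Delta k_z$. Each partition uses the effective
matrix size $n(k_z) = \mathrm{round}(2\,\mathrm{FoV}\,k_{max}(k_z))$ in
the count formula and its own RNG substream derived from the master seed,
so partitions are order-independent. In the limit $n_z \to \infty$ the
ellipsoid-over-cylinder circle-count ratio approaches the reciprocal of
the mean of $1-z^2$ on $[-1,1]$, i.e. $3/2$; the discrete ratio is within
2% of 1.5 by $n_z = 257$. If $R$ exceeds half a partition's extent it is
clamped to $k_{max}(k_z)/2$ — keeping every sample inside the partition
disc — and the plan records a warning.

Because a circle is traversed at constant angular rate
$\omega = 2\pi\,\mathrm{sbw}$, the gradient amplitude $R\omega/\bar\gamma$
and slew rate $R\omega^2/\bar\gamma$ are constant in time. The inverse
relation `max_sbw()` gives the largest bandwidth under amplitude and slew
limits.

## 2. Density compensation and point spread functions

Adjoint (gridding) reconstructions weight each sample by the area of its
Voronoi cell, clipped to the disc of radius $k_{max}+\Delta k/2$. No
computational-geometry library is available to this package, so cell areas
are computed by discrete nearest-sample labeling of a raster oversampled
8-fold relative to $\Delta k$: exact for the partition property (the
weights tile the rasterized disc area by construction, and the
renormalization step keeps that exact even when a starved sub-pixel group
is floored at half a pixel), and accurate to a few percent per cell, which
is ample for density compensation. Coincident samples are grouped and
split their cell equally.

The PSF of a plan is the density-compensated adjoint response to a unit
point source at the k-space origin, normalized to a unit real peak. Two
scalar metrics summarize aliasing: the maximum $|PSF|$ outside a 3-pixel
mainlobe exclusion disc, and the energy fraction outside that disc. The
suite checks the PSF against a brute-force double loop on a 16-point grid
(machine precision), that full Cartesian sampling yields a discrete delta,
and the comparative behaviour that motivates random placement: sidelobes
grow with AF, and concentric-ring undersampling produces a higher coherent
peak sidelobe than eccentric sampling at the same AF.

## 3. The digital phantom and the forward model

`build_derenzo()` rasterizes a resolution phantom: five angular sets of
six tubes (diameters 2–10 mm, center spacing twice the diameter,
triangular layout, apex toward the center at radius $8\,\mathrm{mm} + d$),
in a 133.3 mm saline bath. Geometry that cannot fit raises an error naming
the offending set. Rasterization uses 4x4 sub-pixel area sampling; at 1 mm
resolution each 10 mm tube's area is within 5% of $\pi r^2$. Tubes carry
10 mM creatine; the water-amplitude map is raised inside the tubes to the
gradient-echo steady-state ratio $(1-E_1)/(1-\cos\alpha\,E_1) \approx 5$
for Gd-shortened $T_1 \approx 0.25$ s against $\approx 3$ s saline at
TR 100 ms and a 40° flip angle — the T1-weighted water-imaging contrast —
rather than from a Bloch simulation; saturation and flip-angle effects are
folded into `water_amp_map`.

`build_brain_scene()` provides an elliptical head with a subcutaneous
lipid annulus separated from the brain ellipse by a CSF/skull gap of about
one voxel (masks sharing an edge would put lipid bleed directly into
cortical voxels, which no real head does) and smooth, spatially structured
NAA / total-creatine / choline maps; B0 is a second-order polynomial with ±30 Hz peak offset
(consistent with the few-tens-of-Hz global water linewidths of a shimmed
head) and coils are eight Gaussian-profile sensitivities with smoothly
varying phase.

The voxel signal is a Lorentzian mixture,
$s(t) = \sum_m c_m \sum_j a_{mj}\,
e^{i2\pi(f_{mj}+\Delta f)t}\,e^{-t(1/T_2^* + d_m)}$, with shifts
referenced so water (4.7 ppm) sits at 0 Hz (297.2 Hz/ppm at 7 T) and a
per-metabolite extra damping $d_m$ (10 ms lipid) for broad resonances. The
synthetic basis (water, NAA 2.01 ppm, creatine 3.03 + 3.91 ppm, choline
3.2 ppm, lipid 1.3 ppm) is deliberately small; quantum-mechanical basis
simulation is out of scope. The encoder evaluates
$s_{c,j,\tau} = \sum_i C_c(r_i)\, e^{i2\pi \Delta B_0(r_i) t_\tau}\,
e^{i2\pi k_j\cdot r_i}\, \rho(r_i,t_\tau) + \varepsilon$ exactly —
the non-uniform Fourier sum is computed by a separable-phase BLAS product,
not an approximate NUFFT, so operator tests hold to machine precision —
with i.i.d. complex Gaussian noise of std `noise_sigma`
($\mathbb{E}|\varepsilon|^2 = \sigma^2$), independent across coils.

## 4. Preprocessing

* **HSVD water removal** builds the
  $\lceil T/2\rceil \times (T - \lceil T/2\rceil + 1)$ Hankel matrix,
  truncates to `model_order` (default 25) singular triplets, recovers
  poles by the state-space shift eigenproblem, refits all amplitudes by
  complex least squares, and subtracts components inside the ±60 Hz water
  band. Band and order are configuration, not physics; the defaults are
  this package's choices.
* **B0 estimation** is a weighted phase-slope fit on inter-frame products
  $y_{t+1}\bar y_t$ (coherently combined across coils) — a deliberately
  simple stand-in for parametric spectral estimators; offsets within 10%
  of the aliasing limit $\pm\mathrm{sbw}/2$ are flagged wrap-ambiguous.
* **Coil maps** are smoothed coil images divided by their smoothed
  root-sum-of-squares, exactly RSS-normalized inside the support mask — a
  stand-in for subspace calibration methods; externally supplied maps are
  accepted everywhere.
* **Backward linear prediction** fits backward LP coefficients on the
  early FID and prepends the samples lost to the echo time, removing
  first-order spectral phase. Prediction-polynomial roots outside the unit
  circle are reflected inside (with a warning); a decaying physical
  component has its pole inside the circle and is extrapolated exactly.

## 5. The reconstruction

The solver addresses

$$\min_{U,V,L}\ \lVert W\big(s - \mathcal{F} C B (UV + L)\big)\rVert_2^2
  \;+\; \lambda \sum_{k=1}^{K} \mathrm{TGV}^2\{U_k\},$$

with $U \in \mathbb{C}^{N_r\times K}$ spatial and $V \in
\mathbb{C}^{K\times T}$ temporal components (rank-$K$ partial
separability), $L$ a lipid term supported on the skull mask, $C$ coil
sensitivities, $B = e^{i2\pi t\,\Delta B_0}$ evaluated exactly per time
point, and $W$ the Hamming-shaped residual weighting
$w(k) = 0.54 + 0.46\cos(\pi \lVert k\rVert / k_{max})$ (1 at the center,
0.08 at the edge), entering the gradients as $w^2$ (the standard
weighted-least-squares reading).

Numerical choices, all of them this package's own:

* **Scaling.** Data are normalized so the density-compensated adjoint
  series has unit maximum magnitude (restored on output), and the data
  term is divided by the spectral norm of $A^H W^2 A$ (power iteration,
  fixed seed). With that normalization the proximal step is $1/2$ and
  $\lambda$ weighs TGV against a scale-free data term: sampling-operator
  modes whose normalized eigenvalue falls below roughly $\lambda$ are
  governed by the regularizer — exactly the noise-amplified tail. The
  default $\lambda = 3\times10^{-4}$; for the high-SNR water-phantom
  acceleration experiment $\lambda$ was calibrated once by increasing it
  from a low value until noise-like artifacts in the fully sampled
  reconstruction disappeared, judged on the AF = 1 image alone.
* **Block schedule** (the reference pseudocode is unavailable; this
  schedule is a re-derivation): initialize $(U,V)$ from the rank-$K$ SVD
  of the B0-conjugate density-compensated adjoint; then alternate (i) $V$
  by exact weighted least squares — without B0 the encoding factors
  through $\mathcal{F}CU$, so the normal matrix is a shared $K\times K$
  system; with B0, matrix-free conjugate gradient — followed by
  re-orthonormalization of $V$'s rows (complex QR pivots are folded back
  into $U$); (ii) $U$ by monotone FISTA whose data gradient has the lipid
  temporal subspace projected out and whose prox is the per-component
  TGV$^2$ denoiser; (iii) $L$ by up to three monotone gradient steps on
  the lipid mask, each followed by temporal rank truncation (rank 8), and
  a refresh of the lipid projection basis. $L$ is initialized from the
  adjoint series restricted to the lipid mask so the dominant skull signal
  is explained by $L$ from the start, and the projection basis keeps only
  singular vectors with $\sigma_i \ge 0.05\,\sigma_1$ — lipid-dominated
  temporal behaviour — so metabolite leakage in the skull estimate cannot
  enter the projector and be removed from the metabolite updates.
* **Degenerate regularization.** When $\lambda \cdot \mathrm{step}$ falls
  below the numerical resolution of the 20-iteration primal-dual prox, the
  prox is the identity and the $U$ subproblem is solved by preconditioned
  conjugate gradient instead; the preconditioner is the inverse Fourier
  multiplier of the Cartesian-binned $w^2$ sample density wrapped in the
  inverse coil RSS, with unsampled cells floored so null-space modes (the
  never-sampled k-space corners outside the disc) are not amplified.
* **TGV$^2$** treats real and imaginary parts as a coupled field with
  shared pointwise magnitude, $\alpha_0/\alpha_1 = 2$, forward differences
  with exact adjoints, Chambolle–Pock steps $\tau=\sigma=1/\sqrt{12}$. The
  penalty value needed for the objective trace is computed by a separate
  fixed-iteration minimization over the auxiliary field, so the trace is
  deterministic.
* **Monotonicity.** Every block either exactly minimizes its subproblem or
  carries an accept-if-better safeguard, so the objective trace is
  non-increasing (within 0.1% once past the first iteration, which absorbs
  the SVD initialization); an increase beyond 5% aborts with diagnostics.

The rank-$K$ structure of the output is exact by construction
($\rho = UV$), and $L$ is exactly zero off the lipid mask.

## 6. Quantification and metrics

Metabolite maps come from per-voxel real-nonnegative linear least squares
against the basis FIDs evaluated on the same time grid (a deliberately
linear stand-in for full spectral fitting), referenced to a water
amplitude for institutional units with scale constant 1 — only ratios are
meaningful. SSIM uses a Gaussian window ($\sigma = 1.5$ px) and the
standard stabilization constants $K_1=0.01$, $K_2=0.03$, with the
reference image defining the dynamic range; spectral SNR is peak magnitude
in a signal band over the real-part std of a disjoint noise band; FWHM is
interpolated at half maximum; COV is the across-repetition std (ddof 1) of
region means over their mean.

## 7. Study conditions and problem sizes

The shipped experiments run at desk scale, chosen once:

* *Water-phantom acceleration* (the headline experiment): 64x64 Derenzo
  water scene, 8 coils, fully sampled 2D plan at $R = n/(8\,\mathrm{FoV})$
  (403 circles), one time point, complex noise set so the
  density-compensated water image has SNR ≈ 100 ("high SNR"), retrospective
  AF = 4 subset that always retains the rosette core. Reconstruction uses
  the $K=1$ single-timepoint path.
* *Exact recovery*: 32x32, $T=64$, rank-3 phantom with spectrally
  concentrated (smooth) spatial components — circular coverage never
  samples the Cartesian corner frequencies, so sharp-edged components
  retain irreducible corner energy and no solver could recover them to
  <1%; the test phantom therefore lives inside the sampled disc, which is
  the physically meaningful regime.
* *Brain-like metabolite recovery*: 24x24, $T=96$ at 2280 Hz, 8 coils,
  ±30 Hz B0, lipid ring, water-suppressed encoding at AF = 2 with noise at
  single-voxel metabolite SNR of order 10, coil and B0 maps estimated from
  a simulated water-reference scan.

What passing these tests shows — and does not. The simulator shares its
Fourier/coil/B0 operators with the reconstruction (an inverse-crime
setting), uses Lorentzian lineshapes, a 5-entry basis, no macromolecular
baseline, no motion, drift, eddy currents or chemical-shift displacement.
Passing therefore validates the geometry, the operators, the solver and
the pipeline plumbing, not in vivo performance; in vivo concentration
tables, CRLB-based quality filters and regional statistics are explicitly
out of scope.

## 8. Known limitations

* 2D (single-partition) reconstruction only; stacks are designed and
  counted in 3D but the solver treats one partition at a time.
* The discrete Voronoi estimator has a few-percent per-cell error;
  applications needing exact cell areas should supply their own weights.
* The CG fast path requires the B0-free factorization; with a field map
  the solver falls back to dense per-time evaluation, which is the main
  cost driver at larger $T$.
* `lsqnonneg`-based fitting is per-voxel and O(voxels); it is intended for
  the desk-scale grids used here.
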