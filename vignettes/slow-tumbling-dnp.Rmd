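---
title: "Slow-motional EPR and solid-effect DNP of tumbling radicals: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-motional EPR and solid-effect DNP of tumbling radicals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sednp)
```

## The problem

Dynamic nuclear polarization (DNP) in viscous liquids at high magnetic
field mixes two mechanisms. The Overhauser effect (OE) requires saturation
of the allowed electronic transition and motional modulation of the
electron–nucleus coupling; its enhancement profile follows the
power-broadened electronic saturation factor $s(\Delta)$. The solid effect
(SE) is driven directly by microwaves at offsets near $\pm\omega_I$ (for
protons at 9.4 T, $\pm 400$ MHz) and survives in liquids only when
translational diffusion is too slow to average the dipolar coupling within
the electronic $T_2$. Under those viscous conditions the tumbling of a
nitroxide-type polarizing agent is also slow, so its anisotropic $g$
tensor broadens the EPR line well beyond a Lorentzian.

This package computes both ingredients from first principles and uses them
to decompose measured DNP spectra:

1. cw-EPR line shapes (absorption, dispersion, saturation, derivative
   mode) for isotropic rotational diffusion with an anisotropic $g$
   tensor, via a stochastic-Liouville expansion;
2. the SE rate constants $v_+(\Delta)$ and $p v_-(\Delta)$ for a static
   ("solid") or translationally modulated (liquid, FFHS) dipolar coupling
   under the same slow tumbling;
3. least-squares fits of derivative EPR spectra and DNP enhancement
   profiles, and the chain from the fitted amplitudes to molecular
   parameters (coupling factor, contact distance, diffusion coefficient).

## Spin dynamics

The electronic magnetization obeys the rotating-frame Bloch equations with
relaxation rates $R_1 = 1/T_{1e}$, $R_2 = 1/T_{2e}$, nutation frequency
$\omega_1$ and offset $\Delta$. The steady state is algebraic:
$P_0 = R_2 + \omega_1^2 T_1 + \Delta^2 T_2$, absorption
$\mathrm{abs} = -\omega_1/P_0$, and saturation
$s = -\omega_1 T_1\,\mathrm{abs}$ — exactly proportional to the absorption
at every power.

For the solid effect, the electron–nucleus coherences evolve under the
same Bloch matrix shifted by $i\omega_I$ on its diagonal. Solving their
steady state gives closed forms for the microwave-driven nuclear
relaxation rate $v_+$ (even in $\Delta$) and the polarization-transfer
rate $p v_-$ (odd in $\Delta$ for a symmetric line). In liquids the
inverse of the shifted Bloch matrix $B$ is replaced by the matrix spectral
density $Q = j_{11}(B)$, evaluated through the eigendecomposition
$B U = U \Lambda$, $Q = U\,\mathrm{diag}(j_{11}(\lambda_n))\,U^{-1}$.

The translational model is the force-free hard-sphere (FFHS) spectral
density
$$ j_{11}(z) = \tau\,\frac{(z\tau)^{1/2} + 4}
   {(z\tau)^{3/2} + 4 z\tau + 9 (z\tau)^{1/2} + 9}, \qquad
   \tau = b^2 / D_\mathrm{trans}, $$
with contact distance $b$ and relative diffusion coefficient
$D_\mathrm{trans}$. Its overall scale is carried separately by
$\langle\delta^2\rangle = D_\mathrm{dip}^2\,(6\pi/5)\,N/(3 b^3)$ with the
electron number density $N$; all line-shape information lives in the
reduced $j_{11}$.

## Slow tumbling

Orientation-dependent spin observables are expanded in Wigner rotation
functions $D^L_{M0}$. For isotropic rotational diffusion and a secular
$g$-tensor Hamiltonian, only even $L \le L_\mathrm{max}$ and even
$0 \le M \le L$ couple to the detected orientational average, giving
$n_\mathrm{tot} = L_\mathrm{max}^2/8 + 3L_\mathrm{max}/4 + 1$
coefficients. Every scalar of the Bloch equations becomes an
$n_\mathrm{tot}\times n_\mathrm{tot}$ block: relaxation and identity
blocks stay diagonal (with the rotational eigenvalues $D_\mathrm{rot}
L(L+1)$ added), and only the offset block
$\Delta E + \gamma_0^2 C_0 + \gamma_2^2 C_2$ mixes $(L, M)$.

The coupling matrices $C_0$ and $C_2$ are products of Clebsch–Gordan
coefficients. In the symmetrized basis ($M \ge 0$, the $\pm M$ pair
averaged), rows with $M = 0$ acquire a factor 2 on the surviving rank-2
term because both mirror contributions land on the same coefficient. The
test suite verifies both matrices against an independent numerical
quadrature of the underlying triple-Wigner integrals at
$L_\mathrm{max} = 10$.

The EPR spectrum needs only one $n_\mathrm{tot}\times n_\mathrm{tot}$
inversion per offset (of the matrix generalization of $P_0$); a dense
$3n_\mathrm{tot}$ solve is retained as a cross-check mode. The derivative
spectrum uses the analytic derivative
$\partial P_0/\partial\Delta = R_2^{-1}\Delta + \Delta R_2^{-1}$, never
finite differences, and admixes the dispersive derivative through a mixing
angle $\phi$. For the SE rates in liquids the full
$3n_\mathrm{tot}\times 3n_\mathrm{tot}$ coherence matrix is
eigendecomposed per offset — with $L_\mathrm{max} = 10$ a $63\times 63$
complex problem, fast enough for fitting.

## Parameters that matter

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| $B_0$ | static field | T | 9.403 | high-field regime where $g$ anisotropy dominates |
| $B_1$ | rotating-frame mw amplitude | G | 0.02 (EPR), 5.5 (DNP) | low-power detection vs saturating DNP drive |
| $T_{1e}$, $T_{2e}$ | electronic relaxation | ns | 100–123, 20 | $T_{1e}$ controls power broadening; $T_{2e}$ the homogeneous width |
| $\gamma_0^2, \gamma_2^2$ | secular $g$ anisotropies | MHz | −373, 107 | nitroxide tensor diag(2.00755, 2.00555, 2.0023) at 9.403 T |
| $\tau_\mathrm{rot}$ | rank-2 tumbling time $1/(6D_\mathrm{rot})$ | ns | 5.2 | lipid-attached nitroxide in a fluid bilayer |
| $\tau_\mathrm{ffhs}$ | translational timescale $b^2/D$ | ns | 6.4 | lateral lipid diffusion scale |
| $L_\mathrm{max}$ | SLE truncation | — | 10 | converged for the tumbling range of interest (below) |
| $\omega_I$ | nuclear Larmor frequency | rad/s | $\gamma_H B_0$ | sets SE offsets $\pm 400$ MHz at 9.4 T |

$B_1$ values are interpreted as calibrated rotating-frame amplitudes
($\omega_1 = g_0\mu_B B_1/\hbar$, no factor $1/2$); an uncalibrated linear
drive would only rescale the fitted amplitudes. The tumbling-time
convention is the standard rank-2 one, $\tau_\mathrm{rot} =
1/(6D_\mathrm{rot})$. Thermal equilibrium magnetization is never
materialized: every output is a ratio relative to it.

## The DNP decomposition

A mixed DNP spectrum is modeled as
$$ \epsilon(\Delta) = -\sigma_\mathrm{OE}\, s(\Delta - \Delta_0)
   + \sigma_\mathrm{SE}\, \frac{p v_-}{\langle\delta^2\rangle}
     (\Delta - \Delta_0). $$
The OE term carries an explicit minus sign — the dipolar coupling makes
the OE enhancement negative for protons — so that the stored
$\sigma_\mathrm{OE}$ is a positive magnitude; with this convention the
computed profile has its negative OE dip near zero offset and a positive
SE peak near $+\omega_I$, matching the observed phenomenology. The SE
amplitude $\sigma_\mathrm{SE}$ (units 1/time) multiplies the transfer
timescale $p v_-/\langle\delta^2\rangle$, which is of order 1 ps. The
multiplicative enhancement form is used throughout; its validity condition
$v_+ T_{1I} \ll 1$ is checked by the tests at the measured coupling scale
(`enhancement_from_rates()` reports the product for any caller).

Fitting proceeds in the order used for the experiments: first the
derivative cw-EPR spectrum determines $(\gamma_0^2, \gamma_2^2,
\tau_\mathrm{rot}, \phi)$ at low power with $T_{1e}$, $T_{2e}$ pinned;
then the DNP profile determines $(\tau_\mathrm{ffhs}, T_{1e},
\sigma_\mathrm{OE}, \sigma_\mathrm{SE})$ with the $g$ tensor and tumbling
time carried over. Both fits allow a free horizontal shift (bounded at
$\pm 100$ MHz) because the absolute field at the sample is not known
precisely.

Numerically, the fits use Levenberg–Marquardt with box bounds
($\tau > 0$ via log-parameterization, $|\phi| \le 15^\circ$) and a small
log-spaced multi-start over the time constants, because the landscape can
be rugged. The linear amplitudes — the EPR scale and both DNP $\sigma$'s —
are profiled out by exact linear least squares at every iteration
(variable projection). This removes three directions from the nonlinear
search and makes the EPR fit exactly invariant to rescaling of the data;
the profiled values are reported as ordinary fitted parameters. The loss
is the unweighted sum of squares.

## From amplitudes to molecular parameters

Because the model computes $s$ and $p v_-/\langle\delta^2\rangle$ on
absolute scales, the fitted amplitudes are physically interpretable:
$c = (\sigma_\mathrm{OE}/f)\,\gamma_I/|\gamma_S|$ with the leakage factor
$f = 1 - T_{1I}/T_{1I}^0$;
$\langle\delta^2\rangle T_{1I} = \sigma_\mathrm{SE}\,\gamma_I/|\gamma_S|$;
inverting the $\langle\delta^2\rangle$ expression gives the contact
distance $b$, and $D = b^2/\tau_\mathrm{ffhs}$ the diffusion coefficient.
`derive_molecular_params()` runs the whole chain;
`scripts/acceptance.R` reproduces it from the measured relaxation times
and fitted amplitudes. The chain reports unrounded intermediate values;
for one of the published rows the final diffusion coefficient differs by
about one unit in the last digit from a version computed with rounded
intermediates, which is why no intermediate rounding is applied here.

## Numerical choices

* **Truncation.** $L_\mathrm{max} = 10$ is the working default. At the
  fitted tumbling times (2–5 ns) the $L_\mathrm{max} = 8$ and 10 spectra
  agree to a fraction of a percent of the peak; the difference grows to
  about 1.7 % of peak at $\tau_\mathrm{rot} = 10$ ns, so for slower
  tumbling a larger basis should be chosen. Convergence should always be
  checked by increasing $L_\mathrm{max}$ at the slowest tumbling time of
  interest.
* **Matrix functions.** $Q = j_{11}(B)$ uses the eigendecomposition of the
  non-normal complex matrix $B$. If the eigenvector matrix has condition
  number above $10^8$ the offset is perturbed by one part in $10^8$ and
  the decomposition retried once; exact degeneracies sit on measure-zero
  parameter sets. Eigenvalues with slightly negative real parts from
  roundoff are clipped to the imaginary axis; genuinely negative real
  parts raise an unstable-dynamics error.
* **Branch.** $(z\tau)^{1/2}$ in the FFHS density uses the principal
  branch; eigenvalues of a relaxation matrix have nonnegative real parts,
  so no cut is crossed.
* **Line-shape comparisons.** EPR amplitudes are arbitrary, so
  convergence and narrowing statements in the tests compare unit-peak
  normalized shapes where a scale is not physically fixed. In the
  motional-narrowing limit the residual motional width
  ($\sim\gamma^2\tau_\mathrm{rot}$) is an amplitude effect of a few
  percent at 1 ps while the normalized shape deviation is half that.
* **Degenerate inputs.** $L_\mathrm{max} = 0$ reduces every routine to
  the homogeneous-line formulas exactly (machine precision), and
  $j_{11}(z) = 1/z$ reduces every liquid routine to the static-coupling
  one; both reductions are exercised by the tests as oracle surfaces.

## The synthetic-data generator

`make_fixtures()` generates the two spectra a real study would measure: a
derivative cw-EPR spectrum at $B_1 = 0.02$ G with Gaussian noise of 1 % of
peak, and a DNP enhancement profile at $B_1 = 5.5$ G with noise of 0.2
enhancement units, both on a $\pm 700$ MHz grid with 2 MHz steps. The
ground truth defaults to the fitted values of the 10-position spin-labeled
lipid (anisotropies (−373, 107) MHz, $\tau_\mathrm{rot} = 5.2$ ns, $\phi =
-1.3^\circ$, $\tau_\mathrm{ffhs} = 6.4$ ns, $T_{1e} = 123$ ns,
$\sigma_\mathrm{OE} = 2.43$, $\sigma_\mathrm{SE} = 1.51\,\mathrm{ps}^{-1}$),
and the noise scales match the scatter visible in such measurements. The
generator emulates additive, independent Gaussian noise on an exact
forward-model spectrum; it does **not** emulate baseline drift, field
inhomogeneity, hyperfine structure, orientational ordering (bilayer
director potentials) or correlated drift between scans. Passing recovery
tests therefore demonstrate that the estimator is consistent and
well-conditioned under the stated noise, not that real spectra are free of
model error.

Parameter-recovery studies in the test suite generate and fit with the
same truncation order (self-consistency), using $L_\mathrm{max} = 6$ on
coarse grids for noiseless checks and $L_\mathrm{max} = 4$ on the full 2
MHz grid for the 20-seed noisy studies; these sizes are stated here as the
package's chosen test problem sizes.

## Known limitations

* The hyperfine tensor of the nitroxide nitrogen is neglected; the
  treatment targets high field, where $g$-tensor broadening dominates. At
  lower fields the basis would need a nine-fold larger spin dimension.
* Rotational diffusion is free and isotropic. Ordered media (lipid
  bilayers) would call for an anisotropic diffusion tensor in an orienting
  potential, which enlarges the basis (odd $M$, nonzero $N$) but leaves
  the block structure intact.
* Translational diffusion is isotropic and unconfined (FFHS); the fitted
  $b$ is an effective parameter, not a literal distance of closest
  approach.
* Only steady states are computed; no polarization build-up dynamics.
* The zero- and double-quantum rates are never needed separately: only
  the combinations $v_+$ and $p v_-$ enter the observable enhancement,
  and only those are computed.
* Fit uncertainties are reported as residual norms only; no bootstrap or
  profile likelihood.

## A worked example

```{r example, eval = FALSE}
# forward-simulate the study conditions, then fit the synthetic data back
paths <- make_fixtures(tempfile("fix"), seed = 1)
epr <- read_spectrum(paths$epr)
fit1 <- fit_epr(epr, B0 = 9.403)
dnp <- read_spectrum(paths$dnp, kind = "dnp_enhancement")
fit2 <- fit_dnp(dnp, B0 = 9.403,
                gamma02 = fit1$params$gamma02,
                gamma22 = fit1$params$gamma22,
                tau_rot = fit1$params$tau_rot)
derive_molecular_params(fit2$params$sigma_OE, fit2$params$sigma_SE * 1e12,
                        fit2$params$tau_ffhs * 1e-9,
                        T1I = 44e-3, T1I0 = 580e-3, N = 1 / 26)
```
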