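---
title: "Models and methods behind vesana"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vesana}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesana)
```

# What the package computes

`vesana` implements the complete analysis chain used in temperature-dependent
studies of small unilamellar lipid vesicles (SUVs) interacting with
membrane-active additives — here a DMPC matrix carrying the NSAID naproxen
(10 mol%) and the saponin beta-aescin (0–1 mol%):

* **DSC**: the main phase-transition temperature $T_m$ of the bilayer, from
  Lorentzian peak fits to heat-flow thermograms; a second, broader peak below
  $T_m$ marks aescin-rich domains.
* **WAXS**: the lateral chain–chain correlation distance
  $d_\mathrm{WAXS} = 2\pi/q_\mathrm{peak}$ of the acyl chains, from a
  Lorentzian fit of the wide-angle chain-packing peak.
* **SAXS, model-independent**: the pair-distance distribution function $p(r)$
  and radius of gyration $R_G$ by indirect Fourier transformation (IFT), and
  the membrane thickness $d_m = 2\pi/q_\mathrm{max}$ by the modified
  Kratky–Porod (MKP) construction on $I(q)\,q^4$.
* **SAXS, above $T_m$**: the lamellar repeat distance
  $d_\mathrm{lam} = 2\pi/q_1$ of correlated bilayers, confirmed by the
  second-order position $q_2 \approx 2 q_1$.
* **PCS/DLS**: the hydrodynamic radius $R_H$ via regularized inverse-Laplace
  inversion of multi-angle intensity correlograms, a diffusion fit
  $\Gamma = D_T q^2$, and the Stokes–Einstein relation
  $R_H = k_B T / (6 \pi \eta D_T)$.

Because no raw data of the original study are deposited, the package also
contains a first-class synthetic-data module whose presets encode the study's
compositions and headline numbers as *executable* conditions: the acceptance
checks regenerate data from the presets and push them through the full chain.

# Composition bookkeeping

The molar fraction of an additive is
$w = n_\mathrm{additive} / (n_\mathrm{DMPC} + n_\mathrm{naproxen} +
n_\mathrm{aescin})$. The seven presets cover pure DMPC and a naproxen series
with aescin at 0, 0.2, 0.4, 0.6, 0.8 and 1.0 mol%:

```{r}
list_presets()[, c("name", "n_dmpc", "n_naproxen", "n_aescin", "tm_main",
                   "dm_nominal", "rh")]
```

# The synthetic-data generators

## SAXS: polydisperse vesicle shells

The radial excess scattering-length density of a vesicle is a sum of Gaussian
strips placed on the shell: positive head-group strips at $\pm d_{hh}/2$ from
the bilayer mid-plane flanking a negative hydrocarbon strip — the head/tail
contrast a phosphatidylcholine bilayer presents to X-rays. The amplitude is
the spherically symmetric transform
$F(q) = 4\pi \int \rho(r)\, r^2\, \mathrm{sinc}(qr)\, dr$, evaluated by
trapezoidal quadrature on a 4096-point radial grid (a grid-doubling check
changes the curve by well under 0.1 %). Radii follow a Schulz distribution
(51-node Gauss–Legendre quadrature over $\pm 5\sigma$), the standard
polydispersity model in small-angle scattering; the default relative width of
0.10 reproduces visible low-q oscillations, as extruded vesicle preparations
show. Above $T_m$ the shell contrast and scale collapse (chain melting
reduces the electron-density difference) and, for additive-containing
samples, additive Lorentzian peaks at $q_1$ and exactly $2q_1$ emulate the
lamellar correlation signal. A paracrystal or Caillé lineshape is deliberately
out of scope: only peak positions and the 2:1 position ratio are analyzed.

The head-group separation $d_{hh}$ is **not** a free number: at preset
construction it is calibrated by a one-dimensional root search so that the
MKP pipeline applied to the noise-free 10 °C curve returns the preset's
nominal thickness (34.72 Å for pure DMPC; the seven nominal values average
34.67 Å). The headline numbers are thereby produced by the analysis chain at
run time, never stored as results. The calibration is cached per session.

## WAXS, DSC, DLS

* WAXS curves are a Lorentzian chain-packing peak on a flat background. In
  the ordered gel phase the peak is sharp near 1.50 Å$^{-1}$ and drifts
  slightly with temperature; in the fluid phase it is broad and sits at lower
  $q$, moving back toward higher $q$ as additives compress the chains. These
  positions are plausible chain-packing values, not fixtures — the source
  study prints no numeric $d_\mathrm{WAXS}$.
* DSC thermograms are sums of Lorentzians on a linear instrumental baseline;
  from 0.6 mol% aescin a broad second peak below $T_m$ encodes the
  aescin-rich domains.
* DLS correlograms follow the Siegert relation
  $g_2(\tau) = 1 + \beta\,(\sum_i w_i e^{-D_i q^2 \tau})^2$ with $q$ from the
  optical geometry (632.8 nm HeNe, $n = 1.332$, 40–110° in 5° steps), $D_i$
  from Stokes–Einstein at the sample temperature, $\beta = 0.8$, and
  additive Gaussian noise on $g_2$. Lag times span $10^{-6}$–$1$ s.

Noise models: multiplicative and fractional for SAXS/WAXS (counting-like
statistics after normalization), additive for DSC and DLS. Every noisy
generator call requires a seed and is bit-reproducible.

What the generators do **not** emulate: instrument smearing, absolute
intensity calibration, multiple scattering, aggregation kinetics, and the
non-Gaussian detail of real detector noise. Green tests on synthetic data
therefore validate the *analysis machinery and its calibration*, not
instrument-specific robustness.

# Analysis decisions

## DSC

Peaks are Lorentzians $A\gamma^2/((T-T_0)^2+\gamma^2)$ fitted jointly with a
linear baseline by Levenberg–Marquardt. The baseline model is a convention
choice (the heat-flow difference trace of a heat-flux DSC is locally linear).
Candidates come from a robust baseline subtraction followed by local-maxima
scanning on a lightly median-smoothed trace; fits are seeded from the most
prominent candidates, so noise excursions cannot hijack the fit. With
`n_peaks = "auto"` a second peak is accepted when it improves the reduced
chi-square by at least 10 % *and* its amplitude exceeds three times its
standard error — the executable version of the visual "shoulder" criterion.

## WAXS

Lorentzian plus linear background on a window of 1.1–1.75 Å$^{-1}$ with the
region 1.28–1.34 Å$^{-1}$ masked by default (a known detector artifact sits
near 1.3 Å$^{-1}$); both are configurable, and a pseudo-Voigt is available
for the broadened fluid-phase peak. The window itself is a package default —
the source study does not state one.

## IFT

$p(r)$ is expanded in cubic B-splines on a two-regime knot layout — 10
uniform intervals from 0 to 75 Å for the bilayer cross-section, 15 from 75 Å
to $r_\mathrm{max}$ for the vesicle — with $p(0) = p(r_\mathrm{max}) = 0$
imposed by dropping the edge splines. Coefficients minimize the
$\sigma$-weighted residual plus $\alpha \sum (c_{i+1}-c_i)^2$, the classic
first-difference (smoothness) stabilization; $\alpha$ is either given or
selected at the maximum-curvature corner of the L-curve over a 25-step ladder
from $10^{-4}$ to $10^4$, with a reduced-chi-square fallback when the curve
is degenerate. The intensity is normalized internally so $\alpha$ is
scale-free — scaling $I(q)$ by $k$ scales $p(r)$ by exactly $k$ and leaves
$R_G$ untouched. $R_G$ follows from the $p(r)$ moments,
$R_G^2 = \int p r^2 dr / (2\int p\,dr)$, by trapezoidal integration.

`estimate_rmax()` sets the support from the low-q oscillations: successive
form-factor minima are spaced by $\pi/R$, so the median minimum spacing gives
the shell radius even when the first-order minimum lies below the measured
q-range (large vesicles); $r_\mathrm{max} = 1.2 \times 2R$. A prominence
filter (15 % intensity dip) rejects numerical ripples.

Known limitation: for the largest preset (nominal radius 990 Å) the measured
window starts at $q_\mathrm{min} R \approx 4$, and the recovered $R_G$
overshoots — the same resolution limit that led the source study to exclude
its largest sample as aggregated. The result still increases monotonically
with aescin content, which is what the qualitative check asserts.

## MKP

$I(q)q^4$ on 0.08–0.30 Å$^{-1}$ (bracketing the bilayer form-factor lobe; a
package default, configurable) is fitted with a fourth-order polynomial on a
centered/scaled abscissa; $q_\mathrm{max}$ comes from the real roots of the
analytic cubic derivative, and a boundary maximum or missing interior
maximum raises an error rather than returning a silently wrong thickness.
When the same window contains a *confirmed* lamellar doublet the thickness
is refused: correlated bilayers mean aggregation, and Bragg peaks would bias
the polynomial maximum. This mirrors restricting thickness analysis to 10 °C
data.

## Lamellar analysis

A power law $Aq^{-p}+c$ is fitted iteratively on peak-free flanks; since a
power law cannot follow the lobes of the bilayer form factor the peaks sit
on, the residual is additionally detrended by an annulus running median
(wide against the peak width, so narrow peaks survive). Candidate peaks must
exceed three times the *local* residual scatter, are refined by local
Lorentzian fits, and the stack is flagged lamellar exactly when
$|q_2/q_1 - 2| < 0.1$.

## PCS

The Siegert-reduced field correlation $\sqrt{g_2-1}$ is inverted on a
log-spaced rate grid (default 200 points, 4 decades centered on the apparent
$1/e$ decay rate) by Lawson–Hanson non-negative least squares with a
second-difference Tikhonov penalty — a CONTIN-style construction. Numerical
choices that matter, all decided on synthetic single-exponential Monte
Carlo and kept fixed:

* The trace is truncated where the running-median of $g_2-1$ falls below
  twice the tail noise floor. A *per-point* cutoff would let isolated tail
  noise excursions pose as slow modes with large weight — a tens-of-percent
  bias on the mean rate.
* Points beyond the cut are anchored at zero with an uncertainty of half the
  largest field amplitude the floor allows ($\sqrt{2\sigma}/2$): slow
  components cannot hide past the cut, yet genuine sub-floor tails sit
  within about two standard deviations of the anchor.
* A second-order Jensen correction compensates the downward bias of the
  square-root transform, applied only to points individually above the floor
  (the correction diverges as the signal reaches zero).
* For noisy traces the weighted residual is nearly flat in $\alpha$ over ten
  decades — a smooth decay is fit equally well by a spike and by a hump — so
  neither the L-curve nor the discrepancy principle can resolve the
  regularizer. `auto` therefore uses a noise-scaled default
  $\alpha = 8\,n_\mathrm{eff}\,s_\mathrm{min}^2$ that vanishes in the
  noise-free limit, where the L-curve ladder is used instead.
* Headline moments come from the *dominant* contiguous mode of the
  distribution (NNLS yields exact zeros between modes), as in peak analysis:
  sub-percent satellite masses at the grid edges are barely constrained by
  the data yet carry enormous leverage on the raw first moment.
  Full-distribution moments and a per-mode table are reported alongside.

The diffusion coefficient is the slope of mean $\Gamma$ against $q^2$. The
headline value uses the through-origin form — the relation
$\Gamma = D_T q^2$ has no intercept — while a free-intercept fit is reported
as a diagnostic for non-diffusive contributions. Water viscosity follows
$\eta(T) = 2.414\times10^{-5} \cdot 10^{247.8/(T-140)}$ Pa·s ($T$ in K),
valid for 0–100 °C; whether a 50 mM phosphate buffer is adequately
approximated by pure water is an assumption inherited from the measurement
convention, exposed through the `viscosity` argument.

# The study pipeline

`run_study()` executes the chain per sample with the gating a temperature
series on vesicles requires: IFT only below the fitted $T_m$ (above it the
vesicle contrast is lost), thickness only at 10 °C, lamellar analysis only
above $T_m$; the 1.0 mol% aescin sample's WAXS table stops at 25 °C
(thermally induced aggregation). Failures are isolated per sample and
logged. `make_report()` writes one deterministic CSV per quantity — $T_m$,
$d_\mathrm{WAXS}(T)$, $R_G(w)$, $d_m(w)$, $d_\mathrm{lam}(w)$, $R_H(w)$ —
and simple PDF figures.

Problem sizes used throughout the checks: 1200-point SAXS curves
(0.004–0.6 Å$^{-1}$), 661-point thermograms, 200-lag correlograms at 15
angles, 100-point inversion grids, 20–100 seeded replicates for the
recovery properties. A full seven-sample synthetic study completes in a few
minutes on one CPU.

# Worked example

```{r, eval = FALSE}
st <- run_study(list(
  samples = list(list(preset = "dmpc_pure"),
                 list(preset = "nap10_aescin08")),
  noise = list(dsc = 0.01, dls = 0.02), seed = 7))
subset(st$table, quantity %in% c("tm", "dm", "rh"))
make_report(st, "results/")
```
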