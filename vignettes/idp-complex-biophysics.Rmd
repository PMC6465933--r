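---
title: "Methods: biophysics of a disordered chain bound to a folded domain"
author: "idpbiophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysics of a disordered chain bound to a folded domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpbiophys)
```

`idpbiophys` packages the quantitative workflow used to characterize an
intrinsically disordered protein (IDP) region and its 1:1 complex with a
small folded domain — the setting is the C-terminal region of L-periaxin
(PRX-C, 348 residues) binding the third fibronectin-III domain of
β4-integrin. Because the raw instrument data behind such studies are
rarely deposited, every analysis here is paired with a synthetic-data
generator that emulates the corresponding experiment, so estimator
behavior can be validated end to end.

## Random-chain scaling theory

For an unfolded chain of $N$ residues the radius of gyration follows
$R_g = R_0 N^\nu$. Two parameterizations are built in: chemically
denatured chains ($R_0 = 1.98$ Å, $\nu = 0.602$) and IDPs under native
conditions ($R_0 = 2.54$ Å, $\nu = 0.522$). The RMS end-to-end distance
$\sqrt{\langle L^2\rangle} = \sqrt{L_0 N}$ with $L_0 = 81.8$ Å serves as
the theoretical proxy for the maximum dimension $D_{max}$. Internally all
lengths are in Å; reports convert to nm at two decimals.

```{r theory}
predict_chain_dimensions(348, "idp")
angstrom_to_nm(predict_end_to_end(1383))   # full-length chain: > 30 nm
```

The residue count is always an explicit argument. For the 348-residue
construct the IDP law gives 5.39 nm and the end-to-end law 16.9 nm; note
that the denatured-law value for any $N$ in 345–353 rounds to
6.71–6.73 nm, so a report quoting 6.75 nm for this construct must have
used a slightly different count or rounding — the package does not force
any of these values.

The compactness ratio $R_g/R_h$ discriminates shapes: $\sqrt{3/5}
\approx 0.775$ for a uniform sphere, above 1 for expanded coils. A
disordered chain that remains disordered in a complex shows only a modest
drop in this ratio upon binding.

## Conformer generators

Conformers are coarse-grained at one point scatterer per residue with a
virtual bond of 3.8 Å (the standard Cα spacing), unit weight per bead.

* **Freely jointed chains** — independent random bond directions. The
  exact identity $\langle L^2 \rangle = N_{bonds} b^2$ and the Gaussian
  limit for the RMS $R_g$, $b\sqrt{N_{bonds}/6}$, are used as tests. Note
  the *mean* $R_g$ of a Gaussian chain sits ≈3% below the RMS value
  because the $R_g$ distribution is broad; tests compare the RMS.
* **Self-avoiding chains** — a hard-sphere constraint of
  $2 r_{excl}$ between all non-bonded beads. Chains are first grown
  incrementally (resampling the failed bead, with limited backtracking
  and a global retry budget whose exhaustion reports the acceptance
  rate). Incremental growth alone is a *kinetic growth* ensemble that is
  measurably too compact (apparent Flory exponent ≈0.53), so each grown
  chain is then equilibrated with pivot moves — rotate the tail about a
  random interior bead, accept if the hard-sphere constraint holds —
  which is the standard exact Monte-Carlo scheme for self-avoiding
  walks. With the default `pivot_moves = n_residues` the measured
  exponent of mean $R_g$ versus $N$ over $N = 50\ldots400$ is ≈0.60, as
  expected for excluded-volume chains.
* **Globule mimics** — beads uniform in a ball, rescaled so the realized
  $R_g$ equals the target exactly; this stands in for a small folded
  domain (e.g. a 2.1 nm-$R_g$ FNIII domain) at matched resolution.
* **Tethered complexes** — a globule placed with its sampling-ball
  surface touching a chosen chain residue, re-oriented until no
  chain/domain bead pair is closer than `clash_radius`.

All generators take a `seed` and are bit-reproducible under it; `NULL`
uses the caller's RNG stream. Chains make no claim to Ramachandran-level
realism, hydration layers, or sequence-specific stiffness — passing tests
demonstrate estimator correctness on idealized polymers, not agreement
with any particular real protein.

## Forward scattering and curve analyses

Momentum transfer uses $s = 4\pi\sin\theta/\lambda$ in Å$^{-1}$
throughout; file readers accept a nm$^{-1}$ flag. Scattering from bead
models is the exact Debye double sum
$I(s) = \sum_i\sum_j w_i w_j \,\mathrm{sinc}(s r_{ij})$, evaluated in
compiled code over precomputed pair distances; ensembles are averaged
with equal weight. $I(0) = (\sum w_i)^2$ by construction. When a
bead model stands in for a *continuous* body, the discrete self-term
$\sum w_i^2$ adds a constant floor that becomes visible where the form
factor is small; comparisons against continuum form factors should use
the pair-normalized curve $(I - \sum w_i^2)/\big((\sum w_i)^2 - \sum
w_i^2\big)$, which is what the sphere-validation test does (with a
deterministic lattice-filled ball, since a random 2000-bead sample
fluctuates by several percent near the form-factor minimum).

**Guinier fit.** $\ln I$ is fitted against $s^2$ on the lowest decade of
the s grid, and the window is shrunk iteratively whenever the fitted
$R_g$ would violate $s_{max} R_g \le$ `srg_limit` (1.3 by default,
1.0 recommended for coil-like curves). The cap is deliberately
shrink-only: expanding the window out to the cap produces a systematic
−3.6% (at 1.0) to −5.8% (at 1.3) bias on coil curves because of their
curvature in Guinier coordinates, while the low-decade window recovers
oracle coil $R_g$ values to well under 1%. Degenerate inputs (rising or
flat curves, fitted $R_g$ under 1 Å) raise fit-failure errors.

**Debye-formalism (Calmettes) estimator.** For random coils, $1/I$ is
linear in $s^{2.206}$ over the much wider range $(s R_g)^2 < 3$; a line
fit there gives $R_g = (a/0.359\,b)^{0.453}$ from slope $a$ and intercept
$b$. The window needs an $R_g$ to define it, so the estimate is iterated
from a Guinier seed (or a widest-window fallback) until it changes by
less than 0.5% with a stable window, capped at 20 iterations. Points are
unweighted by default; a `weighted` flag uses the propagated variance of
$1/I$. On ensemble-averaged coil curves this estimator tracks the
ensemble mean $R_g$ more closely than the Guinier fit — the reason this
formalism is preferred for IDPs.

**Dimensionless Kratky and P(r).** The transform
$(sR_g)^2 I/I_0$ versus $sR_g$ peaks at exactly $(\sqrt3, 3/e)$ for an
idealized (Guinier-law) globule and rises monotonically to a plateau of 2
for a Gaussian coil; the package computes the transform only, no fitting.
The pair-distance distribution is a direct, ensemble-averaged histogram
of inter-bead distances from known coordinates (bin width 1 Å by
default) — inverting experimental curves is out of scope. $D_{max}$ is
the largest observed distance and
$R_g^2 = \sum p r^2 \Delta r / (2\sum p \Delta r)$ recovers the direct
$R_g$ to better than 1% at bin widths ≤ 0.5 Å.

Synthetic noisy curves use multiplicative Gaussian noise with constant
relative error (2% default) and record it as per-point σ.

## Ensemble optimization

`select_ensemble()` mimics ensemble-optimization analysis of SAXS data: a
genetic algorithm picks fixed-size multisets (default 20, repeats
allowed — multiplicity substitutes for a weight vector) from a
precomputed conformer pool so that the ensemble-average curve minimizes
the scale-invariant reduced $\chi^2$ against the target. Operators:
tournament selection of size 3, member-swap crossover (rate 0.5),
random-replacement mutation (rate 0.1), elitism (2), default 50
individuals × 200 generations × 10 repeats, all deterministic under a
seed. Elitism makes the best fitness non-increasing, which is asserted as
an invariant. Selected-versus-pool $R_g$ and $D_{max}$ histograms share
Freedman–Diaconis bins computed on the pool and are normalized to unit
mass.

Validation is property-based: a target built from one pool member is
recovered at $\chi^2 \approx 0$ (small ensembles converge to the pure
solution; larger ensembles can stall in compensating mixtures, which is a
property of the fitness landscape, so the planted test uses ensemble
size 3); a target from a bimodal planted subset yields a bimodal selected
distribution with modes within 10%; a target from the full pool average
yields a selected distribution statistically indistinguishable from the
pool; and a target from slightly stretched coils shifts the selected
distributions right of the pool — the signature of a chain "slightly more
elongated than a random coil". The published tool's pool sizes and
operator internals are not reproduced.

## One-site calorimetry

`simulate_titration()` implements the overfilled-cell displacement model
of syringe-into-cell calorimeters. After cumulative injected volume
$\Delta V$ into the active volume $V_0$, effective concentrations are

$$M_t = M_0\,\frac{1 - \Delta V/2V_0}{1 + \Delta V/2V_0},\qquad
  X_t = X_0\,\frac{\Delta V/V_0}{1 + \Delta V/2V_0},$$

the bound ligand follows the one-site mass-action quadratic, the cell
heat content is $Q = n M_t \Delta H V_0\,\theta$ with $\theta$ the
fractional saturation, and the $i$-th injection heat is
$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$.
The default protocol is the study geometry: 680 µM ligand into 350 µl of
68 µM macromolecule, 38 × 1 µl injections, 25 °C — a Wiseman parameter
$c = n M_0 / K_d = 40$ at the reported affinity, comfortably inside the
reliable 1–1000 range.

`fit_one_site()` refits $(n, \log K_d, \Delta H)$ by
Levenberg–Marquardt on the per-mol heats ($\log K_d$ for positivity and
conditioning; the first injection is kept by default with a discard
flag). Noise-free generator/fitter round trips recover parameters to
$\le 0.1\%$ across $c \in \{1, 10, 40, 100, 1000\}$, and the median
$K_d$ over 100 noisy replicates (2% of the largest heat) stays within 5%.

A note on signs: the source report prints $\Delta H = 6.2$ kcal/mol with
$\Delta S = 5.8$ cal/(mol·K), which is thermodynamically inconsistent
with $K_d = 1.7$ µM at 25 °C: that pair gives
$\Delta G = \Delta H - T\Delta S = +6.2 - 298.15\times0.0058 = +4.5$
kcal/mol, while the measured affinity demands
$\Delta G = RT\ln K_d = -7.87$ kcal/mol.
Simulation truth therefore uses the exothermic $-6.2$ kcal/mol, fits
report the signed value, and headline comparisons use $|\Delta H|$.
`derived_thermo()` gives $\Delta G = RT\ln(K_d/c^\circ)$ and
$\Delta S = (\Delta H - \Delta G)/T$ (5.6 cal/(mol·K) here, near the
printed 5.8).

## Thermal melts

Two-state unfolding follows the van't Hoff form
$\theta(T) = \big(1 + e^{(\Delta H_{vH}/R)(1/T - 1/T_m)}\big)^{-1}$ (T in
kelvin), with the observable interpolating two linear baselines — a
fluorescence ratio on a fine grid (20–95 °C at 0.1 °C, emulating a
2 °C/min intrinsic-fluorescence ramp) or a single-wavelength CD signal on
a coarse grid (10–90 °C in 5 °C steps). $\Delta H_{vH}$ is not printed in
the source study; the default 120 kcal/mol gives a transition width
(≈8 °C between 10% and 90% unfolded) typical of a single small folded
domain. Aggregation onset and the spectral dimension of CD melts are out
of scope; the coarse-grid channel is reduced to one wavelength.

$T_m$ is extracted from the first-derivative peak maximum: the
Savitzky–Golay-smoothed (order 2; window 11 points on fine grids,
3 on coarse) derivative's largest absolute value. Using the absolute
value makes the estimate invariant under affine rescaling of the signal,
including sign flips. On grids coarser than 1 °C a quadratic through the
peak-adjacent triplet refines the maximum between grid points; across a
$T_m$ sweep of 40–80 °C this keeps the error below 0.1 °C on the fine
grid and below 0.6 °C on the 5 °C grid. A trace whose derivative has no
interior peak clearly above its baseline level (peak < 2× the median
absolute derivative) raises a no-transition error rather than reporting a
spurious $T_m$.

## Mass and stoichiometry bookkeeping

Sequence masses use standard average residue masses plus one water
(matching ESI-TOF deconvolved masses; monoisotopic behind a flag).
Complex masses are plain sums reported at 2 decimals, and the
"% of expected" statistic rounds half away from zero — the convention
that reproduces both 114% (an extended chain whose apparent
light-scattering mass runs high) and 99% (the 1:1 complex) from the
tabulated inputs. Cloning artifacts (an N-terminal serine left by tag
cleavage, say) are the caller's responsibility to include in the
sequence; nothing is silently edited. `build_report()` joins measured,
fitted and theoretical quantities per species, flags probable Å-for-nm
unit mistakes (magnitudes above 100 in nm columns), and writes CSV.

## Problem sizes and numerical choices

The test suite validates properties at deliberately modest scales chosen
for statistical adequacy: 10⁴ freely jointed chains for the $\langle
L^2\rangle$ and Gaussian-limit identities, 50 self-avoiding chains per
length for the Flory-exponent regression, 150–200-conformer pools for
ensemble curves, ~2000-bead sphere models, 100 noisy titration
replicates. Scattering grids place tens of points per decade, which is
representative of rebinned beamline curves. Tolerances asserted in tests
(1–3% for estimator recovery, 0.1/0.6 °C for melt midpoints, 0.1% for
noise-free calorimetry round trips) were set from the statistical error
of these problem sizes and the approximation structure of each method, as
discussed above.

Known limitations: conformer pools are sequence-agnostic homopolymers;
the Guinier window policy is tuned for smooth synthetic curves and may
need manual windows on data with low-s artifacts; the displacement model
reproduces instrument software conventions but not raw-power baseline
integration; and the melt model has no $\Delta C_p$, so fitted and
simulated enthalpies are van't Hoff, not calorimetric.
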