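---
title: "Restricted rotation in sugar (thio)ureas: models and methods"
author: "rotabar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restricted rotation in sugar (thio)ureas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotabar)
```

## The problem

N-aryl ureas and thioureas built on a 2-amino-2-deoxy-glucopyranosyl azide
scaffold show hindered rotation about two kinds of bonds: the amide-like
N–C(=X) bonds (X = O, S), each of which can sit in a *Z* or *E*
arrangement, and — when the aryl ring carries bulky *ortho* substituents —
the N–C(aryl) single bond, whose twist defines *M*/*P* atropisomers.  At
room temperature these rotamers interconvert slowly enough to broaden NMR
signals; at low temperature the signal sets split, and on warming they
coalesce.  `rotabar` implements the quantitative machinery around this
phenomenology: coalescence-based barrier estimation from
variable-temperature (VT) NMR, descriptor bookkeeping for the conformer
space, torsional-scan analysis for computed rotation profiles, geometric
criteria on 3-D structures, and the molecular-formula arithmetic used in
compound characterisation.

Because quantum-chemistry outputs and spectrometer files are consumed, not
produced, the package ships a synthetic-data generator whose every output
embeds its ground truth, so each analysis stage has a recovery test with a
known answer.

## Dynamic NMR: two-site exchange and the coalescence barrier

Two uncoupled, equally populated sites separated by $\Delta\nu$ Hz in slow
exchange merge into one flat-topped line when the exchange rate reaches

$$k_c = \frac{\pi\,\Delta\nu}{\sqrt{2}}.$$

Transition-state theory links a rate to an activation free energy through
the Eyring equation $k = (k_B T/h)\,e^{-\Delta G^\ddagger/RT}$ (transmission
coefficient 1).  Equating the two at the coalescence temperature $T_c$ gives

$$\Delta G^\ddagger = R\,T_c \ln\!\left[\frac{k_B T_c \sqrt{2}}{\pi h\,
\Delta\nu}\right]
 = 1.987\,T_c\left[C + \ln(T_c/\Delta\nu)\right]\ \text{cal/mol},$$

where the bracket constant is $C = \ln(k_B\sqrt{2}/\pi h)$.  Evaluated with
CODATA-2018 constants, $C = 22.96$; a rounded value of 22.62 also circulates
in the literature.  `coalescence_barrier()` defaults to the first-principles
constant and offers `constant = "legacy"` for comparability with reports
using 22.62 (the difference is about 0.09 kcal/mol at 270 K).  The gas
constant is pinned at $R = 1.987\times10^{-3}$ kcal/(mol K), the
conventional value of this equation family.

Rather than trusting the $k_c$ formula, the package carries an independent
oracle: `two_site_lineshape()` implements the classical Bloch–McConnell
(Gutowsky–Holm) absorption spectrum.  For site populations $p_A$, $p_B$ the
site-to-site rates are $k_{A\to B} = 2 p_B k$ and $k_{B\to A} = 2 p_A k$,
which preserves detailed balance and reduces to a symmetric rate $k$ for
equal populations.  In the sharp-line limit the simulated spectrum switches
from two maxima to one *exactly* at $k = \pi\Delta\nu/\sqrt{2}$ (the central
curvature changes sign when $2k^2 = (\pi\Delta\nu)^2$), and the test suite
verifies the transition numerically across $\Delta\nu$ from 50 to 2000 Hz.
Finite linewidth shifts the transition: with the default $T_2 = 0.05$ s
(6.4 Hz lines) the shift is $\approx 0.2\%$ at $\Delta\nu = 2163$ Hz but
$\approx 7\%$ at $\Delta\nu = 50$ Hz, which is why the oracle-equivalence
suite runs at $T_2 = 0.5$ s — the regime the closed form assumes — while
VT recovery keeps the realistic default.

The full pipeline, `barrier_from_vt()`, measures $\Delta\nu$ from the two
peaks of the lowest-temperature spectrum (parabolic sub-grid refinement),
finds $T_c$ as the temperature where the inter-peak minimum vanishes (peak
counting with a 1% relative prominence floor against numerical ripple,
optional bisection refinement when the series carries a rate model), and
inverts the coalescence equation.  The equal-population relation is only
approximate for biased equilibria; when a synthetic series declares
$p_A \neq 0.5$ the result carries a warning, and the recovery error stays
well under 1 kcal/mol at $p_A = 0.6$.

```{r vt}
sys <- exchange_system(nuA = -2163 / 2, nuB = 2163 / 2, T2 = 0.05)
vt <- make_vt_series(dG = 11.2, sys, temps = seq(250, 290, by = 1))
barrier_from_vt(vt)
```

The default VT ladder (223–330 K, 1 K steps, 4096-point frequency grid) is
sized so that grid discretisation contributes $\le 0.5$ K to $T_c$ and
$\sim 0.02$ kcal/mol to $\Delta G^\ddagger$ — an order of magnitude below
the 0.2 kcal/mol recovery tolerance the tests enforce — while a full
simulate-and-analyse cycle still runs in well under a second.

## Conformer descriptors and populations

`assign_ze()` maps the X=C–N–C(substituent) torsion to *Z* (synperiplanar,
$|\tau| \le 90°$) or *E*.  The pictorial literature definitions do not fix
this algebraically, so the convention is explicit and the mirrored mapping
is available via `convention = "trans_Z"`; $|\tau| = 90°$ ties break to *Z*.
`assign_helicity()` applies the standard axial-chirality convention to the
C(X)–N–C(ipso)–C(ortho) torsion: positive is *P*, negative *M*, with the
higher-CIP ortho substituent (Cl over CH₃) defining the reference branch; a
planar axis has no helicity and errors.  With the NH/H-2 antiperiplanar
arrangement fixed by the observed large couplings, `enumerate_conformers()`
returns the four (Z/E, Z/E) labels, doubled to eight by the M/P axis for
*ortho*-disubstituted aryl rings; (E,E) is enumerated even where energy
tables discard it, and an `exclude` filter reproduces the reduced set.

`relative_energies()` converts hartree input by 627.5095 kcal/mol and
re-zeroes to the most stable member; `boltzmann_populations()` weights by
$e^{-E_i/RT}$.  Populations are invariant to a constant energy shift and
monotone non-increasing in energy, both property-tested.

## Torsional scans

A `torsion_profile` is a periodic (angle, energy) table wrapped into
$[0, 360)$ — the 0–360° · 15° protocol and the 280°-start · 20° protocol
both map onto it.  `stationary_points()` supports two methods: `"grid"`
(cyclic local extrema of the samples, plateau ties collapsing to the arc
midpoint; exactly reproducible from the table) and `"spline"` (a periodic
cubic interpolant evaluated at 0.01° and polished with `optimize()`, for
sub-grid extremum positions).  Minima and maxima always alternate and are
equal in number.  `barrier()` takes the highest energy along a directed arc
minus the starting minimum; with no direction given it reports the lower of
the two directed values (the easiest path), so
$\mathrm{barrier}(a\to b) - \mathrm{barrier}(b\to a) = E(b) - E(a)$.
`direction_consistency()` compares clockwise and counterclockwise scans
point-by-point, with a default 0.5 kcal/mol "practically coincidental"
verdict threshold, and `label_path()` combines extrema with a labeling
function to state which rotamer each minimum converts into across its
lowest adjacent saddle — the analysis behind conclusions of the form "ZZP
transforms into ZEP, not ZZM".

The generator side (`fourier_potential()`, `make_potential()`) declares its
extrema analytically (derivative roots by bracketed `uniroot`, classified
by the second derivative).  `two_well_potential()` solves the two-term
cosine series in closed form so that the barrier out of the global minimum
is *exactly* the requested value (default 13.5 kcal/mol with the secondary
well at 1.5), giving the scan analysis a fixture with zero truth error:

```{r scan}
mk <- make_potential(two_well_potential(13.5, 1.5), step = 15)
stationary_points(mk$profile, method = "spline")
barrier(mk$profile, from = 0, to = 180)
```

On a 15° grid, grid-mode extrema are exact to half a step (7.5°) and
spline-mode to better than 1°; recovered barriers sit within 0.1 kcal/mol
of truth for the potentials exercised in the tests.

## Geometry

Beyond distances, torsions (IUPAC sign convention, range $(-180°, 180°]$
with the boundary at $+180°$, cross-checked against `bio3d::torsion.xyz`)
and three-point "virtual" angles between not-necessarily-bonded atoms, two
domain-specific measurements matter here:

* **van der Waals contacts.** `vdw_contact()` compares a distance with the
  radii sum.  The shipped table uses the contact-analysis values
  H = 1.17 Å, O = 1.52 Å, S = 1.80 Å — hence the diagnostic sums
  H+O = 2.69 Å and H+S = 2.97 Å — and Bondi radii elsewhere; the table is
  an argument and can be overridden.
* **Ring puckering.** `ring_pucker()` computes Cremer–Pople $(Q, \theta,
  \varphi)$ from the mean-plane construction.  With ring atoms ordered from
  the ring oxygen (O5, C1, …, C5), $\theta < 30°$ is labeled `4C1`,
  $\theta > 150°$ `1C4`, anything between `nonchair`; amplitudes below
  $10^{-4}$ Å report `planar` with $\theta$ undefined.  The chair
  thresholds are generous on purpose: ideal chairs sit at $\theta \approx
  0°/180°$ and realistic pyranose chairs within a few degrees.

`karplus_j()` evaluates $J(\theta) = A\cos^2\theta + B\cos\theta + C$ with
heuristic defaults $A = 9.4$, $B = -1.1$, $C = 0.4$ Hz.  The conformational
argument it supports is deliberately qualitative — a vicinal coupling above
7.5 Hz (`antiperiplanar_check()`) indicates a torsion near 180° — so the
coefficients are configurable rather than asserted.

## The synthetic fragment

`make_fragment()` builds a ⁴C₁ chair (uniform 1.50 Å ring edges in an exact
ideal-chair geometry — alternating C–C/C–O bond lengths would break exact
closure of the analytic construction and change nothing the descriptor and
puckering tests measure), an equatorial N at C2 with axial H-2
antiperiplanar to the NH, and a planar sp² (thio)urea arm ending in an aryl
ring with either ortho H atoms or the Cl/CH₃ atropisomerism-inducing pair.
The three defining torsions are laid down by exact internal-to-Cartesian
placement, so measuring them back reproduces the specification to numerical
precision and `fragment_descriptors()` recovers all eight
(Z/E, Z/E, M/P) labels.  Requests that drive atoms within 0.7 Å error out
as clashes.  The geometry is idealised: no acetyl/azide decoration, no
relaxation — adequate for descriptor, contact and puckering logic, not for
energetics.

## What the synthetic data does and does not show

The generators emulate the *structure* of the real inputs: Eyring-driven
exchange spectra on a common grid, cosine-series torsion profiles on coarse
periodic grids, idealised chair fragments.  They do not emulate DFT-quality
energetics, coupled multiplets, baseline/phase artefacts, or solvent
effects.  Passing recovery tests therefore demonstrates that the analysis
chain is correct and self-consistent — not that any particular experimental
system has a given barrier.  Printed-arithmetic checks (elemental analyses,
adduct masses) are exact reproductions, by contrast, since their inputs are
molecular formulas alone.

Monoisotopic masses are computed from principal-isotope masses with the
electron mass (0.000549 Da) subtracted for cations.  This convention
reproduces observed high-resolution m/z values to within 0.1 mDa in the
worked examples; occasionally *calculated* values quoted in compound
listings differ from first-principles arithmetic by around 1 mDa, and the
package deliberately follows the arithmetic rather than any printed value.
The isotope-pattern expansion treats only Cl, S and Br as polyisotopic
(combinatorial expansion capped at three such atoms), which is the level of
detail needed for the ³⁵Cl/³⁷Cl ≈ 3:1 diagnostic; ¹³C satellites are out of
scope.

## Numerical choices, in one place

* Physical constants: CODATA-2018 $k_B$, $h$; $R = 1.987\times10^{-3}$
  kcal/(mol K); 627.5095 kcal/mol per hartree; electron mass 0.000549 Da
  (`physical_constants()`).
* Display rounding: round-half-up, 2 d.p. for percentages, 4 d.p. for m/z
  (`round_half_up()`); all computations keep full precision.
* Peak detection: relative prominence floor, default 1%; raise it (e.g. to
  10× the noise level) for noisy spectra.
* Spline extrema: 0.01° evaluation grid, `optimize()` polish, plateau ties
  to arc midpoints; profile angles wrapped mod 360 with duplicate angles
  rejected.
* Degenerate inputs error loudly: flat profiles, planar helicity axes,
  collinear torsion atoms, merged-everywhere or split-everywhere VT series.

## Pipeline and reproducibility

`run_pipeline()` chains stages (`synth_vt`, `dnmr`, `synth_potential`,
`scan`, `formula`) from a YAML config, resolves stage references, writes
checksummed outputs plus a JSON report, and is deterministic under a fixed
seed — identical config and seed give a byte-identical report.  Logging
goes to stderr; results only to files.  A stage failure marks the run
failed and skips dependent stages; the `exec/rotabar` wrapper maps this to
exit codes 0/1/2 (ok / stage failure / config error).
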