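---
title: "Modelling SANS curves of oligomerizing membrane proteins with sansmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SANS curves of oligomerizing membrane proteins with sansmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sansmix)
```

## The problem

Small-angle neutron scattering (SANS) on a detergent-solubilized membrane
protein in matched-out deuterated detergent measures the orientationally
averaged intensity $I(q)$ of the protein alone: the detergent's scattering
length density equals that of the D$_2$O buffer, so the micelle belt is
invisible. Such samples are rarely perfectly monodisperse — a small number
fraction of the protein typically sits in large, loosely packed oligomers.
Even at the percent level, these dominate the lowest measured $q$ values
and bias every model-free size estimate. `sansmix` implements the complete
analysis chain for this situation:

1. neutron form factors computed directly from atomic structures, with
   implicit hydrogens, H/D exchange, an excluded-volume correction and a
   membrane-aware hydration shell (`load_structure()`,
   `assign_scattering()`, `add_hydration_shell()`, `form_factor()`);
2. a mass-fractal description of the oligomers with the Teixeira structure
   factor under the decoupling approximation (`teixeira_sq()`,
   `effective_sq()`);
3. resolution-smeared weighted least-squares fits of four nested mixture
   models with F-test model comparison (`fit_model()`, `f_test()`);
4. the model-free curve toolbox: Guinier, Kratky, indirect Fourier
   transform $p(r)$, Porod background, scattering invariant and three
   molecular-weight estimators;
5. a synthetic-data module (`make_mock_structure()`, `simulate_curve()`,
   `corpus()`) that generates every input the pipeline needs, so the whole
   chain is testable offline.

## Form factors from atomic structures

For a set of point scatterers with excess scattering lengths $b_j$ at
positions $r_j$, the Debye sum gives the orientationally averaged form
factor

$$P(q) = \sum_j \sum_k b_j b_k \,\frac{\sin(q r_{jk})}{q r_{jk}},$$

stored unnormalized in cm$^2$ so that the absolute intensity of a solution
of number density $n$ is $I(q) = K\,n\,P(q) + B$ with a dimensionless
concentration correction $K$ and a flat background $B$. The excess
scattering length of each heavy atom folds in its implicit hydrogens:
deposited structures lack H, so each heavy atom receives a standard count
of bound hydrogens from a residue template (`residue_hydrogen_table()`),
split into non-labile (C-bound) and labile (N/O/S-bound). Labile hydrogens
contribute the exchange-weighted average
$b_\mathrm{H} + f_\mathrm{ex} f_{\mathrm{D_2O}} (b_\mathrm{D} -
b_\mathrm{H})$; the default exchange fraction is 0.9, the common
accessible-exchange assumption for folded proteins, and it is an explicit
parameter because buried amides exchange more slowly. The excluded-volume
term subtracts $\rho_\mathrm{solv} V_j$ per atom, with displaced volumes
from the Fraser et al. atomic volume set and a water molecular volume of
30 Å$^3$ (both exposed as arguments — neither is a universal constant).

In pure D$_2$O the protein's excess scattering lengths are *negative*
(the solvent is "brighter" than protein); only $\Delta b^2$ enters the
intensity, but mixed-sign point sets are handled throughout.

### Hydration shell

Hydrated proteins carry a single water layer about 10% denser than bulk.
Only the 10% excess scatters, represented by dummy beads of 4.13 water
molecules each, placed deterministically: candidate positions on a
golden-angle lattice at $r_\mathrm{vdW} + 1.4$ Å around every atom, kept
when no other atom's contact sphere covers them, then thinned to the
spacing implied by one bead per
$4.13 \times 30\,\text{Å}^3 / 3\,\text{Å}$ of surface. Beads falling into
a user-defined membrane slab — the detergent-embedded belt, where there is
no hydration water — are omitted. The placement involves no randomness,
so hydrated point sets are bit-reproducible.

### Theoretical $p(r)$ and the 1% rule

`theoretical_pr()` histograms all pairwise distances weighted by
$b_j b_k$ (default bin 1 Å). Because every atom and bead contributes,
atomic $p(r)$ functions approach zero only asymptotically; the maximum
dimension is therefore defined operationally as the first grid point past
the peak from which $|p(r)|$ stays below 1% of the peak. The absolute
value and the "stays below" qualifier make the rule robust to the
oscillating mixed-sign tails that arise when a negative-contrast protein
carries a positive-contrast shell; for all-positive $p(r)$ the rule
reduces to the plain first crossing. The 1% threshold is exposed as a
parameter.

## The oligomer model

Random oligomers are modelled as mass fractals of tetramer subunits: the
subunit count scales as $N = k (R_g/r)^D$ with fractal dimension $D$,
structural coefficient $k$ and mean subunit distance $r$. The per-subunit
structure factor is Teixeira's

$$S(q) = 1 + \frac{D\,\Gamma(D-1)}{(qr)^D}\,
  \frac{\sin\!\left[(D-1)\arctan(q\xi)\right]}
       {(D-1)\left[1 + 1/(q\xi)^2\right]^{(D-1)/2}},
\qquad \xi = R_g\sqrt{\frac{2}{D(D+1)}},$$

which is evaluated through its analytic limit
$S(0) = 1 + D\,\Gamma(D-1)(\xi/r)^D$ at $q = 0$ (the raw expression is
0/0 there). $D$ is fixed to 2 and $k$ to 1 by default: scattering data
carry little information about fractal internals, and $k \simeq 1$ holds
at $D \simeq 2$; both remain settable, and the small-$q$ limit property in
the test suite pins the implemented form. $r$ is fixed to the radius of
the sphere with the protein's total van der Waals volume. Because the
tetramer subunits are far from spherical, the interference term is damped
by the decoupling approximation,

$$S'(q) = 1 + \beta(q)\,[S(q) - 1], \qquad
  \beta = A_0^0(q)^2 / P(q) \in [0, 1],$$

with $A_0^0$ the zeroth-order spherical-harmonic amplitude, computed as
$\sum_j b_j \operatorname{sinc}(q|r_j - r_c|)$ about the
contrast-weighted centroid $r_c$. The centroid is chosen as the expansion
origin because it minimizes the low-$q$ truncation error of the
zeroth-order expansion; the examples pin $\beta \le 1$ and
$\beta(0) = 1$.

## Mixture models and fitting

Four nested models cover the hypotheses of interest (single state;
state + fractal oligomers; two-state mixture; both):

| model | intensity | free parameters |
|---|---|---|
| 1 | $C P + B$ | $K, B$ |
| 2 | $C[(1-\gamma)P + \gamma P S'] + B$ | $K, B, R_g^\mathrm{olig}, \gamma$ |
| 3 | $C[(1-\alpha)P_a + \alpha P_b] + B$ | $K, B, \alpha$ |
| 4 | 2 and 3 combined, oligomers from both states | all five |

$\gamma$ mixes on a per-tetramer (number-fraction) basis: since $S(q)$ is
the *per-subunit* structure factor of the $N$-subunit fractal (its forward
limit already scales like $N$: $S(0) = 1 + \tfrac{2}{3}N$ at $D=2$,
$k=1$), per-tetramer mixing reproduces both the $\gamma \to 0$ and
$S' \to 1$ single-state limits and the forward-intensity consistency
chain, which the test suite asserts. Model 4 forms oligomers from both
conformational states in proportion $\alpha$.

Resolution smearing convolves the model with a Gaussian of width
$\sigma_q(q)$ (the curve's fourth column) using a 21-point Gauss–Legendre
quadrature over $\pm 3\sigma_q$, evaluating the model at the quadrature
nodes directly (negative nodes reflect, as $I$ is even in $q$). Weight
normalization makes constants exactly invariant.

`fit_model()` exploits that every model is linear in the scale
$C = K\,n$ and background $B$ for any values of the shape parameters:
those two are profiled out by an exact box-constrained weighted linear
solve (variable projection), and a bounded Levenberg–Marquardt search runs
only over the shape parameters. Model 1 is a single linear solve. This
removes the seven-decade magnitude disparity between $B$ (cm$^{-1}$) and
$R_g^\mathrm{olig}$ (Å) from the optimizer entirely. Default bounds:
$K \in (0, 10]$, $B \in [-0.1, 0.1]$ cm$^{-1}$,
$R_g^\mathrm{olig} \in [\max(R_g^\mathrm{sub}, r), 2000]$ Å,
$\gamma, \alpha \in [0, 1]$; defaults start at $\gamma = 0.01$,
$\alpha = 0.1$, $R_g^\mathrm{olig} = 300$ Å. Parameter uncertainties come
from the curvature $(J^\top J)^{-1}$ of the normalized residuals over
*all* parameters, with the Jacobian computed by central differences in
scaled units — the inverse must be formed where conditioning reflects the
science, not the units, or flat ridge directions (the strong
$\gamma$–$R_g^\mathrm{olig}$ correlation typical of percent-level
oligomer fractions) would be clamped into spuriously small uncertainties.
The reported correlation matrix makes that ridge visible.

`f_test()` provides the one-sided upper-tail test in two modes, because
model comparisons of both kinds occur: *nested* (different parameter
counts; $F = [\Delta\chi^2/\Delta f] / [\chi^2_c/f_c]$) and *variance
ratio* (equal counts, e.g. the same model with two different structures;
$F = \chi^2_{r,\mathrm{worse}}/\chi^2_{r,\mathrm{better}}$ on $(f, f)$
degrees of freedom). The report names the mode used.

### Calibration of the type-I error simulation

The F-test calibration study simulates the null with the extra parameter
*interior*: data come from a fixed 50:50 composite of two states, fitted
with the fraction fixed (simple) and free (complex). A null at the
$\gamma = 0$ boundary would make the nested test conservative by
construction (the boundary-parameter problem, compounded by
$R_g^\mathrm{olig}$ being undefined under the null) and would measure that
geometry, not the test's calibration. With the interior null the measured
rejection rate is statistically compatible with the nominal 5% (mean
$\Delta\chi^2 = 0.995$ over 400 replicates in the development runs).

## Model-free curve analysis

**Guinier.** `guinier()` iterates a weighted linear fit of $\ln I$ vs
$q^2$ on the widest low-$q$ window satisfying $q R_g \le 1.3$ until the
window is self-consistent. Curves with an aggregation upturn drive
$R_g$ up and the window below the five-point minimum; the result is then
flagged invalid rather than reported.

**Indirect Fourier transform.** `ift_pr()` represents
$I(q) = \int p(r)\operatorname{sinc}(qr)\,dr + B$ on a 100-point $r$ grid
and minimizes $\chi^2 + 2\alpha \lVert L p \rVert^2$ with a
second-difference smoothness operator $L$ (implicit zero boundaries). The
weight $\alpha$ — and $D_\mathrm{max}$, when automatic — is chosen where
the Gaussian model evidence peaks, scanned on a log grid around the
natural scale $\operatorname{tr}(T^\top W T)/\operatorname{tr}(L^\top L)$
(and a coarse-then-2% grid in $D_\mathrm{max}$); the background is
co-fitted. The final $p(r)$ is solved under non-negativity by cyclic
coordinate descent on the convex objective, warm-started from the clipped
ridge solution, with the sign-free background as an unconstrained
coordinate — active-set NNLS solvers with fixed iteration caps cycle on
these nearly singular, strongly regularized systems. The reported
$D_\mathrm{max}$ applies the same 1%-of-peak rule as the theoretical
$p(r)$, which is far more stable than reporting the grid endpoint. The
sphere oracle pins the whole construction: a noise-free 50 Å sphere curve
returns the analytic $p(r)$ to well under 2% normalized RMS and
$D_\mathrm{max}$ within a few percent of 100 Å.

**Invariant and molecular weights.** `invariant_q()` integrates
$q^2[I(q) - B]$ by trapezoid with a Guinier fill-in on $[0, q_1]$ and an
optional $q^{-4}$ tail. Three MW estimators are provided:
`mw_from_i0()` (absolute scale, needs concentration),
`mw_fischer()` (truncated invariant: apparent Porod volume
$V' = 2\pi^2 I(0)/Q'$ at a truncation $q_\mathrm{max}$, power-law
corrected to a true volume, converted to mass at 1.37 g cm$^{-3}$) and
`mw_porod_petoukhov()` (full-tail Porod volume over the empirical
1.66 Å$^3$/Da divisor). The truncated-invariant correction coefficients
shipped in `mw_constants()` were recalibrated in-package by applying the
published procedure to noise-free analytic sphere curves ($R = 15$–60 Å,
one coefficient pair per $q_\mathrm{max} \in \{0.2, 0.25, 0.3\}$ Å$^{-1}$,
power-law fit $V = e^a V'^\beta$, residuals $\le 8\%$); the original
tabulation was not available to transcribe, and the constants file says
so. Note the empirical Porod divisor is calibrated on *experimental*
protein volumes: on ideal homogeneous simulated particles it reads
systematically $\sim$25–30% below the density-based conversion, and the
cross-method consistency test asserts agreement at that level, not
closer.

**Setting merges.** `merge_settings()` scales each non-reference curve by
the weighted least-squares ratio over the $q$ overlap (exact on
constructed inputs); a joint smooth-$p(r)$ refinement is available, and it
is the sole criterion (with a warning) when there is no overlap.

## The synthetic-data module

The generator emulates the structure of the real experiment, not its
absolute size:

* **Mock receptor structures** (`make_mock_structure()`): poly-alanine
  residues (N, CA, C, O, CB at fixed local offsets) scattered through
  three stacked cylindrical layers — a narrow membrane stem
  ($z \in [-40, 0]$ Å, radius 17 Å) under two wide extracellular layers —
  with residues allocated by receptor-like mass fractions
  (0.18/0.36/0.46), since the stem is narrow but densely packed. The open
  state widens and lifts the top layers at the same mass. 220 residues
  give hydrated sizes of $R_g \approx 49/55$ Å and $D_\mathrm{max}
  \approx 145/160$ Å for closed/open.
* **Simulated curves** (`simulate_curve()`): 120 log-spaced points on
  $q \in [0.006, 0.2]$ Å$^{-1}$ (the usable instrument range), a
  $\sigma_q = 0.1\,q/2.355$ resolution column (10% FWHM wavelength
  spread), additive Gaussian noise
  $\sigma_i = 0.002\,I_\mathrm{max} + 0.03\,I_i$ (percent-level relative
  noise with a floor, the character of reduced SANS errors), sample
  concentration 0.54 µM, background $\approx$ 1% of $I(0)$, all
  seed-deterministic.
* **The corpus** (`corpus()`): one curve per model, including a 1.5%
  oligomer case ($\gamma$ in the regime where the F-test, not the eye,
  must decide) and a heavily aggregated case with no valid Guinier
  region; a JSON manifest records every generating parameter, and
  regeneration at the same seed is byte-identical.

What the mock does *not* emulate: it is a sparse point assembly, so its
van der Waals volume is far below the envelope its points span, and
volume-based MW estimators report the scattering volume of the envelope
rather than the composition mass (their absolute accuracy is established
on analytic spheres instead). Its small subunit radius (16.6 Å vs
$\sim$47 Å for a full-size receptor) also means a given oligomer fraction
and size carry a proportionally larger intensity share, so model-free
sizes of the simulated oligomer samples are inflated more strongly than
for real receptor data. Passing tests therefore demonstrate the
correctness of the machinery under controlled conditions, not the
field behaviour of any particular instrument.

## Numerical choices

* Debye sums: exact double sum below 800 points; above, pair distances
  collapse onto 0.05 Å bins carrying the contrast-weighted mean distance
  per bin (first-order binning error cancels), which matches the exact
  sum to better than $10^{-4}$ even in deep form-factor minima.
* Problem sizes: 220-residue mocks (1100 atoms + $\sim$500 beads), 120
  data points per curve, 100-point $p(r)$ grids, 20 recovery replicates
  and 400 F-test null replicates — chosen so the full test suite and the
  acceptance script each complete in well under a minute of compute while
  leaving the statistical assertions sharp.
* $q = 0$ is always evaluated through analytic limits
  ($\operatorname{sinc}(0) = 1$, the Teixeira forward limit).
* Degenerate inputs error early and informatively: empty structures,
  waters-only files, malformed coordinate fields (with line numbers),
  unknown elements/residues (by name), zero total contrast, invariants
  $\le 0$ (MW flagged unreliable rather than returned).

## Known limitations

* mmCIF is not parsed; PDB fixed-column only.
* The hydration shell is a single bead layer; no second shell, no
  cavity waters, no detergent corona (matched out in the intended
  experiments).
* The membrane slab is user-defined; there is no automatic
  membrane-orientation prediction.
* The fractal dimension is fixed, not fitted, and oligomer
  polydispersity is not modelled.
* The IFT evidence is the Gaussian approximation at the unconstrained
  ridge solution; it ranks $(\alpha, D_\mathrm{max})$ well (the sphere
  oracle confirms this) but is not a full posterior.
* Manual judgement in choosing $\alpha$ and $D_\mathrm{max}$ "near the
  automatic values", as practitioners do, cannot be reproduced; both
  knobs are exposed instead.
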