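---
title: "Models and methods behind ephquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ephquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephquant)
library(ggplot2)
```

ephquant implements the quantitative analyses used to characterize the
intracellular region of a receptor tyrosine kinase (the EphA2 receptor
serves as the motivating system) and its lateral association in the plasma
membrane: monomer–dimer FRET equilibrium fitting, fluorescence intensity
fluctuation (FIF) brightness analysis, primary SEC-SAXS analysis, HDX-MS
uptake arithmetic, and kinase-screen / phosphosite-cluster statistics. Every
pipeline stage has a synthetic-data generator with known ground truth, so
the whole package is testable without any experimental downloads. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic tests do and do not show
about real data.

## Monomer–dimer FRET equilibrium

A receptor that dimerizes in the membrane obeys two-dimensional mass
action: with total protomer density $[T]$ and dissociation constant
$K_{diss}$ (both in the same surface-density units), the dimeric fraction
is

$$f_D = \frac{[T] - \frac{K_{diss}}{4}\left(\sqrt{1 + 8[T]/K_{diss}} - 1\right)}{[T]},$$

and the FRET efficiency measured in a membrane region with acceptor
fraction $x_A$ is $FRET = f_D\,x_A\,\tilde{E}$, where $\tilde{E}$ is the
intrinsic FRET of a donor–acceptor dimer — a structural constant set by the
fluorophore separation and orientation, independent of dimerization
propensity. At $[T] = K_{diss}$ the dimeric fraction is exactly one half.

Numerically we evaluate $f_D$ through the equivalent form
$f_D = 8x/(1+\sqrt{1+8x})^2$ with $x = [T]/K_{diss}$. The textbook form
subtracts two nearly equal numbers when $x$ is small; the rewritten form
has no cancellation and is accurate to machine precision over at least ten
orders of magnitude of $x$, which removes the need for a series-expansion
branch. The unit tests pin this against an independent brute-force
mass-action root finder.

`fit_dimerization()` fits $FRET/x_A$ against $[T]$, each point weighted
equally (inverse-variance weights are accepted; the measurement protocol
itself does not dictate a weighting). Two numerical choices matter:

* parameters are optimized as $\log K_{diss}$ and
  $\mathrm{logit}\,\tilde{E}$, which enforces positivity and the
  $\tilde{E} \in (0,1]$ bound without a constrained solver;
* because the conditionally optimal $\tilde{E}$ given $K_{diss}$ is
  available in closed form, the objective is first profiled on a
  log-spaced multi-start grid of $K_{diss}$ values spanning
  $10^{-2}$–$10^{4}$ times the median density, then polished with
  Nelder–Mead/BFGS steps (relative tolerance $10^{-10}$, at most 500
  iterations) and a final one-dimensional Brent pass on the profile.

Standard errors come from the Jacobian curvature at the optimum (the usual
asymptotic nonlinear-least-squares approximation); `bootstrap_fit()`
provides case-resampling percentile intervals when the asymptotics are in
doubt. Fully dimeric data cannot identify $K_{diss}$ — any sufficiently
small value fits equally well. The fitter detects this either as a flat
$K_{diss}$ profile (flat region wider than two decades at a relative
tolerance of $10^{-4}$ on the objective), reporting the smallest value in
the flat region, or as an optimum escaping below the multi-start grid; both
set the `non_identifiable` flag.

The generator `sim_fret_samples()` draws densities log-uniformly and
acceptor fractions uniformly, applies the forward model, and adds Gaussian
noise on the efficiency clipped to $[0,1]$ — the simplest noise model
consistent with the scatter seen in dimerization-curve experiments, chosen
as a package default because measurement protocols rarely publish their
efficiency noise law. Defaults (300 regions, noise SD 0.03, densities
spanning 10–4000 units around a $K_{diss}$ of 200, acceptor fractions
0.3–0.8) emulate a typical single-construct imaging session. What the
recovery tests show is that the estimator is unbiased and precise *under
this noise model*; they do not exercise spectral-unmixing errors,
density-calibration drift, or cell-to-cell heterogeneity in $\tilde{E}$.

## FIF molecular brightness

FIF computes, in each 15×15-pixel segment of a hand-outlined membrane
image, the mean intensity $\langle I\rangle$ and variance $\sigma^2$, and
from them a molecular brightness. For an analog detector
$\varepsilon = (\sigma^2 - \sigma_D^2)/\langle I\rangle$ with detector
noise variance $\sigma_D^2$; for a photon-counting detector
$\varepsilon = \sigma^2/\langle I\rangle - 1$, so pure shot noise gives
$\varepsilon = 0$ and an oligomer of $s$ labelled protomers emitting $q$
photons each per exposure gives $\varepsilon \to q\,s$ in a pure
population. For a mixture of species with per-pixel means $\mu_s$ the
law of total variance gives the apparent brightness
$\varepsilon_{app} = q \sum_s \mu_s s^2 / \sum_s \mu_s s$, which the
generator `sim_membrane_image()` realizes exactly: per pixel, species
counts are Poisson, photons are Poisson given the fluorophore number.

Design choices: segments are anchored at the mask bounding-box origin and
partial edge segments are discarded, so every segment has exactly 225
pixels and variance estimates are comparable; the per-segment variance is
the unbiased (n−1) estimator; negative-brightness segments (possible from
noise) are kept in distributions but excluded from concentration proxies.
Brightness histograms default to log-spaced bins over the central 99% of
positive brightness values — brightness distributions in the field are
displayed on logarithmic axes — with a linear-bin option that can also hold
negative values. Each cell's histogram is normalized to unit sum and cells
are the unit of averaging, with the standard error taken across cells;
segment counts per cell are deliberately not equalized.

The generator emulates spatial Poisson statistics only: no point-spread
function, no diffusion or temporal correlation, no cell-to-cell expression
variability beyond what the user scripts. Passing the oracle tests
therefore validates the estimator arithmetic and its sampling behaviour,
not robustness to optical blur (which correlates neighbouring pixels and
biases $\sigma^2$ downward in real images).

## Primary SAXS analysis

Four operations reproduce the desk half of a standard SEC-SAXS analysis.

**Guinier fitting.** `guinier_fit()` fits $\ln I$ vs $q^2$ on the largest
low-$q$ window satisfying $q_{max} R_g \le 1.3$ (the standard globular
cutoff; configurable), expanding from the five lowest-$q$ points and
refitting as the window grows. Positive-slope windows are tolerated while
small (they occur by noise) but an entirely positive-slope low-$q$ region —
the signature of aggregation or interparticle interference — is an error,
not a number.

**Debye forward model.** For a point model,
$I(q) = \sum_{ij} w_i w_j \,\mathrm{sinc}(q r_{ij})$. The direct double
sum is $O(n^2)$ per $q$; the default path aggregates pairs into a distance
histogram (bin width 0.1 Å) and evaluates the sum per bin at the
*weighted mean* distance of the bin, which makes the first moment exact and
leaves an error of order (bin width)² — under $10^{-3}$ relative against
the direct sum in the tests. Point weights default to 1: the package works
at the shape level, and per-atom form factors and the hydration shell are
intentionally out of scope (they rescale intensities but barely move
$D_{max}$ or $R_g$ at this scale).

**P(r) from coordinates.** A weighted pair-distance histogram (1 Å bins)
normalized to unit area, with $D_{max}$ the maximum pairwise distance and
$R_g^2 = \int r^2 P(r)\,dr / 2$.

**Indirect Fourier transform.** `ift_pr()` discretizes
$I(q) = 4\pi\int_0^{D_{max}} P(r)\,\mathrm{sinc}(qr)\,dr$ on a 101-point
r-grid per candidate $D_{max}$ (trapezoid quadrature, boundary values
pinned to zero), adds a second-difference smoothness penalty whose weight
is chosen by a discrete L-curve corner heuristic unless supplied, and
solves under $P \ge 0$ by non-negative least squares. Candidates whose
weighted $\chi^2$ exceeds twice the best candidate's are rejected (an
undersized support simply cannot fit the data, and its $\chi^2$ blows up by
orders of magnitude); among the survivors a score combining relative
$\chi^2$, an oscillation count on the recovered curve, and a mild parsimony
term in $D_{max}$ picks the winner, and the reported $D_{max}$ is the end
of the recovered support after trimming trailing mass below $10^{-3}$ of
the peak. This is a package-designed perceptual criterion in the spirit of,
but not bit-identical to, the classical regularized IFT programs, whose
exact regularization settings are generally unpublished; comparisons
against them should allow a few Å in $D_{max}$.

The toy structures (`sim_toy_structure()`) have closed-form geometry —
a solid sphere of radius $R$ has $R_g = R\sqrt{3/5}$ and $D_{max} = 2R$, a
dumbbell with centres $d$ apart has $D_{max} = d + 2R$ — so the full
forward–inverse round trip is checkable: on the default fixtures (1500
beads, 90-point curves from $q$ = 0.008 to 0.35 Å⁻¹) the recovered
$D_{max}$ is within 10% and $R_g$ within 3%, and the three $R_g$ routes
(coordinates, Guinier, $P(r)$ moment) agree within 2% on the sphere. The
Guinier route carries a small positive systematic (≈1.9% on an ideal
sphere) because the Guinier approximation is truncated at
$q R_g = 1.3$ — a well-known property, not a bug; tightening the cutoff
trades it for noise sensitivity. These fixtures are noiseless and
monodisperse by construction; they validate the inversion machinery, not
buffer-subtraction or frame-averaging choices, which happen upstream of
this package.

## HDX-MS uptake arithmetic

Centroid-based uptake analysis is deliberately plain arithmetic, done
carefully. Raw uptake is the replicate mean of (deuterated centroid −
undeuterated centroid); the global back-exchange correction divides by
$(1 - f)$ with $f = 0.25$ by default, the typical value determined from
disordered-termini standards (so 1.5 Da raw becomes 2.0 Da corrected);
relative fractional uptake (RFU) divides by the peptide's maximum number of
exchange-competent amides. That maximum is `length − 2 − interior
prolines`: the N-terminal amide is lost with the residue, the second
residue's amide back-exchanges too fast to observe, and prolines have no
amide proton. This convention is standard but not universal, so
`convention = "minus1"` is available.

Difference profiles between two conditions use
$\Delta RFU = RFU_a - RFU_b$ on the intersection of peptide/time coverage,
with a pooled SD $\sqrt{sd_a^2 + sd_b^2}$ built from the *replicate* SDs
(not standard errors). A peptide/time pair is flagged when
$|\Delta RFU| > 2 \times$ pooled SD. Using replicate SDs makes the
threshold conservative — roughly 3.5 noise standard deviations of the
difference of triplicate means — which is why the 100-seed synthetic study
(eleven 10-residue peptides tiling a 60-residue construct, replicate SD
0.05 Da, a +0.2 RFU bump in a contiguous block) detects the shifted block
with 100% sensitivity while flagging under 5% of unshifted records. The
multiplier is configurable; published difference plots shade "significant"
regions without stating a rule, so the package exposes the threshold rather
than guessing any particular study's.

Residue maps average the RFU of all covering peptides with equal weight
(shortest-peptide and back-calculation schemes are out of scope) and mark
uncovered residues explicitly. The generator's exchange model is
single-exponential per amide with a shared back-exchange factor; it does
not emulate EX1 bimodality, proline cis/trans effects, or peptide-specific
back-exchange, so agreement on synthetic data validates the bookkeeping,
not those physical complications.

## Kinase-screen and phosphosite-cluster statistics

The screen analytics are deterministic table operations with explicit
conventions: ranking sorts by descending signal with ties broken
alphabetically; the cumulative-fraction column supports "top $k$ carry
share $s$" queries; `threshold_count()` uses a strict inequality, matching
">50,000 CPM"-style statements; CPM (radioassay) and RLU (luminescent
assay) signals are never mixed in one ranking. Site preference compares
substrate-peptide variants that differ in exactly one site's availability
(Ala replacement) or priming (pre-phosphorylation), after arithmetically
averaging variants that differ only in their last residue; ratio
thresholds of 3× ("prefers") and 10× ("mainly phosphorylates" /
"requires priming") are package defaults, configurable and reported,
since such comparisons are described qualitatively in the literature.
Multisite statistics count observations with two or more simultaneously
modified sites among the cluster (S892/S897/T898/S899/S901 in the
motivating system), and `site_correlation()` is plain Pearson correlation
across cell lines with constant columns flagged rather than silently
dropped.

The synthetic screen (`sim_kinase_table()`) is built, not sampled, to its
headline property: signals follow a rank power law whose exponent is solved
by root finding so the top $n_{top}$ kinases carry exactly the requested
share of total signal, then log-normal jitter is applied within the top and
tail groups and each group rescaled, with the jitter automatically damped
if it would ever let a tail kinase overtake the top group. This makes the
share exact for every seed. The fixture used to exercise the
count-above-50,000-CPM behaviour additionally rescales the table so the
24th and 25th ranked values straddle the cutoff; it is a synthetic
emulation of a published screen's shape, not data.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; a dataset is
generated under one seeded RNG whose state is restored afterwards, so
generation is bit-reproducible and order-independent. The default test and
acceptance workloads were sized as the smallest problems on which the
statistical claims are stable: 10⁴ (T, K) pairs for the equilibrium
oracle, 30 seeds × 300 regions for FRET recovery, 150×150-pixel images
(100 segments) for brightness, 1500-bead fixtures with 90-point curves for
the SAXS round trips, and 100 seeds for the HDX difference study.

## Known limitations

* Surface densities are never converted to molecules/µm²; calibration
  against purified-fluorophore standards is out of scope, so $K_{diss}$ is
  reported in the data's own units.
* The IFT is not a reimplementation of any specific legacy program; its
  regularization choices are its own, documented above.
* FIF assumes uncorrelated pixels (photon-counting statistics); optical
  blur violates this and biases brightness downward in real images.
* HDX significance is a per-record threshold rule, not a hierarchical
  model; peptides with very few replicates get noisy pooled SDs.
* The site-preference labels are rule-based summaries of pairwise ratios,
  not a statistical test; they inherit the configured thresholds.
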