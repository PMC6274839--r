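---
title: "Measuring coiled-coil bending flexibility from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coiled-coil bending flexibility from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilflex)
```

## The problem

Tropomyosin (Tpm) and other two-chain alpha-helical coiled-coils work as
semi-rigid mechanical elements: how stiffly the molecule resists bending
determines, for instance, how cooperatively a Tpm strand transmits regulatory
displacements along an actin filament. Molecular-dynamics (MD) simulation
gives access to this stiffness: a long trajectory of the molecule in a thermal
bath samples its bending fluctuations, and the fluctuations encode the
persistence length. `coilflex` implements that analysis as a reusable,
testable package, together with a synthetic ensemble generator with known
ground truth so every estimator in the chain can be validated by parameter
recovery rather than by eye.

## From atoms to an axis

The molecular axis of the coiled-coil is approximated per snapshot by a
polygonal line:

1. Both chains are cut into short residue segments of `segment_length`
   residues (default 11, about three helical turns) whose consecutive
   segments share one residue; with the defaults the segments span residues
   106–116, 116–126, ..., 206–216. The shared endpoint residues carry weight
   1/2 in the segment centroid so that each residue contributes unit total
   weight (`segment_scheme()`, `weighted_centroid()`).
2. Per chain and segment, the weighted centroid of the C-alpha atoms is
   computed; the midpoint between the two chains' centroids is a polygon
   vertex (`build_axis()`).
3. Unit vectors between consecutive vertices are the axis tangents
   \(t_{ij}\) (position \(i\), snapshot \(j\)). The arc-length coordinate of
   tangent \(i\) is the cumulative time-mean vertex spacing, so the whole
   trajectory shares one fixed abscissa \(s_i\) (with \(s_1 = 0\); only
   differences in \(s\) enter the estimators, so the choice of origin is
   immaterial).

The same per-chain centroids give the inter-helix distance profile
\(d_i = \langle |c^{A}_{ij} - c^{B}_{ij}| \rangle_j\)
(`helix_distance_profile()`), the local separation of the two helices.

## The worm-like-chain estimators

For an intrinsically straight elastic rod in a thermal bath (worm-like
chain), tangent correlations decay exponentially with contour distance,

\[\langle (t(s), t(0)) \rangle = e^{-s/L_p},\]

with persistence length \(L_p = k / (k_B T)\) for bending stiffness \(k\)
(`stiffness_from_lp()`, `lp_from_stiffness()`). Real coiled-coils are
intrinsically *curved*, and correlating with the first tangent then conflates
deterministic curvature with thermal flexibility. The estimator implemented
as the default therefore correlates each tangent with its own normalized
time average,

\[c_i = \big\langle (t_{ij}, \langle t_i \rangle) \big\rangle_j,
  \qquad
  \langle t_i \rangle = \frac{\sum_j t_{ij}}{\big|\sum_j t_{ij}\big|},\]

which absorbs any static curvature into \(\langle t_i \rangle\) and leaves
only the fluctuation about it (`correlation_profile(reference = "mean")`;
the classic first-tangent variant is available as `reference = "first"`).
On synthetic rods with a 5-degree built-in bend per joint the mean-tangent
estimator recovers the generator's \(L_p\) to within a few percent while the
first-tangent estimator underestimates it several-fold — that comparison is
recomputed by `scripts/acceptance.R` on every run.

\(L_p\) is extracted from \(\ln c_i\) versus \(s_i\) by two slope
estimators (`fit_lp()`): ordinary least squares over all positions, and the
secant through the first and last points. Both report
\(L_p = -1/\mathrm{slope}\). Slopes above \(-10^{-12}\,\mathrm{nm}^{-1}\)
are reported as `Inf` (a rigid rod), not as a huge number.

### Why the least-squares fit has a free intercept

The worm-like-chain law forces \(\ln c(0) = 0\), but a measured profile
carries position-independent decorrelation (superposition residuals,
centroid noise) that shifts the whole line down without changing its slope.
A free intercept absorbs that shift; the theoretical zero intercept can be
forced with `intercept = FALSE`. Only the slope enters \(L_p\) either way.

### The body frame matters

The mean tangent \(\langle t_i \rangle\) is only meaningful in a body-fixed
frame. A subtlety we established with the synthetic generator: if every
frame is superposed on the *whole* molecule (mean-structure Kabsch fit over
all C-alphas), the fitting spreads the fluctuations symmetrically — both ends
wiggle relative to the best-fit frame and the middle is quiet — so \(c_i\)
becomes U-shaped in \(s\) and carries no exponential decay at all; the fit
then reports a rigid rod regardless of the true stiffness. The decaying
profile presumes a frame *anchored at the start of the chain*, in which
fluctuations accumulate along the contour. `run_analysis()` therefore
superposes on the C-alphas of the **first segment only** (both chains) by
default; with that anchoring the estimators recover the generator's
\(L_p\) to ~2% at the study geometry. `superpose()` itself accepts any
selection, uses a proper rotation + translation only (isometry), and
iterates its mean-structure reference to convergence. Clamped synthetic
ensembles (first tangent fixed to +z) need no alignment at all, which is
how estimator testing is isolated from alignment testing.

### Uncertainties and comparisons

Consecutive MD snapshots are strongly autocorrelated, so naive SEMs over
frames would be optimistic. All standard errors use block averaging: the
frames are split into `n_blocks = 8` contiguous blocks (1000 frames each at
the study scale of 8000 analyzed snapshots) and the SEM is the scatter of
block means over \(\sqrt{8}\). Condition comparisons (`compare_lp()`,
`compare_conditions()`) report the ratio of full-trajectory estimates,
formatted to two decimals as `"least-squares(secant)"`, and a two-tailed
equal-variance Student's t-test on block-wise \(L_p\) estimates — the block
is the replicate unit, since per-frame estimates are not independent.
Display rounding (ratios to two decimals, percent changes to the nearest
percent, \(L_p\) to one decimal) happens only in the `_label` columns;
full precision is kept everywhere else.

### Local flexibility

The local slope of \(\ln c\) at interior position \(i\) by central
differences, \((\ln c_{i+1} - \ln c_{i-1}) / (s_{i+1} - s_{i-1})\), is a
per-position flexibility map (`flexibility_profile()`): for a uniform chain
all local slopes equal \(-1/L_p\); a locally soft region appears as the
steepest (most negative) slope and is reported as the author-numbered
residue interval its tangent pair spans. On generator ensembles with one
joint softened 5-fold, the steepest slope localizes the soft joint in at
least 9 of 10 seeds (recomputed in the acceptance script).

## Main-chain hydrogen bonds

Regional backbone H-bond occupancy complements the mechanical picture: a
locally melting helix loses its i+4 -> i amide-to-carbonyl bonds.
`detect_mainchain_hbonds()` counts a bond when the donor-acceptor N···O
distance is at most 0.35 nm and, when an amide hydrogen is present, the
H–N···O angle at the donor is at most 30 degrees (the common MD-analysis
convention; both cutoffs are configurable via `hbond_criterion()` since
counting conventions differ between tools). Donors within one residue of
the acceptor on the same chain are excluded; inter-chain backbone bonds are
counted. A geometric fact worth knowing when comparing conventions: at
ideal alpha-helix geometry the i+2 and i+3 carbonyls *also* sit within
0.35 nm of the donor nitrogen, so distance-only counting triple-counts the
helical pattern — the angle criterion is what isolates the i+4 bonds, which
is why the synthetic builder places amide hydrogens by default.

`region_hbond_stats()` aggregates per-frame counts over named residue
regions (possibly disjoint, both chains, assignment by donor residue — a
convention needed for bonds straddling a region boundary) and reports
mean ± SD over frames. `tpm_middle_regions()` ships the three regions
conventionally used for the Tpm middle fragment (106–129 plus 138–160;
129–138, the trypsin-cleavage neighbourhood; 161–215).

## The synthetic generator: what it emulates, what it does not

`sample_wlc_ensemble()` draws *independent* equilibrium conformations of a
discrete Kratky–Porod chain: each joint bends by a polar angle with density
\(p(\theta) \propto \exp(-(L_p/b)(1-\cos\theta))\sin\theta\) and uniform
azimuth. Sampling is by the exact closed-form inverse CDF in
\(\cos\theta\) — no small-angle approximation — so softened joints with
large angles are sampled correctly. Defaults mirror the study geometry:
11 vertices (10 tangents), segment length 1.5 nm (about one 10-residue
step of 0.1485 nm/residue), 8000 frames. Options add a deterministic
intrinsic bend per joint (curved-rod scenario), one softened joint, and
random per-frame rigid motions (to exercise the superposition path).

`build_coiled_coil_ensemble()` wraps a pseudo-atomic two-chain backbone
around a smooth centerline through the sampled vertices: two chain axes at
±0.49 nm in a parallel-transported frame, and per-residue backbone atoms
(CA, or N–H–CA–C–O) placed from cylindrical offsets measured once from an
internally built ideal straight alpha-helix (NeRF construction with
\(\phi=-57^\circ, \psi=-47^\circ\) and standard bond geometry). Because
polygon vertices are *segment centroids*, the residue span overhangs the
vertex span by half a segment per end; the builder enforces that
consistency. Round-trip accuracy: axis vertices recovered by
`build_axis()` fall within 0.05 nm of the generator centerline, tangents
within 2 degrees on rigid builds, and the inter-helix distance profile
reproduces twice the inter-axis radius.

What the generator does *not* emulate: real side chains or sequence, the
coiled-coil supertwist and knobs-into-holes packing, force-field physics,
solvent, or the temporal autocorrelation of MD frames (draws are
independent, so block SEMs on synthetic data are conservative).
Consequently, passing parameter-recovery tests demonstrates that the
estimator chain is unbiased for worm-like-chain physics at the study
geometry — not that any particular force field or sampling protocol is
adequate.

## Numerical choices and degenerate inputs

* Correlation values \(c_i \le 0\) are a hard error for the fits (the
  log-linear model is undefined; such disorder is outside the worm-like
  chain regime), and a vanishing mean tangent
  (\(|\sum_j t_{ij}| < 10^{-9} N\)) is reported as a fully disordered
  position.
* Slopes \(\ge -10^{-12}\) per nm report `Inf` persistence length; block
  estimates that come out rigid are dropped from t-tests.
* Superposition refuses collinear selections (second singular value below
  \(10^{-9}\) of the first) and needs at least three atoms; the iterated
  mean converges in 2–3 passes and the converged configuration is anchored
  by mapping its mean onto the input's first frame, which makes the
  operation exactly idempotent.
* Coordinates are stored in nm throughout; PDB angstroms are converted on
  read/write, and the TSV xyz-table dialect carries full double precision
  for synthetic round trips (PDB is limited to \(10^{-4}\) nm).
* Residue intervals are inclusive on both ends in author numbering.
* Ties in the flexibility minimum resolve to the first (N-terminal)
  position via `which.min`.

## Problem sizes used in the shipped checks

The package's own validation runs at the study scale where it matters:
persistence-length recovery uses 8000-frame ensembles, 10 tangents of
1.5 nm, \(L_p \in \{30, 100, 300\}\) nm, median over 10 seeds (agreement
within 10%); curved-rod comparisons use 8000 frames at a 5-degree per-joint
bend; soft-joint localization uses 2000-frame ensembles. Unit tests use
smaller ensembles (tens to hundreds of frames) chosen so that each check is
sharp: exact identities at machine precision, stochastic recoveries at
3-sigma block-SEM bands.

## A worked example

```{r example, eval = FALSE}
library(coilflex)

# ground-truth ensemble: Lp = 100 nm at the study geometry
w <- sample_wlc_ensemble(n_vertices = 11, b_nm = 1.485, lp_nm = 100,
                         n_frames = 2000, seed = 1)
ens <- build_coiled_coil_ensemble(w, backbone = "N-CA-C-O")

cond <- run_analysis(ens, name = "synthetic", align = FALSE,
                     regions = tpm_middle_regions())
cond
tidy(cond$fits$least_squares)
autoplot(cond$profile)
```

## Known limitations

* The correlation profile's absolute values (and hence the fitted
  intercept) depend on the superposition convention; only the slope is a
  robust stiffness readout. Cross-study comparisons should use matched
  conventions.
* The secant estimator carries no standard error of its own (two points
  define it); its scatter is accessible through block-wise estimates.
* H-bond counts depend on the criterion; the defaults follow the common
  0.35 nm / 30-degree convention, and comparisons against tools with other
  conventions require matching `hbond_criterion()` settings.
* The reader supports multi-model PDB and the TSV dialect only; binary
  trajectory formats (XTC/DCD) should be converted upstream or contributed
  behind the same reader interface.
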