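---
title: "Localizing ectopic activation origins with fastest-route simulation and time warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing ectopic activation origins with fastest-route simulation and time warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectoloc)
```

## The problem

A focal ventricular activation — an ectopic beat or a pacing stimulus —
starts at one point on the heart surface and spreads outward. Knowing the
origin noninvasively, from many-electrode body surface potential maps
(BSPMs) plus the patient geometry, guides ablation and pacing-lead
assessment. `ectoloc` implements a model-based full search: every node of
a triangulated heart surface is tried as the origin, its activation
sequence is simulated, mapped to electrode potentials, and compared with
the measured map. The node whose simulated map is most similar is
reported as the origin.

Two similarity measures are supported:

* **Correlation (FRA)** — the classic fastest-route approach scores each
  candidate by the global Pearson correlation between the simulated and
  measured maps.
* **Reciprocal DTW distance (FRA-DTW)** — the candidate and measured maps
  are first aligned by multichannel dynamic time warping, which absorbs
  *local* delays in the temporal profile; the score is the reciprocal of
  the optimal warping cost.

The warping step is the point of the package. The fastest-route model
assumes one global conduction velocity (CV). Real ventricles — scar,
bundle branch block, CRT patients — conduct inhomogeneously, so the
simulated temporal profile is locally too fast or too slow even when the
origin is correct, and the correlation score drags the estimate away from
the true origin. Monotone temporal realignment compensates for exactly
this class of model error while leaving the spatial pattern untouched.

## The forward model

**Sources.** During depolarization each point of the closed heart surface
(epicardium plus endocardium) is either at rest or activated, so the
equivalent-dipole-layer (EDL) source is fully described by the activation
times $\tau(x)$. Electrode potentials at time $t$ are

$$ y(t) = \int_{S_h} H(t - \tau(x))\, A(x)\, dx, $$

where $A(x)$ is the lead field of a unit dipole layer at $x$ and $H$ is
the Heaviside step. We take $H(0) = 1$: a node contributes from its own
activation instant, so the focus is visible in the first sample.

**Lead field.** In an unbounded homogeneous medium the potential of a
uniform double layer is proportional to the solid angle its surface
subtends at the electrode. `solid_angle_transfer()` evaluates exact
per-triangle solid angles (van Oosterom–Strackee) and lumps them
barycentrically to vertices; node area weights are kept explicit
(one-third of incident triangle areas), so `A[p, n]` is a per-unit-area
lead field and the area-weighted row sums vanish at exterior points — a
fully-on closed layer has no external field. This identity is the main
numerical self-check of the forward model and holds to machine precision.
`bounded_torso_correction()` optionally bounds the conductor with a
closed torso surface by a collocation BEM solve (deflated singular
Neumann system, zero-mean gauge). Conductivity heterogeneities (lungs,
blood cavities) are out of scope; their amplitude effect is largely
removed by the normalization below anyway.

**Propagation.** Candidate activation sequences come from a fastest-route
(Dijkstra shortest-path) model on the heart's edge graph: edge travel
time is length over CV, with the global CV 0.8 m/s by default. Transmural
edges run at half speed (`transmural_factor = 0.5`), mimicking slower
through-wall propagation. A spherical region specification multiplies the
CV of every edge whose *midpoint* falls inside the sphere — midpoint
membership is unambiguous for straddling edges and easy to test.
Propagation is along mesh edges only; no obtuse-angle or eikonal
correction is applied, matching the adjacency-graph formulation of the
fastest-route method.

## The inverse search

For a reference map $Y \in \mathbb{R}^{P \times T}$ with sampling
interval `dt`, every candidate sequence is linearly scaled so its total
duration equals the reference span $(T-1)\,dt$ (the QRS-duration matching
step of the fastest-route method), synthesized at the same sampling, and
both maps are normalized column-wise: each time sample is centered and
scaled to unit population variance across electrodes; zero-variance
columns map to zero. Normalization is applied to both test and reference
maps for *both* scoring methods, so all scores are amplitude-invariant.

"Column-wise" is read as per-time-sample (the columns of a $P \times T$
map are the instants that DTW realigns); per-electrode normalization
would destroy the spatial pattern that localizes the focus.

**DTW.** With equal-length sequences, a warping path
$p = (p_1, \dots, p_L)$, $p_l = (n_l, m_l)$, must satisfy the boundary
conditions $p_1 = (1,1)$, $p_L = (T,T)$, componentwise monotonicity, and
steps in $\{(1,0), (0,1), (1,1)\}$. The total cost of a path sums the
euclidean distances between the paired columns, and the optimal cost is
found by dynamic programming on the accumulated matrix with a sentinel
row/column ($D(0,0) = 0$, the rest of the border $\infty$). Backtracking
starts at $(T,T)$; the printed boundary rule (pure horizontal/vertical
moves when $n = 1$ or $m = 1$) is implemented literally, and argmin ties
prefer the diagonal predecessor, then $(n-1, m)$, then $(n, m-1)$ —
diagonal-first tie-breaking makes identical inputs return the diagonal
path, which the identity tests rely on. No global band constraint is
imposed. Path indices are reported 1-based; costs accumulate in double
precision and the returned total is re-checked against the independent
re-summation along the path at relative tolerance `1e-12`.

An enumeration oracle (`enumerate_warping_paths()`, feasible only for
$T \le 7$; the path counts are the central Delannoy numbers 1, 3, 13, 63,
...) provides an implementation-independent minimum for testing; the
dynamic program must agree with it exactly.

A zero DTW distance maps to a `+Inf` reciprocal score and wins the
argmax; this occurs only under exact self-consistency (the "inverse
crime" checks). Score ties are broken toward the lowest node index and
reported.

## Synthetic geometry

No clinical geometry ships with the package; `generate_heart()` builds a
synthetic stand-in: an outer (epi) and inner (endo) half-ellipsoid shell
joined at a basal rim, closed, outward-oriented, with per-vertex labels.
Defaults — 90 mm apex-to-base, 50 mm equatorial diameter, 10 mm wall —
are typical adult ventricular dimensions. A seeded azimuthal jitter
breaks the exact rotational symmetry so that localization is not helped
by symmetry artifacts.

How the two surfaces connect transmurally is not dictated by the method;
our construction keeps it explicit and testable: the rim annulus carries
an intermediate *unlabeled* vertex ring, so no mesh edge joins epi to
endo directly and on-surface geodesics (used for localization errors)
must route through the rim; separately, each endo vertex is joined to its
nearest epi vertex by a *connector* edge flagged transmural. Connectors
conduct (at half speed) but are excluded from geodesic distances. With
the default wall thickness the double crossing (≈ 40 mm equivalent path)
never shortcuts same-surface routes, so uniform-CV activation times equal
geodesic distance over CV on each sub-surface — a tested invariant.

`generate_torso()` places electrodes quasi-uniformly (Fibonacci lattice
under a seeded rotation) on an ellipsoid enclosing the heart with a 40 mm
default standoff; clinical mapping systems use up to 240 electrodes, the
evaluation battery uses 64. When a torso mesh is requested the electrodes
are projected radially onto the faceted surface so they are exact
collocation points for the BEM.

What the generator does **not** emulate: two ventricles and a septum,
fiber anisotropy beyond the single transmural factor, repolarization,
measurement noise, electrode misplacement, and torso inhomogeneity.
Passing tests therefore demonstrate internal correctness and the
*mechanism* by which warping absorbs CV heterogeneity — not clinical
accuracy on real recordings.

## Evaluation design

The study conditions for the slow-conduction scenario are: a spherical
region of 20 mm radius with CV reduced three-fold, centered about 60 mm
from the focus; global CV 0.8 m/s; and the *unaltered* global-CV times
matrix for both search methods. Under these conditions the correlation
estimate is displaced away from the slow region (negative projection of
the displacement onto the focus-to-region axis) while the warped search
recovers the origin — the qualitative signature reported for this class
of methods. The magnitude of the shift is geometry-specific and is not a
target.

`scenario_battery()` repeats the design with randomized draws: the focus
is uniform over nodes, the region center is a node 40–70 mm (geodesic)
from the focus, radius 15–25 mm, CV reduction 2.5–3.5. Scenarios whose
draws leave no vertex in the distance band are regenerated with an
advanced seed and counted. Paired geodesic errors are summarized as mean,
SD, median, quartiles (type-7 interpolation; the convention is otherwise
arbitrary), min/max, and the correct-surface ratio R; mean/SD use the
sample (n−1) convention. Uncertainty comes from BCa bootstrap intervals
(1000 replications, 2.5/97.5 percentiles, Mersenne-Twister, seeded);
method comparison uses the Wilcoxon signed-rank test with zero
differences dropped — paired localization errors on a mesh do tie — with
an exact two-sided p for up to 25 nonzero pairs (a shift-algorithm
convolution over doubled midranks handles ties exactly) and a
tie-corrected normal approximation beyond. The BCa bias term counts
replicates tying the point estimate with half weight: the bootstrap
distribution of a median of 20 values has atoms, and a strict count
biases $z_0$ on symmetric samples. On a single-ventricle mesh the
correct-surface ratio is epi/endo only; there is no LV/RV chamber
assignment.

Problem sizes used by the tests and the acceptance script — chosen to
exercise the method at realistic scale while staying cheap to reproduce:
inverse-crime exactness on an 812-node heart with 64 electrodes and 2 ms
sampling (≈ 70–120 samples per beat), the slow-CV scenario on a 554-node
heart, and a 20-scenario battery on 344-node hearts. The sampling
interval matters little: the search scales candidate durations rather
than resampling signals, which is equivalent under Heaviside sources and
cheaper.

## Numerical choices and degenerate inputs

* Vertex indices are 1-based everywhere in R; 0-based file formats (OFF,
  PLY, VTK) are converted at the I/O boundary.
* An electrode coinciding with a heart node makes the solid angle
  singular and is rejected by name; electrodes inside the heart are
  rejected.
* Disconnected conduction graphs yield `Inf` travel times with a warning;
  all-zero activation sequences cannot be duration-scaled and are
  rejected.
* Constant (zero-variance) BSPM columns normalize to zero columns rather
  than raising; a fully constant map correlates as 0 with a warning.
* Degenerate (all-equal) bootstrap samples collapse the CI to the
  constant; all-zero Wilcoxon differences give p = 1 with a warning.
* The deflated BEM system fixes the Neumann nullspace; the zero-mean
  gauge over electrodes is applied and verified.

## Known limitations

The synthetic geometry has a single ventricle-like cavity, so septal and
right-ventricular phenomenology (notably the thin-wall epi/endo
misclassification seen clinically) is outside what the battery can show.
Only depolarization is modelled — no T wave, no repolarization
heterogeneity. The fastest-route model itself ignores wavefront curvature
and anisotropy beyond the transmural factor. The subsequent nonlinear
least-squares refinement of activation times, for which the full search
provides the initial estimate in clinical pipelines, is deliberately not
implemented.

## A worked example

```{r example, eval = FALSE}
heart <- generate_heart(n_subdiv = 4, seed = 11)
torso <- generate_torso(heart, n_electrodes = 64, standoff = 40, seed = 12)
A     <- solid_angle_transfer(heart, torso)

# reference beat: focus on the lateral epicardium, slow region 60 mm away
v     <- heart$mesh$vertices
cand  <- which(heart$mesh$labels == "epi" & abs(v[, 3] + 45) < 8)
focus <- cand[which.max(v[cand, 1])]
ctr   <- vertex_at_geodesic_distance(heart, focus, 60, label = "epi")
slow  <- region_spec(v[ctr, ], radius = 20, cv_factor = 1 / 3)
g_mod <- build_conduction_graph(heart, 0.8, regions = list(slow))
act   <- activation_from_focus(compute_times_matrix(g_mod), focus)
ref   <- simulate_reference_bspm(heart, A, act, focus, dt = 2)

# search with the unaltered global-CV model
times <- compute_times_matrix(build_conduction_graph(heart, 0.8))
fit   <- localize(heart, A, times, ref, method = "fra_dtw", true_node = focus)
fit$result
```
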