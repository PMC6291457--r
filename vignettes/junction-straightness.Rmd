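---
title: "Junction straightness dynamics and the scaled average cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction straightness dynamics and the scaled average cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ajdyn)
```

## The problem

During epithelial contraction — the amnioserosa of *Drosophila* dorsal
closure is the motivating system — cells shrink their apical area while
their E-cadherin adherens junctions shorten in step, so that the junctions
stay taut but not overstretched. `ajdyn` quantifies this length control.
The central observable is the junction **straightness**

$$ s = \frac{d_v}{L} \in (0, 1], $$

the ratio of the inter-vertex distance $d_v$ (straight-line separation of
the two tricellular vertices) to the path length $L$ (arc length of the
junction trace). A taut junction has $s = 1$; ruffles push $s$ below 1.

## The model

Both lengths shrink exponentially, with separate rates:

$$ \frac{\mathrm{d} d_v}{\mathrm{d} t} = -k_c\, d_v, \qquad
   \frac{\mathrm{d} L}{\mathrm{d} t} = -k_j(s)\, L, $$

where $k_c$ is the tissue contraction rate and $k_j$ the junction-removal
rate. Straightness then obeys $\dot s = (k_j(s) - k_c)\, s$. With constant
rates this has no preferred straightness — $s$ grows or decays
exponentially. Length control arises because removal is
straightness-dependent, with a decreasing sigmoid law

$$ k_j(s) = \frac{k_{j0}}{e^{r (s - s_0)} + 1}. $$

The package default parameters are the wild-type dorsal-closure fit:
$k_{j0} = 0.0205\,\mathrm{min}^{-1}$, $s_0 = 0.9202$, $r = 68.3$, and mean
contraction rate $k_c = 0.0091\,\mathrm{min}^{-1}$. Because $k_j$ is
strictly decreasing, the balance $k_j(s^*) = k_c$ has the unique closed
form $s^* = s_0 + \log(k_{j0}/k_c - 1)/r$ whenever $0 < k_c < k_{j0}$, and
linearising around $s^*$ gives the relaxation timescale
$\tau = -1/(k_j'(s^*)\, s^*)$:

```{r}
m <- removal_rate_model()
steady_state_straightness(m)
```

Ruffled junctions ($s < s^*$) remove material faster than the tissue
contracts and straighten; taut junctions remove more slowly and relax
downwards. Convergence to $s^*$ is monotone, since the sign of $\dot s$ is
the sign of $s^* - s$:

```{r}
s <- integrate_straightness(0.7, m, seq(0, 200, by = 1))
tail(s, 1)
```

Integration uses `deSolve` (lsoda, relative tolerance `1e-9` by default);
the dynamics are non-stiff at these rates, and the tolerance is far below
every assertion made on the trajectories. The state is deliberately not
clamped at $s = 1$: geometry requires $s \le 1$, so a trajectory crossing 1
means the constant-rate assumptions have broken down, and the result is
flagged (`breakdown` attribute) rather than silently truncated.

## Rate estimation and sigmoid fitting

Given per-junction time series of $(t, L, d_v)$, `estimate_rates()`
recovers interval rates by log-ratios over consecutive windows,
$k_j = \log(L(t)/L(t + \Delta t))/\Delta t$ (and the same for $k_c$ from
$d_v$), tagged with the straightness at the interval start. The log-ratio
estimator is exact for exponential kinetics, which is why it is preferred
over finite differences here. The default window is 12.5 min, the midpoint
of the 10–15 min measurement convention. `fit_removal_rate()` then fits
the sigmoid by nonlinear least squares (`minpack.lm`, optionally
weighted by $1/\mathrm{SE}^2$), while $k_c$ is taken as the plain mean of
the contraction-rate samples — its straightness dependence is empirically
unclear, so modelling it as constant is the package's default (an explicit
choice, not a fit result).

Two biases of the interval estimator are worth knowing. First, over a
finite window the measured rate is the time average of $k_j(s(t))$, not
its value at the interval-start straightness; near the fixed point the
dynamics are slow and the bias is below 5 %, but for trajectories far
below $s^*$ a single window sweeps much of the sigmoid and the pointwise
comparison degrades (and where $k_j \to 0$ the *relative* error blows up
even though the absolute error stays small). Second, the same averaging
flattens the apparent sigmoid, biasing the fitted steepness $r$ downward.
The fixed point is much more robust than $r$: the crossing of the fitted
curve with $k_c$ stays put, which is why the end-to-end recovery test
asserts $s^*$ (within 0.005) rather than the raw steepness.

## Synthetic data

No imaging data ship with the package; every analysis stage is exercised
on generated inputs whose ground truth is known by construction.

* `make_ruffled_polyline()` builds a junction of prescribed straightness
  as a sum of transverse sinusoidal modes vanishing at the vertices, with
  seeded random coefficients; the overall amplitude is calibrated by
  bisection on the discrete arc length, so the *measured* straightness of
  the returned polyline matches the request to better than $10^{-3}$.
* `simulate_junction_ensemble()` integrates the exact model dynamics with
  the same integrator used for analysis and adds Gaussian measurement
  noise; samples violating $d_v \le L$ are resampled and counted. Initial
  inter-vertex distance defaults to 12.3 µm, the mean early-closure value.
* `make_recoil_traces()` produces post-ablation tip displacement
  $A(1 - e^{-t/\tau}) + \varepsilon$ at 1–3 Hz.
* `render_cell_movie()` renders a grid of polygonal cells with persistent
  labels, a myosin and a cadherin channel, and exact ground-truth tables.
  Interior cell–cell interfaces are ruffled polylines at the phenotype's
  target straightness (0.95 for wild type, stretched and E-cadherin
  knockdown; 0.8 for the endocytosis-blocked and E-cadherin
  overexpression phenotypes); the tissue hull is kept straight since it
  borders background, not another cell. Myosin is split between a
  junctional pool (puncta plus baseline along the outline) and a medial
  pool (drifting Gaussian foci, $\sigma \approx 15\%$ of the cell radius)
  in phenotype-specific proportions, which fixes the ground-truth
  junctional:medial ordering (stretched ≈ knockdown > wild type >
  overexpression). The pulsation period (4 min default) and the area
  oscillation amplitude are free knobs: the source imaging prints no
  period, so no quantitative claim is attached to them. The `coupling`
  parameter sets the target *correlation magnitude* between junctional
  myosin and cadherin by mixing the standardised myosin profile with an
  independent component — a deterministic depression would pin the
  correlation at $-1$ regardless of the knob.

What the generator does **not** emulate: curved global tissue geometry,
cell rearrangements and tracking errors, photobleaching, depth-dependent
blur, and mechanical coupling between neighbouring junctions. Passing
tests therefore validate the estimators against their own stated model
assumptions, not against everything real imaging can do.

## The scaled average cell (SAC)

To compare intensity distributions across cells of different shapes and
sizes, each cell is reduced to polar coordinates about its centroid:
`radial_contour()` finds the boundary distance $r(\theta)$ by supersampled
ray marching (step 0.25 px) with a sub-pixel boundary estimate from the
0.5-level crossing of the bilinearly interpolated mask;
`scaled_cell_profile()` samples the (top-hat background-subtracted)
channel at fixed fractions of each ray's own $r(\theta)$, dividing out
cell shape; `scaled_average_cell()` averages maps and contours across
cells. Defaults are 360 angular and 100 radial samples — finer than the
pixel grid of a typical 40–80 px cell, so resolution is set by the image,
not the map. The boundary is taken as the *last* in-mask crossing along
the ray, which tolerates mild non-convexity; rays that leave and re-enter
the mask are counted in `n_reentrant` as a warning signal.

Derived readouts follow the conventions of the imaging they mirror:
junctional intensity is the mean over a 3-pixel-wide band along the
junction path; the junctional:medial ratio partitions the cell at 3 px
from the segmented junction (computed on the Euclidean distance
transform, threshold inclusive); boundary pixel pairs take cell pixels
within 1.5 px of the edge, each channel normalised by its cell-centre
reference. The centre reference region has no canonical size; the package
uses the mean over a 3 px disc at the centroid, and this choice is only a
normalisation — correlations are invariant to it.

Numerical edge cases: a uniform channel always yields a
junctional:medial ratio of exactly 1 whatever the geometry; if the medial
mean is zero the ratio is capped (default $10^6$) and flagged rather than
returned as infinity; cells touching the image border are an error for
the radial analysis, since their boundary cannot be located along every
ray. EBImage grayscale morphology clamps values to $[0,1]$, so the
top-hat filter rescales intensities around the operation and pads the
image by edge replication to avoid border artefacts of the erosion.

## Laser-ablation recoil

`fit_recoil()` fits tip displacement after a cut with
$f(t) = A (1 - e^{-t/\tau})$ — no offset term, since displacement is
pinned to zero at the cut (an optional offset exists for drifting real
data) — and reports the initial recoil velocity $V_0 = A/\tau$, the
standard relative tension proxy under constant friction. Fits with
$\tau$ above ten times the trace duration are rejected as unconstrained
rather than reported.

## Problem sizes and design choices

The test and acceptance workloads were sized to what the estimators need,
and state their conditions explicitly: 50 recoil traces at 1 Hz for 40 s
with 0.1 µm noise for the velocity recovery; 500 noiseless junction
traces over 60 min (0.5 min sampling, initial straightness uniform in
[0.55, 1)) for the end-to-end sigmoid recovery; rendered movies of 4–9
cells at 180–240 px for the image-pipeline checks, where a cell diameter
of ~80 px keeps pixelisation error in areas below 2 %. Raw 8-connected
boundary chains overestimate arc length on oblique paths (staircase
bias — measured straightness 0.6 for a true 0.8), so
`junction_paths_from_labels()` offers Gaussian chain smoothing
(`smooth_sigma`, default off); with `smooth_sigma = 2` the rendered-movie
junctions measure within ±0.02 of their constructed straightness.

Open choices resolved by the package: the squeeze-geometry estimate uses
a constant-area circle-to-ellipse transformation with Ramanujan's second
perimeter approximation (for a 30 % lateral strain this gives −23 %
height and +5.2 % perimeter; rougher printed approximations of similar
magnitude exist, but the package reports the model's own numbers); the
sigmoid fit is unweighted by default with a weighted option, since the
weighting convention of the reference fit is unknown; after stretch
release the return-to-baseline time is only checked to be of the same
order as $\tau$, because the initial condition of that comparison is not
pinned down.

## Limitations

The ODE model is deterministic and per-junction: no stochastic pulsing,
no coupling between junctions, no tension–straightness constitutive law.
The SAC assumes star-shaped cells about their centroid; strongly
non-convex cells are flagged, not handled. The CLI and file formats
(CSV/TIFF/JSON) are thin wrappers over the R functions; cell segmentation
and tracking of real movies are out of scope — the package consumes label
images.
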