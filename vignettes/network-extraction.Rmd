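---
title: "Extracting weighted networks from raster images with transport dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting weighted networks from raster images with transport dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(img2net)
```

## The problem

Images of retinal vessels, slime-mould plasmodia or river beds depict
network-like subjects, but an image is not a network: it carries no node set,
no edge set, no weights. Extracting these by hand is slow and subjective;
classical image-processing pipelines (skeletonisation, pruning) require
per-image tuning of pruning thresholds. This package instead poses the
extraction as a routing-optimization problem. The colour mass of the image is
treated as a fluid that must flow between terminal pixels; adaptation
dynamics of Physarum type concentrate that flow onto a cost-optimal
sub-network of the pixel grid, and the stationary state *is* the extracted
network — edges come out with principled weights (optimal conductivities,
proportional to drawn stroke diameter) instead of requiring a separate
estimation step.

## The model

**Pre-extraction.** A pixel with intensity above a threshold $\delta$ becomes
a node at its centre of mass; two such pixels sharing an edge or a corner
(8-connectivity) are joined. Edge lengths are $1$ or $\sqrt 2$ in pixel
units. By default intensity is *inverted luminance* — the subjects of
interest are dark strokes on light backgrounds — normalised by the
theoretical channel maximum, and each edge starts with conductivity
$\mu_e(0)$ equal to the mean intensity of its endpoints (floored at
$\varepsilon_0 = 10^{-6}$ so $\mu(0) > 0$). This raw graph is $G^{pe}$.

**Dynamics.** Given a balanced forcing $f$ ($\sum_i f_i = 0$: one source,
many sinks), node potentials $u$ solve Kirchhoff's law
$\sum_e B_{ie} F_e = f_i$ with flux $F_e = \mu_e (u_{v_1} - u_{v_2}) /
\ell_e$, where $B$ is the signed incidence matrix. Conductivities adapt as

$$ \mu_e'(t) \;=\; |F_e(t)|^{\beta} - \mu_e(t), \qquad \mu_e(0) > 0 , $$

so highly used edges grow and idle edges decay. Stationary states are
critical points of the transport cost

$$ L_\beta \;=\; \tfrac12 \sum_e \mu_e \Big(\frac{\Delta u_e}{\ell_e}\Big)^2
\ell_e \;+\; \frac{\beta}{2(2-\beta)} \sum_e \mu_e^{(2-\beta)/\beta}
\ell_e , $$

an operational cost plus an infrastructure cost. For $\beta \ge 1$ the
dynamics consolidate: with a single source the surviving support is a tree.
The package fixes $\beta = 1.5$ by default, the regime where filtering is
effective without being overly aggressive; the valid range is $(0, 2)$.

**Terminals.** No terminals come with a raw image. They are selected by
running the dynamics once with *every* node as a terminal (a random node as
source, all others as sinks of demand $1/(n-1)$); the leaves of the filtered
all-terminal tree are the eligible terminals. These leaves sit in distant
parts of the subject, which is what makes them good anchors. Hand-picked
terminal lists are accepted and override this selection. Terminal selection
is done per connected component: components are independent subjects and a
joint tree across them does not exist.

**Loops.** A single run returns a tree, but subjects have loops. `image2net`
therefore repeats the single-source run `n_runs` times (default 5), each
time with a *different* source drawn without replacement from the terminal
set (capped at the terminal count), and superposes the filtered trees: node
and edge sets are unions, and each edge weight is the sum of its stationary
conductivities over the runs that used it. Distinct sources break a ring at
distinct points, so the union closes the loop.

**Baseline.** `image2net_mst` replaces the dynamics with classical routing
optimization on the *identical* $G^{pe}$: an MST (cost $\ell_e$,
deterministic tie-break by edge id) supplies leaf terminals; per run a
random terminal subset of predefined size is connected by an approximate
Steiner tree (metric-closure 2-approximation: MST of the shortest-path
distance graph over the terminals, expanded, reduced to a tree, non-terminal
leaves pruned); runs are superposed the same way. The baseline selects edges
only — its weights remain the input conductivities of $G^{pe}$, which is the
structural difference the comparison is designed to expose. (The effective
reweighing rule sometimes used to post-process conductivities is defined
outside this package; here weights are the plain stationary conductivities
summed over runs.)

**Similarity.** Quality is scored on a grid of $P = g^2$ cells tiling the
unit square: the binary score
$\hat w_b = \frac1P \big[\sum_\alpha (|\#\text{edges}_\alpha -
\#\text{supra-}\delta\text{ pixels}_\alpha|)^2\big]^{1/2}$ compares per-cell
edge counts with supra-threshold pixel counts (same $\delta$ as the
extraction); the weighted score $\hat w$ compares per-cell edge-weight sums
with pixel-intensity sums and needs no threshold. Both are $\ge 0$, zero
exactly at per-cell equality, lower is more similar. Edges are assigned to
the cell of their midpoint by default; a length-fraction mode (`"split"`) is
available for sensitivity checks. The grid side defaults to 32; absolute
score values are only comparable at a fixed grid.

## Coordinates and units

Pixel $(r, c)$ of an $H \times W$ image has centre $x = (c - 0.5)/W$,
$y = 1 - (r - 0.5)/H$: the image spans the unit square with $y$ increasing
upward. The dynamics use pixel-unit lengths ($1$, $\sqrt2$); reported edge
lengths (`length` column, `network_length`) are Euclidean distances in the
unit-square frame, so the two differ by the single scale factor $1/W$ on
square images.

## Numerical choices

* **Integrator.** Explicit Euler with initial step `dt = 0.5`. $L_\beta$ is
  a Lyapunov function of the continuous flow, so a step that would increase
  the cost beyond $10^{-10} L_\beta(0)$ is retried with the step halved; the
  step relaxes back (×1.1, capped at its initial value) after accepted
  steps. The recorded trajectory is therefore non-increasing up to that
  tolerance by construction, and descent failures surface as persistent
  halvings rather than silent divergence.
* **Stopping rule.** $\max_e |\Delta\mu_e| / (dt \cdot \max_e \mu_e) <$
  `tol`, i.e. the sup-norm of the ODE right-hand side relative to the
  largest conductivity — dividing by `dt` keeps the criterion meaningful
  when the step has been halved. The default `tol = 1e-6` is chosen to
  separate scales in the filter: at stationarity the weakest *surviving*
  edge of a single-source tree carries flux $1/(n-1)$, hence
  $\mu \approx (1/(n-1))^\beta$ ($\approx 10^{-4}$ at $n = 400$,
  $\beta = 1.5$), while decaying edges stall near
  `tol`$\cdot \max\mu / dt \approx 2\times10^{-6} \max\mu$. A looser
  $10^{-5}$ would push stalled edges uncomfortably close to the smallest
  legitimate ones.
* **Filtering.** By default an edge survives if
  $\mu_e > (f_{\min}/2)^\beta$ with $f_{\min}$ the smallest terminal demand
  — every edge of a single-source stationary tree carries at least the
  smallest sink demand, so this threshold is size-independent and sits an
  order of magnitude above stalled decaying edges. An explicit `eps_rel`
  switches to the plain rule $\mu_e > \texttt{eps\_rel} \cdot \max\mu$.
* **Linear algebra.** The grounded weighted Laplacian (gauge $u = 0$ at the
  lowest-id node of each support component) is solved sparsely
  (`Matrix`), with iterative refinement until the flux-conservation
  residual is below $10^{-10} \|f\|_\infty$. Edges with
  $\mu < 10^{-12}$ are frozen out of the system to keep it
  well-conditioned and reported as zero. If the forcing requires mass
  exchange between support components, the solve aborts naming the
  disconnected terminals rather than returning a least-squares artefact.
* **Degeneracy.** Exactly tied parallel routes make the consolidating
  fixed point non-unique; real images break ties through anti-aliased
  intensities (which seed $\mu(0)$), and the synthetic generators keep
  fixtures in generic position (random intensities; ring centres jittered
  off the exact grid-symmetric point) for the same reason.

## Reproducibility

One global seed drives everything. Per-stage seeds (terminal choice, source
order, Steiner draws, scene geometry, noise) are derived from it by hashing
the stage name, so stages are independent and can be re-run in isolation.
Sources are a seeded permutation of the terminal set consumed as a prefix:
the edge set extracted with $r$ runs is contained in the one extracted with
$r + 1$ runs at the same seed. All output files embed the resolved
configuration and seed in `#` header lines and contain no timestamps, so a
rerun reproduces them byte for byte.

## What the synthetic scenes do and do not show

`make_scene` plants graphs with known topology — rings (one cycle, no
leaves), planar random trees grown by recursive angular-sector branching
(exact leaf count, no edge crossings), lattices, and bounded-curvature
filaments — and `rasterize` renders them with anti-aliased strokes
(subject $\ge 0.8$, background $\le 0.1$ before noise, so the default
$\delta = 0.5$ separates them without tuning), plus optional Gaussian and
salt-and-pepper noise. `topology_match` then scores leaf recall, cycle
counts and endpoint displacement against the plant.

These scenes validate the machinery: that the dynamics produce spanning
trees, that superposition recovers loops, that leaves land where drawn tips
are. They are *not* photorealistic: real vessel and river images have
textured backgrounds, varying stroke contrast, occlusions and compression
artefacts that the generator does not emulate, so passing desk-scale tests
bounds implementation correctness, not field performance. Scene experiments
use 64×64 canvases (a few hundred pixel-graph nodes), which resolve the
planted topologies while keeping the full validation suite at interactive
speed. For tree scenes the extraction uses a single run — for a subject
that *is* a tree one source suffices, and additional runs can only add
redundant detail; ring scenes use the default five runs, which is the point
of the loop-recovery experiment.

## Parameters that matter

| key | default | meaning |
|-----|---------|---------|
| `delta` | 0.5 | intensity threshold defining $G^{pe}$ (unitless, [0,1]) |
| `beta` | 1.5 | consolidation exponent, (0, 2); $\ge 1$ filters to trees |
| `n_runs` | 5 | single-source runs superposed; 1 suffices for tree subjects |
| `seed` | 0 | global seed |
| `dt` | 0.5 | initial Euler step |
| `tol` | 1e-6 | stationarity tolerance (relative RHS) |
| `max_iter` | 3000 | iteration cap per run |
| `eps_rel` | NA | filter override; NA = flux-aware threshold |
| `grid_side` | 32 | similarity grid side ($P = 1024$ cells) |
| `connectivity` | 8 | pixel adjacency (4 for ablation only) |

`delta` and `beta` are the two knobs that change results qualitatively:
lowering `delta` admits fainter strokes (more detail, more noise), and
`beta` trades filtering strength against detail retention.

## A worked example

```{r example}
scene <- make_scene("ring", list(size = 64), seed = 1)
field <- rasterize(scene)
net <- image2net(field, delta = 0.5, beta = 1.5, n_runs = 5, seed = 1)
summary(net)
topology_match(net, scene)$cycles_extracted   # loops recovered
similarity_binary(net, field, delta = 0.5, similarity_grid(8))
```

```{r plot, fig.alt = "Extracted ring network over the rendered scene"}
plot(net, field = field, main = "superposition of 5 single-source trees")
```

## Known limitations

* The method presumes a conserved incompressible flow behind the image;
  subjects without one (fracture networks, foams, grain boundaries) can be
  processed but the extracted weights lose their interpretation.
* Loop recovery is stochastic in the sources: a ring is recovered only if
  two runs break it at different places. Five runs have always sufficed on
  the bundled scenes, but heavily looped subjects may need more (the cap is
  the terminal count).
* The superposition of trees over a thick stroke can disagree pixel-wise
  between runs, yielding small parallel cycles rather than one clean
  centerline loop; the cycle *count* is therefore an over-count of subject
  loops, and downstream topological analysis should work at stroke-width
  resolution.
* Runtime is dominated by one sparse Laplacian factorisation per iteration
  per run; it is comfortable at $10^4$ nodes but the pixel graph of a
  megapixel image should be cropped or downsampled first.
* Exact Steiner optimality is not attempted; the baseline's 2-approximation
  bound is the guarantee, and measured ratios on enumerable instances are
  far below it.
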