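---
title: "Representing dynamics over latent manifolds with flowrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing dynamics over latent manifolds with flowrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowrep)
```

## The model

flowrep takes, for each experimental condition $c$, a set of trials of a
$d$-dimensional continuous state variable (for example smoothed firing
rates of a neural population) and treats them as samples of a *vector
field* $F_c$ anchored to a point cloud $X_c$ on an unknown smooth
$m$-dimensional manifold in $\mathbb{R}^d$: the anchored vector at a state
is the first difference of the trial passing through it. The object of
interest is not any single trajectory but the field of *local flow
fields* (LFFs) — the vector field restricted to the neighbourhood of each
state — whose empirical distribution characterises the dynamics under
that condition. Trials are never averaged; every trial contributes its
own states.

The pipeline has five stages.

1. **Manifold scaffold.** Optional farthest-point subsampling equalises
   sampling density (spacing parameter $\alpha$ relative to the cloud
   diameter; $\alpha = 0$ keeps everything). A continuous $k$-nearest
   neighbour graph connects $i, j$ whenever
   $\|x_i - x_j\|^2 < \delta\,\|x_i - x_u\|\,\|x_j - x_v\|$ with $u, v$
   the $k$-th neighbours of $i, j$ — unlike plain $k$-NN this adapts to
   density variations. Tangent frames $T_i \in \mathbb{R}^{d\times m}$ are
   the top-$m$ left singular vectors of the local edge-vector matrix;
   adjacent frames are aligned by the orthogonal (Kabsch) solution of
   $\min_{O \in O(m)} \|T_i - T_j O\|_F$, giving parallel-transport
   connections $O_{ij}$.

   The within-subspace *gauge* of an SVD basis is arbitrary, and this
   matters more than it first appears. In embedding-agnostic mode the
   basis signs are fixed against data-derived anchor directions (position
   relative to the cloud centroid, the locally averaged field, the mean
   edge vector — all of which rotate with the data), which makes the
   entire feature construction exactly equivariant under ambient
   rotations; when $m = d$ the anchors orient the full basis. In
   embedding-aware mode a fixed convention is used instead (the identity
   basis at $m = d$), deliberately keeping the representation sensitive
   to the orientation of the flow — that sensitivity is what lets two
   constant fields with different directions separate.

2. **Vector diffusion (optional).** The random-walk connection Laplacian
   (identity diagonal blocks, off-diagonal blocks $-O_{ij}/\mathrm{deg}(i)$)
   generates a diffusion $e^{-\tau L}$ that smooths the projected field
   while respecting parallel transport, and hence preserves the
   fixed-point structure that scalar smoothing would destroy.

3. **Gradient features.** The field is projected to tangent coordinates
   ($f_i' = T_i^\top f_i$) and augmented with directional derivatives up to
   order $p$: per node and tangent direction, a filter row is obtained
   from a Gaussian-weighted local linear least-squares fit over
   parallel-transported neighbour vectors. The filters are exact on affine
   fields and annihilate parallel fields, which is precisely the
   first-order Taylor contract they implement; transport makes the values
   insensitive to local curvature. The stack has
   $c = \sum_{k=0}^{p} m^k$ vectorial channels.

4. **Inner products (embedding-agnostic mode).** Because all channels at
   a node live in one tangent frame, channel-pair inner products
   $E^{(r)} = \sum_s \langle f^D_{\cdot r},\, A^{(r)} f^D_{\cdot s}\rangle$
   (with learnable $A^{(r)}$, initialised at the identity) produce
   rotation-invariant scalars: the representation then does not depend on
   how the manifold happens to be embedded or oriented, so differently
   curved or rotated systems can be compared. Embedding-aware mode skips
   this step and keeps the raw channels, which *is* sensitive to
   orientation — useful when conditions share one recording frame.

5. **Contrastive embedding.** A two-layer ReLU MLP (Kaiming
   initialisation) maps each node's features to $z_i \in \mathbb{R}^E$.
   Because LFFs vary continuously over the manifold, graph neighbours are
   positives and uniformly drawn nodes (across all conditions) negatives
   in the negative-sampling loss
   $J = -\log\sigma(z_i^\top z_j) - Q\,E_k[\log\sigma(-z_i^\top z_k)]$,
   optimised by minibatch Adam with an 80/10/10 train/validation/test
   node split and early stopping on the validation loss. Condition labels
   organise feature extraction only; training is shared and unsupervised.

Conditions are then compared as empirical distributions of latent
vectors with the exact optimal-transport cost under a squared-Euclidean
ground metric (uniform marginals; the reported value is the transport
cost itself). Classical MDS and average-linkage hierarchical clustering
of the distance matrix summarise the structure of a condition sweep, and
generic decoders (optimal linear estimation with cross-validated $R^2$,
$k$-NN with cosine or Euclidean metric) quantify what the latent space
retains.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` | 2 | manifold dimension; frames use the identity gauge when `m == d` (aware mode) |
| `p` | 2 | filter order; second order suffices for the systems treated here |
| `k`, `delta` | 15, 1.0 | continuous k-NN scale |
| `K` | `ceiling(1.5 * degree)` | frame-fit neighbourhood; trades locality for robustness |
| `tau` | 0 | diffusion time, in units of the random-walk Laplacian spectrum (order 1); 0 disables |
| `alpha` | 0 | farthest-point spacing relative to the diameter |
| `E` | 5 | latent dimension |
| `Q` | 1 | negative-sampling weight |
| `lr`, `batch`, `epochs`, `patience` | 1e-2, 256, 100, 20 | Adam minibatch schedule with validation early stopping (`min_delta` 1e-4) |
| `clip` | off | per-column feature winsorisation quantile |

Two numerical choices deserve explanation.

* **Feature conditioning.** MLP input columns are rescaled by their
  pooled root-mean-square. Gradient channels are heavy-tailed near fixed
  points (derivative magnitudes grow like one over the local spacing), and
  a handful of such nodes can dominate both the contrastive loss and the
  transport cost; the optional `clip` quantile winsorises each column.
  Both operations act per column and therefore preserve the
  rotation-invariance of the agnostic features.
* **τ is a fixed hyperparameter here, not a trained one.** The diffusion
  layer is differentiable in principle, but with the recommended
  initialisation at 0 the optimiser rarely moves it; we expose it as a
  plain argument and leave it off by default rather than backpropagate
  through the Krylov evaluation of $e^{-\tau L}$ at every step.

Other open choices made here: the inner-product matrices $A^{(r)}$ are
unconstrained dense and trained jointly with the MLP; one shared scalar
$\tau$ is used rather than per-channel times; neighbour selection ties
break by hop distance, then Euclidean distance, then node index, making
the whole geometry deterministic; disconnected graph components are
processed separately and never paired as positives.

## The built-in simulators, and what they do (not) show

`run_pipeline()` ships three presets that generate their own data.

**Planar toy fields** (`preset = "toy"`): constant and rotational linear
fields on the unit square, 300 nodes per condition, embedding-aware,
$E = 3$. Two constant fields with different directions should map into
two separated clusters; a rotational field's nodes should trace a closed
ring in latent space (the LFF varies continuously with the angle around
the fixed point). This validates that the representation preserves both
discrete and continuous dynamical variation.

**Van der Pol on a paraboloid** (`preset = "vdp"`):
$\dot x = y,\ \dot y = \mu(1 - x^2)y - x$, integrated by RK4
(`dt = 0.01`), 20 damping values evenly spaced in $[-1, 1]$, lifted onto
$z = -(\alpha x)^2 - (\alpha y)^2$ with $\alpha = 0.5$, embedding-agnostic,
$E = 5$, $p = 2$. Choices a user should understand:

* *Initial conditions* are drawn once per run from a Latin hypercube over
  $[-1,1]^2$ and reused for every damping value (a paired design: the
  condition comparison is then not confounded by initial-condition
  sampling noise, and the stratified draw covers the box evenly). For
  $\mu < 0$ the origin is stable only inside an unstable limit cycle;
  initial conditions much beyond amplitude 2 blow up in finite time, so
  the box is chosen inside the basin for the whole sweep (`ic_range` and
  `ic` expose both choices).
* *Five training repetitions.* The contrastive optimum is degenerate:
  independently trained embeddings agree on coarse structure but differ
  in fine latent geometry. The preset therefore trains five times and
  averages the transport distance matrices, which is also how results
  were confirmed reproducible for the systems this emulates.
* *Trajectory length* is 10 time units (about one and a half cycle
  periods), long enough that positive-damping trajectories reach the limit
  cycle — whose amplitude is near 2 for every $\mu > 0$ — while
  negative-damping trajectories stay inside the shrinking envelope of the
  initial box. The spatial support of the sampled cloud therefore changes
  abruptly across $\mu = 0$, which is exactly the Hopf signature the
  distance matrix should pick up; much shorter trajectories sample only
  near-identical spiral segments on both sides of the bifurcation, and the
  split becomes undetectable in principle.
* *Speed normalisation*: each condition's vectors are reduced to unit
  direction vectors. Raw speeds vary over orders of magnitude along the
  sweep (relaxation spikes at $\mu = 1$, exponential slowing at
  $\mu = -1$) and would otherwise dominate the squared-cost transport
  distances; the flow geometry, not the clock rate, is what the sweep is
  meant to compare.
* 200 farthest-point nodes per condition, `clip = 0.95`, and vector
  diffusion at $\tau = 2$: with only 200 nodes per condition the gradient
  features are noisy, and diffusion (the pipeline's fixed-point-preserving
  denoiser) keeps the slowly-deforming positive-damping branch from
  collapsing in latent space, where its 1-D MDS coordinate would
  otherwise fold back on itself.

With this protocol the two-way split of the averaged distance matrix
lands at the bifurcation (occasionally one half-step, 0.05 in $\mu$, to
either side — residual training stochasticity) and the leading MDS
coordinate rank-correlates with $\mu$ at $|\rho| \approx 0.88$–$0.91$
(the acceptance script recomputes the boundary).

**Rank-two RNNs on a working-memory task** (`preset = "rnn-gain"`): rate
networks $\tau \dot x = -x + J\phi(x) + u(t) + \eta$ with
$J = \frac1N \sum_r m_r n_r^\top$ of rank 2, $\phi = \tanh$,
$\tau = 100$ ms, noise s.d. $3\times10^{-2}$, trained by Adam with
backpropagation through time on the delayed-match-to-sample loss
$|o(T) - \hat o(T)|$. Trials have five epochs (fixation 100–500 ms,
stimulus 500 ms, delay 500–3,000 ms, stimulus 500 ms, decision
1,000 ms); each stimulus epoch presents one of two stimuli, encoded by
which of the two input channels carries the gain, and
$\hat o(T) = +1$ iff the two stimuli match. The four stimulus
combinations are balanced, so chance performance is 0.5 and a constant
responder gains nothing. The two-alternative encoding matters: because
the rate dynamics are odd-symmetric ($\tanh$ units, linear readout,
zero initial state), a task variant containing trials with no input at
all could never be answered deterministically on those trials, capping
accuracy below the trained ceiling. The desk-scale default is $N = 128$
units (rank-two dynamics are insensitive to $N$ above roughly 64) with a
2–5 ms Euler–Maruyama step against $\tau = 100$ ms. Gain modulation —
scaling the stimulus amplitude — degrades task accuracy abruptly, and
the representation pipeline, fed stimulated-epoch firing rates
(PCA-projected to 5 components; vectors deliberately *not*
unit-normalised, since gain is a magnitude effect), should place
zero-gain control conditions close together relative to their distance
from stimulated conditions.

Training this task from a cold start deserves a note: the match
computation has no first-order gradient signal at a symmetric random
initialisation, and direct optimisation stalls at chance indefinitely.
`train_rnn` therefore uses a shaping curriculum — express the identity
of stimulus 1 continuously from its offset, hold it across realistic
delays, hold it through the second stimulus as a distractor, learn the
match rule at short delays, and finally fine-tune on the full protocol
— with per-stage best-checkpointing, learning-rate annealing on
validation plateaus (rewinding to the best parameters), and stage-level
retries from the last reliable checkpoint under fresh sampling streams
if the memory or match stage stalls. Evaluation always uses the full
task protocol. The
training loss is the mean of $|o(t) - \hat o|$ over the decision epoch,
which at convergence coincides with the final-time form but supplies
gradient signal that has not decayed through ten membrane time
constants of input-free dynamics.

What passing these synthetic suites does **not** show: robustness to the
statistics of real recordings — spiking noise that survives rate
smoothing, non-stationarity across sessions, behavioural covariates
correlated with condition, electrode drift. The simulators emulate the
geometry of the problem (curved manifolds, condition sweeps, trial
structure), not the measurement process. For real data the practical
recommendation is to project to a handful of principal components first
(`project_pca()`), as is standard for this class of methods, and to
treat the latent distances as relative, not absolute, quantities.

## Degenerate inputs and numerical tolerances

Isolated graph nodes are skipped as anchors with a warning; nodes whose
neighbourhood cannot support a rank-$m$ frame or an $m$-term derivative
fit are flagged (frames keep the available directions, kernels fall back
to zero rows). Edges whose tangent spaces are nearly orthogonal get an
identity connection and a warning. The matrix exponential action is
evaluated by scaled truncated Taylor series on sparse products to a
relative tolerance of 1e-8 and is never densified. Exact optimal
transport requires equal cloud sizes; unequal (or > 2000-point) clouds
are uniformly subsampled with a recorded seed, and an entropic
(Sinkhorn) approximation is available behind an explicit flag because
regularisation changes the value. Frames fix signs deterministically;
connections absorb the residual gauge.

## Problem sizes

The shipped presets are sized for a single desktop core: 300 nodes per
toy condition, 20 Van der Pol conditions of 200 nodes, and a 128-unit
RNN trained for a few hundred Adam updates. All of them scale up by
changing the corresponding config entries; the algorithms are
$O(n^2)$ in the per-condition node count (dense distance computations)
and linear in the number of conditions for preprocessing, with the
$C(C{-}1)/2$ transport solves at $O(n^3)$ each dominating wide sweeps.

## Known limitations

* Hop-count geodesics only; no curvature estimates beyond what transport
  absorbs.
* The contrastive objective can collapse regions whose LFFs are genuinely
  indistinguishable (e.g. every point of a constant field); distances
  between such conditions are then driven by the remaining features, which
  is intended, but it means latent *within*-condition spread is not a
  reliable uncertainty measure.
* Transport distances compare distributions of local dynamics; two
  globally different systems assembled from the same local motifs in
  different proportions can look closer than their global flow diagrams
  suggest.
* Filters beyond order 3 are not supported (cost grows as $m^p$ and the
  least-squares fits become ill-conditioned on realistic neighbourhood
  sizes).
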