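---
title: "Modelling cell migration as reinforcement learning in a reconstructed tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell migration as reinforcement learning in a reconstructed tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`cellmigrl` casts a migrating cell in a developing embryo as a
reinforcement-learning agent. The tissue is reconstructed from
nucleus-tracking time series (per frame: lineage name, x/y/z position in
micrometres, nucleus diameter, as produced by lineage-tracing pipelines for
*C. elegans* embryos). All cells except the migrating one are *environment
cells*: they replay their recorded positions frame by frame and are never
perturbed by the agent. One environment cell is the *target* (for the
canonical Cpaaa intercalation, the ABarpaapp cell). At each timestep the
agent chooses one of 8 compass directions in the xy plane and moves by a
noisy step; the environment advances one frame and returns a reward and an
image observation.

## Rewards

The per-step reward is a sum of three model feedbacks.

* **Neighbor relationship.** Two cells are neighbors when their Voronoi
  regions share a face (Delaunay adjacency of the nuclei). The ground truth
  is a 3-D Delaunay tessellation (exhaustive empty-circumsphere
  enumeration, exact at embryo scale); a random-forest classifier over
  handcrafted pair features (distance, nucleus sizes, estimated radius sum,
  distance ratio, cell count, and two geometric blocking counts) can stand
  in for the tessellation.
* **Neighbor distance.** For each direct neighbor, the centre distance is
  divided by the sum of the two cells' estimated radii. Ratios in the
  acceptable band (0.3, 0.8) incur a linear penalty from −1 (at 0.3) to 0
  (at 0.8); ratios above 0.8 incur nothing; ratios below 0.3 (overlapping
  cells) incur −1000. The per-cell reward `R_N` is the sum over direct
  neighbors. The low boundary itself belongs to the linear regime: the
  −1000 penalty applies strictly below 0.3.
* **Destination.** When the agent has been a neighbor of the target for 5
  consecutive timesteps *and* is within the time budget — 90% of the
  observed migration window — it receives +100 once and the episode ends.

Two mechanism hypotheses modify the destination model:

* **Gradient hypothesis** (single-level DQN): a dense term proportional to
  the current agent–target distance, normalised by the initial distance so
  its coefficient is scale-free: `−c·d/d0`, default `c = 1`.
* **Collective behavior hypothesis** (hierarchical DQN): no dense term;
  instead a meta-controller selects *subgoals* — pairs of cells drawn from
  the agent's secondary neighbors (neighbors of neighbors) — and +10 is
  paid the first time the agent is simultaneously a neighbor of both
  subgoal cells. Subgoal cells are annotated white in the observation.

## Observations

The environment renders an orthographic top view of the scene at each step:
a grayscale image in which each cell is a filled disc of its projected
nucleus radius, with role-specific intensities (migrating 1.0, subgoal 0.9,
target 0.8, environment 0.5), and a depth image holding the normalised
camera distance to the nearest sphere surface. The two 64×64 (configurable)
images are stacked into a 2×S×S observation: the gray channel carries x, y
and size, the depth channel carries z.

## Speed model

The agent's average step size is derived from the data: the initial
agent–target distance divided by the migration window length in steps. Each
step multiplies it by `1 + δ` with `δ ~ Normal(0, 0.1)` truncated to
±0.2 — i.e. ±20% noise, with the band at about 2σ.

# Key parameters

| parameter | default | meaning |
|---|---|---|
| `ratio_low`, `ratio_high` | 0.3, 0.8 | acceptable distance-ratio band |
| `overlap_penalty` | −1000 | reward below the band |
| `destination_reward` | +100 | reward at stable arrival |
| `subgoal_reward` | +10 | intermediate reward per subgoal |
| `stable_steps` | 5 | consecutive neighbor steps defining stability |
| `time_budget_fraction` | 0.9 | fraction of the window allowed |
| `ratio_cutoff` | 2.0 | Delaunay edge pruning (hull artifacts) |
| `frame_interval` | 60 s | native acquisition interval |
| upsampling factor | 10 | 60 s → 6 s steps for finer control |
| `noise_halfwidth` | 0.2 | ±20% speed noise |

# The contact-radius calibration

Cell radii are estimated from volume equipartition,
`r = (3·V·w(g)/(4πN))^{1/3}` with `w ≡ 1` by default (`estimate_radius()`,
with `w` a hook for lineage-specific size laws). A geometric fact forces a
calibration on top of this estimate wherever *ratios* are formed: in any
3-D point process the mean Delaunay edge length is close to **twice** the
equipartition radius, so raw equipartition radii put typical adjacent-pair
ratios near 1.0 — outside the (0.3, 0.8) band, which would leave the
neighbor-distance reward permanently inert. Ratios therefore use *contact
radii*, the equipartition radius times 1.55. The factor was calibrated once
against close-packed synthetic embryos so that adjacent-pair ratios centre
in the acceptable band (≥90% inside (0.3, 0.8) across seeds) and frozen;
it reflects that a cell's contact extent in confluent tissue exceeds its
volume-equivalent sphere.

# The synthetic embryo generator

Real recordings cannot ship with the package, so every downstream module is
exercised on synthetic embryos (`generate_embryo()`,
`generate_migration_scenario()`).

*What it emulates*: an ellipsoidal eggshell (default semi-axes 32×12×10 µm
for the elongated corridor world); ~20 cells at tissue density placed on a
jittered close-packed (fcc) lattice clipped to the shell — early embryos
are near confluence, and lattice-like packing is what keeps neighbor
ratios inside the empirical band; nucleus diameters at 70–85% of the cell
diameter; 60 s frames with 0.2 µm/frame Gaussian positional jitter;
optionally one division via lineage-name suffixing (`divide_cell()`). The
migration scenario adds two static rows of flanking cells along +x (the
intercalation geometry), a migrating cell that traverses the corridor seam
on a straight path with reduced jitter, and a target at the corridor's far
end; the migrating cell starts 3.4 effective radii from the target —
already between the rows, the latter half of an intercalation — with
filler cells clustered at the corridor entrance so the agent starts
embedded in tissue rather than at a reward cliff.

*What it does not emulate*: cell deformation, volume exclusion forces, row
rearrangement or rosette formation, realistic lineage trees, division
waves, imaging noise, or tracking errors. A green learning test therefore
establishes that the machinery (environment, rewards, networks, training
loop) works end to end at desk scale — not that either biological
hypothesis is supported; that inference needs real recordings and
full-scale training.

# Numerical and design choices

* **Delaunay by enumeration.** Adjacency is computed by exhaustively
  testing all 4-point circumspheres (Rcpp). For tens of cells this costs
  milliseconds and is exact by definition; co-spherical inputs (lattices)
  yield the union of all valid triangulations. Coplanar frames fall back to
  a 2-D tessellation, collinear ones to a nearest-neighbor chain, two cells
  to a single edge — each with a warning.
* **Actions in-plane.** The 8 actions live in the xy plane with z held,
  pairing naturally with the top-view observation; the agent is clamped to
  the series bounding box inflated by one mean radius.
* **Division boundaries in upsampling.** Linear interpolation never crosses
  an appearance/disappearance: a disappearing parent's last sub-frame is
  the copy of its last original frame, children start at the copy of their
  first.
* **Truncation vs termination.** Only payment of the destination reward is
  a true terminal state for TD targets; running out of budget is a time
  limit and bootstraps through. Treating the time limit as terminal makes
  idling look as good as migrating (both end on 0) and empirically prevents
  any learning at desk scale.
* **Desk-scale training devices.** The published setting (900 epochs,
  multi-hour GPU training) is far beyond a test suite, and a plain
  one-step DQN with per-frame decisions does not learn the corridor task
  in 150 epochs on one CPU: per-step action advantages are sub-pixel and
  the −1000 spikes dominate the value scale. The trainer therefore
  supports, as config switches (all defaulting to the plain behaviour):
  per-step reward clipping inside the learner, n-step TD returns,
  action-repeat (frame-skip), sticky exploration, Double-DQN bootstraps,
  and best-checkpoint selection from periodic greedy evaluations during
  training. The scaled test configuration uses clip 10, 3-step returns,
  action-repeat 5 and checkpoint selection; with them, three-seed majority
  success is reached by both agents within 150 epochs.
* **Classifier decision threshold.** The forest's vote threshold is chosen
  on the training pairs by maximising balanced accuracy (no held-out data
  involved), because the 1:1 negative sampling makes 0.5 slightly
  miscalibrated for the true edge prior.
* **Alignment edges.** Midpoint-aligned averages report mean and sd only
  where at least two embryos overlap; a band from a single curve would be
  undefined.

# Known limitations

* The brute-force tessellation is O(n⁵) and intended for frames of tens of
  cells (< 100); later embryo stages need a proper incremental Delaunay.
* Scaled-down learning is stochastic across seeds; the tests use a
  three-seed majority, mirroring how such checks are usually stabilised.
* The 30-plane z-stack at 0.1 µm per plane quoted for the source imaging
  configuration implies a 3 µm physical depth; the values are kept as
  configuration defaults without reconciling them.
* PNG byte output from the graphics device is not contractually stable
  across platforms; determinism is guaranteed (and tested) at the level of
  the rasterised matrices.
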