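---
title: "Modelling personal construct systems as fuzzy cognitive maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling personal construct systems as fuzzy cognitive maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsfcm)
```

## Overview

`pcsfcm` turns a repertory grid and an implications grid into a fuzzy
cognitive map (FCM), simulates the dynamics of the personal construct
system (PCS) it describes, flags cognitive conflicts, and runs what-if
intervention scenarios. This vignette documents the model, the choices
behind every tunable parameter, and what the packaged tests do and do not
demonstrate.

## Rating-scale semantics

Ratings are integers 1–7 on bipolar constructs. The package adopts the
monotone reading: 1 = "very" like the left pole, 2 = "quite", 3 =
"slightly", 4 = neither pole, 5 = "slightly" like the right pole, 6 =
"quite", 7 = "very". Activations live in a right-pole-positive frame via
the affine map `a = (r - 4) / 3`, the unique linear map sending the two
scale extremes to ∓1 and the midpoint to 0, so the scale's image is the
seven points {−1, −2/3, −1/3, 0, 1/3, 2/3, 1}. Different conventions exist
in the grid literature (some number the right pole 5–7 in decreasing
intensity); files produced under such a convention must be recoded before
import, and `read_repgrid()` makes no attempt to guess.

## Construct classification

With `s` the Self-Now rating and `i` the Ideal-Self rating of a construct:

* **dilemmatic** iff `i == 4`: the ideal offers no preferred pole, so
  "desired change" is undefined. This includes the fully undefined pair
  `(4, 4)`; classification is driven by the ideal alone, which keeps the
  rule a biconditional (dilemmatic ⇔ ideal at midpoint) rather than a
  special case.
* **congruent** iff `sign(s - 4) == sign(i - 4) != 0`: content, no change
  desired.
* **discrepant** otherwise — opposite poles, or a midpoint self with an
  off-midpoint ideal (the person has not yet located themselves but knows
  where they want to be, so change *is* desired).

Only the exact rating 4 counts as the midpoint: ratings are integers, so a
fuzzy band around 4 would be empty anyway. The `desired_direction` is
`sign(i - s)`, reported for every construct (it is also nonzero for a
congruent construct whose self-identification is weaker than its ideal;
conflict detection only consults it for discrepant constructs).

## From implications grid to weight matrix

The implications grid is elicited in the frame *"if you moved from your
current pole to the opposite pole"*. Stored scores `s[i, j]` are expressed
in the right-pole-positive frame of the target (sign = implied pole,
magnitude 1–3 = slightly/quite/very). Since the hypothesized movement of
the source runs *away* from its current pole, its direction is
`d_i = -sign(a0_i)`, with a fallback to the desired direction (toward the
ideal) when the self sits at the midpoint. The canonical weight is
`w[i, j] = d_i * s[i, j] / 3`, which makes the frame-consistency property
testable: a one-step unit push of source `i` in direction `d_i` moves every
target `j` in direction `sign(s[i, j])`.

A construct with nonzero implications but no defined direction (self *and*
ideal at the midpoint) is an error, not a silent guess; `validate_case()`
reports this combination as a violation so a validated case can never fail
downstream.

## Dynamics

Two synchronous update rules are provided, both squashed through a
threshold function `f`:

* `kosko` (classical): `a'_j = f(Σ_{i≠j} w_ij a_i)` — a node with no
  inputs decays immediately;
* `self_memory` (default): `a'_j = f(a_j + Σ_{i≠j} w_ij a_i)` — each node
  carries its previous activation into the sum.

The default is `self_memory` because a personal construct system is
persistent: self-perceptions do not vanish in one step when nothing pushes
on them, and the stable, change-resistant systems this tool is built to
expose only arise when state is carried forward. Threshold options are
`tanh(λx)` (default, λ = 1 — smooth, saturating, keeps trajectories in the
open interval), a hard clamp (piecewise-linear; convenient for exact,
hand-iterable fixtures because 1/3-valued weights stay on a lattice), and
`sign` (the tri-valued map, which makes limit cycles exactly periodic).

Convergence machinery, all configurable via `sim_config()`:

* `fixed_point_tolerance` ε = 1e−4: a fixed point is declared when the
  max-abs difference between consecutive states drops below ε. Under
  `tanh` + `self_memory`, states approach saturation asymptotically, so an
  exact fixed point is never reached in finite time; ε trades runtime for
  resolution and 1e−4 is well below anything interpretable on a 7-point
  scale.
* `max_iterations` = 100: dynamics of interest in this application are
  read off a few dozen iterations; the worked case reaches its ε-fixed
  point at 322 iterations if the budget is raised.
* `cycle_detection_horizon` = 50 and `state_rounding_digits` = 6: a limit
  cycle is declared when a state, rounded to 6 decimals, repeats a state
  seen within the last 50 steps. Rounding is needed because floating-point
  cycles are rarely bit-identical; 6 decimals is far finer than ε. The
  fixed-point check runs first, so a period-1 repeat is reported as a
  fixed point.
* Clamped constructs are overwritten after every step and in the initial
  row, so the clamp contract (clamped entries exact in every trace row)
  holds by construction.

The engine is fully deterministic; no randomness anywhere.

## Distances and goal achievement

The distance of construct `i` to the ideal at iteration `t` is
`d_i(t) = |a_i(t) - I_i| / 2 ∈ [0, 1]`; the aggregate is the unweighted
mean across constructs. No formula is canonical here; the normalized
absolute difference is chosen because it is pole-swap invariant,
interpretable (0 = at the ideal pole at full intensity, 1 = opposite
extreme) and keeps per-construct curves and their mean on the same axis.
A construct's desired change counts as *achieved* when its final distance
is below τ; the default τ = 1/6 is half of one rating step on the
normalized scale, i.e. "closer to the ideal than any observable rating
difference". Dilemmatic constructs (I = 0) are included in the distance
matrix but flagged, since distance-to-ideal is semantically weak when no
pole is preferred.

## Conflict detection

Conflicts are defined on the network, not on inter-element correlations.
For every nonzero edge `w[i, j]`:

* `goal_harms_content`: `i` discrepant, `j` congruent, and
  `sign(w_ij · g_i) = -sign(I_j)` — pursuing the goal pushes a contented
  construct off its ideal pole;
* `content_blocks_goal`: `i` congruent, `j` discrepant, and
  `sign(w_ij · a0_i) = -sign(g_j)` — the held position pushes a desired
  change backwards.

Severity is `|w|`; output is sorted severity-descending with (source,
target) index order breaking ties, so results are deterministic. No
composite conflict index is invented. Negative loops between two
*congruent* constructs are not flagged — they may still destabilise a
system, and users examining oscillating traces should inspect them, but
they do not match the desired-change-versus-contentment pattern this
detector formalises.

## Scenarios

`scenario_spec()` combines three mechanisms:

* **perturbations** — one-shot overrides of the initial state. A "simple
  change in behaviour" is modelled this way (not as a permanent clamp)
  precisely so the system can exhibit relapse: the behaviour is imposed
  once and the person's own attributions then take over.
* **clamps** — activations held fixed every iteration, modelling a
  sustained external intervention.
* **weight edits** — changes to the implication structure, supplied as
  *stored* scores (−3..3, 0 removes the edge) and re-encoded through the
  same elicitation-frame rule as `build_weight_matrix()`, using the
  original grid's Self-Now/Ideal-Self (the elicitation frame belongs to
  the interview, not to the perturbed state).

`apply_scenario()` is pure: it returns a new model and never mutates its
input. `compare_scenarios()` reports per-construct initial/final distances
under both runs, achieved flags, and a *relapse* indicator: distance below
τ at t = 1 but above τ at the end.

## Map digraphs

Nodes are named by the pole the person currently occupies (left pole if
the displayed state is negative, right if positive; at exactly 0 the label
falls back to the pole opposite the ideal — the side still to be left —
and to a combined "left vs right" label when the ideal is also at the
midpoint). Node colour encodes status (red = discrepant, green =
congruent, yellow = dilemmatic); node size is `10 + 20·|a|` and edge width
`0.5 + 2.5·|w|` — affine rather than proportional so zero-activation nodes
and weak edges remain visible; the constants are display-only. Edge colour
encodes the *displayed* sign `ŵ_ij = w_ij · p_i · p_j` (black = direct,
red = inverse), where `p_k` is +1 when node `k` displays its right pole.
This re-expression makes the involution property testable: swapping both
endpoint polarities preserves `ŵ`, swapping exactly one flips it. Export
is 2-D only (DOT, GraphML, JSON); layout is left to downstream tools.

## The packaged case and the generator

`worked_example()` ships a complete healthy-habits case whose anchored
cells are the narrated ones: construct 1 ("overweight vs. correct weight")
rated 1 (self), 4 (self in a year), 2/5/3 (father/mother/partner), 7
(ideal) and implying exactly three other constructs with intensities
very/very/quite; construct 2 rated 3 (self) and 7 (ideal). Every other
cell is a fixed synthetic completion, chosen once so the case realises the
qualitative narrative — a stable system, the eating-related goals tied
inversely to the contented "enjoys eating" pole, the undefined
"healthy vs. unhealthy" construct resolving toward the unhealthy pole —
and flagged `synthetic_completion` in the object metadata and the shipped
JSON file's name. The completions are illustration, not data; only the
anchored cells carry evidential weight.

`random_case()` emulates the *shape* of such cases: uniform ratings with
the Self-Now/Ideal-Self cells adjusted so the construct-status census
matches the configured fractions exactly (round-half-up allocation,
`floor(f·n + 0.5)`), and implication cells populated independently with
probability `implication_density` and uniform magnitudes. Defaults (12
constructs, 11 elements, density 0.25, a quarter congruent, none
dilemmatic) mirror the worked case's census. The generator does **not**
emulate structured real grids: no correlation between element columns, no
thematic clustering of implications, no reciprocity or transitivity in the
causal network, and independent uniform magnitudes rather than the
small-world, hub-dominated structures elicitation tends to produce.
Passing tests on generated cases therefore demonstrate contract
correctness (validation, frame consistency, determinism, conflict
enumeration) — not that the dynamics of real construct systems are
predicted well.

## Numerical and testing notes

Degenerate inputs: both-midpoint constructs are accepted but may not carry
implications; empty implication grids give zero weight matrices and
immediately stationary (kosko: collapsing) dynamics; clamp values are
applied exactly, including at t = 0. JSON interchange writes doubles with
17 significant digits so round trips are bit-exact. The test suite checks
the propagation engine against an independent naive double-loop
implementation (200 random systems of up to 8 constructs per
rule/threshold combination, agreement to 1e−12), exercises exact
hand-iterable fixtures (a two-node chain through `(0, tanh 1)` to the
origin; a period-2 antagonistic pair; a three-construct relapse case on
the clamp lattice with τ = 0.2, where the blocking score of 2 leaves the
t = 1 distance at 1/6, inside tolerance, before the drift of 1/3 per step
carries the goal away), and verifies the symmetry properties (odd
trajectories under global negation for odd thresholds; pole-swap
invariance of classification, exhaustive over all 49 rating pairs, and of
distances). Simulation sizes in tests stay at n ≤ 12 and a few dozen
iterations, which is the scale grids are actually elicited at.

## Known limitations

* The propagation/threshold families implemented are the standard discrete
  synchronous ones; continuous-time variants and FCM weight learning are
  out of scope.
* Conflict detection requires the construct statuses from the grid; it
  cannot run on a bare weight matrix.
* The implications grid is taken at face value as a signed causal
  attribution; the package does not attempt to infer implications from
  element-rating correlations, nor to reconcile an implications grid that
  contradicts the repertory grid.
* Dilemmatic constructs participate in dynamics but have no defined goal;
  interpreting their "distance to ideal" is left to the analyst.
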