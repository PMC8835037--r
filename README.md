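# pcsfcm

Fuzzy cognitive maps (FCMs) for personal construct systems, applied to the
psychology of adopting healthy habits.

## The problem

People who want to eat better, control their weight or exercise more often
fail even when the motivation is genuine. From the standpoint of personal
construct psychology, one reason is *cognitive conflict*: the change a
person desires on one bipolar construct (say, moving from "overweight"
toward "correct weight") is causally tied, in their own meaning system, to
losing something they are content with (say, "enjoys eating"). Such
conflicts are invisible to a motivational checklist but show up clearly
once the person's construct system is modelled as a causal network.

`pcsfcm` is for researchers and practitioners who elicit **repertory
grids** (constructs × elements ratings on a 1–7 bipolar scale) and
**implications grids** (construct × construct signed change-attribution
scores in −3..3) and want to:

1. build a fuzzy cognitive map from the two grids,
2. simulate how the Self-Now would evolve under the person's own causal
   attributions,
3. locate the conflicts that block desired change, and
4. test intervention scenarios (one-shot behaviour changes, sustained
   clamps, or changes to the implication structure itself) before trying
   them in real life.

## The model

Each construct *i* becomes a node with activation
*aᵢ* ∈ [−1, 1] in a right-pole-positive frame: rating *r* maps to
*a* = (*r* − 4)/3, so 1 ("very" the left pole) → −1, 4 (midpoint) → 0 and
7 ("very" the right pole) → +1. The initial activation vector is the
Self-Now column of the repertory grid.

The implication score *sᵢⱼ* ∈ {−3..3} answers: *if you moved from your
current pole of construct i to the opposite pole, toward which pole of j
would you move, and how strongly?* With the hypothesized movement
direction *dᵢ* = −sign(*aᵢ*) (falling back to the direction of the ideal
when the self sits at the midpoint), the canonical causal weight is

> *wᵢⱼ* = *dᵢ* · *sᵢⱼ* / 3.

Dynamics iterate a synchronous update

> *aⱼ*(t+1) = f( *aⱼ*(t) + Σ_{i≠j} *wᵢⱼ aᵢ*(t) )   (self-memory rule, default)
>
> *aⱼ*(t+1) = f( Σ_{i≠j} *wᵢⱼ aᵢ*(t) )   (classical rule)

with a squashing function f ∈ {tanh(λx), hard clamp, sign}, until a fixed
point, a limit cycle, or the iteration budget. Distances to the Ideal-Self,
*dᵢ*(t) = |*aᵢ*(t) − *Iᵢ*| / 2 ∈ [0, 1], summarise whether desired changes
actually happen.

Constructs are classified **congruent** (Self-Now and Ideal-Self on the
same pole), **discrepant** (opposite poles — change desired) or
**dilemmatic** (Ideal at the midpoint — no preferred pole). A conflict is a
nonzero weight whose sign means a desired change pushes a contented
construct off its ideal pole (`goal_harms_content`) or a contented pole
pushes a desired change backwards (`content_blocks_goal`).

## Worked example

The package ships a complete 12-construct × 11-element healthy-habits case
(`worked_example()`; unanchored cells are fixed synthetic completions, see
`?worked_example`). The subject rates himself "very" overweight (1) with an
ideal "very" at the correct weight (7), is content enjoying food, and does
not know whether he is healthy or unhealthy.

```r
library(pcsfcm)
case <- worked_example()
case$grid
#> Repertory grid: 12 constructs x 11 elements
#>   predefined constructs: 6
#>   elements: Self-Now [self_now], Self-in-a-year [self_year], father, mother, ...

model    <- build_fcm(case$grid, case$imp, sim_config(max_iterations = 400))
statuses <- classify_grid(case$grid)
detect_conflicts(model, statuses)
#>   source target     weight                kind  severity
#> 1      3      2  1.0000000 content_blocks_goal 1.0000000
#> 2      3      8  1.0000000 content_blocks_goal 1.0000000
#> 3      8      3  1.0000000  goal_harms_content 1.0000000
#> 4      2      3  0.6666667  goal_harms_content 0.6666667
#> 5      3      5 -0.6666667 content_blocks_goal 0.6666667
#> 6      3      7  0.6666667 content_blocks_goal 0.6666667
#> 7      5      3 -0.6666667  goal_harms_content 0.6666667
#> 8      7      3  0.6666667  goal_harms_content 0.6666667
```

Construct 3 is "enjoys eating vs. indifferent to eating": every one of the
subject's eating-related goals (control of eating, health, willpower,
healthy eating — constructs 2, 5, 7, 8) is inversely tied to the pole he is
content with, and holding that pole blocks those same goals.

```r
trace    <- fcm_simulate(model)
dynamics <- distance_trajectory(trace, ideal_vector(case$grid))
stability_report(trace, dynamics, statuses)
#> Stability report: fixed_point after 322 iteration(s)
#>   pole flips: construct 9 (+1 -> -1), construct 12 (+1 -> -1)
#>   midpoint resolutions: construct 5 -> +1 (away from ideal)
#>   desired but unachieved: construct 1, construct 2, construct 4, construct 5, ...
```

The system settles into a stable state in which the desired changes do not
occur; the initially undefined "healthy vs. unhealthy" construct resolves
toward the unhealthy pole. `plot(dynamics)` draws the distance-to-ideal
curves; `to_digraph()` + `export_graph()` write the colour-coded map
digraph (red/green/yellow nodes, black/red edges) as DOT, GraphML or JSON.
Scenario machinery (`scenario_spec()`, `apply_scenario()`,
`compare_scenarios()`) then shows that a behaviour-only perturbation
relapses while removing the blocking implications lets the goals endure —
see the vignette.

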