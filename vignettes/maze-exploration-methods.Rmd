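---
title: "Models and methods for binary-maze exploration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for binary-maze exploration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labmaze)
```

`labmaze` analyses the behaviour of mice that freely explore a labyrinth
shaped as a full binary tree of T-junctions, connected to their home cage by
a tunnel. The raw observable is the trajectory of the animal's nose; every
analysis in the package operates on its discretisation, the *node sequence*:
the time-stamped list of tree nodes (63 junctions, 64 end nodes for the
6-level maze) the nose enters. This vignette describes the models, the
parameters that matter, the numerical choices, and what the synthetic data
generator does and does not emulate.

## The maze as a graph

The maze is a heap-indexed binary tree: the central junction is node 0,
the children of junction $i$ are $2i+1$ and $2i+2$, and the 64 end nodes
are ids 63..126. The entrance corridor is not a node, so a "perfect path"
from the entrance to the water port is six steps through six junctions.
Physically the corridors form an H-tree on a 1.5-inch grid with corridor
lengths halving every other level; the embedding is used only for ring
classification and for rendering synthetic tracks, never for graph logic.

Left and right are *geometric* labels: the branch an animal perceives as
left when arriving from the stem of a T-junction. Because corridor axes
alternate with depth, the geometric label of a branch combines the heap
parities of the junction and child with an alternating handedness factor.
This matters: under geometric turn addressing, flipping the **first** turn
of a leaf's turn sequence lands on the end node diametrically across the
maze (the image of the port under a 180° maze rotation; coordinates exactly
negated, 12 steps away), and flipping **every** turn reflects the maze
about the entrance axis. These two operations and their composition form
the symmetry group of order 4 used to pick the three control nodes for any
target. Under heap-parity labels none of these geometric identities hold.

The water-port leaf is a configuration parameter. The default (node 125, an
outer-ring leaf adjacent to a corner) is an arbitrary documented choice;
nothing in the analyses depends on which outer leaf is picked.

The ring classification uses only the counts the embedding forces: the 64
leaves occupy an 8×8 grid of positions; the bounding perimeter holds 28
leaves (the published 26 plus the water port and its neighbour) and the
central 4×4 block the 16 "inner" leaves.

## From tracks to node sequences

`to_node_sequence()` marks the first entry of the (lightly smoothed) nose
position into each node cell; re-entering the same cell without visiting
another node cell is not a new event. Two numerical choices are ours
because no debounce rule is published:

* a new cell registers only once the nose crosses the cell midline
  (`register_radius = 0.25` cell widths), and
* coordinates are smoothed with a 5-frame moving average first.

With these defaults, synthetic tracks rendered at 30 Hz round-trip exactly
through reduction up to gaussian jitter of 0.2 cell widths; at 0.6 the
round trip breaks, which the tests exercise as a documented failure mode.
Non-adjacent consecutive node events ("teleports") are repaired by
splitting the sequence and warning — never by silently inventing decisions;
shortest-path interpolation is available but off by default.

A *bout* is a maximal run of maze-labelled events, entrance to exit. A
*direct path* is a node run without reversals, where a reversal at position
$i$ means the node after $i$ equals the node before it. Turning errors
follow from path length alone: in a tree every wrong step must be
backtracked, so errors = (length − direct length)/2, and an odd difference
is a data-integrity error rather than a number.

## Behavioural modes

Maze time is partitioned into three modes. *Drink* is the maximal
reversal-free run terminating at the water port plus the dwell there until
the first step away; *leave* is the terminal home run of the bout;
*explore* is everything else (for unrewarded sessions, everything except
the home runs). The drink and leave runs are detected retrospectively —
the run is only known to be an approach once it ends at the port — which
makes the three modes an exact partition but also means the analysed drink
time can reach slightly further back into the walk than a generative
model's intent (a few percent of total time; see the generator section).
Dwelling at the port during the reward timeout beyond the first step away
counts as explore, a documented choice.

Ethogram transitions out of *leave* are read from the first mode of the
next bout. Windows, histories and bias tallies never span mode-clip or
bout boundaries.

## Cage–maze transition hazards

The instantaneous rate of leaving a location after $t$ seconds of residency
is recovered from the identity $\int_0^t r = -\ln(1 - \int_0^t p)$ linking
the cumulative hazard to the residency-time distribution. The empirical
distribution uses the product-limit (Kaplan–Meier) estimate so the final,
right-censored residency of a session is used rather than discarded;
dropping it would bias long-duration hazards upward. The instantaneous rate
is the numerical derivative after gaussian-kernel smoothing of the
cumulative hazard (bandwidth 5 s by default; the source analysis does not
state its smoother). Where the survival estimate hits zero on the
evaluation grid, the cumulative hazard is clipped at the resolution limit
$\ln(2n)$ with a warning.

## Exploration efficiency

The discovery curve $d(n)$ is the mean number of distinct end nodes in a
sliding window of $n$ end-node visits, pooled with equal weight over all
windows of all explore-mode clips. The efficiency is $E = 32/N_{32}$, with
$N_{32}$ the interpolated crossing of $d(n) = 32$. The implementation uses
an exact first-occurrence-gap identity that computes all windows of one
clip in linear time, so full-session curves over hundreds of window sizes
cost milliseconds.

End-node *visits* are debounced with the two-step rule: after an arrival, a
new visit at the same end node counts only once the animal has moved at
least two steps away, so a leaf–junction–leaf flicker is one visit. This
rule is stated in the source analysis for target-node visit counting, and
it is quantitatively decisive here: the unbiased random walk yields
$E \approx 0.23$ under the two-step rule and $\approx 0.15$ under raw
first-entry counting. Occupancy distributions over end nodes default to
plain first entries, where the choice matters little.

The summary fit is $d(n) \approx 64\,(1 - (1+b)/(1 + z + b z^3))$ with
$z = n/a$: $a$ is approximately the number of visits to survey half the end
nodes (and $E = 32/a$), while the small parameter $b$ captures a late
acceleration in finding the last few nodes. Unweighted least squares over
the full range is used; the fits are tight enough that weighting is
immaterial.

## Turning biases and agents

Every step is one of four actions (in-left, in-right, out-left, out-right
by the geometric branch label). Tallying consecutive action pairs at
junction passages and forming the conditionals $p(a_1|a_0)$ yields the four
biases: $P_{SF}$ (forward from the stem), $P_{SA}$ (alternate given
forward), $P_{BF}$ (forward along the bar), $P_{BS}$ (branch into the stem
given forward). An unbiased three-way walk gives exactly
$(2/3, 1/2, 2/3, 1/2)$. Only explore-mode passages are tallied, and the
central junction is excluded by default: a maze-confined trajectory gives
the root no stem corridor, so its passages are not comparable (with
cage-labelled data the entrance step supplies the stem and
`include_root = TRUE` is appropriate).

The simulated agents are maze-confined. End nodes force reversal. At the
root, the stem-branch probability mass of the four-bias rule is
renormalised onto the two remaining moves; with unbiased parameters this
coincides exactly with the uniform rule. Alternation memory is reset at
the start of each simulation segment. The optimal explorer is the
depth-first sweep that visits each end node exactly once, giving
$d(n) = n$, coverage in 64 visits, and $E = 1$ identically.

The alternation bias, expressed in geometric turns, is what produces the
centrifugal preference for the outer ring of end nodes: persistent
alternation yields period-two heap signs, which maximise both coordinates
of the H-tree embedding. At $P_{SA} = 0.75$ a four-bias walker prefers
outer over inner leaves by a factor of about 2; at $P_{SA} = 0.55$ the
preference is mild (~1.2).

## Sudden-insight changepoints

Event trains (e.g. completions of long direct paths to the port, counted
on the in-maze clock with cage time excised, and with a strict ">6
junctions" rule that excludes the perfect entrance run) are modelled as
inhomogeneous Poisson processes,
$\ln L = \sum_i \ln r(t_i) - \int_0^T r$. Two rate families are fitted:
a sigmoid $r(t) = r_i + (r_f - r_i)(1 + \mathrm{erf}((t-t_s)/w))/2$ — the
form as sometimes printed lacks the offset that makes $r(-\infty) = r_i$;
we use the normalised form consistent with its verbal description — and a
step, whose likelihood is evaluated in closed form, profiled over $t_s$ on
a 10-s grid, and summarised by the mean and SD of $t_s$ under the
normalised profile likelihood. A change is *sudden* when the sigmoid width
is below 300 s and the step-time SD below 900 s; wide widths are gradual,
and narrow widths with too-uncertain step times are dropped.

One numerical point deserves emphasis. The plain 4-parameter maximum
likelihood estimate of the width is degenerate at realistic event counts
(~150 events): the step model nested at $w \to 0$ can always exploit fine
placement of $t_s$ between events, so the global ML width collapses to
zero even for genuinely gradual data. The default `fit_sigmoid()` therefore
estimates the width from the profile likelihood over a logarithmic $w$ grid
with the step time *marginalised* over its normalised likelihood — the same
treatment the step model applies to $t_s$ — and the rates profiled out
exactly (the per-cell likelihood is concave in $(r_i, r_f)$ and solved by
damped Newton). The spec-style multi-start ML remains available as
`method = "ml"`. Even so, with ~150 events the sudden/gradual distinction
at a 300-s threshold retains an irreducible error of roughly 10–20%: the
likelihood-ratio classifier with oracle parameters is only ~95% accurate
on these settings, and no parameter-free estimator we evaluated exceeded
~87%. Step-*time* recovery is much better behaved: the profile mean
locates a true step to ~40 s at these rates.

## Markov models of junction decisions

Decisions are evaluated during explore mode at T-junctions only (end-node
and drink/leave moves are fully predictable). A history is the string of
the $k$ most recent nodes; actions are in-left/in-right/out. Counts are
turned into probabilities by Laplace smoothing,
$p(a|h) = (n(h,a)+1)/(\sum n + 3)$, so unseen histories predict uniformly
and a model can never assign zero probability. Model quality is the
held-out cross-entropy $H = \langle -\log_2 p(a_t|h_t)\rangle$, in bits per
action against the prior uncertainty $\log_2 3 = 1.585$ bits.

Cross-validation splits the decisions into five folds of interleaved
fixed-length chunks (default 500 decisions) so each fold samples the whole
session evenly; fixed-depth models are scored on decisions with a full
depth-$k$ history. The variable-depth chain retains histories only while
their training count exceeds a threshold $m$ (suffix-closed retention,
default $m = 10$, swept on a grid) and predicts from the deepest retained
suffix. Optional pooling merges node labels of the same level and
geometric left/right type; the root keeps its own label since it has no
parent turn.

On synthetic four-bias data (a depth-2 source in node terms) the depth-2
model attains the source's conditional entropy, deeper fixed models
overfit at session length (held-out H rises beyond $k=2$), and the best
variable-depth model comes within 0.02 bits of the depth-2 model — the
count-threshold pruning cannot isolate exactly depth 2, so it does not win
on data whose true structure is uniform-depth; its advantage is on sources
with heterogeneous history relevance.

## The synthetic session generator

`generate_session()` emulates the study's data-generating process with
full ground truth: cage residencies drawn from a hazard that starts
fourfold elevated and relaxes with a 20-s time constant (the animal is most
likely to re-enter the maze right after returning); maze bouts ended by a
constant exit hazard; within bouts a drink/explore/leave activity cycle
with a configurable biased-walk policy, a 90-s reward timeout at the port,
and scheduled abrupt policy switches for changepoint studies. Defaults are
chosen to match the study's scale: 0.7 s per step gives ~16,000 steps per
7-h session at roughly half the time in the maze, bouts average two
minutes, and the post-drink choice is a 90% explore / 10% leave Bernoulli.
The default bias set (0.85, 0.55, 0.90, 0.60) is representative of
measured animals.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: continuous kinematics (speeds, accelerations,
pauses), grooming and naps, drift in the policy within an epoch,
persistent spatial memory beyond the turning biases, and the retrospective
character of real approach runs. The last point is visible in the tests:
the generator labels as drink only the deliberate approach, while the
analysis backdates the drink run to the last reversal, so recovered explore
fractions sit systematically a few percent below the generated ones; the
recovery tests budget ±0.07 for this.

## Problem sizes used in the tests

The test-suite simulations are sized for tight tolerances at interactive
runtimes: bias recovery and entropy anchors use walks of 1.6–3×10^5 steps
(≥10^5 junction passages, ±0.01 on each bias; ±0.02 bits against the
brute-force entropy oracle); efficiency checks use 100 replicates of 10^5
steps (±0.02 on E); changepoint recovery uses 100 step trains of ~165
events (median step-time error well under 200 s); overfitting checks use
16,000-step session-length walks.
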