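---
title: "Comparing modes of episodic memory use in spatial reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing modes of episodic memory use in spatial reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinav)
```

## The scientific question

Episodic memory can drive learning in at least two fundamentally different
ways. In *retrieval* mode, a single stored episode is used directly: an
animal repeats a route because it remembers reaching food along it once
(one-shot learning). In *replay* mode, stored experiences are reactivated
offline -- as hippocampal replay does during quiescence -- and used to train
an incremental learner on the statistics of many episodes (replay
learning). A brain without access to episodic memory can still learn
*online*, using each experience exactly once as it occurs. `epinav`
implements all three paradigms as reinforcement-learning agents in a
common family of gridworld navigation tasks so that their learning speed,
asymptotic solution quality, exploration footprint and reward-information
propagation can be compared under controlled, fully reproducible
conditions.

The three agents share the same task interface: sparse reward (+1.0 on
reaching a hidden goal, 0 elsewhere), discount factor $\gamma = 0.9$,
$\varepsilon$-greedy action selection with $\varepsilon = 0.1$, trials
capped at 600 steps, and performance averaged over independent runs.

## The environments

`build_tunnel_maze(level)` generates a parametric family of topology-graph
mazes. An open rectangular chamber (5x3 at level 1) sits at the south; a
1-wide corridor ("tunnel") arcs over its north side, rising 2 units at
level 1, running east, and descending into the chamber's north-east
corner. Each level increment elongates the tunnel north-south by one unit
and enlarges the chamber by one unit east and west and two units south, so
both the state count and the goal distance grow with task complexity. The
agent occupies *oriented states* -- (node, heading) pairs with four
headings -- and has six actions: forward, backward, two lateral
translations, and two in-place rotations. Translations only succeed along
graph edges; blocked moves leave the agent in place, because the topology
graph defines the allowed transitions and nothing else.

The start is the chamber's north-west node, at the tunnel mouth; the goal
is the chamber's north-east node, at the tunnel's other end. This yields
the two route classes the analyses depend on: a wall-constrained tunnel
route that funneled exploration discovers easily, and a strictly shorter
open route across the chamber's north side. (An earlier design placed the
goal at the chamber's south-east corner; in pilot simulations no agent of
any paradigm then ever adopted the tunnel route, because the corridor led
nowhere near the goal, so the goal was moved to the corridor's exit where
the two-route structure actually materializes. The exact geometry of the
original visual environments is not recoverable; only the route-class
properties are guaranteed, and `tunnel_maze()` accepts any explicit layout
as a drop-in replacement.)

## Observations instead of images

The original agents saw 84x84x3 camera images. At desk scale the codec
replaces the camera with a deterministic, spatially smooth embedding: the
pose $u(s) = (x/x_{max},\, y/y_{max},\, \cos\theta,\, \sin\theta)$ is
mapped through $D = 64$ random Fourier features whose bandwidth is chosen
so that observations of adjacent nodes at equal heading correlate at
about 0.8. Smoothness matters because episodic control bootstraps values
of novel states from their nearest stored neighbors -- meaningless under
white-noise embeddings, meaningful under visually-similar-nearby-views
ones. The number 0.8 is a modeling constant, not an empirical claim: the
similarity structure of the original visual inputs was never
characterized, so we pick a value high enough for neighbor lookups to
generalize and low enough for states to stay well separated
(`adjacent_cor` is configurable).

Episodic control additionally projects observations through a seeded
random matrix $\phi(x) = Mx$ with standard-normal entries and $F = 256$
rows, as in the original algorithm; by the Johnson-Lindenstrauss lemma
the map approximately preserves relative distances. The projection is kept
even though $F \ge D$ here, to preserve the algorithm's structure.

## The three learners

**Episodic control** (`ec_memory`, `ec_update`, `ec_q_lookup`) keeps a
table $Q^{EC}$ keyed by projected state and action. At every episode end,
each visited pair is set to the episode's discounted return from that
step, under a max rule: values never decrease, so the table always encodes
the best outcome realized so far, and
$Q^{EC}(s,a) = \gamma^{d-1}$ with $d$ the fewest realized steps to goal.
Because the codec is deterministic, revisited states collide exactly;
$k$-nearest-neighbor averaging (k = 5, Euclidean distance in projected
space) is used only for genuinely novel states. Two details the original
description leaves open are resolved as documented decisions: neighbors
lacking a value for the queried action contribute 0 to the mean
(configurable to skip them), and capacity eviction (cap 50,000 entries,
never binding at desk scale) removes least-recently-updated entries
first. The package also ships the *forward-sweep* formulation -- store all
episodes verbatim, sweep forward from every occurrence on demand, take
the max -- as `ec_oracle()`; the two are provably equivalent and the test
suite asserts entrywise equality on seeded histories.

**Replay learning** (`q_approximator`, `replay_buffer`, `replay_update`)
trains a parametric Q function by mini-batches (32) drawn uniformly with
replacement from a FIFO buffer, against a soft-updated target network
($\bar w \leftarrow \bar w + \alpha (w - \bar w)$, $\alpha = 0.01$).
Because the original convolutional network is image-specific and the
phenomena depend on incremental function approximation rather than
convolution, the approximator is configurable: a one-hot tabular map, a
linear map on the observation, or a two-hidden-layer ReLU perceptron.
Linear and MLP nets use Adam with the stated learning rate $10^{-4}$;
the tabular net uses plain gradient steps of size 0.1. Two printed-form
ambiguities are resolved to standard Q-learning semantics -- the TD target
is discounted and terminal-masked, and the online network predicts while
the target network bootstraps -- with `literal = TRUE` switches that
reproduce the printed forms exactly.

Two numerical safeguards matter at desk scale. First, updates begin only
once the buffer holds one full batch: sampling 32 tuples with replacement
from a near-empty buffer repeats a single transition up to 32 times in
the summed loss, which destabilizes any usable step size. Second, within
a tabular mini-batch a table entry drawn several times steps toward the
*mean* of its TD targets rather than accumulating repeated summed
gradients (which is unstable whenever $2\,\eta\, n_{rep} > 2$); linear
and MLP nets keep the literal summed-loss gradient, whose repeats average
out across weights.

**Online learning** (`online_update`) is the lesion model: one squared TD
error per transition, one gradient step, nothing stored. A counting audit
in the test suite verifies that each environment transition is consumed
by exactly one update.

Two diagnostic replay variants disentangle *why* replay helps
(`update_schedule`): `batch_size_one` keeps one update per step but
shrinks the batch to 1 (removes gradient averaging, keeps decorrelation),
and `sparse_sampling` keeps batch 32 but updates every 32 steps (keeps
averaging, matches the online data budget). Both consume exactly as many
training tuples as online learning.

## Sequential replay

The biologically motivated sampler (`experience_store`,
`generate_replay_event`) replays at trial end only, in events of
`n_batches` x 32 reactivations, each batch driving one network update.
The probability of reactivating experience $e$ after $e'$ follows
$p(e\mid e') \propto e^{\beta R(e\mid e')} - 1$ with reactivation score
$R = C(e)\, D(e\mid e')\, (1 - I(e))$:

* **Strength** $C(e) = c(e)\,(1 + \lambda_r \bar r(e))$, with $\bar r$
  the tuple's mean reward and $c(e)$ its visit count. By default the
  count is normalized by the maximum stored count so that $C \le 1 +
  \lambda_r$. The exact functional form lives in prior work, not in the
  description this package follows; with raw counts (available as
  `strength_norm = "none"`) scores reach the hundreds after a few dozen
  trials and $e^{\beta R}$ saturates to an argmax for every
  $\beta \ge 1$, erasing the documented dependence of sequence length
  and batch similarity on $\beta$ over the range 0-10. Normalization
  keeps $\beta R$ on the order-1 scale that the stated $\beta$ range
  presupposes.
* **Similarity** $D = e^{-d_G/\sigma}$ over the graph distance between
  anchor nodes, $\sigma$ = 1 node. In reverse mode (the default
  experimental setting) the candidate's *next* state is anchored against
  the previous reactivation's *current* state, so chains extend backward
  along behavior; forward mode mirrors this; at an event start $D
  \equiv 1$.
* **Inhibition**: a reactivated tuple is fully inhibited ($I = 1$,
  probability exactly 0 thanks to the $-1$ shift) and all inhibitions
  decay by $\lambda_I$ per reactivation step. Whether inhibition decays
  within or across events is not specified in the source description; it
  resets at each event start and decays within the event. The default
  $\lambda_I = 0.99$ keeps the disinhibition horizon
  $1/(1-\lambda_I) = 100$ reactivations on the scale of an event
  (320-1600 reactivations): a horizon of ~10 steps lets one event loop
  over a handful of tuples near its anchor instead of covering the
  store, while 100 still permits revisits within long events.
  Refractoriness additionally acts at the level of the co-localized
  assembly: when the wave covers a node, every experience that would
  pull it back into that node is inhibited together with the
  reactivated tuple. Each oriented node hosts up to 24 tuples (four
  headings, six actions); with purely per-tuple inhibition the "wave"
  diffuses among them and never leaves the anchor's neighborhood,
  whereas assembly-level refractoriness makes reverse waves sweep
  outward ballistically -- the defining feature of the replay
  phenomenon being modeled.

Three further regime choices make the trial-end mode a working model of
offline replay rather than a re-labeled mini-batch learner:

1. **Events initiate at the agent's current position.** A replay event
   receives the trial's final state as its anchor (on successful trials,
   the goal), seeding the first similarity factor there; reverse events
   therefore begin near the reward and sweep backward, which is how the
   reward information propagates. An unanchored event seeds from the
   strength factor alone and starts in whatever region the agent visited
   most -- usually the start area, where replay propagates nothing.
2. **Each batch is one replay sequence.** The event re-initiates at the
   anchor at every batch boundary; the inhibition laid down by earlier
   batches pushes each successive sweep farther out, so one event tiles
   the route from the goal outward in order. A single un-reset chain
   drifts to an intermediate distance and parks there.
3. **Trial-end updates bootstrap from the online values** (for the
   random comparator too). Under the per-step replay learner's slowly
   tracking target network ($\alpha = 0.01$), value information moves at
   most about one bootstrap layer per event no matter how the batch is
   ordered, which silences sequential replay's chaining advantage
   entirely; bootstrapping the offline regime from the online values
   lets an ordered reverse sweep propagate reward across many states in
   a single event, which is precisely the mechanism under study. The
   per-step replay learner keeps the standard target-network semantics.

At $\beta = 0$ the sampling rule switches discontinuously to uniform
over eligible (visited, disinhibited) tuples -- deliberately distinct
from the *random replay* comparator (`random_replay_event`), which
samples proportionally to visit frequency. Experiences are deduplicated
by (state, action, next state) with rewards tallied, so the two
distributions genuinely differ whenever visit counts are unequal.
Replay sequence lengths are scored at the spatial resolution replay
statistics are usually scored at: a run continues while consecutive
reactivations' anchor nodes stay within one node of each other.

## Training protocol and analyses

`run_training()` executes the full protocol: fixed start (facing north),
$\varepsilon$-greedy actions, per-algorithm learning, 600-step timeout,
with every random stream derived from one master seed (runs are exactly
reproducible; greedy ties are broken uniformly from dedicated seeded
streams, a choice that matters because zero-initialized value tables make
ties ubiquitous early on). Analyses mirror the study's result classes:

* `learning_curve()` / `learning_auc()`: trialwise mean and sd of escape
  latency; the area under the first 100 trials is the scalar
  learning-speed statistic compared across runs by rank tests.
* `test_trial()` runs greedy probes ($\varepsilon = 0$; test-time
  exploration is not specified in the source description, and greedy
  probes make solution labels deterministic given the tie-break stream).
* `solution_state_analysis()` partitions states into never-visited /
  visited-non-solution / solution by probing every visited state.
* `route_classification()` labels a test trajectory `tunnel` iff it
  visits a tunnel corridor node, `timeout` if it never reached the goal.
* `batch_similarity()` / `event_similarity()` measure the deduplicated
  shared-tuple proportion between replay batches (multiset intersection
  available), aggregated over the events of the first 200 trials.
* `relative_performance()` is the inverse latency ratio
  (random / sequential; values above 1 favor sequential replay).

## Study sizes used by the shipped tests

The package's acceptance analyses regenerate each result class at sizes a
desktop reproduces comfortably, chosen once: learning-speed and
replay-variant comparisons on the level-1 maze with the linear
approximator, 20 runs x 200 trials, rank-tested across runs on the
100-trial area under the latency curve; asymptotic-quality and
reward-propagation comparisons with the linear approximator on level 1
(8 runs x 300 trials) and level 4 (5 runs; 300 trials, 250 for the
online learner, whose exploration-footprint claim more trials could only
strengthen); route-choice fractions on level 4 with 50 runs (episodic
control with the full projection-and-neighbors machinery over 500
trials, replay learning tabular over 300, by which point its route
choice has long stabilized); sequential-vs-random replay on level 4 with
tabular trial-end learning, 10 runs x 80 trials per cell for
$\beta \in \{0, 1, 2, 5, 10\}$ at 10 batches per event, plus 50-batch
cells (60 trials) for the many-replays comparison. Equation-level
properties (returns, max updates, soft updates, reactivation scores and
probabilities, samplers) are checked against closed forms and
brute-force oracles at machine precision. The tabular approximator is
deliberately avoided in the asymptotic-quality comparison: a table plus
32-fold replay propagates reward to essentially every visited state in
these small mazes, collapsing the propagation-efficiency contrast that
an incremental function approximator (like the original network)
exhibits.

## What the synthetic environments do and do not show

The generator emulates the *structure* of the original tasks -- topology,
action set, sparse reward, timeout, route classes, observation
smoothness -- not their visual front end. Conclusions that rest on that
structure (one-shot learning is fastest; replay's advantage comes from
data reuse; slower learners explore more and find shorter routes;
reverse sequential replay beats frequency-weighted random replay when
replays are few and mildly stochastic) replicate here and are asserted
by the test suite. One quantitative result does not carry over: the
*proportion* of one-shot agents locked into the tunnel route. That
fraction is set by the probability that a uniform random walk's first
successful, loop-erased trajectory traverses the corridor, which under
every reconstruction of this maze family we examined (chamber depths 9
to 21, corridor rises 2 to 5, several start/goal placements, an
open-bulge variant) is capped near one quarter to one third by
one-dimensional hitting statistics against the shorter wall-guided
route -- well below the roughly one half reported for the original
geometry, which text alone cannot recover. The package reports the
fraction its own conditions produce; the *direction* of the contrast
(one-shot agents lock into the long route far more often than replay
learners, which converge to the short one) is robust here.

## Known limitations

* Goal locations are fixed for a maze's lifetime; relearning after goal
  displacement is out of scope.
* No prioritized experience replay comparator, eligibility traces, or
  model-based baselines.
* The MLP approximator is deliberately small and CPU-bound; at image
  scale one would swap in a convolutional network behind the same
  `q_approximator` surface.
* Statistical output is limited to descriptive aggregation and rank
  tests across runs; no mixed-effects modeling of learning curves.
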