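---
title: "A latching attractor-network account of semantic priming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A latching attractor-network account of semantic priming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semlatch)
```

## The model

semlatch simulates the standard semantic-priming task — a prime word, a
delay (the stimulus onset asynchrony, SOA), a target word, and a measured
recognition time — as the dynamics of two coupled attractor networks.

Each layer is a fully connected recurrent network of $N = 500$ analog units
with activity $x_i = g(h_i)$, $g(z) = 1/(1 + e^{-z/T})$, whose local input
follows

$$\tau_n \dot h_i = -h_i + \sum_j J_{ij}\, x_j \;-\; \lambda(\bar x - p)
\;-\; \theta \;+\; [I^{ext}_i - \theta^{ext}]_+ \;+\; \eta_i ,$$

integrated by forward Euler at $\Delta t = 0.66$ ms. Memories are sparse
binary patterns (a fraction $p$ of units active) stored in the sparse-pattern
Hopfield (covariance) matrix

$$J^{max}_{ij} = \sum_\mu \frac{(\xi^\mu_i - p)(\xi^\mu_j - p)}{N p (1-p)},
\qquad J_{ii} = 0 .$$

The **semantic layer** ($p = 0.06$) stores concepts; semantic relatedness is
the number of active units two concepts share (strong 10%, moderate 6.6%,
weak 3.3% of a pattern). Its recurrent synapses undergo Tsodyks–Markram
short-term depression,

$$\dot J_{ij} = \frac{J^{max}_{ij} - J_{ij}}{\tau_r} - U\, x_{max}\, x_j\,
J_{ij},$$

so no attractor can be held indefinitely: together with temporally
correlated Gaussian noise (an exact AR(1) discretisation with stationary
standard deviation $\eta_{amp}$ and autocorrelation $e^{-\tau/\tau_{corr}}$),
the state *latches* — hops stochastically between attractors, preferring
correlated neighbours. This is the model's free-association process, and the
noise amplitude is its attention dial: high noise ($0.05$) permits latching
(mode I), low noise ($0.01$) freezes the current concept (mode III), and a
drop after the first transition holds the concept just reached (mode II).

The **lexical layer** ($p = 0.04$) stores words as mutually disjoint
patterns with no depression: a steady-state recogniser. Words and concepts
are paired one-to-one; active units of a pattern excite all active units of
its paired pattern, with the raw gain divided by the presynaptic pattern
size. Bottom-up (lexical-to-semantic) connections are strong (raw gain 2)
but depress with a slow recovery ($\tau_r = 1333$ ms), giving the lexical
layer a fast, short-lived influence; top-down feedback is weak (raw gain
0.21), never depresses, and only matters where it sums with congruent
bottom-up input above the lexical external threshold ($\theta^{ext} =
0.25$). A trial's reaction time is the time from target onset until the
lexical state reaches correlation $\ge 0.95$ with the target word.

Both layers also store an extra *baseline* pattern — unpaired across layers
— on which they rest at trial start; it stands in for the neutral prime.

Priming falls out of this arrangement: a related prime leaves the semantic
layer on (or one transition away from) a concept sharing units with the
target's concept, and the feedback through those shared units accelerates
the lexical convergence. Mediated priming additionally requires an actual
transition (lion → tiger) before the target (stripes); backward priming
needs only the symmetric correlation and therefore dies at long SOA, when
transitions have likely led elsewhere.

## Control: noise reinforcement learning and expectancy

The two-component semantic noise vector (trial-start, post-first-transition)
is adapted across trials by a reward rule on reaction time:

$$\eta_{amp}(n+1) = \eta_{amp}(n) + \alpha\,(\overline{RT}_{n-1} - RT(n))\,
\varepsilon(n), \qquad \varepsilon(n) \sim \mathcal N(0, A e^{-\beta n}),$$

with $\alpha = 0.002$, $A = 0.06$, $\beta = 0.0125$; $\overline{RT}$ is the
exact running mean of accepted trials, the first trial performs no update,
timeouts are excluded, and amplitudes clamp at zero. We read
$A e^{-\beta n}$ as the exploration **standard deviation**: as a variance it
would imply exploration (~0.24) dwarfing the operating range of the
parameter itself (0.01–0.05) and destroying any gradient signal; the choice
is configurable (`exploration_scale`).

The expectancy strategy is modelled as its end state, not learned online: on
the first transition of a trial the noise drops to the low component and the
feedback gain switches to an elevated value (0.5145 in the category-shift
simulation, 0.4977 in the frequency/degradation simulation, both above the
lexical threshold). Above threshold the feedback acts alone: congruent
targets are strongly facilitated, incongruent ones inhibited through the
lexical layer's recurrent competition — which is how the model produces
genuine inhibition relative to neutral, absent at the default gain.

## Choices the equations do not fix

Several implementation decisions were genuinely open; we record them here
with their rationale. Each is also a configurable switch or a documented
mode where a user might reasonably want the alternative.

**Unrelated patterns share units at chance level.** The covariance rule is
built for random sparse patterns. Forcing every unrelated pair to share
exactly zero units in $N = 500$ with seventeen 30-unit patterns puts each
unit in at most one pattern, which leaves a systematic $+p^2$ residue in
every cross-pattern weight and halves the inhibition between patterns; a
strongly correlated neighbour is then *statically* recruited and the state
is a two-pattern mixture whose Pearson correlation saturates near 0.70 —
convergence at the 0.95 criterion never happens and latching is
undetectable. We therefore generate unrelated (and baseline) patterns with
chance-level overlaps, capped at 2 shared units: the cap removes the upper
tail of the chance distribution (4–5 shared units), which otherwise seeds
partial "coalition" states that hold the stationary correlation near
0.85–0.87. Designated pairs keep their exact shared counts. With this
construction every stored pattern is a genuine fixed point (correlation
$\ge 0.99$ without noise and depression), latching appears at $\eta_{amp} =
0.05$ and vanishes at $0.01$, and first transitions prefer the strong
neighbour. A strict `unrelated_overlap = "zero"` mode remains, and is the
default for lexical sets, which are few enough to be safely disjoint.

**Episodic salience is expressed in the same currency as the semantic
weights.** The episodic term adds $\kappa\,\xi^{\upsilon}_i \xi^{\mu}_j$
with $\kappa = 0.0336$. As an absolute per-synapse increment this equals a
full Hopfield active–active weight, so a fully active source would drive
every destination unit with $\approx 30\kappa \approx 1$ — the destination
co-activates outright and the memory structure collapses. Since $\kappa$ is
defined as the salience of episodic connections *relative to the semantic
ones*, we scale the increment by the Hopfield normalisation $1/(Np(1-p))$: a
full source then biases its destination by about 1.1 shared-units-worth of
drive. Measured on a strong pair, the link raises the first-transition
probability from 37% to 84% while leaving all other behaviour intact.
`add_episodic_link()` exposes the raw increment for direct weight surgery.

**Depression is presynaptic.** The depression equation is printed with
$x_i$, but the cited depressing-synapse mechanism consumes presynaptic
resources, and a presynaptic drive makes the depression state a property of
the sending unit. We use $x_j$ (for $J_{ij}$, $j \to i$);
`step_depression(variant = "postsynaptic")` gives the literal reading for
sensitivity checks. The bridge from Table-3 units to rates is $U\,[1/\mathrm
{spike}] \times x_{max}\,[\mathrm{spikes/s}] \times x \in [0,1]$, i.e. a
depletion rate $U x_{max} x / 1000$ per ms — the only dimensionally
consistent reading.

**One rectification per layer.** A layer's external-origin inputs (visual or
relay drive plus inter-layer drive) are summed and rectified once against
its $\theta^{ext}$. This reproduces both statements the threshold has to
satisfy: weak feedback alone (0.21 raw) does nothing to the lexical layer,
yet it adds to congruent bottom-up input; elevated feedback (≥ 0.5) acts
before the target arrives.

**Transition bookkeeping.** A transition is a change of the converged
pattern (max correlation $\ge 0.95$) from one non-baseline pattern to a
different pattern; passing through "not converged" is not a transition, and
the externally driven departure from the baseline at stimulus onset is not
one either — otherwise every primed trial would count one "transition" and
the low-noise mode III could never report zero. The first transition of a
trial triggers the policy (noise component switch; expectancy gain switch);
later modulations are ignored.

**Initialisation "converged on a pattern".** $x = \xi$, $h =
g^{-1}(\mathrm{clip}(\xi, 10^{-6}))$, then 50 ms of deterministic relaxation
with depression frozen, so trials start exactly at the attractor with
undepressed synapses. Trials reset fully (baselines, depression ceilings,
fresh noise): the human inter-trial interval is not simulated, and the slow
inter-layer depression would otherwise leak across trials in ways the
original account does not model.

**Prime input duration.** 100 ms by default (clipped to the SOA), matching
the cue duration of the free-run demonstrations; whether the prime stayed on
until target onset in the original trials is not stated, so it is a
`trial_spec` field.

**Timeouts.** 2000 ms after target onset; timed-out trials are flagged,
excluded from RT means and from the controller's update and running mean.

## The built-in semantic structures

`build_named_structure()` provides four 16-concept structures. The
category-shift structure (`neely_3x4`) and the frequency structure
(`freq_4x4`) follow their stated designs (four neighbourhoods of four
moderately correlated concepts; the first two neighbourhoods episodically
cross-linked in the category-shift case). The `mixed_vocab` vocabulary
(dog, cat, kitten, mouse, beware + fillers) is a demonstration vocabulary
with graded relations chosen to produce the canonical orderings (dog–cat
strong and associated both ways; kitten→cat moderate and associated;
mouse–kitten weak; beware→dog a backward association), plus a few filler
correlations. `mixed_ldt` mirrors a mixed lexical-decision list:
direct pairs (strong, forward-associated), mediated triples
(prime–mediator–target, with the prime–target correlation absent), and
backward pairs whose primes carry a forward associate *away* from the
target — the competing associate is what makes backward priming collapse at
long SOA and what makes a backward/category-exemplar list favour the
no-transition strategy. Because chance-level overlaps make any single
realisation's "unrelated" pairs unrelated only in expectation, the list's
evaluation crossings (mediated prime–target pairs, the re-paired unrelated
contrasts) are designated as a `zero` overlap class — exactly no shared
units, the construction-level analogue of norming stimuli for verified
unrelatedness — and its baseline is generated strictly disjoint
(`baseline_overlap = "zero"`), so the related/unrelated and
neutral/unrelated contrasts are unbiased by construction.

For the list-learning simulations the controller starts at the task-typical
defaults: low noise $(0.01, 0.01)$ for lexical-decision-like experiments —
the cautious mode in which transitions must be *learned* when the list makes
them profitable (associative lists at long SOA drive the vector toward mode
II) and are simply never acquired when it does not (category-exemplar-like
lists stay in mode III). The relatedness proportion gates how often the
learner sees informative related trials, hence mode-II learning is stronger
at RP 0.8 than at RP 0.2. The clean readout of that learning is the *gap*
between the trial-start and post-transition amplitudes: latching gives a
small generic speed-up even on unrelated targets (stray congruent feedback
through the joint rectification), so the start component drifts up under any
list, while only related trials reward holding the concept just reached —
a learned drop of the second component — and that reward scales with the
RP. Exploration decays as $e^{-\beta n}$, so the
total movement the controller can make is bounded; with pronunciation-like
high-noise starting points the same lists produce the same *directions* of
change, but crossing the mode boundary within a few hundred trials is not
guaranteed — a property of the published learning constants, not of this
implementation.

## What the synthetic data do and do not emulate

All inputs are synthesized: there is no corpus, no embeddings, no subject
data beyond two embedded reference tables of printed mean reaction times
used as analysis fixtures. The pattern generator reproduces the *prescribed
statistics* of the memory structures (sizes, sparseness, pairwise overlap
classes, episodic links); it does not claim that real semantic memory has
clique neighbourhoods, uniform pattern sizes, or exactly three relatedness
grades. Simulated reaction times cover only the pre-lexical pathway — a
constant display/decision/motor offset (450 ms when comparing to human
scales) is outside the dynamics — so passing tests show that the *ordering
and interaction patterns* of conditions (relatedness, SOA, RP, expectancy,
frequency, degradation) emerge from the mechanism, not that millisecond
magnitudes match human data. Word/nonword decisions, error rates, and
multi-item working memory are out of scope.

## Numerical and testing choices

The compiled core (RcppArmadillo) exploits the exact low-rank structure of
all weight matrices — $J^{max} = AB^{\top} - \mathrm{diag}(c)$ with one
column pair per stored pattern or episodic link, and per-presynaptic-unit
depression factors $J(t) = J^{max}\mathrm{diag}(d)$ — so a step costs a few
$N \times K$ products instead of $N^2$ updates. A dense, plain-R reference
integrator implements the same algebra; the test suite asserts the two paths
produce identical trajectories on deterministic trials. Noise inside the
compiled core uses a dedicated Mersenne-Twister stream seeded per trial;
determinism is therefore per (seed, trial), and the noise contract
(stationary sd within 5%, autocorrelation $e^{-1}$, $e^{-2}$ at lags
$\tau_{corr}$, $2\tau_{corr}$ over $10^6$ samples) is tested statistically.

Problem sizes in the test-suite and acceptance runs are chosen to keep a
full check under half an hour on one core: statistical priming comparisons
use 50 seeded trials per cell pooled over counterbalanced pairs (every
comparison crosses its $2\,\mathrm{SEM}$ band comfortably at that size);
latching-regime rates use 100 free runs of 1500 ms; the stability check
holds every pattern of the frequency structure for 5000 ms; the full-model
learning checks use 10 seeds × 120 trials per list. The reference-table
computations are exact and instantaneous.

## Known limitations

The stationary state of a pattern with a strong, episodically linked
neighbour sits a few percent below a Pearson correlation of 1 (the
neighbour is partially co-activated — the model's own account of automatic
spreading activation); detection at 0.95 happens on the approach, so
convergence times are well-defined, but analyses that require the *static*
correlation to exceed 0.95 should use structures without bidirectional
episodic pairs. The controller's reachable set is bounded by the decaying
exploration schedule (see above). Chance-level overlaps make "unrelated"
pairs only unrelated in expectation: condition contrasts should
counterbalance targets across primes, as the built-in designs do.
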