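---
title: "Designing functional gene circuits: from Boolean trajectories to robustness scores"
author: "CircuitDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing functional gene circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircuitDesign)
```

# The design problem

Given a target dynamic behaviour written as a sequence of ON/OFF network
states — here the *E. coli* SOS DNA-damage response: damage signal
appears, repair genes pulse, the repressor dips and recovers, the signal
is cleared — which regulatory circuits can execute it, and which of
them do so *robustly*? CircuitDesign answers in two steps:

1. **Discrete step.** Every signed topology whose synchronous Boolean
   dynamics reproduce the target trajectory is enumerated analytically;
   the fewest-edge ("minimal") networks are extracted.
2. **Continuous step.** Surviving topologies are converted to
   Hill-kinetics ODEs and scored by the fraction of random kinetic
   parameter sets (the **Q value**) and the number of perturbed initial
   states (the **basin size**) that still produce a successful
   response.

# The discrete model

Each node $i$ carries a state $S_i(t) \in \{0, 1\}$; a signed adjacency
matrix $a_{ij} \in \{+1, -1, 0\}$ encodes activation and inhibition.
The update is synchronous with **dominant inhibition**: one active
inhibitor forces a node OFF regardless of its activators, any active
activator turns an uninhibited node ON, and a node with zero net input
keeps its state. Self-edges follow the constraint form of the rule: an
ON node stays ON unless self-inhibited, and an OFF self-activating node
switches ON when nothing inhibits it. This last clause is what lets the
sigma-factor node of the SOS network ignite spontaneously once its
repressor clears — without it the packaged trajectory is not
reproducible, which is why the package treats the constraint form as
canonical for self-edges.

Because each node's next state depends only on its own incoming
regulation, trajectory consistency factorises node by node: for every
node we enumerate all $3^N$ regulator assignments and keep those that
reproduce the node's bit across *every* transition. One modelling
choice matters here: the trajectory ends when the system has *returned
to its normal state and stays there*, so the terminal fixed point's
self-transition is part of the constraint set (the terminal row is kept
duplicated in `BooleanTrajectory` objects to make this explicit). On
the SOS fixture this yields per-node counts (20, 20, 30, 37, 4, 4),
i.e. 7,104,000 consistent networks out of $3^{36} \approx 1.5\times
10^{17}$ topologies; dropping the self-transition would inflate the
space 25-fold.

```{r discrete}
fix <- loadSOSFixture()
sol <- reverseEngineer(fix$trajectory, inputNode = 1)
sol
length(minimalNetworks(sol))
```

Minimal networks keep, per node, all configurations tied at the
minimum edge count (no arbitrary tie-break) and exclude any self-loop
on the input node — the damage signal cannot regenerate itself. The
7.1-million count is reported *before* that exclusion, which the
analysis introduces only at the minimal-network stage;
`reverseEngineer(allowInputSelfLoop = FALSE)` exposes the other
convention.

# The continuous model

Non-input nodes follow saturating transcription kinetics with Hill
coefficient 2, multiplicative independent inhibition, basal production
0.1 and unit degradation:

$$\frac{dx_i}{dt} = \Big[\sum_{j \in \mathrm{act}(i)} \frac{W_p\, a_j\, x_j^2}{\delta b_j + x_j^2}\Big]
\prod_{j \in \mathrm{inh}(i)} \frac{1}{c_j + W_n d_j x_j^2} + 0.1 - x_i .$$

The input node is consumed by repair rather than transcribed:
$dx_{\mathrm{in}}/dt = -\sum_j x_j^2/(c_j + x_j^2)$ over its
inhibitors, unweighted. Two numerical choices around this equation:

* The printed decay is strictly negative whenever repair genes are
  expressed at all, so the signal would cross zero and keep falling.
  The implementation multiplies the decay by a continuous ramp (full
  strength above $10^{-3}$, linearly vanishing below) so the cleared
  state is absorbing, exactly mirroring the discrete model. A hard
  on/off gate was tried first and rejected: the discontinuity makes
  the step-size controller chatter at the crossing.
* $\delta$ (promoter leakage) is a single global factor scaling every
  dissociation constant $b_j$; activation edges onto the input node
  are ignored because its rate law has no production term.

Integration uses `deSolve::lsoda` (compiled right-hand side) with
relative tolerance $10^{-6}$, over a fixed horizon of 50 dimensionless
time units reported at 501 points — fifty times the unit degradation
timescale, after which an unregulated node is within $10^{-4}$ of its
basal level. A fixed grid keeps trajectories directly comparable
across parameter sets; no early-exit steady-state test is used.
Negative undershoots beyond $10^{-6}$ are treated as integration
failures; smaller ones are clamped to zero.

# Success criteria and pattern classes

A run succeeds when (i) the signal is cleared (final input below
0.01); (ii) the system relaxes to the normal state — the designated
normal node (LexA) strictly tops every other final value *and* every
other non-input node ends below 0.2; (iii) each node's continuous time
course reproduces its discrete pattern class — `decline` for the
signal, `peak` for the pulsing genes, `valley` for the repressor,
classified with an absolute margin of 0.05 on the concentration scale
(constant Boolean nodes are exempt); and every gene's maximum
expression exceeds the 0.1 floor, so a "response" in which a gene
never expresses does not count. The thresholds 0.01 / 0.2 / 0.05 / 0.1
are package defaults, exposed as arguments: the criteria must be
decidable on finite-precision trajectories, and ranking alone (the
literal reading of criterion ii) would accept end states far from
normal. When a series has both a qualifying interior maximum and
minimum, the extremum that occurs first in time decides the class — a
convention; the discrete model never produces such a series.

```{r criteria}
expectedPatterns(fix$trajectory)
```

# Scoring robustness

**Q value.** For each topology, `sampleParameters()` draws one Latin
hypercube over all free dimensions (per-edge $a, b, c, d$ plus $W_p,
W_n, \delta$). Kinetic and dissociation constants default to
log-uniform on $[0.1, 10]$, the weights and leakage to $[0.5, 5]$ — a
symmetric two-decade span around 1 for the dimensionless constants.
The ranges are *part of the experimental condition*: a Q value is only
meaningful relative to a declared range, and all ranges are overridable
in the configuration. Integration failures count as criterion
failures, not dropped samples — a parameter set that cannot be
integrated is not demonstrably functional.

**Basin size.** The state-space score pins the input at 1.0 and starts
every other node at either basal 0.1 or expressed 1.0 ($2^{N-1} = 32$
states). A state counts when criteria (i), (ii) and the floor hold;
the pattern criterion is dropped because a different start legitimately
changes the transient shapes. Which parameter sets to use is not
dictated by the method, so the package conditions on the topology's
own *functional* sets and reports the mean count (plus the maximum and
the first set's count); with no functional set the basin is missing,
never zero.

**Class comparison.** Q distributions are histogrammed with bin width
0.05 on $[0, 1]$, basin distributions with unit bins on $[0, 32]$; the
groups are compared by Jensen–Shannon divergence (base-2 logs, bounded
by 1) with a label-permutation test, default 10,000 permutations —
the reference analysis reports a significance level without naming a
test, and a permutation test makes no distributional assumption.
`rankNetworks()` orders topologies by (Q, basin), annotates the Pareto
front, and reports which designs strictly dominate the biological
reference on both scores.

# The SOS fixture

The packaged network is a reconstruction: signal → RecA activation,
RecA-promoted cleavage encoded as RecA ⊣ LexA, sigma70 with a
self-activation loop driving LexA, UmuDC and SSB, LexA repressing all
three, and the repair genes clearing the signal and shutting down
RecA. The text source does not fully pin down which repair gene
inhibits which target; all four assignments generate the *same*
Boolean trajectory (UmuDC and SSB are dynamically interchangeable), so
the fixture encodes the full variant and the trajectory invariant — the
network must replay the packaged trajectory exactly, ending at the
normal state, with no input self-loop — is enforced at load time and
fails loudly rather than patching.

# What the synthetic scales do and do not show

The package's own validation runs at two scales. Exhaustive oracles
(all $3^{9}$ topologies for 3-node problems, brute-force stepping,
graph-search basins) prove the enumeration and the update rule exactly.
The study-scale run — 48 minimal + 100 sampled candidate networks,
1000 parameter sets each — reproduces the deterministic counts exactly
and the scaled screening statistics within sampling error.

Two caveats for interpreting the stochastic scores. First, with the
default two-decade ranges the response is rare everywhere (median Q
around 0.01–0.03): igniting the sigma-factor branch needs a favourable
corner of parameter space, so Q differences *between* consistent
topology classes are small relative to binomial noise, and
distribution-level separations (JSD between minimal and candidate
groups, dominance counts against the biological design) are much
weaker than under narrower ranges concentrated near the ignition
regime. In particular, an extra inhibition edge whose saturation
constant $c$ falls below 1 *amplifies* its target's production by up to
$1/c$ even when the inhibitor is silent, which blunts the penalty that
extra edges would otherwise carry. Second, the generator emulates
parametric and initial-condition uncertainty only: no molecular noise,
no unequal timescales between transcription and signal repair, and no
asynchronous updating in the discrete layer. Passing tests therefore
certify the enumeration, the dynamics and the scoring machinery — not
that a wet-lab implementation of a high-Q topology will function.

# Known limitations

* Single-trajectory constraint only; noisy or partial trajectories are
  out of scope.
* Deterministic ODEs; no stochastic (Langevin/Gillespie) scoring.
* The dominant-inhibition rule makes sustained oscillation rare
  (an uninhibited ON node persists), so limit-cycle targets need
  self-inhibition motifs.
* Exact counting uses an internal decimal big-integer product; per-node
  enumeration is $3^N$ and practical to roughly $N = 12$, the basin
  scan is $2^{N-1}$ integrations per functional parameter set.
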