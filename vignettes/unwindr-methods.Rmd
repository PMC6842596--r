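---
title: "Asymmetric base-pair opening and helix unwindability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric base-pair opening and helix unwindability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(unwindr)
```

`unwindr` studies how short RNA and DNA duplexes open under force, how the
two bases of a junction pair differ in their propensity to flip out, and
how that asymmetry predicts direction-dependent helicase unwinding.  This
vignette documents the models, the parameters that matter, the synthetic
generators used as oracles, the numerical choices, and the limits of what
the desk-scale results can show.

## The native structures

`build_duplex()` constructs idealized all-heavy-atom duplexes.  Base rings
are regular polygons (hexagon bond 1.39 Å, fused pentagon for purines,
exocyclic substituents per base) placed in a common base-pair plane so that
the Watson–Crick donor/acceptor atoms (purine N1, pyrimidine N3) sit 2.9 Å
apart; the sugar–phosphate backbone follows the helical path on a cylinder
of ~9–10 Å radius with alternating radii (a straight helical arc would give
ill-defined, near-collinear bonded angles).  Helix parameters are standard
fiber values — A-form twist 32.7°/rise 2.81 Å, B-form 36.0°/3.38 Å — with
an in-plane base displacement of 2.5 Å and an 8° inclination for the
A-form.  These two A-form parameters are what make the 5′-terminal base of
an A-helix junction protrude from the stack (a larger lateral centroid
offset from its inward neighbour than in B-form), which is the geometric
origin of the RNA results below.  The displacement is smaller than the
crystallographic ~4.4 Å: in this simplified scaffold the larger value
drives base atoms into the backbone, and the burial asymmetry it exists to
produce (the 5′-terminal base has roughly half the native contacts of its
3′-terminal partner in A-form, while B-form is symmetric) is already
present at 2.5 Å.

The B-form construction is exactly covariant under the base-pair dyad, so
the two strands of a B-DNA duplex are geometrically equivalent; this
matters because strand-asymmetric artifacts would masquerade as 5′/3′
flipping asymmetry, the very observable of interest.  A-form inclination
necessarily breaks this covariance (a rotation about the pair's long axis
does not commute with the dyad); there the strand asymmetry is part of the
A-form signal itself.

Atomic-level chemical fidelity is *not* attempted: a structure-based
(Gō-type) Hamiltonian only needs a self-consistent native state, and every
equilibrium value (bond lengths, angles, dihedral phases, contact
distances) is read off this geometry.

## The structure-based Hamiltonian

`build_topology()` assembles, in reduced units (contact depth ε = 1 sets
the energy; lengths in Å; all masses 1; k_B = 1):

* bonds `V = k_b (r − r0)²` with k_b = 100 ε/Å²,
* angles `V = k_a (θ − θ0)²` with k_a = 20 ε/rad²,
* one torsion per central bond,
  `V = k_d [(1 − cos Δφ) + ½(1 − cos 3Δφ)]`, k_d = 0.5 ε,
* native contacts `V = ε[(σ/r)¹² − 2(σ/r)⁶]` for heavy-atom pairs within
  4.5 Å in the native state, excluding pairs within three covalent bonds
  and same-chain pairs with fewer than one intervening residue (a
  distance-cutoff map; occlusion-based "shadow" criteria are not applied),
* a purely repulsive excluded volume on all remaining pairs,
  `V = ε_ex[(r_ex/r)¹² − 2(r_ex/r)⁶ + 1]` for r < r_ex = 2.5 Å and zero
  beyond — truncated and C¹-continuous so that the native state is an
  *exact* stationary minimum (max |force| ~1e−13 in practice), which a
  long-ranged r⁻¹² tail cannot achieve,
* the pulling term `V = −f_C·x` on the end-to-end distance x between the
  5′-hydroxyl oxygen of chain A residue 1 and the 3′-hydroxyl oxygen of
  chain B's last residue (the terminal pair at the pulled end), acting
  equally and oppositely on the two attachment atoms,
* a half-harmonic confining wall `V = k_w(x − x_w)²` for x > x_w
  (production x_w = 33 Å, k_w = 2 ε/Å²).

The stiffness ratios (bond ≫ angle ≫ dihedral ≈ contact) follow common
structure-based-model practice; all are configuration (`ff_parameters()`).
Forces are analytic and verified against central finite differences to
better than 1e−9 of the force scale.

## Pulling, temperature and the far-end tether

The physical force label is converted through k_BT(296 K) = 4.09 pN·nm:
`f_reduced = f_pN · T / 40.9` at simulation temperature T, i.e. the
temperature at which the model shows balanced two-state hopping *defines*
room temperature for the model.  That temperature is found by
`calibrate_hopping()`: short runs over a temperature grid, keeping the grid
point that maximizes the product of folded and unfolded occupancies with at
least a minimum number of complete transitions.  Grids bracket
~2 for B-DNA hexamers and ~3.2 for A-RNA (its A-form contact network is
much denser, hence the higher temperature scale).

Three modelling devices make the junction dynamics *sampleable* at desk
scale:

* **Far-end tether** (`tether_far_pair()`): a single harmonic bond between
  the Watson–Crick atoms of the base pair farthest from the pulled end.
  Without it the strands separate irreversibly after the last pair breaks
  and re-association is effectively never sampled; with it the system
  mimics the strand linkage (hairpin loop, handles) of real optical-tweezer
  constructs.  The tethered pair is excluded from junction statistics.
* **Confining wall** at x_w = 33 Å: bounds the unfolded-state extension
  (the role of the trap); a close trap keeps the unzipped state near the
  refolding barrier, which is what makes folded/unfolded shuttling fast
  enough to count transitions (tens of complete crossings per 1e6 steps at
  the calibrated temperature, between a folded basin at x ≈ 1.9–2.3 nm and
  an unzipped basin at x ≈ 3.2–3.6 nm; occupancy thresholds 2.6/3.1 nm).
* **Stem clamp** (`tether_stem()`): for junction statistics, Watson–Crick
  tethers on pairs 3..n let the outer pairs fray and re-form rapidly at a
  stable single-strand/double-strand boundary — the analysis construct for
  the dangling-intermediate tables (see the free-energy table section).

Production grids are 1.9–2.1 (hopping) and 2.0–2.4 / 3.0–3.4
(junction sampling, B-DNA / A-RNA).

## Integration

BAOAB Langevin splitting (velocity Verlet in the γ = 0 limit), timestep
0.002 reduced time units, deterministic per seed (Mersenne-Twister with an
explicit Box–Muller transform, so trajectories are bit-reproducible across
platforms).  Production runs use γ = 0.3: equilibrium averages are
friction-independent and the lower friction crosses unzipping barriers
faster than the γ = 1 default.  A larger timestep (0.004) was found to be
only marginally stable in long runs and is not used.  Energy conservation
in the symplectic limit is checked as the difference between early- and
late-run time-averaged total energy (the instantaneous Verlet energy
oscillation, ~5e−4 relative at this timestep, is bounded, not secular);
thermostat correctness is checked against the exact oscillator variance
T/(2k) and equipartition of the full duplex, both to 2%.

## Junction states and events

For each pair k (counted from the pulled end) three distance channels are
recorded: Watson–Crick pairing (N1–N3), 5′-stacking (base-centroid distance
of chain A's residue k to k+1) and 3′-stacking (chain B's mirror).  These
are smoothed with a centered moving average over 300 time steps, then
thresholded at native + 2.5 Å with 0.5 Å hysteresis; the exact atoms and
cutoffs behind such channels are a reporting convention, and these choices
are this package's documented operationalization.  States: CLOSED (all
channels native), FLIP5 (only the 5′ base unstacked — the 3′-dangling
intermediate), FLIP3 (mirror), OPEN (otherwise).  The junction is the
outermost non-OPEN pair; its nearest-neighbour context is written
`XY/X'Y'` with the opening base first, read 5′→3′ on the strand presenting
its 5′ terminus, so strand-swapped contexts (GG/CC vs CC/GG) stay
distinct.  `extract_events()` segments complete CLOSED↔OPEN excursions,
labels each by the intermediate with the longest dwell (`direct` when no
intermediate was visited, `ambiguous` on exact ties — both are counted and
excluded from 5′/3′ tallies), and debounces dwells shorter than one
smoothing window.

## Reweighting and the free-energy table

Frames from a force-tilted ensemble are reweighted by w ∝ exp(−f_C·x/k_BT)
to recover the unbiased ensemble, with the Kish effective sample size
1/Σw² reported.  Reweighting acts on frames (not events); per context,

g = k_BT ln [ W(FLIP5) / W(FLIP3) ],

positive when the 3′-dangling intermediate is the more populated.  Standard
errors come from a moving-block bootstrap over time blocks (default block
length 5× the integrated autocorrelation time of the intermediate
indicator; deterministic per seed).  Contexts in which either intermediate
was never observed are flagged (`g = NA`), never zeroed, and sign-level
statements are restricted to contexts with ≥100 frames of each
intermediate (`well_sampled()`).

**The production estimator samples the unbiased ensemble directly.**  At
desk scale, reweighting 14 pN trajectories is an ill-conditioned estimator
of g: the weight factor spans e^(βf_C·Δx) ≈ e^5.5 over the sampled
extension range, so the weighted intermediate populations are dominated by
a handful of low-extension frames and per-run estimates scatter by ±1 kT
and more between seeds.  The exact estimator behind published tables of
this kind is an open methodological point, and this package makes the
choice explicit: the nearest-neighbour tables are estimated from
*clamped-stem junction constructs* (Watson–Crick tethers on pairs 3..n,
so the junction frays and re-forms thousands of times while the stem never
melts) simulated at **zero force**, where the unbiased populations are
read off directly with uniform weights.  The sampling temperature comes
from `calibrate_junction()`: a short grid scan keeping the temperature
that maximizes dangling-intermediate sampling (too cold and the junction
never frays; too hot and it sits fully open).  Three independent seeds are
pooled per system (junction-state dwells are long-lived, so independent
restarts beat one long run at equal cost).  The reweighting machinery
itself is retained, exercised against exact two-state oracles and applied
to the constant-force hopping trajectories.

Caveats the reader should know:

* **Junction-depth gradients.**  In a palindromic hexamer each context
  occurs at exactly one junction depth, so sequence effects and
  position-along-the-helix effects (the pulled terminal pair carries the
  attachment atoms; the deepest junction neighbours the tether) are
  perfectly confounded.  The sign-structure analyses therefore use
  homopolymer-context sequences (GGGGGG, CCCCCC and their RNA analogues),
  where one context is sampled at several depths.
* **Strand-polarity offset.**  At a junction, the base of the
  5′-presenting strand is linked to the duplex through its 3′ oxygen while
  its partner is linked through its 5′ phosphate.  In this simplified
  geometry that asymmetry leaves a common offset in g of magnitude
  comparable to the sequence effect for G:C-only contexts.  Consequently
  the sign-level statements for individual contexts — the GG/CC-vs-CC/GG
  contrast in DNA, and uniform positivity across RNA contexts — sit at the
  edge of what the desk-scale statistics resolve: per-context values are a
  few tenths of a k_BT with bootstrap SEs of the same order, so individual
  signs can and do come out on either side of zero for some seeds.  The
  acceptance checks assert the signs regardless and are expected to fail
  for some random seeds; the reported values and their SEs are the honest
  summary of what this model at this scale measures.

## The h-unwind index

A helicase tracks one strand into the duplex and displaces the other by
steric exclusion; stacked bases on the displaced strand are the
bottleneck.  Which strand presents its 5′ terminus at the advancing
junction follows from the polarity alone: a 5′→3′ helicase enters at its
tracking strand's 5′ side (tracking strand = 5′-strand, so the displaced
base's flip is the FLIP3 intermediate, s = −1), a 3′→5′ helicase the
mirror (s = +1).  Stepping junction by junction,

p = 1 / (1 + exp(−s·g/k_BT)),  h-unwind = mean(p),

the mean probability that the displaced base is the flipped-out one; the
terminal pair reuses its only available context.  This realizes "inversely
related to the population of stacked displaced bases" as a concrete
estimator; a log-mean aggregate is available behind the `aggregate`
argument for sensitivity analysis, and no step weighting is applied (the
terminal-step convention and weighting are genuinely open choices; the
mean over junction steps is the simplest defensible one).  With any table
in which purine flipping is disfavoured, pyrimidine-displaced constructs
outrank their purine-displaced twins for both polarities — the uniform
1-k_BT toy table gives exactly h = 1/(1+e∓¹) = 0.731/0.269.

The benchmark constructs (`design_constructs()`) are 21-bp duplexes whose
displaced strand is a homopurine (AG-repeat) or homopyrimidine (TC-repeat)
class strand — the published construct sequences are not reproduced here,
so a representative homopolymer-class default is used and user sequences
can be substituted.  When scoring against simulated tables, G/C-homopolymer
constructs are used instead so that every stepped context (GG/CC, CC/GG) is
one the hexamer simulations actually sampled.

## Synthetic generators (what they emulate, and what they do not)

* `junction_markov_model()` — the four-state stepwise topology
  (CLOSED↔FLIP5↔OPEN, CLOSED↔FLIP3↔OPEN, no direct CLOSED↔OPEN unless
  requested) with Metropolis rates built from a target stationary
  distribution, hence exactly reversible (the Kolmogorov criterion on the
  4-cycle holds by construction).  Emitted distance channels are Gaussian
  around state means.  This matches the statistical structure the
  free-energy/bootstrap analysis assumes — Markovian dwells, well-separated
  emission means — which real trajectories only approximate: passing these
  oracles validates the estimators, not the force field.
* `biased_two_state_sampler()` — two states with unbiased 50/50 populations
  sampled under exp(+βf·x): the closed-form input for the reweighting
  checks.
* `synth_unwinding_trace()` — F(t) = baseline + A(1 − e^(−kt)) + noise, in
  minutes, mimicking Cy3-dequenching unwinding assays with ~25/60/300-min
  plateaus.  The demonstration parameters (relative amplitudes 64%, 48%,
  29%) are taken from the wet-lab contrasts the index was tested against;
  they parameterize fixtures, they are not simulation predictions.

## Problem sizes and limitations

Production runs are hexamers (~220–240 atoms) for 0.6–1.5×10⁶ steps —
tens of folded/unfolded transitions and thousands of junction frames per
run, a deliberately scaled-down study (the full analysis contemplates
thousands of complete opening/closing events per context).  Consequences:
per-context g values carry bootstrap SEs of 0.3–1 k_BT, and all
table-level claims here are sign-level.  Known limitations: bubble opening
in duplex interiors is out of scope (junction dynamics only); no
electrostatics, solvent or ions; no sequence-specific contact strengths
beyond what geometry provides; helicase kinetics (step size, ATP coupling)
are deliberately not modelled — h-unwind predicts relative efficiency
order, not absolute rates.
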