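---
title: "A lattice model of chromosome compaction by loop extrusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice model of chromosome compaction by loop extrusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lextrude)
```

## The model

`lextrude` simulates loop-extruding factors (LEFs) — two-headed molecular
machines such as condensin — on a one-dimensional lattice of `L` sites, each
site standing for roughly one nucleosome plus linker (200 bp, ~10 nm of
chromatin fiber). The dynamics follow four rules:

1. a LEF binds a pair of adjacent sites and its heads slide apart, each at
   rate `v` per site, extruding a chromatin loop at rate `2v`;
2. heads block on contact with another head or a lattice end; in the default
   model the two heads of one LEF are independent, so a blocked head does not
   stop its partner;
3. every bound LEF dissociates at rate `1/tau`, independent of its state;
4. the dissociated LEF immediately rebinds at a random free adjacent pair
   (`constant_N` mode), or enters a free pool and rebinds at rate `k_on`
   (`explicit_exchange` mode).

The simulation is an exact continuous-time (Gillespie) algorithm: at each
step the waiting time is drawn from the exponential distribution of the total
propensity and one event is chosen proportionally to its rate. The core loop
is implemented in C++ but draws all random numbers from R's generator, so a
run is reproduced bit-for-bit by `set.seed()` via `sim_params(seed = )`.

Two derived length scales control everything:

* the **processivity** `lambda = 2 v tau` — the loop an isolated LEF extrudes
  during one residence time;
* the **separation** `d = L / N` — the mean spacing between bound LEFs.

When `lambda/d << 1` (sparse regime) LEFs act alone: loops of mean size
`lambda` separated by wide gaps, weak compaction, rapid turnover. When
`lambda/d >> 1` (dense regime) the chromosome folds into a gapless array of
consecutive loops, each maintained by a stack of LEFs, and the array persists
even though every individual LEF exchanges on the timescale `tau`. The
package labels `lambda/d < 0.5` sparse and `> 20` dense, with a transition
band between; the thresholds are rough by nature.

## Steady-state theory

Dense-state loops evolve by two competing stochastic processes. A loop
**dies** when its supporting stack fluctuates to zero; the stack gains LEFs
at rate `(ell/d)/tau` (landings inside the loop) and loses each at `1/tau`,
an immigration–death process whose stationary occupancy is Poisson with mean
`ell/d`, giving the extinction flux

    R_death = (1/tau) (ell/d) exp(-ell/d).

A loop **divides** when two LEFs land inside it almost simultaneously and
partition it; the rate-limiting double landing gives

    R_division = (1/tau) (ell/d)^3 (d/lambda).

Both are scaling laws with unspecified constants; the package implements them
with unit prefactors (`rate_loop_death()`, `rate_loop_division()`), and the
tests compare shapes and ratios, never absolute constants. Death falls and
division rises with loop size, a negative feedback that pins the mean loop
length where the two balance:

    mean loop length = 2 d W(3 lambda / (8 d)),
    LEFs per loop    = 2 W(3 lambda / (8 d)),

with `W` the principal Lambert W branch. `lambert_w0()` evaluates `W` by
Halley iteration to 1e-12 relative accuracy; the tests check it against an
independent Newton iteration and against `pracma::lambertWp`. The inverse
problem — which `lambda/d` produces an observed mean loop size — has the
closed form `(8/3) (r/2) exp(r/2)` at `r = ell/d`, which
`infer_lambda_over_d()` uses directly; it round-trips with the forward
formula to machine precision. With human inputs (loops of 80–120 kb, one
condensin per 30 kb, loop bases of 10–20 nm), `estimate_human_parameters()`
returns `lambda/d ~ 20` (raw root 17.9), processivity ~600 kb, ~3 LEFs per
loop and a compaction of 4–12 kb/nm.

## Reconstructing the loop array

Because heads only move apart and block on contact, LEF intervals are always
properly nested or disjoint; `build_nesting_forest()` exploits this to build
the containment forest in one sweep and treats any crossing interval as
evidence of a corrupted state. On top of the forest, `extract_loops()`
defines:

* **stacked**: a LEF whose heads both sit within `stack_tolerance` sites of
  its parent's heads. The default tolerance of 1 site is the distance at
  which a re-extruding LEF halts against the loop base; larger tolerances
  conflate transiently nearby LEFs.
* **loop**: a maximal stack chain; its span is the outermost member's heads,
  its size the extruded interior `end - start - 1`. Counting interior sites
  makes the bookkeeping exact: interior + gaps + two head sites per
  top-level loop = `L` on every state, which the suite asserts on simulated
  snapshots.
* **nested child loop**: a LEF inside a loop that is not (yet) stacked —
  reinforcement in progress, or the remnant of a division.
* **branched**: a loop whose innermost stack member carries two or more
  child loops. This is the transient configuration created by a division
  (two LEFs landing nearly simultaneously), and it is the operational
  observable we use for division detection.

Two LEFs-per-loop summaries are deliberately reported side by side.
`mean_stack_size` counts the strict stack chain. `mean_lefs_per_loop` counts
every LEF within a top-level loop; in a gapless array this equals `N` over
the number of loops, so the identity `mean loop length ~ n * d` holds by
construction and the quantity is the one comparable to the `2 W(3 lambda/8d)`
prediction. The two differ noticeably in the dense state because a
substantial minority of LEFs are mid-re-extrusion or parked in division
remnants at any instant; conflating them would make the theory comparison
look artificially poor. For the same reason the branched fraction under our
operational definition is small only in the sparse regime; in the dense
regime transient division states are a visible standing population. The
definition of "branched" in terms of raw LEF configurations is genuinely
open; ours is chosen to make division events detectable and is stated
precisely so results are reproducible.

## Loop dynamics and event detection

`match_loops()` pairs top-level loops of consecutive snapshots by the
overlap of their extruded interiors (Jaccard at least 0.5, best partner on
each side; nascent loops with interiors under 3 sites are compared by span,
since a 1-site interior carries no overlap signal). An unmatched loop whose
old span is jointly covered (at least 50%) by two or more new interior
loops divided; any other unmatched loop died; unaccounted new loops are
births. Interiors rather than spans are compared so that the fragment of a
clean half-and-half division scores just below the match threshold and the
event registers as a division rather than a continuation plus a birth.
These thresholds are the simplest symmetric choices and are fixed so that
rate estimates are reproducible.
`estimate_event_rates()` accumulates events and loop-time exposure in
unit-width bins of `ell/d` and reports per-bin Poisson rates with counting
errors.

Event detection from sampled snapshots is the one place where reasonable
operational rules genuinely diverge, and the fitted scaling exponents are
sensitive to the rule. The settling on the rule above reflects two findings
from its alternatives: counting a well-overlapping successor as a division
"child" folds ordinary loop turnover into the division channel and flattens
the division-rate curve, while detecting division as the onset of branching
measures a related but different (earlier) event. With the rule as shipped,
the death-rate curve follows `(ell/d) exp(-ell/d)` and the division-rate
curve follows `(ell/d)^3`, within the regression error of the deep-dense
simulations the acceptance suite runs. The sampling interval for lineage
tracking defaults to `tau/50`, fine enough that halving it leaves the rates
unchanged within error (a suite property).

`detect_steady_state()` declares convergence at the first time the sliding
window mean (window `tau` by default) of an observable enters a relative
tolerance band (default 0.1) around the long-run level and stays inside it
for `hold` consecutive window lengths (default 3), and reports the steady
mean with a batch-means standard error. Two estimator details matter for
small systems and are deliberate. First, the long-run reference is the mean
over the final *half* of the run: the reference must be estimated more
tightly than the band it anchors, and loop observables decorrelate on the
timescale `tau`, so a short tail leaves several percent of noise in the
reference itself. Second, the hold is finite by default: for a system with
tens of loops the stationary fluctuations of the windowed mean loop size
sporadically exceed a 10% band, so demanding the band hold to the end of
the trajectory (`hold = Inf`) measures the time of the *last* excursion in
the observation horizon — a quantity that grows with `t_max` — rather than
the physical transient. Under the reference dense conditions
(`L = 2000, N = 200, tau = 450, v = 1`) with all LEFs loaded at time zero,
the suite checks that settling occurs within `10 tau`; at this lattice size
the system holds only a few dozen loops, so individual replicates vary by
several `tau` around that scale.

## Loading schedules

With instantaneous loading the array first forms as many small loops that
must coarsen by deaths and divisions over several `tau`. Gradual activation
(`activation_rate > 0`: every LEF starts inactive and activates, then binds,
at that rate) lets early LEFs extrude large loops immediately and later LEFs
mostly reinforce them, so the loop *array* — tracked naturally by the loop
count, `observable = "n_loops"` — assembles far faster at intermediate
activation rates than at either extreme; `convergence_time_vs_activation()`
measures this sweep. Two caveats are documented rather than hidden: the
settling criterion above is stricter than a first-crossing criterion, so
convergence times around `tau` rather than well below it are reported at the
optimum; and with exponential per-LEF activation the last activations
straggle, so very slow rates converge late. The slowly relaxing mean loop
size is a poor observable for this comparison and is not the default here.

## Numerical choices and degenerate inputs

* Binding samples a free adjacent pair by rejection (capped at 1000 draws),
  then falls back to exhaustive enumeration; only a lattice with no free
  adjacent pair raises an error, which names the head density.
* Lattice ends block like occupied sites; there is no periodic wrap, since a
  chromosome segment has ends.
* Engine coordinates are 1-based inclusive sites; BEDPE export converts site
  `i` to the 0-based half-open interval `[(i-1) * bp_per_site, i * bp_per_site)`.
* A fully jammed state with no turnover (`tau = Inf`, all heads blocked) has
  zero total propensity; stepping it raises an explicit error rather than
  hanging, and `run` fast-forwards the remaining snapshots.
* Blocked LEFs dissociate at the same `1/tau` as free ones — turnover is
  state-independent.
* An empty loop table reports coverage 0 and `NA` (absent) means; empty
  rate bins report `NA` rates, never zero.
* The Fig-style caption phrase "time steps" is interpreted as time units at
  `v = 1`; with exponential waiting times there is no global clock tick.

## What the simulations do and do not emulate

The generator reproduces the 1D geometry of loop extrusion: blocking,
turnover, exchange, stacking, gaps, loop death and division, and their
dependence on `lambda/d`. It deliberately omits 3D polymer conformation,
excluded volume, contact maps, topoisomerase action, sequence-specific
binding and boundary elements, and it does not distinguish condensin I from
condensin II. Passing tests therefore demonstrate the self-organisation and
scaling behaviour of the loop array, not agreement with Hi-C contact
statistics or imaging of real chromosomes; the human-parameter estimates
combine this model's steady-state relations with externally measured loop
sizes and condensin spacing.

Problem sizes in the test-suite simulations are chosen as the smallest that
leave the checked signal comfortably above Monte-Carlo noise: lattices of
2,000–12,000 sites with 40–400 LEFs for steady-state and collapse checks
(tens of loops per snapshot, 16–30 residence times per run), a
40,000-site lattice for the sparse-state law (isolated loops need room), a
50-residence-time deep-dense run for event-rate regressions (hundreds of
death events), and exact 6–8-site lattices where the full master equation
is integrable for the brute-force engine validation.
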