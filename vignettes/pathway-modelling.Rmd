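---
title: "Continuous Petri net modelling of PI3K/Akt-OGT crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous Petri net modelling of PI3K/Akt-OGT crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogtpn)
```

## The modelling problem

Type II diabetes and breast cancer share a metabolic axis: glucose entering
the cell partly flows through the hexosamine biosynthetic pathway (HBP) to
UDP-GlcNAc, the substrate of O-GlcNAc transferase (OGT). OGT decorates
signalling proteins with O-GlcNAc marks, antagonised by O-GlcNAcase (OGA).
The same enzyme has opposite net effects in the two diseases: in the
adipocyte, OGT hyperactivity dampens insulin signalling (O-GlcNAcylation of
IRS-1 and Akt blocks their activation, driving insulin resistance), while
in the hyperglycemic breast cancer cell it enhances Akt activation, GLUT4
surface expression and proliferation.

`ogtpn` models this crosstalk as a *continuous Petri net*: a bipartite
graph of places (entities, holding nonnegative real token levels read as
relative activity) and transitions (processes), where each transition fires
continuously at a mass-action rate, inducing an ODE system over the
marking. The formalism is deliberately non-parametric: token levels are
relative, time units dimensionless, and almost every kinetic constant is 1;
the interest is in directions and fold changes between paired conditions,
not absolute kinetics.

## Firing semantics

For transition $t$ with rate constant $k_t$, standard input arcs of weight
$w_{pt}$ from places with marking $m_p$, and inhibitory input arcs of
weight $w_{qt}$ from places $q$:

$$v_t(m) = k_t \prod_{p} m_p^{w_{pt}} \prod_{q} g(m_q, w_{qt}),
\qquad \frac{dm}{dt} = C\,v(m),$$

where $C$ is the incidence matrix (output minus input weights over
standard arcs; inhibitory arcs move no tokens) and $g$ is the inhibition
gate. Kinetic order equals arc weight, the standard continuous-PN
convention; since shipped weights are 1 this rarely matters. Source
transitions (no inputs) fire at $k_t$, modelling constant supply; sink
transitions model decay.

**Inhibition gate.** A literal reading of the inhibitory arc — firing
stops once the inhibitor reaches the arc weight — is a step function,
which a stiff ODE solver handles poorly. The default gate is therefore the
smooth Hill form $g(m, w) = w^h/(w^h + m^h)$ with steepness $h = 4$
(`inhibition_steepness` in `sim_settings()`): $g = 1$ at $m = 0$, $1/2$ at
$m = w$, and $\to 0$ beyond. The hard step is available
(`hard_gate = TRUE`) for semantics checks; both gates are monotone
non-increasing in the inhibitor level, a property the tests verify.

## Numerical choices

* Integration: `deSolve::lsoda` (adaptive, stiff-capable), dense output on
  a uniform grid of 201 points over a default horizon of 100 time units.
* Tolerances: `rel_tol = 1e-8`, `abs_tol = 1e-9`. The relative tolerance
  is tighter than a casual default because we assert P-invariant
  conservation within 1e-6 over the full horizon, and integrator drift
  should sit well below the assertion, not at it. At these model sizes
  (~20 ODEs) the cost is negligible.
* Negativity: entries with $|m| \le 100\,\texttt{abs\_tol}$ are clipped to
  zero; anything more negative raises an error with the offending place
  and time. Silent clipping of large negatives would hide modelling bugs.
* Readout: fold changes use the mean over the last 20% of the grid
  (`mean_tail`), damping transients relative to a single end point.
  Direction thresholds are 1.2 (up) and 0.8 (down), symmetric on the log
  scale; the qualitative calls are insensitive to this choice because the
  shipped comparisons land far from the boundaries.

## Structural analysis

`p_invariants()` computes a generating set of nonnegative left-null
vectors of $C$ (Farkas algorithm, minimal-support filtering). In every
shipped variant the invariants are exactly the four active/inactive
protein pairs — IRS-1, PI3K, Akt, GLUT4 — because activation transitions
move tokens within a pair and catalysts are consumed-and-reproduced.
Conservation of these pools along trajectories is a standing regression
check on the integrator and the wiring.

## What the model builders encode

Each variant exposes 20 places: one active/inactive pair per signalling
protein (activity readout = active-place marking), the receptor module
(insulin, receptor, complex1), second messengers (PIP3), the kinases PDK1
and mTORC2 held at constant capacity by supply/decay pairs (they are
catalysts, not consumed reactants), the GLUT4 internal/membrane pair, an
accumulating `cell_survival` readout place (named "cell proliferation" in
the cancer context; the same place plays both roles), and the metabolic
branch glucose → UDP-GlcNAc → OGT activity with OGT mRNA and OGA.

* **normal_adipocyte** — intact insulin signalling; OGT-driven
  deactivation of IRS-1 and Akt is balanced by OGA-driven reversal at
  equal low gains.
* **insulin_resistant_adipocyte** — same topology; OGT transcription
  raised 4x and the OGT-driven deactivation gains raised 10x, overwhelming
  OGA. All four key readouts fall below the normal cell.
* **cancer_hyperglycemia** — glucose supply and initial tokens raised 7x,
  feeding the HBP and hence OGT activity; OGT targets Akt only (no IRS-1
  arm: the evidence there concerns the adipocyte) and *enhances* Akt
  activation, GLUT4 translocation and proliferation.

The HBP branch rate (0.04 per time unit against a glycolysis rate of 1)
encodes the few-percent share of glucose flux entering the HBP. All arc
weights are 1; the only calibrated constants are the OGT-branch gains, the
variant-specific supply rates and the proliferation gain, all collected in
`inst/extdata/default_config.yaml` with comments. That file is the single
source of truth; `default_config()` reads it and `build_model()` accepts
per-id overrides, refusing unknown ids.

The calibration was done once, against the full set of reported
fold-change bounds simultaneously — one fixed configuration serves every
comparison below, with no per-case adjustment.

## Interventions

Interventions are declarative edits returning a new net (the base net is
never mutated):

* **shRNA** (default dose 10 tokens): a `shrna` place plus a degradation
  transition consuming shRNA and OGT mRNA together. Stoichiometric rather
  than catalytic: the dose bounds the total mRNA degraded, so knockdown
  depth follows dose.
* **BZX** (default dose 10): a covalent suicide inhibitor; BZX and free
  OGT are consumed irreversibly into an inert `ogt_bzx_complex` (no back
  reaction, nothing consumes the complex). Token bookkeeping of
  OGT + complex matches the unperturbed OGT balance, which the tests check
  on the incidence matrix.
* **Metformin** (default dose 10): a single inhibitory arc onto the
  proliferation transition and nothing else — no OGT interaction is
  modelled, so OGT trajectories are bitwise unchanged. The drug level is
  held at its dose by a supply/decay pair (supply = turnover x dose,
  decay = turnover); a bare source would grow the drug without bound and
  close the gate completely, contradicting the intended partial (~fivefold)
  inhibition. The inhibitory arc weight (7.5) is the calibrated threshold
  setting that depth at the default dose.

Combinations fold left-to-right over disjoint targets, so order does not
matter; dose 0 of any kind reproduces baseline within integrator
tolerance.

## What the generators emulate — and what they do not

The builders and `random_net()` (the seed-deterministic fixture generator
for engine tests) produce exactly the class of nets the study design
needs: small, mass-action, unit-weight, with sparse inhibitory arcs. They
do not emulate features of real signalling data: no measurement noise, no
cell-to-cell variability, no saturation kinetics (Michaelis-Menten),
no spatial effects, no absolute time calibration. Passing tests therefore
demonstrate that the *model* reproduces the reported qualitative and
fold-change behaviour under its stated assumptions — not that those folds
would be observed quantitatively in cells. The model is deterministic;
no replicates or p-values are produced.

## Known limitations and open edges

* The exact continuous semantics of inhibitory arcs in graphical PN tools
  vary; the smooth gate is this package's documented choice, with the hard
  gate behind a flag.
* "x-fold decrease" is reported both as residual ratio
  (perturbed/control, `fold`) and reduction factor (control/perturbed,
  `reduction_factor`) because both conventions are in common use;
  knockdown bounds quote the residual ratio, efficacy bounds the
  reduction factor.
* The suicide-inhibitor and knockdown cases drive free OGT — and with it
  OGT-dependent proliferation flux — to near zero, so their reduction
  factors are large and should be read as "at least", not as point
  estimates.
* Reachability analysis, model checking, stochastic (Gillespie) or hybrid
  execution, and timed/colored extensions are out of scope, as are
  read/test arcs (never needed here).

## Problem sizes

Default runs integrate ~20-place nets over 100 time units; the full
six-case comparison suite takes a few seconds. The engine validation suite
cross-checks the adaptive integrator against an independent fixed-step
Euler oracle (step 1e-4, horizon 1) on 50 seed-fixed random nets of up to
6 places, and round-trips all shipped and 50 random nets through PNML.
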