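---
title: "Modeling DYRK1A-mediated cardiomyocyte cell-cycle control with logic-based ODEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling DYRK1A-mediated cardiomyocyte cell-cycle control with logic-based ODEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyrknet)
```

## The biological question

Adult mammalian cardiomyocytes are post-mitotic: they sit in a quiescent
state enforced, in large part, by the DREAM complex (DP, RB-like, E2F and
MuvB) and by hypophosphorylated RB1, both of which silence the G1/S
transcriptional program. The kinase DYRK1A sits upstream of both arms — it
phosphorylates LIN52 at serine 28, nucleating DREAM assembly on the MuvB
core, and it phosphorylates cyclin D, targeting it for degradation, which
keeps RB1 active. Knocking DYRK1A down therefore releases both brakes at
once, and is a candidate route to re-activating cardiomyocyte proliferation
after injury.

`dyrknet` implements this regulatory circuit as a logic-based ordinary
differential equation (ODE) network, ships the curated network as an
editable plain-text asset, and provides the in-silico experiments used to
interrogate such models: graded knockdown concentration responses with
EC50/IC50 extraction, a full single-node knockdown screen, dose
simulations, and a harness that scores predicted directions of change
against literature observations.

## The modeling framework

Every node $i$ (a protein, complex, or process) carries a dimensionless
activity $Y_i \in [0, Y_{max,i}]$ obeying

$$\frac{dY_i}{dt} = \frac{Y_{max,i}\, g_i(\mathbf{Y}) - Y_i}{\tau_i},$$

where $g_i$ is the gated input of node $i$. Regulation enters through the
normalized Hill activation

$$f(x) = \frac{B\,x^n}{K^n + x^n}, \qquad
B = \frac{EC_{50}^n - 1}{2\,EC_{50}^n - 1}, \qquad
K = \left(B - 1\right)^{1/n},$$

the unique sigmoid of this form satisfying $f(0) = 0$, $f(EC_{50}) = 0.5$
and $f(1) = 1$. The constraint $EC_{50}^n < 0.5$ keeps $B > 1$ and $K$
real; `hill_constants()` rejects parameters outside that region.

Rules combine regulators with continuous fuzzy-logic gates:

* within one rule, regulators are AND-combined by multiplication, with
  inhibitors contributing $1 - f(x)$;
* distinct rules sharing a product are OR-combined by
  $OR(a, b) = a + b - ab$, folded in declaration order (the fold is
  mathematically order-independent; the fixed order makes output
  byte-stable);
* each regulator term is clamped to $[0, 1]$ *before* gate combination.

The clamp deserves a note. Overexpression protocols push activities to 10,
where $f(x) \to B > 1$; without clamping, inhibitory terms $1 - f$ would go
negative and the OR algebra would leave $[0, 1]$, producing negative
activities and undefined powers ($x^n$ for $x < 0$, non-integer $n$). With
the clamp, gates stay in $[0, 1]$, trajectories started inside the box
$[0, Y_{max}]$ stay inside it, and overexpression saturates rather than
diverges. The trade-off is that an overexpressed regulator whose baseline
activation is already $f \approx 1$ has little additional effect — which
directly shaped the input calibration below.

### Default parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| $w$ | reaction weight | 1 | — |
| $n$ | Hill coefficient | 1.4 | — |
| $EC_{50}$ | half-maximal input | 0.50 | activity |
| $Y_{init}$ | initial activity | 0 | activity |
| $Y_{max}$ | maximal activity | 1 | activity |
| $\tau$ | time constant | 1 | time |

### Steady-state detection

A state counts as steady when, over a check window of 1 time unit, every
node's relative activity change is below $5\times10^{-4}$ (0.05%). For
activities below $10^{-3}$ a relative criterion is ill-posed (a node
decaying to zero has relative change near $1 - e^{-1/\tau}$ forever), so an
absolute change below $5\times10^{-7}$ is required instead. The default
horizon is `max_time = 1000`; non-convergence is reported, never silently
accepted, and the last state is returned.

Two numerical consequences are worth knowing. First, the stopping rule
halts within roughly $10^{-4}$ of the exact fixed point; analyses that
compare against analytic fixed points should tighten `rel_tol`/`abs_tol`
(the package's own oracle tests run at `rel_tol = 1e-7`). Second, slow
dynamics ($\tau \gg$ window) can linger: with `max_time` too small the
result is honestly flagged `converged = FALSE`.

Integration uses `deSolve::lsoda` (rtol $10^{-8}$, atol $10^{-10}$):
overexpression clamps set $\tau = 10^9$, so the system can be stiff and a
stiff-capable adaptive method is the safe default. Halving the tolerances
moves reported activities by less than $10^{-6}$.

## Perturbation protocols

* **Knockdown** scales the target's $Y_{max}$ by $(1 - k)$; $k = 1$ is the
  full knockout ($Y_{max} = 0$). The graded form is what makes 1%-increment
  concentration responses meaningful, and at $k = 1$ it coincides with the
  binary knockout convention.
* **Overexpression** sets $Y_{max} = 10$ for input nodes (the source rule
  then drives the node to 10) and, for intermediate or output nodes, sets
  $Y_{init} = 10$ with $\tau = 10^9$, clamping the node near 10 over any
  realistic horizon.
* All perturbations follow the *perturb-after-steady-state* protocol:
  the unperturbed model is brought to steady state first, and the perturbed
  system is re-integrated from that state (continuation). A knocked-down
  node therefore decays from its pre-perturbation activity; its `y_init` is
  not rescaled.

## The shipped network

The packaged asset (`models/dyrk1a_cellcycle.tsv`, 13 species, 16 rules)
encodes:

```
=> DYRK1A ; => BMyb ; => CDK2                  (inputs)
DYRK1A => pLIN52                               (LIN52-S28 phosphorylation)
pLIN52 & !BMyb => DREAM                        (DREAM assembly; B-Myb competes)
!DYRK1A => CycD                                (direct cyclin D destabilization)
E2Fi => CycE   (i = 1,2,3; OR, w = 0.8)        (E2F transactivation)
CycE & CDK2 => CycE_CDK2
!CycD & !CycE_CDK2 => RB1                      (redundant RB1 inactivation)
!DREAM => E2Fi (i = 1,2,3)                     (DREAM repression)
E2F1 & E2F2 & E2F3 & !RB1 => DNA_replication
CycE_CDK2 => DNA_replication                   (OR with the E2F arm)
```

Input activities are calibrated so that perturbations produce visible
change at baseline: DYRK1A $Y_{max} = 0.9$, B-Myb $Y_{max} = 0.1$, CDK2
$Y_{max} = 0.9$. Holding an input slightly below 1 matters because gate
terms saturate at $f(1) = 1$: an input pinned at activity 1 is invisible to
overexpression under the clamp.

Three gating choices were genuinely open, and were resolved by requiring
the network to reproduce the full set of qualitative behaviors it exists to
explain; the alternatives provably cannot:

1. **DREAM, not RB1, represses the E2Fs; RB1 gates the replication program
   directly.** Double multiplicative repression of E2F (by DREAM *and* RB1)
   drives baseline E2F activity to ~0.006, so any perturbation delta at the
   output is below the 0.01 direction-classification threshold and
   overexpression predictions degenerate to "no change". Splitting the two
   brakes — transcriptional repression of E2F by DREAM, functional
   inhibition of E2F-driven replication by RB1 at the target program (RB1
   binds activator E2Fs at their promoters) — yields a baseline that is
   quiescent (replication ~0.10) yet responsive in both directions.
2. **The E2F arm of `DNA_replication` is AND-gated across E2F1/2/3.** Under
   a full DYRK1A knockout all three E2Fs saturate at activity 1; with
   OR-gated single-E2F rules the output is pinned at 1 and knocking out any
   single E2F changes nothing. The AND gate makes the three activator E2Fs
   individually necessary for the full program — which is exactly the
   observed epistasis (each single E2F knockout attenuates the
   knockdown-induced rise by ~12%) — while the parallel `CycE_CDK2` OR arm
   keeps single-cyclin knockouts redundant (<1% attenuation), because cyclin
   D and cyclin E/CDK2 also back each other up upstream at RB1.
3. **CDK2 is calibrated to $Y_{max} = 0.9$**, the same responsiveness
   calibration applied to DYRK1A: at $Y_{max} = 1$, $f(\text{CDK2}) = 1$ is
   saturated and CDK2 overexpression is a no-op; at 0.9 it leaves headroom
   ($f: 0.91 \to 1$) while keeping cyclin E/CDK2 a near-saturating RB1
   inhibitor under knockout, preserving the cyclin redundancy. The cyclin E
   transactivation weight $w = 0.8$ keeps baseline cyclin E below 0.2.

The asset is a file, not code: if a different curation (e.g. with
additional MuvB or G2/M nodes) becomes available, it can replace the TSV
without touching the package.

```{r baseline}
model <- build_dyrk1a_model()
baseline_steady_state(model)
```

## The in-silico analyses

**Concentration response.** `concentration_response()` knocks the target
down over the grid $0, 0.01, \dots, 1$, restarting each run from the
baseline steady state. Each responding node (grid-end change $>10^{-3}$) is
min-max normalized between its 0%- and 100%-knockdown activities, and the
half-max point is the first 0.5-crossing, linearly interpolated. The signed
normalization maps rising and falling nodes onto one formula, so EC50
(rising) and IC50 (falling) come from the same estimator. Halving the grid
step moves the estimates by less than 0.005. On the shipped network the
output is markedly more sensitive (half-max ~26% knockdown) than the
proximal targets pLIN52 and cyclin D (~49%): partial DYRK1A inhibition is
predicted to suffice for cell-cycle entry.

**Knockdown screen.** `knockdown_screen()` computes a reference steady
state under a context (by default the full DYRK1A knockout), then knocks
out every node in turn on top of it, reporting raw steady-state activity
changes (rows: knocked-down node; columns: readouts). The row for a node
already knocked down by the context is ~0 by construction.

**Dose simulation.** `dose_simulation()` evaluates 15/30/45% knockdowns —
the low/medium/high inhibitor-concentration surrogates — plus dose 0, for
DNA replication and cyclin D by default.

## Direction validation

`run_validation()` replays curated literature experiments (perturbation →
readout → expected direction) and classifies each prediction as
increase/decrease/no-change with an absolute activity threshold of 0.01 —
small enough to register genuine regulation, large enough to ignore solver
noise near the 0.05% stopping criterion. Accuracy per biological context is
matches/total in percent, rounded half-up to an integer (11/13 → 85%).
The packaged cardiomyocyte suite contains five literature-anchored
experiments; a header-only template is installed so a cancer-literature
suite can be transcribed from primary sources and scored the same way.

## Synthetic fixtures and what passing tests mean

`generate_cascade()` and `generate_random_network()` produce models whose
ground truth is known by construction: cascades have closed-form steady
states (compositions of $f$), acyclic networks are checked against a
brute-force fixed-point sweep that never touches the ODE solver, and a
steep three-node repressor ring supplies a genuinely non-convergent
(oscillating) case. Note that a *two*-node negative feedback loop cannot
oscillate in this framework — the divergence of the vector field is
$-1/\tau_1 - 1/\tau_2 < 0$ everywhere, so Bendixson–Dulac excludes limit
cycles; sustained oscillation needs a longer loop with steep gates.
`generate_validation_suite()` labels simulated experiments with known
match/mismatch counts, so accuracy arithmetic is tested independently of
any curation.

The fixtures emulate network *structure*, not biological data: they contain
no measurement noise, no unmodeled crosstalk, and time constants of order
1. Passing tests therefore demonstrate that the engine solves the stated
equations correctly and that the shipped network reproduces the qualitative
literature behaviors — not that the model quantitatively predicts
cardiomyocyte biology.

Problem sizes used by the test suite (chosen to exercise the properties
densely while staying quick): 120 sampled $(n, EC_{50})$ pairs for the
normalization identities, 100 random acyclic networks of 4–8 species for
the ODE/fixed-point correspondence, 25 random cascades for the closed-form
oracle, and concentration-response grids at steps 0.01 and 0.005.

## Known limitations

* Activities are normalized and unitless; the model predicts directions
  and relative sensitivities, not concentrations or rate constants.
* The curated network deliberately omits p53/p21 signaling, Hippo/YAP
  crosstalk, and G2/M-specific machinery.
* Overexpression magnitudes (not directions) depend on the gate clamp
  convention; alternative conventions would rescale, but not re-sign, the
  predicted changes.
* The steady-state criterion is a windowed heuristic: extremely slow modes
  ($\tau$ far above the check window) can satisfy it while still drifting.
  The $\tau = 10^9$ overexpression clamp exploits exactly this property by
  design.
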