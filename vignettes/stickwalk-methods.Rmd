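---
title: "A neuromechanical model of six-legged stick-insect walking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuromechanical model of six-legged stick-insect walking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`stickwalk` simulates walking of a stick insect as a closed sensorimotor
loop. Each of the six legs (L1--L3 on the left, R1--R3 on the right) carries
three antagonistic muscle pairs: protractor--retractor (PR), moving the leg
horizontally about the thorax--coxa joint (angle $\alpha \in [28,
128]^\circ$, $28^\circ$ most protracted); levator--depressor (LD), moving
the leg vertically ($\beta \in [30, 60]^\circ$, with $30 \le \beta <
32^\circ$ signalling ground contact and $\beta > 32^\circ$ swing); and
extensor--flexor (EF), moving the tibia relative to the femur ($\gamma \in
[45, 110]^\circ$, $45^\circ$ stretched). Each pair is controlled by a local
network of identical architecture: a central pattern generator (CPG) of two
mutually inhibitory nonspiking neurons, four motoneurons (a fast and a slow
one per muscle), four inhibitory premotor interneurons (one per motoneuron),
and two sensory relay interneurons that carry the gated position inputs.
That makes $6 \times 36 = 216$ neurons with three state variables each (648
first-order ODEs) plus one second-order equation per muscle pair (18),
i.e. 666 dynamical states. The structural tallies -- 18 CPGs, 72
motoneurons, 108 interneurons, 9 neuromuscular units per side -- are derived
by enumeration in `model_counts()`, never hard-coded.

## Neurons

Every neuron follows the same three-variable conductance-based form
$$C \dot V = -g_L (V - E_L) - g_P\, m (V - E_P) - g_q\, q (V - E_K)
  + \textstyle\sum_j g_j s(V_j)(E_j - V),$$
with a persistent inward current gated by the slow activation $m$
($\dot m = (m_\infty(V) - m)/\tau_m$), an adaptation current gated by $q$
($\dot q = (q_\infty(V) - q)/\tau_q$), and instantaneous sigmoidal synaptic
transfer $s(V) = 1/(1 + e^{-(V + 30)/4})$. Keeping synapses algebraic
preserves the 648-ODE count. Motoneurons and interneurons use the same form
with $g_P = 0$; the slow motoneurons have a three-fold larger adaptation
conductance than the fast ones and a membrane capacitance scaled by
$\tau_{act,slow}/\tau_{act,fast} = 8$, which realizes the much longer
activation time constant of the slow muscles without adding muscle filter
states (the mechanical system stays strictly second order).

Two CPG parameterizations are used. The LD networks are free-running
half-center oscillators (adaptation $g_q = 0.4\,\mu S$, $\tau_q = 400$ ms):
increasing the drive conductances $g_{app}$ shortens the period, the unit is
quiescent without drive, and for symmetric drives the two plateaus alternate
in antiphase (phase difference $0.5$ of a period, measured between plateau
midpoints). The calibrated gait drive tables are asymmetric -- the levator
plateau (the swing) is deliberately shorter than the depressor phase -- so
for those tables the onset-based phase difference sits near the swing duty
(about 0.27 in tetrapod), not 0.5; alternation is strict in either case. The
PR and EF networks instead have one dominant neuron (drives $0.15$ (PR) or
$0.08$ (EF) vs $0.015\,\mu S$, $g_q = 0.45/0.3\,\mu S$): the dominant side holds a stable
plateau until a sensory gate forces the antagonist, which cannot
self-sustain once the gate releases. This makes PR and EF gate-slaved
switches rather than clocks, which is also what lets a static gate setting
park them during still stand.

Strongly depolarized CPG neurons are insensitive to moderate inhibition
(depolarization block): a mid-plateau inhibitory pulse at the contralateral
connection strength ($0.05\,\mu S$) leaves the plateau intact, while the
same pulse near the plateau-to-silent transition terminates it early. Very
small pulses in fact slightly *prolong* the plateau (they slow the
adaptation build-up), so the plateau-duration-versus-pulse-strength curve is
not globally monotone; it is monotone within the terminating branch
($\gtrsim 0.1\,\mu S$).

## Muscles and joints

The mechanical model is kinematic -- joint angles only, no body
translation. Each antagonistic pair obeys
$$\ddot\theta = k_r\,(\theta_{eq} - \theta) - b\,\dot\theta, \qquad
  \theta_{eq} = \bar\theta + \tfrac{\Delta\theta}{2}
  \tanh\!\big((\pm(G_f \Delta a_f + G_s \Delta a_s) + \beta_0)/T_{sc}\big),$$
where $\Delta a$ are the fast/slow activation differences (the synaptic
transfer of the motoneuron potentials), $G_s = 0.3 G_f$ (setting $G_s = 0$
reproduces the fast-only mode without removing equations), and the
saturating $\tanh$ keeps the equilibrium strictly inside the joint range, so
the limits act as smooth restoring terms and velocities stay continuous.
Stiffness and damping ($k_r = 0.01$ ms$^{-2}$, $b = 0.21$ ms$^{-1}$,
$\zeta \approx 1.05$) give a near-critically damped settling of a few tens of
milliseconds, fast enough for the 200-ms stop budget.

Two passive biases matter. The levation bias ($\beta_0 = -0.6$) pulls
$\beta$ into the contact band whenever levator and depressor activations
balance; this keeps the leg grounded through the CPG's slow inter-plateau
phases (and through the small slow-muscle stance ripple, which never reaches
$32^\circ$). The tibia bias ($-0.5$) makes extension the default posture.
A consequence discussed under *Limitations*: a leg in this model cannot hang
lifted in an ambiguous motor state, which suppresses the "leg remains
lifted" irregularities reported for the original parameterization.

## Intraleg coordination

Sensory signals from the joints -- $\beta$, its angular velocity, $\gamma$,
and the binary ground-contact flag -- switch three binary gates per leg with
direction-dependent thresholds and $2^\circ$ release hysteresis (no-chatter
dwell times far above 10 ms):

* $g_\beta(PR)$ and $g_\beta(EF)$ switch high when $\beta$ falls through
  $\beta_{crit} = 33^\circ$ (shortly before ground contact) and low when it
  rises through $35^\circ$. High means stance: the gate excites the
  retractor (resp. flexor) CPG neuron through relay IN5 and inhibits its
  antagonist through relay IN6.
* $g_\gamma(LD)$ switches on the tibia angle at $\gamma_{crit} = 75^\circ$
  and provides a modest depressor support during stance ($0.05\,\mu S$; its
  polarity follows the leg's tibia role). Larger values were explored and
  hard-lock the levator escape -- see *Numerical choices*.

The hind-leg EF network carries a cross connection: its CPG-to-premotor
routing is exchanged, so the same stance-high gate that flexes a front
tibia extends a hind tibia. Backward walking re-uses exactly this device
(below).

Swing extension/flexion, stance retraction and ground contact therefore
follow from one loop: the LD clock lifts the leg, the falling leg trips the
PR/EF gates into stance mode, and the gates hold those networks until the
next liftoff.

## Interleg and contralateral coordination

Ipsilaterally, each leg inhibits the levator CPG neuron of its next anterior
neighbour ($g_{inh3}$ onto the prothoracic, $g_{inh9}$ onto the mesothoracic
target, both $0.3\,\mu S$) with a level set by a quadrant rule on the
posterior leg's $(\beta, \dot\beta)$: full conductance while lifted and
rising, a configured fraction while lifted and descending (default 1.0),
and a tonic level while grounded (default 0). The anterior leg is thus
blocked during the posterior swing and released at touchdown. Because the
LD rhythm of the more anterior segments runs slightly fast (adaptation time
constants scaled by 0.82/0.90/1.0 from front to hind, with a matching small
levator drive grading), each leg is always ready before its release, and the
release pins the liftoff: the metachronal wave hind-to-front with a lag of
one swing duration plus the escape delay (about 470 ms) is a stable attractor, not an
initial-condition artifact. With the tetrapod drive table (period
$\approx 1910$ ms) this yields the tetrapod wave; with the tripod table
(period $\approx 1200$ ms) the same lag is about half a period, so the front
and hind legs of a side swing together -- the tripod. The swing duration
being nearly drive-independent is what lets one mechanism produce both
patterns, and what makes the contralateral pair structure (B-type:
L1--R2, L2--R3, L3--R1) carry over through the tripod-to-tetrapod
transition.

Contralaterally there are four connections. An excitatory pathway from the
lifted state of L2 ($\sigma(\beta_{L2})$, half-activation $45^\circ$) to the
levator CPG neuron of R3 is the single left/right asymmetry; it pulls R3
into phase with L2 at the transition to tripod and is ineffective during
established patterns (the excitation then arrives during R3's plateau,
where it changes nothing). The two bidirectional pair pathways (L1--R1 and
L3--R3) and their mutual inhibition contain no explicit neurons; they are
realized as a signal-level arbiter plus a small partner excitation, active
only while a tripod transition is being initiated, and enforce that both
sides initiate at the same segment.

## Behavioural modes

All mode changes are requests with acceptance constraints, applied
instantaneously at the integration step where the constraint first holds:

* **To tripod:** a front or hind leg (never the middle one) must be lifted
  above $\beta_{min} = 40^\circ$ and rising; the side's drive table then
  switches at once, and the pair arbiter restricts the other side to the
  same segment.
* **To tetrapod:** per side, the middle and hind legs must both be slow or
  descending ($\dot\beta < 0.02$ deg/ms); the sides transition
  independently.
* **Stop:** accepted when no right leg is descending (tolerance
  0.02 deg/ms, the scale of the slow-muscle stance ripple). The still-stand
  gate settings are then applied statically: front PR gate 0 (protract),
  other PR gates 0.5 (retract), LD gates 0.5 (ground), EF gates 0
  front/middle and 0.5 hind (extend, the hind via its cross connection).
  The pose -- front legs at $\alpha = 28^\circ$, the others at $128^\circ$,
  all $\beta$ in the contact band, all tibiae stretched -- is reached
  within roughly 110--200 ms of acceptance, depending on the phase at which
  the stop is accepted.
* **Restart:** unconstrained; gates revert to dynamic operation and the
  tetrapod drive table is restored. Under this calibration the first swing
  after restart comes from a front leg and a B-type tetrapod re-emerges;
  see *Limitations* for how this differs from the behaviour reported for
  the original parameterization.
* **Search:** front legs only, no constraints. The premotor interneurons of
  the leg's LD and PR networks are overridden (depressor and retractor
  motoneurons inhibited, levator and protractor motoneurons disinhibited),
  holding the leg protracted ($28^\circ$) and lifted ($\approx 59^\circ$),
  while the EF CPG receives the search drive pair ($0.03, 0.03\,\mu S$,
  scalable per leg), making the tibia oscillate at about 770 ms -- well
  above the stepping frequency. No other leg reads the front legs'
  sensory state, so the walking legs are untouched by construction, and
  the previous pattern resumes when the override is lifted.
* **Backward:** accepted when a middle leg is lifted near its maximal
  vertical position ($\beta \ge 58^\circ$); rejected during still stand
  (all legs grounded, so the constraint is unsatisfiable -- backward
  walking and still stand cannot overlap). Presynaptic inhibition
  exchanges the CPG-to-premotor routing of every PR network and of the
  front- and hind-leg EF networks: stance becomes protraction, and the
  front and hind legs exchange tibia roles. The levation rhythm is
  untouched. The return to forward walking is unconstrained.

Schedules are validated before a run: still-stand and backward intervals
may not overlap; search combines freely with everything.

# Numerical choices

The 666 continuous states are integrated with a fixed-step classical RK4
scheme implemented in C (default $dt = 0.1$ ms, output every 1 ms). The
discrete layer -- gates, interleg levels, the mode controller -- is hybrid:
a variable-step stiff solver that backtracks over switch times cannot carry
direction-dependent gate automata safely, so the discrete state is updated
once per step, switch times are logged with linear interpolation of the
triggering crossing (accurate to one step), and drive-table switches take
effect at step boundaries, which realizes "set instantaneously" exactly.
The step size plays the role of the solver tolerance: halving it changes
measured step periods by well under 1%, and two runs with identical
configuration are bit-identical. Unit-level operations (`simulate_cpg`,
`mn_activity`) use `deSolve::lsoda` at tolerance $10^{-8}$; a dedicated
test cross-checks the compiled assembly against this independent
integration on a decoupled CPG (periods agree within 2%).

Degenerate inputs: a zero-length horizon returns an empty record; non-finite
states abort with the failure time and a partial record; empty traces,
non-positive steps and out-of-order gate updates raise argument/state
errors.

Calibration was done once, bottom-up, in the order single unit, single leg,
one side, six legs: drive tables were chosen so that the tetrapod period is
just under 2 s and the tripod period about 1.15 s with a near-constant swing
of 0.4--0.5 s; $\beta_{crit}$, the hysteresis, the quadrant-rule factors and
the segment speed grading were then fixed by the requirements that the
single leg steps with CV < 5%, the wave re-locks within two to three cycles
after a drive switch, and the gate automata never chatter. Stronger
$\gamma$-gate conductances (any value $\ge 0.07\,\mu S$ in either polarity)
were found to deadlock the levator escape and were rejected.

Simulation sizes used by the tests and the acceptance analyses -- 13--24 s
runs, transition scans of 41 starts at 50-ms increments, backward/forward
scans of 21 starts at 100-ms increments -- were chosen to cover at least one
full step cycle per scan and several cycles per classification window.

# What the synthetic traces do and do not show

`synth_traces()` generates idealized square-wave levation traces at the
defining phase offsets of each coordination pattern, with optional uniform
timing jitter. They exercise the classifier: closure (zero-jitter traces
classify back to their pattern), the left-right mirror symmetry (mirroring
maps B-type onto C-type tetrapod and fixes the other labels), and
robustness (jitter of 0.3 periods destroys classifiability in most seeds).
They are fixtures for the analysis toolkit only: they contain no dynamics,
no $\alpha$/$\gamma$ angles and no transitions, so passing classifier tests
says nothing about the neuromechanical model itself -- that is what the
simulated trajectories are for -- and nothing about real animal data, which
has duty-cycle drift, velocity dependence and measurement noise that the
generator does not emulate.

# Design decisions taken where the design was open

* Premotor interneuron count: twelve premotor INs per leg (one per
  motoneuron) plus six sensory relay INs (two per local network), giving
  the 108 total.
* The relay interneurons are tonically active and the gate value scales
  their synaptic conductance; this keeps the sensory pathway inside the
  neuronal network (and the ODE count intact) while the gate itself stays
  binary.
* The quadrant rule's grounded level defaults to zero: a tonic level
  delays the anterior escape and degrades the tripod; the release-pinning
  mechanism needs no tonic term.
* The L2-to-R3 pathway is tonically wired; its inactivity outside
  transition windows is emergent (depolarization block), not gated. The
  pair pathways are controller-gated, since they model pathways whose
  interneurons the original account explicitly omitted.
* The backward role exchange and the hind-leg EF cross connection are the
  same primitive (a CPG-to-premotor routing swap), applied statically to
  the hind legs and dynamically by the direction controller.
* Search movements freeze the searching leg's EF gate at its low value and
  restore dynamic gating at the off command; no dedicated release
  condition exists.

# Known limitations

* Several *emergent statistics* of the original parameterization do not
  reproduce: transitions here are regular at every scanned start (no
  21:5 regular-to-irregular ratio and no periodic irregularity map),
  backward transitions never stall a leg (failure fraction 0 instead of
  about 0.3), and the forward-restore failure rate is about 0.1 instead of
  0.25. The model's own robustness features cause this: the levation bias
  removes the ambiguous lifted states, and the direction swap is
  structurally decoupled from the levation rhythm. The tested fragile
  alternative (a strong $\gamma$-to-LD gate) deadlocks rather than
  producing intermittent failures.
* After restart the first swing comes from a front leg and a B-type
  tetrapod emerges, not R3 and a C-type: the restart order is a
  photo-finish among equilibrated oscillators that the per-segment speed
  grading decides in favour of the front legs.
* The failed contralateral variants reproduce the core finding (no tripod
  emerges under either inhibitory scheme) but not its detailed
  phenomenology: influence flows posterior-to-anterior only, so the
  L2-to-R2 variant cannot ground R3; and bilateral synchrony is phase
  neutral rather than attracting, so the L3-to-R3 variant drifts into a
  tetrapod instead of returning to synchrony.
* Curve walking, velocity-dependent gait selection, intermediate-pattern
  taxonomy, ground-reaction mechanics and aperiodic search trajectories
  are out of scope.
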