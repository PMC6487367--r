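# stickwalk

A neuromechanical simulator of six-legged stick-insect walking, for motor
control researchers and computational neuroethologists who want a tested,
scriptable re-implementation of the classic CPG-based kinematic walking
model: a network of half-center oscillators, premotor interneurons and
fast/slow motoneurons driving antagonistic muscle pairs at three joints per
leg, closed through position-dependent sensory gating.

## The model in brief

Each leg has three local control networks (PR, LD, EF), one per antagonistic
muscle pair, each built from a CPG of two mutually inhibitory nonspiking
neurons, four motoneurons and six interneurons. Every neuron follows

    C dV/dt = -gL (V-EL) - gP m (V-EP) - gq q (V-EK) + sum_j g_j s(V_j) (E_j - V)

with slow activation m, adaptation q and instantaneous sigmoidal synapses
s(V); the full model is 216 neurons (648 first-order ODEs) plus one
second-order joint equation per muscle pair (18), with joint angles
alpha in [28, 128] deg (protraction-retraction), beta in [30, 60] deg
(levation; 30 <= beta < 32 deg signals ground contact) and gamma in
[45, 110] deg (tibia extension-flexion). Sensory gates (g_beta(PR),
g_beta(EF), g_gamma(LD)) coordinate the networks within a leg; interleg
pathways (g_inh3, g_inh9) inhibit the anterior levator CPGs according to the
posterior leg's levation angle and its direction of movement; four sparse
contralateral connections shape the transition to tripod. A behaviour
controller implements gait switching, stop/restart, front-leg search
movements and backward walking as timed requests with acceptance
constraints. A gait toolkit extracts swing phases, classifies coordination
patterns (tripod, B-/C-type tetrapod, bilateral synchrony, a "new" pattern)
from pairwise swing overlaps, and runs transition-start scan experiments.

## A worked example

Walk, switch gaits, and classify the result:

```r
library(stickwalk)

m <- assemble()          # full model: slow muscles + all contralateral pathways
sched <- list(
  mode_command("set_gait", 3000, gait = "tripod"),
  mode_command("set_gait", 7500, gait = "tetrapod")
)
rec <- run_model(m, sched, config = sim_config(t_end = 14000))
classify_gait(step_intervals(rec), window = c(5000, 7500))
#> gait: tripod (window [5000, 7500] ms, defining-pair overlap 0.60)
classify_gait(step_intervals(rec), window = c(9500, 14000))
#> gait: tetrapod_B (window [9500, 14000] ms, defining-pair overlap 0.57)
```

The model starts in bilaterally synchronous stepping, transitions to tripod
when a front or hind leg is lifted and rising (both sides initiating at the
same segment), and later settles into a B-type tetrapod whose defining leg
pairs (L1-R2, L2-R3, L3-R1) swing together; the overlap score is the mean
intersection-over-minimum of the defining pairs' swing phases. Events
(`rec$events`) log every gate switch, transition initiation and mode change
with interpolated timestamps, and `export_trajectories(rec, "run.csv")`
writes the joint-angle record with a JSON event sidecar.

Behavioural modes chain the same way:

```r
sched <- list(
  mode_command("set_gait", 3000, gait = "tripod"),
  mode_command("set_gait", 7500, gait = "tetrapod"),
  mode_command("stop", 12500),        # held until no right leg is descending
  mode_command("restart", 15000)
)
```

An accepted stop drives all legs into the still-stand pose -- front legs
protracted to 28 deg, the others retracted to 128 deg, every leg grounded
and stretched -- within roughly 180 ms.

A command-line front end is installed with the package
(`system.file("exec/stickwalk", package = "stickwalk")`) with `simulate`,
`scan` and `classify` subcommands over CSV/JSON/YAML files.

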