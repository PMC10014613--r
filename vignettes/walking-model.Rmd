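---
title: "The cpgwalk neuromusculoskeletal walking model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cpgwalk neuromusculoskeletal walking model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cpgwalk simulates planar bipedal walking as a closed loop between a
seven-segment skeleton, 18 Hill-type muscles, and a spinal
pattern-generator controller, and searches the controller's parameters with
a genetic algorithm. This vignette is the package's account of the model:
what is computed, which parameters matter, which parts are reconstructed
defaults, and what the numerical and design choices are.

## Skeleton and contact

The skeleton is a 9-degree-of-freedom planar chain in minimal coordinates:
hip position $(x, y)$ plus seven absolute segment angles
(counter-clockwise positive) for the HAT (head--arms--trunk), and the thigh,
shank and foot of each leg. Joint angles are differences of segment angles
with the conventions hip flexion $+$, knee flexion $+$, ankle dorsiflexion
$+$; the standing reference posture has every joint angle at zero. The
equations of motion are assembled by Newton--Euler projection
($M(q)\,\ddot q = Q(q,\dot q)$, mass matrix from the segment COM Jacobians)
and solved with a dense Cholesky factorization; a non-positive-definite mass
matrix signals an invalid inertia configuration.

Each joint carries a linear viscous element with coefficients 1.09, 3.17
and 0.943 Nms/rad at the hip, knee and ankle. The knee and ankle "locks"
against hyperextension and hyperflexion are one-sided torsional
spring--dampers (1000 Nm/rad, 50 Nms/rad by default) engaged beyond the
allowed range; a hard constraint would complicate a fixed-step explicit
integrator, and a stiff one-sided spring is the standard device in this
model family. Range-of-motion limits, segment masses, lengths and inertias
are *reconstructed* from the anthropometric literature this class of model
is built on (a ~70 kg adult; `body_model()` documents every value) — they
are editable defaults, not measured data shipped with the package.

Ground contact acts at the heel and toe of each foot through a linear
spring--damper: vertical stiffness $2.5\times10^4$ N/m and damping
$5\times10^2$ Ns/m, horizontal stiffness $5\times10^3$ N/m and damping
$1\times10^3$ Ns/m. Two choices are not dictated by those coefficients and
are therefore fixed here explicitly: (1) the horizontal spring references
the *touchdown point*, which is re-anchored whenever a point regains
contact and released at lift-off; (2) the vertical force is floored at
zero, because an unclamped damper would otherwise pull the foot down during
rapid lift-off (adhesion).

## Muscles

Nine muscles per leg (GM, IL, BFL, RF, BFS, VA, GC, SO, TA; BFL, RF and GC
bi-articular) follow a Hill-type law

$$F = \bar F^{CE} k(\xi)\, h(\eta)\, \alpha + c^{PD}\dot L +
  k^{PE}\left(e^{15(L-\bar L)} - 1\right),$$

with the force--length gain
$k(\xi) = 0.32 + 0.71\, e^{-1.112(\xi-1)} \sin(3.722(\xi - 0.656))$
(floored at zero) and the force--velocity gain $h(\eta) = 1 + \tanh(3\eta)$,
where $\xi = L/\bar L$ and $\eta = \dot L / \bar{\dot L}$. The passive
elastic term acts only in stretch; in shortening the exponential would
produce a compressive force, which a muscle cannot transmit.

Two conventions deserve note. First, the sign of $\eta$: the package
default (`fv_sign = 1`) takes positive normalized velocity to mean
*lengthening*, so $h > 1$ in eccentric contraction — the physiologically
expected force enhancement. The flag is exposed because the opposite
convention ("contraction velocity" positive in shortening) is also found in
this literature; flipping it reverses the asymmetry of the gain.

Second, the muscle path model is linear: constant signed moment arms about
each spanned joint, calibrated so that $L = \bar L$ in the standing
reference posture. The antecedent models give no path geometry, so moment
arms (3--7 cm, signs encoding anatomy) and the strength/length constants
in `default_muscles()` are reconstructed, physiologically plausible
defaults. Activation couples instantaneously to the contractile element —
no activation dynamics — because the tension law above consumes the
motoneuron output directly.

## Neural controller

Twelve Matsuoka-style units (flexor/extensor pairs for the hip, knee and
ankle oscillators of each leg) obey

$$\tau_i \dot u_i = -u_i + \textstyle\sum_j w^{CPG}_{ij} y_j - \beta v_i
  + u_0 + \mathrm{Feed}_i, \qquad
  \tau'_i \dot v_i = -v_i + y_i, \qquad y_i = \max(0, u_i).$$

Defaults $\tau = 0.08$ s, $\tau' = 0.16$ s, $\beta = 2.5$ and pair
inhibition $-2$ put the isolated pair on a limit cycle of period
$\approx 0.6$ s, a natural stride timescale; the tonic input $u_0$ (a
searched gene) scales the oscillation amplitude. The 12×12 connection
matrix is generated from 11 named coupling strengths (within-pair
inhibition per joint, contralateral hip coupling for leg antiphase, and six
descending intra-leg couplings; see `build_wcpg`). This wiring — like the
time constants — is a reconstructed default in the Matsuoka-controller
tradition, and all 11 strengths are genes in the normal-scenario genome, so
the search can reshape it.

**Sensory feedback.** Each leg owns 16 weighted feedback slots mapping
fixed sensor features to its six units: thigh angles (ipsi- and
contralateral), shank, foot and HAT angles, and the body-weight-normalized
vertical GRF, contact-gated at 10 N. The slot-to-sensor table is fixed and
documented in `compute_feedback()`; the 32 weights (16 per leg) are what
the scenarios search. Since the exact feedback expressions of the
antecedent models are not available, the table is a package design choice;
the GA searches the coefficients regardless of slot semantics, which is
what makes the symmetric/asymmetric comparison meaningful.

**Motoneurons.** Muscle activation is
$\alpha_m = \mathrm{clamp}\!\left(2/(1 + e^{-0.25(\sum_i w^\alpha_{mi} y_i
+ P_m)}) - 1,\, 0,\, 1\right)$ — an increasing sigmoid of oscillator drive
plus posture correction. Two deliberate choices: the exponent is negative
(a positive exponent would make activation *decrease* with drive,
contradicting $0 \le \alpha_m \le 1$ rising with excitation), and the
mixing matrix is 18×12 (18 muscles cannot be indexed by 12 oscillator
units; each muscle listens to its flexor/extensor unit, bi-articular
muscles to a half-weighted second unit — see `default_walpha`).

**Posture reflex.** $P_m$ is a stance-gated correction, strictly linear in
its 23 coefficients: per-muscle-group P and D weights on the group's
primary-joint error (18 coefficients) plus HAT-pitch P/D routed to the
hip, knee and ankle groups (5). All features vanish in the reference
posture, extensors and flexors receive opposite signs, and swing-leg
muscles receive nothing. Linearity in the coefficient vector is a design
requirement: it keeps the posture block, like the feedback block, a pure
weight layer for the GA to search.

## Scenarios, fitness and search

The **normal** scenario searches 51 genes: $u_0$, 16 feedback weights
(applied to both legs), the 11 CPG couplings and the 23 posture
coefficients. After a prosthesis is applied (`apply_prosthesis`: shank+foot
mass ×0.65, inertia ×0.40, passive ankle stiffness 400 Nm/rad, TA/SO/GC
removed on that side), two re-adaptation scenarios freeze everything at the
normal solution and re-search only $u_0$ plus the feedback weights:
**utta_symmetric** keeps the legs tied (17 genes) and **utta_asymmetric**
frees them independently (33 genes), warm-started from the normal values
plus exploration noise.

Fitness is $J = D + P$ below 3 m walked and $J = D + P + 60/C$ beyond,
with fall penalty $P = -3$ and $C$ the gross metabolic cost of transport
$C = \frac{1}{TMV}\int_0^T \sum_m \dot E_m\,dt$, evaluated over the full
trial. A trial ends in a fall when the hip drops below 55 % of standing
height, trunk pitch exceeds 1 rad, a knee approaches the ground, or the
state becomes non-finite (GA exploration produces unstable gains; blow-up
is scored as a fall at the current distance, never an error).

The GA itself is generational with tournament selection (size 3), BLX-0.5
blend crossover (rate 0.8), Gaussian mutation (SD 5 % of each gene range,
per-gene rate 0.15), elitism 2 and clipping to bounds after every
operator. These hyperparameters are conventional values, exposed in the
config rather than hard-coded, since nothing in the model constrains the
GA variant.
Evaluations run through a pluggable map (`map_fn`), serial by default,
`parallel::mclapply` if workers are requested; a throwing evaluation is
fault-isolated and scored as a fall.

## Energetics

The cost-of-transport integrand needs a muscle energy model, and the model
family this package follows does not fix a single formulation; the package
implements a documented three-term model behind the single interface
`metabolic_rate()` so it can be swapped:

$$\dot E_m = a\,\bar F^{CE}\bar L\,\alpha \;+\; s\,\bar F^{CE}\alpha\,
  \max(0, -\dot L) \;+\; \max(0, -F^{CE}\dot L),$$

activation/maintenance heat ($a = 0.06\,\mathrm{s^{-1}}$), shortening heat
($s = 0.25$) and positive contractile-element work. There is no basal
term; inactive and removed muscles consume nothing. Absolute CoT values
depend directly on this choice (and on the reconstructed muscle
constants), which is why the package treats CoT comparisons *between*
scenarios as meaningful and absolute magnitudes as model-specific.

## Gait metrics

Events come from threshold crossings of each limb's vertical GRF (10 N
default) with a 20 ms debounce that absorbs contact-model chatter; stance
time is toe-off minus strike; step length is the anterior distance between
the striking heel and the contralateral heel at the strike. The symmetry
index is $\mathrm{ASI} = 2(R-L)/(R+L)\times100$; the signed value is kept
internally and the absolute value reported alongside. The analysis window
is **strides 3–8 inclusive** per limb: early strides are transient, and six
strides bound five step-to-step transitions, so this window captures five
steady steps; it is fully configurable in `summarize_trial()`. CoT over
the window uses the
trapezoid rule on the logged grid and is sample-rate invariant to well
under 0.1 %.

## Numerics and determinism

Everything — mechanics, muscles, CPG — is one monolithic state advanced by
classical RK4 at a fixed 0.1 ms step. Contact anchors are discrete states
updated once per full step (frozen during substages). The simulator has no
internal randomness: identical configuration gives bitwise-identical
trajectories, which the tests assert; all stochasticity lives in the GA
and is controlled by its seed. The initial condition is a standing posture
with straight legs, the hip lowered by the static contact penetration, a
slight forward lean, a 0.5 m/s forward push, and an asymmetric CPG seed
(left hip flexor, right hip extensor pre-charged) to break the left-right
symmetry — walking cannot emerge from an exactly symmetric state.

## What the synthetic fixtures do and do not show

`make_fixtures()` builds square-wave GRF traces and periodic trials with
*known* stance times and step lengths, used to verify the metric code
exactly, plus random bounded controllers and the normal/UTTA body pair.
These fixtures emulate the logged outputs of a trial, not its physics:
passing metric tests shows the event detection and formulas are right, not
that simulated gaits resemble human data. Conversely, the scaled-down GA
runs exercised by the tests (population 16--32, tens of generations,
4-second trials — sizes chosen so the whole suite stays interactive)
demonstrate that the search improves monotonically and finds
forward-progressing solutions; they are far below the thousands of
generations needed for the polished steady gaits of the full-scale
experiment, and their gaits should be read as smoke-level, not as the
model's converged behavior.

## Known limitations

Two-dimensional dynamics only; no toe joints (which truncates late-stance
GRF peaks), no muscle wrapping, no tendon compliance or activation
dynamics, no neural noise. The fine-grained parameter tables of this model
family (segment anthropometry, muscle constants, CPG constants, feedback
expressions) vary between published variants and are shipped here as
reconstructed, clearly flagged defaults; absolute energetic and kinematic
magnitudes inherit that uncertainty even where the model structure is
faithful.
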