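---
title: "Propagating muscle-tendon parameter uncertainty to knee contact force estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating muscle-tendon parameter uncertainty to knee contact force estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatmc)
```

# The problem

Musculoskeletal simulations of deep knee flexion estimate the tibiofemoral
contact force (KCF) from motion data by solving, frame by frame, the muscle
redundancy problem and summing muscle and intersegmental forces across the
joint. Every muscle-tendon parameter entering that pipeline — maximum
isometric force (MIF), tendon slack length (TSL), pennation angle (PEN), and
the origin, insertion and via points defining the muscle pathways (OIP, VIA)
— is uncertain at the level of inter-individual variability. `squatmc`
implements the full chain at desk scale: a reduced sagittal-plane lower-limb
model, anthropometric scaling, inverse kinematics and quasi-static inverse
dynamics, static optimization, joint reaction force assembly, Gaussian
parameter-perturbation Monte Carlo designs, and the percentile-band
statistics that attribute output uncertainty to parameter classes and muscle
groups. A synthetic-data module generates subjects, squat trials,
ground-truth "measured" KCF traces and EMG-like signals, so the entire
analysis runs from code alone.

# The reduced model

The skeleton is a planar kinematic tree: pelvis (root, carrying the lumped
trunk/head/arms and contralateral-limb mass so the chain totals the subject
mass), thigh, shank and foot, coupled by hip, knee and ankle flexion
(flexion-positive, radians). Fourteen muscle-tendon units cover the seven
muscle groups of the probabilistic design: three vasti, rectus femoris, both
biceps femoris heads, semimembranosus, semitendinosus, both gastrocnemii,
soleus, tibialis anterior, gluteus maximus (lumped) and iliopsoas (lumped).
Pathways use via points only (a femur-fixed via point in front of the knee
stands in for the patellar mechanism); wrapping surfaces are out of scope
because the perturbation study targets the path points themselves. Segment
lengths, masses and inertias follow standard anthropometric fractions of
stature and body mass; the same fractions generate subject landmark
distances, so a subject at the generic stature scales by exactly one.

Scaling to a subject works per segment: lengths, centres of mass, joint
locations and path-point coordinates scale isotropically by the ratio of the
subject's landmark distance (pelvis width, femur length, tibia length; the
foot follows the tibia) to the generic one; masses scale with total mass;
optimal fiber length and tendon slack length scale with the ratio of the
scaled to generic MTU length in the neutral pose, preserving their ratio;
maximum isometric forces are copied unchanged from the generic model.

# Muscle mechanics

Muscles are Hill-type with a rigid tendon. Fiber kinematics follow the
constant-thickness pennation model,

$$l_f \cos\alpha = L_{MTU} - TSL, \qquad l_f \sin\alpha = l_{opt}\sin\alpha_{opt},$$

with the fiber clamped (and flagged) when the MTU shortens to the tendon
slack length. One explicit curve set is used, normalized so that
$f_L(1) = 1$, $f_{PE}(1) = 0$ and $f_V(0) = 1$:

* active force-length: $f_L(\tilde l) = \exp(-(\tilde l - 1)^2 / 0.45)$;
* passive force-length: $f_{PE}(\tilde l) = (e^{4(\tilde l - 1)/0.6} - 1)/(e^4 - 1)$ for $\tilde l > 1$;
* force-velocity: a hyperbola with $\tilde v_{max} = 10\,l_{opt}/s$ and
  curvature 0.25 on the concentric side, and a slope-continuous eccentric
  branch with asymptote 1.8.

The force along the tendon is $MIF\,[a\,f_L f_V + f_{PE}]\cos\alpha$; a
simplified variant (`include_flv = FALSE`) uses the ideal generator
$MIF\,a\cos\alpha$ with no passive force, reproducing the "no force-length
characteristics" comparison. The default pipeline runs quasi-statically
($f_V \equiv 1$), appropriate for a four-second squat.

Tendon slack lengths of the shipped generic model are calibrated at
construction: each muscle's fiber reaches optimal length at the longest MTU
length it sees over a 0-75 degree knee-flexion sweep of the standard squat
coupling. Fibers therefore operate at or below optimal length over most of
the cycle and engage the passive curve mildly in the deepest poses — the
behaviour of cadaver-calibrated generic models driven beyond their validated
range. Calibrating at mid-squat instead was rejected: it parks long-tendon
muscles high on the passive curve at the ends of the cycle, and TSL draws
then produce multi-body-weight passive forces at standing, which is neither
physiological nor numerically useful.

# Squat kinematics and kinetics

The synthetic squat prescribes a raised-cosine knee flexion profile
(0 to depth and back, default 90 degrees over 4 s, 101 frames). The closure
tying hip and ankle to the knee angle keeps the foot flat and the trunk
vertical, which forces $q_{hip} = q_{knee} - q_{ankle}$; the remaining
freedom (ankle dorsiflexion) is solved per frame so the model's centre of
mass stays vertically above the ankle. The per-limb ground reaction force is
quasi-static — half body weight with a documented 1% oscillation — with the
centre of pressure under the centre of mass.

Net joint moments come from a planar Newton-Euler recursion from the foot
upward, using the measured GRF; in the default quasi-static mode all
accelerations are zero, and a dynamic mode obtains segment accelerations by
zero-phase low-pass filtering (2nd-order Butterworth, 6 Hz default) followed
by central differences. Tests verify the recursion against an independent
static-equilibrium oracle that sums cross products of all distal external
loads about each joint. Marker-based inverse kinematics (Gauss-Newton
weighted least squares per frame, numeric Jacobians) is available when
trials carry TRC marker data; the synthetic generator emits joint angles
directly, so IK stays an optional entry point.

# Static optimization and the contact force

Each frame solves

$$\min_a \sum_i a_i^2 \quad \text{s.t.} \quad \sum_i a_i\,C_{ji} = m_j,\; 0 \le a_i \le 1,$$

where $C_{ji}$ is the muscle's maximal active along-tendon force at the
current state times its tendon-excursion moment arm $r = -\partial L /
\partial q$ (central difference, step $10^{-5}$ rad), and the
activation-independent passive forces are moved to the right-hand side. The
box-bounded equality QP is solved exactly by an active-set method on the
bounds; the free-variable subproblem has the closed-form least-norm solution
$a_F = C_F^{+}\,rhs$, and bound release uses the constraint multipliers plus
an NNLS-style residual-reduction step that distinguishes genuine capacity
shortfalls from a too-aggressive working set. Genuinely infeasible frames
(demand beyond capacity, e.g. in weak perturbed models) are never fatal:
they return the bounded least-squares minimum-violation activation, flagged,
and the Monte Carlo records them. Solver tolerance is $10^{-8}$; tests check
the solution against exhaustive grid enumeration on small problems and the
KKT stationarity structure at interior solutions.

The knee contact force is the vector sum, on the tibial side, of the
intersegmental force from inverse dynamics and the pull of every muscle
whose pathway crosses the knee, along the unit vector of its knee-crossing
pathway segment; the magnitude is reported in units of body weight
($BW = m\,g$).

# The Monte Carlo designs

Scalar parameters are Gaussian with literature-style coefficients of
variation: when several sources report a CV for the same muscle and
parameter, the subject-count-weighted average is used; muscles without a
source inherit the unweighted mean CV of that parameter across the other
muscles. Pathway points get an absolute 5 mm standard deviation,
interpreted as an independent per-axis Gaussian on each point's local
coordinates (a magnitude-in-random-direction alternative is available).
Draws are truncated to physical bounds (MIF, TSL positive; PEN in
[0, 80 deg]) by resampling rather than clipping, preserving the shape of the
distribution near the mean. The shipped default table uses TSL CVs inside
the 2-9% working range and documented placeholder CVs for MIF and PEN, with
one deliberately missing entry per scalar parameter to exercise the fallback
rule. Parameters are drawn independently across muscles and classes; no
correlation structure is imposed.

The general design perturbs all five classes of a muscle group at once
(default 2000 iterations); individual designs perturb one class at a time
(default 500). Each iteration derives its own RNG substream from
`(design seed, iteration)` by exact integer mixing, so results replay
bit-identically and failed iterations never shift later draws. The full
study plan — six subjects, seven groups, one general plus five individual
MCs each — totals 189,000 planned iterations, with 72,000 general-MC joint
reaction force simulations feeding the six-group contribution comparison;
`plan_mc_design()` reproduces this arithmetic. Convergence is declared when
adding 10% more iterations changes the mean 5th-95th percentile band width
of the KCF by less than 1%; the check is shipped as a post-hoc probe.

Band statistics use empirical per-frame percentiles with linear
interpolation between order statistics (quantile type 7). Contribution
factors are width ratios in percent — individual over general for parameter
classes, group over the all-lower-limb reference for muscle groups — and are
deliberately not renormalized to sum to 100%: interactions and overlapping
(biarticular) groups make them overlap. Traces can be resampled to 101
points of percent squat cycle for cross-trial arithmetic; RMSE is computed
in BW on the trial grid.

# What the generator emulates, and what it does not

The synthetic cohort draws anthropometry from the study population
statistics (six subjects, 89 +/- 13 kg, 1.72 +/- 0.04 m, 74 +/- 6 years,
truncated positive). Landmark distances follow fixed allometric fractions
of stature, which makes synthetic subjects geometrically self-similar: in
body-weight units their baseline KCF traces are nearly identical (about
4.6 BW at deepest flexion at desk scale). Real cohorts add skeletal shape
variation, marker artefacts, trunk lean and co-contraction, so passing the
synthetic suite shows the pipeline's internal consistency, not transfer to
real data. The trunk-vertical closure in particular keeps hip extension
demands small, so hip-muscle contributions to KCF uncertainty stay lower
than a forward-leaning squat would produce.

Ground-truth "measured" traces simulate a truth-perturbed model and add
frame-wise Gaussian noise (default 0.1 BW; the planted-truth experiments use
0.05 BW). Synthetic EMG amplitude-modulates a 20-250 Hz band-limited noise
carrier with the activation trace, so the conditioning chain — zero-phase
4th-order Butterworth band-pass (the stated 10 Hz / 300 Hz corner pair is
read as a 10-300 Hz passband, the standard surface-EMG band), offset
correction, full-wave rectification, 100 ms centred moving average, and
subject-maximum normalization — approximately recovers the activation
shape.

# An identifiability result worth knowing

Two exact mechanisms make a *uniform* rescaling of a muscle group's MIFs
nearly invisible in the predicted KCF. First, at interior solutions the
minimum-activation objective redistributes load within a uniformly rescaled
group so that muscle *forces* are unchanged (activations scale inversely);
this is the same mechanism behind the exact uniform-MIF-scaling invariance
the test suite asserts for the whole model. Second, with a rigid tendon the
MIF-scaled passive force is compensated by reduced active force along the
same tendon, cancelling in the joint load. Consequently a synthetic
"measured" trace generated from a +30% extensor-MIF model is statistically
the baseline plus noise, and minimum-RMSE selection can only match — not
meaningfully beat — the baseline against it. A pathway plant (for example a
5 mm anterior shift of the extensor via points) changes the knee moment arms
and is recovered with a clear RMSE improvement; `analysis/04_best_model.R`
runs both plants side by side.

The same geometry explains why, at desk scale, the parameter-contribution
ranking is dominated by the pathway classes (VIA, OIP) and TSL while MIF and
PEN contribute a few percent: the reduced extensor set is geometrically
homogeneous, so independent strength draws mostly redistribute force along
near-identical lines of action. In a full-scale model with dozens of
heterogeneous actuators, strength draws shift load between muscles with
genuinely different geometry, and MIF becomes a leading contributor. The
directional MIF > PEN ordering survives the reduction and is asserted in the
acceptance suite.

# Numerical choices and problem sizes

* Moment arms: central differences, step $10^{-5}$ rad, one-sided with a
  warning at joint-range boundaries.
* QP: active-set with SVD-based least-norm subproblems, tolerance $10^{-8}$,
  warm-started across frames; bounded least-squares fallback
  (L-BFGS-B) only on flagged infeasible frames.
* Percentiles: type 7; bands require at least 20 successful iterations.
* Ties in best-model selection break toward the lowest iteration id; the
  baseline participates as candidate 0.
* Seeds: all randomness flows through explicit integer seeds; substreams are
  derived by exact modular mixing, with every multiplier small enough that
  the arithmetic is exact in doubles.
* Test and script problem sizes are deliberate package choices: unit tests
  use 21-frame trials and tens of iterations; the acceptance suite runs one
  2000-iteration general MC (the study-scale count per subject and group)
  plus 500-iteration designs; the acceptance script uses 500-iteration
  designs throughout and reports its convergence probe honestly (at 500
  iterations the band is typically a few percent from its converged width).

# Known limitations

Sagittal plane only; via points, no wrapping surfaces; rigid tendon (the
elastic-tendon equilibrium solve is a non-goal, and with it goes part of the
MIF/TSL sensitivity a compliant tendon would transmit); trunk-vertical squat
closure; single-limb analysis with symmetric load sharing; no co-contraction
or alternative cost functions; desk-scale muscle set with placeholder
strength CVs. The contribution *magnitudes* of this reduced model should not
be read as estimates for full-scale models — the pipeline, designs and
statistics are the reusable part.
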