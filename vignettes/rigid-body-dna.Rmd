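---
title: "Rigid-body dynamics of DNA under magnetic tweezers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body dynamics of DNA under magnetic tweezers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rbdna)
```

## The model

rbdna simulates a DNA molecule as an articulated system of rigid bodies:
`N` cylinders of length `b` (10 base pairs, 3.4 nm -- one helix pitch each),
connected end to end by ball-and-socket joints. The first cylinder can be
anchored to the plane `z = 0` (the coverslip) and the last welded to a
sphere (the magnetic bead). The magnets enter as a constant stretching
force on the bead along `+z` plus one of three rotational boundary
conditions: free rotation (force clamp), a kinematically prescribed number
of bead turns (turn clamp), or a constant axial torque with free rotation
(torque clamp).

Internally everything is in reduced units: `b = m = kBT = 1`, with the
natural time unit `tau = b sqrt(m/kBT)` (about 0.17 ns for a 10 bp
cylinder). SI units appear only at the interface (`make_unit_system()`,
`force_pN_to_reduced()`). The default cylinder mass is 10 bp at 650 Da/bp;
a different experimental mass can be supplied as `mass_kg`.

### Constrained dynamics

Joints impose holonomic constraints `C(x) = 0` -- the separation of the two
joint bearings. The solver works at the velocity level: each step it solves

```
A lambda = rhs,     A = J W^-1 J^T + cfm/dt
rhs = (v_target - (erp/dt) C - J u_f)/dt,   u_f = u + dt W^-1 F_ext
```

and applies `u' = u_f + dt W^-1 J^T lambda`, followed by a semi-implicit
Euler position update and an exponential-map quaternion update. Here `J` is
the constraint Jacobian, `W` the block-diagonal generalized mass, `erp` the
error-reduction parameter (fraction of the bearing separation corrected per
step, default 0.8), and `cfm` a small constraint-force-mixing term that
makes `A` strictly positive definite and acts as an implicitly integrated
spring-damper: no energy is stored in the softened joints. With the
returned multipliers the identity `J u' + (erp/dt) C - v_target + cfm
lambda = 0` holds to solver precision; multipliers carry force units and
`F_c = J^T lambda` is the generalized constraint force.

Three solvers share this system:

* **Exact O(N)** -- for a serial chain without contacts, `A` is block
  tridiagonal (3x3 blocks for ball joints; welds and bead-clamp rows are
  merged into their neighbouring group), and a block LDL forward
  elimination / back substitution solves it to machine precision in one
  sweep. This is the default path for every collision-free step.
* **Projected SOR** -- with contacts present, successive over-relaxation
  sweeps (default `omega = 1.3`, 64 sweeps, early exit on convergence)
  with the contact multipliers projected onto `lambda >= 0`.
* **Direct** -- if the SOR solution's implied per-step bearing-separation
  growth exceeds `accept_tol` (default `1e-6 b`), the step is re-solved
  exactly: the permanent-joint block reuses the tridiagonal factorization
  and the contact block is reduced to a small Schur complement solved by
  active-set pivoting (guaranteed for the SPD system; no Lemke pivoting
  needed).

Collisions are detected with a uniform spatial hash grid (cell size
`b + 2r`) plus capsule-capsule, capsule-plane and capsule/bead-sphere
closed-form narrow phases; each overlapping pair produces one contact
(closest-approach midpoint, common normal, depth), a single unilateral row
with restitution 0 and no friction. The contact push-out velocity
`(erp/dt) depth` is capped (`max_push`, default `1 b/tau`) so that a deep
initial overlap relaxes smoothly instead of detonating.

Chain neighbours within `|i - j| <= floor(2r + 1)` never collide: the joint
geometry forces those capsules to overlap permanently (adjacent bodies
always; second and third neighbours whenever the effective radius is large,
as in low-salt buffers where `2r` exceeds `b`). Treating those built-in
overlaps as contacts would pit the contact solver against the joints. The
chain cannot fold back on itself within that window anyway -- the
persistence length is ~15 cylinders.

### Elasticity

Bending and twisting are soft interactions (part of `F_ext`), not
constraints. Between adjacent cylinders the ZXZ Euler decomposition of the
relative rotation (tangent as the Z axis) defines the bending angle `theta`
(angle between tangents) and the twist `phi` (sum of the outer Euler
angles). The joint energy is

```
E = g_b (1 - cos theta) + g_t (1 - cos phi)
```

whose exact negative rotational gradient gives the equal-and-opposite
restoring torque pair

```
Gamma = -g_t sin(phi) (t_i + t_{i+1}) / (1 + cos theta) - g_b (t_i x t_{i+1})
```

on the distal body (derived through the dual basis of the ZXZ axes; the
twist part acts along the tangent bisector, the bending part along the
common normal). Rigidities are calibrated from persistence lengths through
the Langevin-function relation `L(g) = exp(-b/xi)`, `L(x) = coth x - 1/x`,
which is exact for this energy: averaging `cos` of the joint angle over the
Boltzmann distribution on the sphere gives `L(g)`. For DNA (`xi_b = 50 nm`,
`xi_t = 95 nm`, `b = 3.4 nm`) this yields `g_b = 15.2 kBT` and
`g_t = 28.4 kBT`. Per-joint twist is unwrapped cumulatively (the timestep
keeps increments far below pi), which provides the total twist `Tw` for
linking-number bookkeeping. At the gimbal degeneracy (`theta > pi - 1e-3`,
elastically unreachable at DNA rigidities) the twist is frozen at its
previous value for that step, deterministically.

Because `1 - cos theta` deviates from `theta^2/2` at fourth order, the
quadratic small-angle law holds to a relative accuracy of `theta^2/12`
(e.g. 8e-6 at `theta = 0.01`); the tests assert exactly that.

### Thermostats

The **local** thermostat is standard Langevin dynamics: friction
`-gamma M v`, `-gamma I w` per body plus Gaussian noise of per-component
variance `2 gamma kBT m/dt` (resp. `2 gamma kBT I_k/dt` along the body
principal axes), the discrete fluctuation-dissipation pairing. The
kinetic-energy autocorrelation time is `1/(2 gamma)` -- the velocity
autocorrelation decays as `exp(-gamma t)`, so its square decays twice as
fast.

The **global** thermostat extends stochastic velocity rescaling to the
rotational degrees of freedom: each step draws the exact one-step rescaling
factor `alpha` for the canonical kinetic-energy target `n_dof kBT/2`
(Gamma-distributed kinetic energy with shape `n_dof/2`), with
`c = exp(-2 gamma dt)` so that the kinetic-energy relaxation time matches
the local thermostat at equal `gamma`. The equivalent generalized force
`((alpha - 1)/dt) W u` is exactly parallel to the momentum `P = W u`, so
its contribution to the constraint right-hand side is proportional to
`J u` and vanishes whenever the constraints hold: the thermostat neither
disturbs the joints nor is filtered by them, which is why it accelerates
sampling so dramatically for articulated chains. `n_dof` counts permanent
constraints only (3 per ball joint, 6 per weld, plus the bead-clamp rows of
the active protocol); intermittent contacts are not counted.

**Conserved collective modes.** Because the exact solver applies joint
forces as exactly equal-and-opposite pairs, a free chain's total linear
and angular momentum are conserved to machine precision (and an anchored
chain's pendulum swing is nearly conserved). A pure rescaling thermostat
cannot thermalize such modes; worse, the log of the rescaling factor has a
negative drift (`-2(1-c)/n_dof` per step), so their energy drains to zero
within ~10^4 steps and the remaining modes run warm by
`n_dof/(n_dof - n_conserved)`. The engine therefore adds a weak local
Langevin background (`gamma_background = gamma/100` by default) under the
global scheme: both thermostats leave the canonical measure invariant, so
the combination is exact; the background re-thermalizes the conserved and
quasi-conserved modes on a `1/(2 gamma_background)` ~ 50 tau timescale
while leaving the global scheme's sampling acceleration intact (the
background alone would relax the chain hundreds of times more slowly).
Engines with noisier constraint solvers get this re-thermalization for
free from their numerics; an exact solver has to put it back deliberately.

**An ergodicity caveat found while validating the package**: for a chain
*without* twist rigidity (`g_t = 0`, the freely-jointed limit) the axial
spin of every symmetric cylinder is an exact integral of the motion --
joint forces act through the axis and exert no axial torque. A thermostat
whose only action is rescaling the momentum vector can never thermalize
those modes: their kinetic energy stays frozen at whatever the initial
conditions gave them, and the remaining modes equilibrate at an effective
temperature `(K_target - K_frozen)/(n_live/2)`, biasing every
configurational observable. We verified this quantitatively (a frozen spin
energy of 7.0 kBT against a canonical share of 5.0 kBT produced exactly
the measured effective temperature of 0.8). Freely-jointed validations
therefore use the local thermostat; with DNA twist rigidity the twist
coupling restores ergodicity and the global thermostat is safe.

### Initial configurations

Two ensembles admit exact direct sampling
(`sample_chain_configuration()`): the freely-jointed chain under any
tension (independent segment tilts, inverse-CDF on the sphere) and the
worm-like chain at zero force (Markov chain of bend angles with sphere
measure and von Mises twist). Starting production runs from such draws
removes the slow collective equilibration entirely -- the end-to-end Rouse
time of a 50-segment free-draining chain under the local thermostat is
~850 tau (1.4 million steps), which would otherwise dominate every run.
Where exact draws are unavailable (welded tweezers assemblies), runs start
from the straight build and equilibrate under the global thermostat.

### Statistical errors

Every reported curve point carries a standard error. Within a single run,
batch means (20 batches) are used, with a first-half/second-half drift
flag; because batch means underestimate the error when a collective mode
outlives the batch length, the protocols can instead average over
independent replicas (`replicas` argument), each started from its own
exact Boltzmann draw, whose across-replica scatter is free of slow-mode
autocorrelation. The freely-jointed force-extension and
persistence-length validations pool several replicas for exactly this
reason.

## Observables

* Extension `z` (anchor plane to the distal chain end), end-to-end
  distance, kinetic energy, contact counts, per-step constraint quality
  `max |C|`.
* `Tw` from the cumulative unwrapped joint twists; `Wr` by the exact
  solid-angle (Klenin-Langowski) pairwise sum over the centreline, with
  the open chain virtually closed by two vertical rays (downward below the
  anchor, upward above the end). With both ends torsionally constrained,
  White's theorem `n = dTw + dWr` is an assertable runtime invariant.
* Reference laws: the freely-jointed `z/L0 = L(f b/kBT)` and the
  seven-coefficient worm-like-chain interpolation formula (Bouchiat et
  al. 1999 coefficients, transcribed).
* Fits: exponential relaxation times from autocorrelation functions,
  persistence length from tangent-tangent correlations, the plectonemic
  hat-curve slope via a hinge (plateau-plus-line) fit, two-state
  buckling statistics via a univariate Gaussian mixture, the critical
  torque as the overtwist-variance peak of a torque sweep, and the
  plectonemic affine law `Gamma = (2 pi kBT xi_p / p)(sigma - sigma*)`.

Two constructions deserve explicit caveats. The plectoneme geometry
estimator (`estimate_plectoneme_geometry()`) measures the superhelix
radius as half the mean axis distance of contacting contour-distant pairs
and the angle from their crossing angle (valid for `alpha > 45 deg`, where
DNA plectonemes live); it is this package's own construction, not a
published procedure. And the slope relation `supercoil_relation()`
implements the standard plectoneme mechanics `q = -(4 pi R / sin 2 alpha)
rho(f)` -- each turn converts `4 pi R / sin(2 alpha)` of extended molecule
(the inverse writhe density of a two-start superhelix) into plectoneme,
with `rho(f) = 1 - (1/2) sqrt(kBT/(f l_p))` the extended-state relative
extension. The twist-to-bend ratio argument is accepted for interface
compatibility but unused; inverting the relation requires an independently
measured angle.

## Parameter defaults and their origins

| parameter | default | meaning |
|---|---|---|
| `b` | 3.4 nm | cylinder length, 10 bp = one helix pitch |
| `bp_mass` | 650 Da | per-bp mass (override with `mass_kg`) |
| `l_p`, `l_t` | 50, 95 nm | persistence lengths -> `g_b = 15.2`, `g_t = 28.4 kBT` |
| `r_eff` | `1 nm + 0.304/sqrt(c[M]) nm` | crystallographic radius + Debye length |
| `dt` | 0.000592 tau | integration timestep |
| `gamma` | 10 / tau | thermostat coupling frequency |
| `erp`, `cfm` | 0.8, 1e-10 | constraint stabilization (hard joints) |
| `sor_omega`, `sor_iter` | 1.3, 64 | SOR settings (config-exposed) |
| `accept_tol` | 1e-6 b | SOR acceptance threshold (config-exposed) |
| `N` | 300 | 3 kb molecule at 10 bp per cylinder |
| bead radius | 50 nm | blocks end looping at desk scales |
| bead mass | 10 m | equilibrium observables are mass-independent |
| ramp rate | 0.05 turns / 1000 steps | quasi-static turn loading |

The bead's transverse rotations are locked in both clamp modes (the
magnetic field's transverse stiffness); its axial rotation is prescribed
(turn clamp) or free under constant torque (torque clamp). Gravity and
buoyancy are neglected. Restitution is zero and contacts are frictionless.

## Numerical choices

* Quaternions stored `(w, x, y, z)`, world-frame angular velocities,
  renormalization every step; the exponential map uses a series branch
  below `|w| dt/2 < 1e-3` (error below 1e-13 there).
* The gyroscopic torque `-w x (I_world w)` is included explicitly; the
  torque-free symmetric top test pins its accuracy.
* The engine RNG is xoshiro256++ (splitmix64-seeded) with polar
  Box-Muller normals and Marsaglia-Tsang gamma deviates; one stream per
  run, draw order fixed by body index, so runs are bit-reproducible from
  the integer seed. The R-level reference implementations use R's RNG.
* The compiled engine and the dense R reference implementations are two
  independent codings of the same step; the suite asserts agreement to
  1e-10 on full tweezers assemblies.

## What the validations do and do not show

The test-suite validations run at desk scale (50-100 cylinders,
~0.2-1.7 um DNA, millions of steps) rather than the 3 kb / tens of
millions of steps of a full study: equipartition and the Gamma law of the
kinetic energy under both thermostats, the freely-jointed and worm-like
chain force-extension laws, persistence-length recovery from tangent
correlations, linking-number bookkeeping under the turn clamp, constraint
quality under collisions, and the global-over-local sampling acceleration.
Problem sizes were fixed once from pilot runs sized by the target
statistical error. Passing them shows the mechanics, elasticity,
thermostats and topology bookkeeping are implemented correctly at the
coarse-graining scale of the model; it does not by itself certify
behaviour that only emerges at full experimental scale (multi-plectoneme
coexistence on 21 kb molecules is explicitly out of scope) nor
sequence-dependent or denaturation physics, which the model does not
contain.

## A worked example

```{r example}
library(rbdna)

# a 1-um DNA (300 cylinders) in 100 mM salt, torsionally clamped
asm <- build_assembly(n_cylinders = 300, salt_mM = 100)

# rotation-extension curve at 1 pN
hat <- run_turn_clamp(asm, force_pN = 1, turns = seq(-20, 20, by = 4),
                      equil_steps = 2e5, sample_steps = 5e5, seed = 1)
autoplot(hat)
fit <- hat_curve_slope(hat)
glance(fit)   # plectonemic slope q in b per turn
```
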