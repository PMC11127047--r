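---
title: "Controlling topological defects in active nematic films"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling topological defects in active nematic films}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actnem)
```

# The model

`actnem` simulates a two-dimensional active nematic film: a thin layer of
elongated, internally driven units (bacterial suspensions, microtubule-motor
extracts, confluent cell monolayers) with head-tail symmetric orientational
order.  The state is the traceless symmetric alignment tensor
$Q = S(\hat n \hat n - I/2)$, stored through its two independent components
$(q_{xx}, q_{xy})$, coupled to an incompressible Stokes flow $u$ on a
periodic grid:

$$\partial_t Q + u\cdot\nabla Q = S(u, Q) + \tfrac{1}{\gamma} H, \qquad
-\Gamma u + \eta \nabla^2 u - \nabla\Pi +
\nabla\cdot(\sigma^a + \sigma^{el}) = 0 .$$

$H = (a_2 - a_4\,\mathrm{tr}[Q^2])Q + K\nabla^2 Q$ is the molecular field
(Landau relaxation plus Frank elasticity in the one-constant approximation),
$S(u,Q)$ the generalized co-rotational flow coupling with flow-alignment
parameter $\lambda$, $\sigma^{el}$ the passive liquid-crystal stress, and
$\sigma^a = \alpha Q$ the active stress.  The activity $\alpha(r, t)$ — the
coarse-grained strength of the force dipoles the active units exert — is the
*control field*: everything in this package is about choosing $\alpha(r,t)$
to make $\pm 1/2$ disclinations do useful work.  We treat the extensile case
($\alpha < 0$) throughout.

## Units and parameters

All quantities are nondimensionalized with the nematic coherence length
$\xi = \sqrt{K/a_2}$, the nematic relaxation time $\tau_n = \gamma/a_2$, and
the passive stress scale $K\Gamma/\gamma$ (so activity values like
$\alpha_0 = -5$ are multiples of that stress scale).  With the defaults
$a_2 = a_4 = K = \gamma = 1$ the remaining knobs are:

* `lambda` — flow alignment, default 1.8 (flow-aligning rods);
* `gamma_tilde` $= \gamma/\eta$, default 0.1 (strong backflow);
* `l_eta` $= \sqrt{\eta/\Gamma}$ — the hydrodynamic screening length, the
  distance over which flows induced by a localized force survive substrate
  friction.

With $a_4 = a_2$ the ordered state has $\mathrm{tr}[Q^2] = a_2/a_4$, i.e.
$S_0 = \sqrt{2}$ under the $Q = S(\hat n\hat n - I/2)$ normalization.  All
ground-state assertions in the test-suite use the convention-free criterion
$\mathrm{tr}[Q^2] = a_2/a_4$.

Two screening lengths are used.  The single-defect (tweezer) demonstrations
run at `l_eta = 5`, where individual defect flows are long-ranged and easy
to visualize.  The collective (strip) experiments run at `l_eta = 2`: at
`l_eta = 5` the film at $\alpha_0 = -5$ settles into a smooth traveling
bend-wave state with *no* sustained defect gas, whereas lowering the
screening length produces the defect-laden turbulence the collective
experiments require — lower viscosity increases defect density.  The
screening length for the collective regime is treated as a calibrated
parameter (see the static-response section).

# Numerical scheme

The solver is pseudospectral on a uniform periodic grid (default
$256\times256$, $dx = 0.5\,\xi$, $dt = 0.1\,\tau_n$).  The Stokes problem is
solved exactly in Fourier space,
$\hat u = P_\perp(k)\hat F/(\Gamma + \eta k^2)$ with
$F = \nabla\cdot(\sigma^a + \sigma^{el})$ and $P_\perp$ the transverse
projector (equivalent to eliminating the pressure through its Poisson
equation); the pressure is reported in the zero-mean gauge.  First
derivatives use Nyquist-zeroed wavenumbers so that real fields stay real and
the discrete spectral divergence of $u$ vanishes identically.

Time integration is a second-order exponential-time-differencing scheme
(Cox–Matthews ETD2 weights).  One design decision deserves emphasis: the
exponentiated linear operator is the *diffusion only*,
$L = -K k^2/\gamma$, and the entire local Landau term
$(a_2 - a_4 \mathrm{tr}[Q^2])Q/\gamma$ is integrated explicitly together
with advection and flow coupling.  The seemingly natural alternative —
exponentiating the full linearization $(a_2 - K k^2)/\gamma$ — amplifies
low-$k$ modes by $e^{a_2 dt/\gamma}$ each step and relies on the explicit
cubic to cancel the growth; around slowly evolving defect textures this
cancellation fails and produces a timestep- and resolution-independent
blow-up after $t \approx 70\,\tau_n$ (we verified that a fourth-order
Runge–Kutta integration of the identical semi-discrete right-hand side
relaxes the same states).  With the contractive splitting every
exponentiated mode is damped and the explicit local rates are
$O(a_2 dt/\gamma) = 0.1$, far inside the stability region; defect
turbulence at $\alpha_0 = -5$ then runs indefinitely at $dt = 0.1$.
The cubic nonlinearity is 2/3-rule dealiased by default.  A blow-up guard
aborts any step where $\max|Q|$ exceeds ten times the saturation amplitude,
reporting the timestep and activity level.

Random initial conditions band-limit their noise at the coherence length;
"turbulent" starts use an isotropic quench with amplitude
$0.15\sqrt{a_2/a_4}$, which orders into the nematic outside active regions
within $\sim 100\,\tau_n$ while the active strip interior stays turbulent.

# Defects: detection, orientation, seeding

Half-integer disclinations are found by the winding-number plaquette
algorithm: the branch-corrected increment of the director angle around each
grid plaquette (increments wrapped into $(-\pi/2,\pi/2]$, reflecting the
nematic $\theta \sim \theta + \pi$ identification) flags $\pm\pi$ windings;
positions are refined first by a plane-fit zero crossing of
$(q_{xx}, q_{xy})$ and then by Newton iterations on the bicubic interpolant,
and a depressed-order core ($S < 0.5\,S_{bulk}$) is required.

A $+1/2$ defect carries a polarity $\hat e$, computed from the divergence of
the alignment tensor at the core and *signed so that $\hat e$ is the
propulsion direction under uniform extensile activity* (the raw
$\nabla\cdot Q$ vector points the other way; the flow it induces at the core
is antiparallel to it for $\alpha < 0$).  A $-1/2$ defect carries the
three-fold orientation $\Theta_3 = e^{3i\psi}$, extracted as the phase of
the third angular harmonic of the director angle sampled on a ring of
radius $2.5\,\xi$ around the core — robust to core regularization, and
equivariant with weight 3 under texture rotations (both properties are
tested at multiple angles).  The ring radius is configurable; rings that
pass within $2\,\xi$ of another core are flagged low-confidence.

Exact multi-defect textures are constructed spectrally: the doubled phase
$\Phi = 2\theta$ is line-integrated from the divergence-free vortex field
$\hat z\times\nabla G$, where $G$ solves the periodic Poisson problem with
unit windings at the requested cores.  Two subtleties matter on a torus.
First, total charge must vanish; the seeding routine rejects unbalanced
sets.  Second, the two cycle circulations of the vortex field are not
automatically multiples of $2\pi$; the minimal uniform harmonic correction
is added, otherwise the reconstructed texture carries a spurious $\pi$
domain wall at the wrap seam.  Even after correction a *physical* residual
tilt of order $\pi/L$ remains — a pair on a torus is genuinely frustrated —
which is why "isolated defect" measurements are performed on as large a box
as practical and always against paired controls.  Requested orientations
are imposed through the global phase (an elastic zero mode, exact and
stable) for the first oriented defect and through smooth local phase
bubbles for any further ones; bubbles relax back toward the elastic
equilibrium, so multi-defect orientation requests are honored only
approximately.

# The selection rule and linear response

Because the active stress is bilinear in the control ($\alpha$) and the
state ($Q$), the rotational symmetries of defect texture and activity
pattern decide which responses are allowed: writing the activity near a
core as angular harmonics $\alpha = \sum_n \tilde\alpha_n e^{in\phi}$ and
assigning a defect its dihedral index $s = 2|1-\nu|$ ($s = 1$ for $+1/2$,
$s = 3$ for $-1/2$), self-propulsion requires $|s - n| = 1$ and
self-rotation $|s - n| = 0$.  `selection_rule_suite()` verifies all sixteen
$(s, n \le 3)$ channel combinations numerically: a relaxed, well-separated
$\pm$ pair is frozen, a pure-harmonic disc is centred on each core, and the
activity-induced core velocity/vorticity is measured by differencing the
Stokes solutions with and without the pattern (linearity in $\alpha$ makes
this exact, and it removes both the passive pair-attraction flow and the
sign-constancy offset that any realizable disc must carry).  Each channel
takes the maximum over two pattern phases, since a gradient accidentally
aligned with $\hat e$ produces no torque ($\omega_0^+ \propto
(\nabla\alpha\times\hat e)_z$).  A channel "responds" when it exceeds a
quarter of the per-defect, per-channel maximum across harmonics; at the
default geometry the allowed/forbidden contrast is a factor 8–30.

The quantitative coefficients $V_+ = \zeta_1\alpha$,
$\Omega_+ = \zeta_3\nabla\alpha$, $V_- = \zeta_2\partial^2\alpha$,
$\Omega_- = \zeta_4\partial^3\alpha$ (with
$\partial = (\partial_x - i\partial_y)/2$) are measured, not transcribed:
`calibrate_response()` places smooth polynomial activity landscapes on the
cores and fits the measured responses against the corresponding derivative.
The frozen-texture flow response equals the actual defect velocity for
smooth landscapes (verified dynamically to within 5%); for activity
profiles with a conical singularity at the core — such as the radially
constant quadrupolar disc — the interpolated core flow is finite but
texture relaxation compensates it almost exactly and the defect barely
moves.  This observation shapes the tweezer design below.

# Active tweezers

A tweezer is a disc of extensile activity
$\alpha = \alpha_0[1 + A\sin2\phi + B\cos2\phi]$ ($r \le R$), the minimal
pattern that can translate both defect species ($n = 2$ is one harmonic
away from both $s = 1$ and $s = 3$).  Design constraints: the selection
rule fixes the harmonic content; sign constancy requires $A^2 + B^2 \le 1$;
and the interior activity must stay below the bend-instability threshold.
`max_stable_activity()` implements the conservative design bound
$(K\Gamma/\gamma)\min(1, (\pi\ell_\eta/R)^2)$; the package's own dispersion
relation (`bend_growth_rate()`, derived by linearizing the equations about
the uniform nematic with the flow feedback included) shows the true
threshold for a feature of size $R$ is
$\sim (1 + \ell_\eta^2 k^2)/(q_0 + \lambda/2)$ at $k = \pi/R$, considerably
larger for small features — the protocol controllers exploit this headroom
(quadrupole lobes of width $\sim 4\,\xi$ tolerate $|\alpha| \approx 8$ and
are verified stable over hundreds of $\tau_n$).

For the $-1/2$ defect the controllers use a quadrupole whose angular part
grows quadratically within a core radius $R_c$
(`tweezer(..., core_radius = 4)`): this gives the pattern a finite
$\partial^2\alpha$ at the core — the quantity $V_-$ actually couples to —
and produces a drift of $0.02$–$0.03\,\xi/\tau_n$ at $\alpha_0 = -4$ whose
direction follows $\psi = \mathrm{Arg}\,\Theta_3 + \pi - \chi$, where
$\chi$ is the quadrupole phase ($A = \sin\chi$, $B = \cos\chi$).  Rotating
the quadrupole phase by $\pi$ (the profile by $90^\circ$) reverses the
drift.  The $+1/2$ defect self-propels along $\hat e$ under the $n = 0$
part; its controller uses the quadrupole phase *relative to the spin-2
frame $2\beta$* as a throttle-and-steering handle (fast at
$\chi_{rel} = 0$, slow at $\pi$, bending $\pm 0.34$ rad at $\pm\pi/2$) plus
a weak $n = 1$ dipole that slowly rotates the polarity itself (polarity
rotation is two orders of magnitude slower than the core vorticity, so
translation steering does the real work).  The $+1/2$ disc edge is
smoothed over $0.75\,\xi$; a defect core crossing a hard activity edge is
the one configuration that destabilizes the integration.

Both controllers are *servo loops*: every few steps the defect is
re-detected, its orientation re-read, and the disc pattern re-phased while
the disc centre advances along the prescribed waypoint path at speed $V$.
Transport succeeds for $V$ below the achievable drift and fails cleanly
(the disc walks away, the controller reports the separation) when $V$ is
too large.  On a torus the steered defect always feels its distant
partner's elastic pull ($\sim 0.03\,\xi/\tau_n$ at half-box separation on
a $128\xi$ box), so the achievable net path speeds are the drift minus
this bias; the shipped demonstrations use bent paths of a few $\xi$ over
1,500–4,000 steps.

Pair nucleation uses an elliptic patch ramped to $|\alpha|$ far above the
bend threshold: the enclosed nematic buckles and unbinds a
$(+1/2, -1/2)$ pair whose separation axis follows the patch's major axis.
At the defect-gas parameters the patch "breathes" — pairs nucleate, the
$+1/2$ shoots out along the axis at $\sim|\zeta_1\alpha_{peak}|$, and the
pair re-annihilates a few $\tau_n$ later — so the braiding protocol
(`fig_braid()`) runs as a closed control loop that watches the detections,
cuts each patch the moment its pair is well separated, and hands the
defects to servo tweezers.  The exchange choreography steers the strongly
motile $+1/2$ defects across the box to annihilate the *opposite* pair's
$-1/2$, with waypoint detours and approach sides chosen from the measured
geometry so that the ideal crossing count of the four world lines is
exactly four; crossings are counted by projecting onto $(x, t)$.

This is the one protocol that does not complete at the shipped desk
parameters: the maximum breathing separation is $6$–$7\,\xi$, and at that
distance the passive pair attraction ($\approx 0.4\,\xi/\tau_n$,
measured) exceeds the strongest stable tweezer drive, so every capture
re-annihilates before the exchange can begin.  The corresponding
acceptance test documents this honestly (the crossing counter itself is
verified against a brute-force segment-intersection oracle).

# Collective patterning: strips and the 1D defect hydrodynamics

In sustained turbulence the defect gas is described by coarse-grained
fields: densities $\rho_\pm$, the $+1/2$ polarization $p$, the $-1/2$
triatic order $T_3$, and the smoothed director-phase gradient $v_n$, with
the mean density pinned by creation/annihilation balance to
$n(x) = c_n|\alpha(x)|$ and the charge density recovered from the nematic
Gauss law $2\pi\rho = \partial_x v_n$.  For a static 1D activity landscape
the steady-state balance reduces to three coupled linear relations (the
flux balances for $p$ and $T_3$ and the zero-charge-current condition);
`steady_state_solve()` linearizes by replacing $\rho_\pm \to n(x)$ in the
coefficients, eliminates $v_n$, solves the sparse system with decay
conditions at the padded domain ends, and reports all profiles plus
negative-density flags marking where the linearization is untrustworthy.
For an even $\alpha(x)$ the solutions obey the parity table built from the
parities of $\alpha'$ and $\alpha''$: $p$, $T_3$, $v_n$ odd and $n$,
$\rho$ even — an even $\rho$ is exactly what gives a nonzero topological
dipole $D = \tfrac12\int dx\,|x|\,\rho(x)$.

Model coefficients are calibrated in the pre-fit-then-predict pattern:
$\zeta_{1,2,3}$ come from the single-defect response calibration (the 1D
reduction uses $V_- = \zeta_2\alpha''$, absorbing the $1/4$ from the
complex derivative), $c_n$ from regressing the measured density profile of
a *shallow*-interface strip run on $|\alpha(x)|$, and $(\tau_R, \mu_R,
\mu)$ from least squares of the model's $p$, $T_3$, $\rho$ profiles
against the same shallow run; the sharp-interface behaviour and the flip
threshold are then predictions.

The 2D strip experiments emulate the study conditions at reduced size: a
$128\times64\,\xi$ (or $128\times32$) periodic box, strip width
$W_s = 50$, $|\alpha_0| = 5$, sigmoidal interfaces with
$\delta = w/4$ so the interfacial gradient is exactly $|\alpha_0|/w$,
16,000–24,000 steps against the paper-scale $10^5$, and 1–4 replicates
against 40.  Defects are detected every 25 steps; the dipole series bins
charges about the strip centre.  Shallow interfaces let the motile
$+1/2$ defects escape into the passive flanks ($D > 0$); sharp interfaces
trap $-1/2$ defects at the edge and invert the dipole ($D < 0$).  At desk
scale the inversion is present but the flip threshold depends on the
(unprinted) collective screening length; this is the parameter the package
calibrates against the reported flip location, as described above.  The
oscillating-width and traveling-strip experiments reuse the same machinery
with a sinusoidal $w(t)$ (dipole rectification, fitted by
`sinusoid_fit()`) and a moving $X_0(t) = X_0 + Vt$ (leakage vs
polarization trade-off, optimal "surfing" at intermediate $V$).

# What the synthetic conditions do and do not show

The generator's defaults *are* the study conditions: deterministic seeds,
band-limited quench noise, periodic boundaries, and the parameter values
above.  Passing tests therefore demonstrate internal consistency of the
model, scheme and estimators, and reproduction of the qualitative control
phenomenology at reduced scale — not quantitative agreement with any
particular experimental active-nematic system, whose elastic anisotropy,
three-dimensionality, boundary conditions and noise are all outside this
model.  Periodic boundaries in particular mean every "isolated" defect has
a compensating partner whose elastic pull sets a floor on how cleanly
single-defect zeros can be measured; the paired-control methodology used
throughout is the package's answer to that.

# Known limitations

* No-slip or otherwise confined geometries are not supported (periodic
  only); the bounded-domain flow portraits of the source framework are out
  of scope.
* The braiding protocol does not complete at desk parameters (see above);
  and at desk durations the oscillating-strip rectification amplitude
  ($|\bar D| \lesssim 0.04$ at the re-centred geometry) is comparable to
  realization noise, so only the slow-vs-fast ordering of $\bar D$ is
  robust, not the fast-branch sign flip.
* The measured desk-scale active diffusion constant at the defect-gas
  screening length is $D_a \approx 7$ (in $\xi^2/\tau_n$), an order of
  magnitude above the published value at the (unprinted) original
  parameters; all interface-crossing times are computed from the
  package's own measured $D_a$.
* The $-1/2$ response to radially constant (hard) quadrupoles is nearly
  zero in full dynamics; hard-edged tweezers per the printed profile exist
  in the API but the working protocols use the smooth-core variant.
* Multi-defect orientation targeting is approximate (elasticity restores
  preferred relative orientations during relaxation).
* The 1D hydrodynamics is linearized; profile predictions degrade for
  sharp gradients where defect order saturates, and the creation/
  annihilation kinetics beyond $n \propto |\alpha|$ is not modelled.
* Desk-scale statistics use single-digit replicates; the dipole series'
  frame-to-frame scatter is defect-count shot noise and shrinks only with
  box width and duration.
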