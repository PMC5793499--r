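---
title: "A moving-boundary model of biphasic magnesium corrosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A moving-boundary model of biphasic magnesium corrosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Biodegradable magnesium implants corrode in aqueous and physiological
media in two stages. Water reacts at the metal surface,

$$\mathrm{Mg} + 2\,\mathrm{H_2O} \rightarrow \mathrm{Mg(OH)_2} + \mathrm{H_2},$$

leaving a porous magnesium hydroxide film, which dissolved CO2 (or the
bicarbonate it buffers to) converts into a more stable carbonate shell,

$$\mathrm{Mg(OH)_2} + \mathrm{CO_2} \rightarrow \mathrm{MgCO_3} + \mathrm{H_2O}.$$

`mgcorr` models an ideal 1D pellet (slab, rod or ball; geometry index
$d = 0, 1, 2$) as three concentric zones — metallic core, hydroxide layer,
carbonate layer — separated by sharp reaction fronts at radii
$\alpha(t) \le \beta(t)$, with outer surface $S(t)$. The product layers are
porous media with solid volume fractions $\varepsilon_1, \varepsilon_2$:
the solid crystal phase and the pore fluid move with distinct velocity
fields $v_{s,i}(r)$ and $v_{f,i}(r)$, each of the closed form
$\mathrm{const}/r^d$ fixed by mass conservation and interface
stoichiometry. Water (concentration $W$) and CO2 ($C$) advect with the
fluid and diffuse through both layers; all reactions occur at the
interfaces.

Because each conversion gains volume — the molar density ratios
$\omega_\alpha = \mu_0/\mu_1 \approx 1.78$ (Mg : hydroxide) and
$\omega_\beta = \mu_1/\mu_2 \approx 1.14$ (hydroxide : carbonate) both
exceed 1 — the outer surface moves outward while the fronts recede, and
total magnesium conservation fixes $S$ *algebraically*:

$$S^{d+1} = \omega_\alpha\omega_\beta S_0^{d+1}
  - (\omega_\beta - 1)\beta^{d+1}
  - \omega_\beta(\omega_\alpha - 1)\alpha^{d+1},$$

so the final carbonate block size is known a priori,
$S_\infty = S_0(\omega_\alpha\omega_\beta)^{1/(d+1)}$. The package never
integrates $S$ as an ODE; it always evaluates this conservation form, so
the global magnesium balance holds to round-off by construction (and is
still checked as a runtime invariant, `mg_balance_residual()`).

Lengths are scaled by a reference size $S_0^* = 1$ cm, time by the CO2
diffusion time $S_0^{*2}/D_C$ (about 14.5 h for the default constants),
and concentrations by their ambient values. The dimensionless groups are
the diffusivity ratio $D_W$, the interface flux coefficients
$\gamma_0 = M_W\rho_0/(M_0 W_0^*)$, $\gamma_1 = M_W\rho_1/(M_1 W_0^*)$,
$\gamma_2 = M_C\rho_1/(M_1 C_0^*)$, and the surface reaction rate
$\kappa = S_0^* W_0^* k / D_C$. Because ambient CO2 is three orders of
magnitude more dilute than water, $\gamma_2 \approx 1605 \gg 1$: carbonate
conversion is CO2-supply-limited and much slower than core corrosion,
which is the central timescale separation of the problem.

### Reaction cases and phases

Two kinetic regimes at the metal surface are supported:

* **Case 1** ($\kappa = \infty$): water is consumed instantly,
  $W(\alpha) = 0$, and the front obeys the Stefan condition
  $-(1-\varepsilon_1)D_W\,\partial_r W|_\alpha = 2\gamma_0\dot\alpha$.
  Phases: `P1_1` (core present) then `P1_2` (core gone) until the
  hydroxide is exhausted.
* **Case 2** (finite $\kappa$): the front moves by mass-action kinetics,
  $\gamma_0\dot\alpha = -\kappa W(\alpha)^2$, with the same flux balance
  acting as a Robin condition. Early on the carbonate shell is so thin
  that CO2 reaches the metal immediately and Mg converts directly to
  carbonate at a single joint interface (`P2_1`); once the thickening
  shell starves the interface of CO2 (time $T_{\alpha=\beta}$), a
  hydroxide layer appears and the run proceeds through `P2_2` and `P2_3`.

The three reported timescales are $T_{\alpha=\beta}$ (CO2 first exhausted
at the joint interface, Case 2 only), $T_\alpha$ (core exhausted) and
$T_\beta$ (hydroxide exhausted; corrosion complete).

## Numerical method

Each zone is mapped by the affine front-fixing (Landau) transform onto the
fixed interval $\rho \in [1,2]$; the transformed equations gain the usual
mesh-motion advection term $-\dot r(\rho)\,\partial_r X$. Space is
discretised with central differences on uniform interior nodes (an
optional first-order upwind flag exists for robustness experiments but is
slower and more diffusive). Boundary and interface values are eliminated
algebraically with second-order 3-point one-sided gradient stencils: the
Dirichlet values directly, the Robin/kinetic conditions by solving the
resulting scalar polynomial (written in a cancellation-free normalised
form — important when a zone is thin and the gradient coefficient is
enormous). The ODE state is therefore the interior nodes plus the
interface positions; `deSolve::lsodar` (variable-order stiff BDF with
root-finding) integrates each phase to its terminal event: the
reconstructed interface CO2 value crossing zero (`P2_1`), or an interface
reaching its stopping threshold. Tolerances default to
`rtol = 1e-7`, `atol = 1e-9`.

Two state transformations improve conditioning: in `P2_1` the integrated
variable is the receded depth $S_0 - \beta$ (so finite-difference Jacobian
perturbations scale with the tiny displacement rather than with
$\beta \approx S_0$), and in `P1_2`/`P2_3` it is $\log\beta$ (so implicit
trial steps cannot drive the shrinking hydroxide zone to negative width).
The initial integrator step is set explicitly to
$0.01\,h_{\min}^2/\max(D_W, 1)$, below the fastest diffusive relaxation
of a freshly seeded grid, because the automatic choice based on the
residual norm alone overshoots it.

### Singular start and endgame

The exact initial condition $\alpha = \beta = S = S_0$ is singular, and a
zone much thinner than machine-resolvable cannot be discretised
meaningfully (second differences of a near-ambient profile fall below
double precision). The package therefore brackets the stiff integration
with asymptotic phases whose accuracy is testable:

* **Start (Case 2).** While the carbonate shell is thinner than the
  seeding scale `delta_seed * S0` (default $10^{-5}$), its interior is
  quasi-steady and the joint interface recedes at the kinetic rate,
  $\dot\beta = -\kappa/\gamma_0$ to leading order (corrections are
  $O(\mathrm{slope}\times\mathrm{width}) \lesssim 10^{-6}$). The state is
  advanced in closed form to the seeding width and handed to the
  integrator with the quasi-steady linear profiles implied by the
  interface flux conditions. For fast kinetics the lift is additionally
  capped so the interface CO2 value stays above half ambient. Runs start
  from `tau0 = 1e-8`; results are insensitive to `tau0` across
  $[10^{-9}, 10^{-6}]$ and to `delta_seed` across $[10^{-6}, 10^{-4}]$ at
  the $10^{-4}$ relative level (asserted in the test suite).
* **Start (Case 1).** Both product layers are seeded at thickness
  `delta_seed * S0` with a linear water profile (the quasi-steady shape of
  a thin layer); the same insensitivity checks apply.
* **Transition `P2_1` to `P2_2`.** The new hydroxide layer is seeded at
  `delta_seed * S0` below the joint interface with the pre-transition
  interface water value, and the carbonate grids are re-interpolated onto
  the slightly displaced outer radius.
* **Endgame (`P1_2`/`P2_3`).** As $\beta \to 0$ two things degrade: the
  hydroxide mesh spacing falls towards machine precision, and for
  $d \ge 1$ the quasi-steady CO2 profile develops a boundary layer of
  radial scale $\beta$ that a fixed zone-2 mesh cannot resolve below a few
  spacings. Integration therefore stops at
  $\beta = \max(\texttt{endgame\_width}\,S_0,\ 8 h_2)$ and the remaining
  exhaustion time is obtained by quadrature of the quasi-steady interface
  flux, $\dot\beta = -(1-\varepsilon_2)\,\partial_r C|_\beta/\gamma_2$
  with the exact radial profile and $S$ slaved to $\beta$ by conservation.
  Quasi-steadiness is accurate to $O(1/\gamma_2) \sim 10^{-3}$ here, and
  the handover is cross-checked in the tests: the PDE and the pure
  quadrature agree on the final-phase duration to about 0.1%. The inner
  interface events (`P1_1`/`P2_2`) have no such blow-up and stop at
  `stop_radius` (default $10^{-6} S_0$, truncated-volume error
  $O(\text{stop\_radius}^{d+1})$).

The final reported state sets $\beta = 0$ and $S = S_\infty$ exactly.

### Event handling details

The `P2_1` terminal event is the *downward* crossing of the reconstructed
interface CO2 value; numerical undershoot below zero at the located root
is tolerated at the integrator-accuracy level. Interface rates are clamped
to be non-positive: a transiently inverted discrete gradient (possible
during equilibration of a fresh seed) stalls the front rather than
regrowing the metal.

## Parameters

Dimensional defaults (`mg_physical_params()`) are standard literature
values in cm/g/day units: diffusivities $D_W = 2.85$, $D_C = 1.66$
cm²/day, molecular masses 24.3/58.3/84.3 (Mg, hydroxide, carbonate) and
18/44 (water, CO2) g/mol, layer densities 1.74/2.34/2.96 g/cm³ (inclusive
of void fraction), ambient concentrations $W_0^* = 1$ and
$C_0^* = 0.0011$ g/cm³. The three free parameters — the surface rate $k$
and the solid fractions $\varepsilon_1, \varepsilon_2$ (defaults 0.6 and
0.4) — are the quantities an in vitro calibration would target; $k$ spans
alloy quality, and the $\varepsilon$'s are measurable from CT imaging of
the corrosion layers.

Two deliberate choices deserve a note:

* **Diffusivity ratio.** The tabulated dimensionless set uses
  $D_W = 1.5625$, while the ratio of the tabulated dimensional
  diffusivities is $2.85/1.66 \approx 1.717$. The presets
  (`mg_preset()`) carry the tabulated 1.5625 for comparability with the
  reference simulations; `mg_nondimensionalize()` computes the ratio from
  its actual inputs. Both paths are exercised in the tests.
* **Preset reaction rates.** The worked-example presets carry the
  *unrounded* $\kappa = k/D_C$ implied by the quoted dimensional rates
  ($0.07/1.66 \approx 0.0422$ for the cylindrical finite-rate example,
  $0.5/1.66 \approx 0.301$ for the size sweeps) rather than their rounded
  one-significant-figure displays (0.04, 0.3). A quasi-steady analysis of
  the joint-interface phase shows the reference timescales correspond to
  the unrounded values: $T_{\alpha=\beta}$ scales as $\kappa^{-2}$, and
  with $\kappa = 0.0422$ the computed 0.0985/32.95 match the reference
  0.095/33.1 closely, while exactly 0.04 would give 0.1095/34.6.

The advection-mode switch (`advection_mode` in `mg_solver_config()`)
reruns the identical configuration with the reactant advective velocity
set to the pore-fluid velocity (the native porous-media model), zero, or
the solid-phase velocity; the interface balances use the generic
moving-frame flux $(1-\varepsilon)[(V - \dot c)X - D\partial_r X]$, which
reduces exactly to the native conditions under no-slip. Because the
conversions gain volume, the fluid drifts inward and the solid outward,
so core exhaustion is fastest under fluid advection and slowest under
solid advection, while the long-time behaviour and the final size are
insensitive to the choice.

## Problem sizes and test design

Default production meshes are $n_1 = n_2 = 200$ interior nodes per zone
(the cylindrical finite-rate run takes on the order of a minute); the test
suite uses 40–100 nodes per zone, where the transition times are already
converged to well under 1% (a mesh-doubling check from 100 to 200 nodes is
part of the suite), and the sweep-based scaling checks use 40 nodes.
Trajectory output is log-spaced in time because the dynamics span ten
decades.

What passing tests do and do not show: the suite verifies internal
consistency (conservation, monotonicity, orderings, mesh and seeding
insensitivity, agreement with closed forms and with an independent
quasi-steady quadrature) and reproduction of the reference timescales
within the stated bands. It does not validate the model against laboratory
corrosion data; the sharp-interface, smooth-surface, constant-pH
assumptions exclude pitting, cracking, chloride chemistry, hydrogen gas
pockets and carbonate dissolution, all of which matter in vivo. The
model's geometry is strictly 1D.

## Known limitations

* The joint-interface start and the endgame are asymptotic, not resolved:
  sub-`delta_seed` shell dynamics and sub-`endgame_width` hydroxide
  remnants are represented by their leading-order closed forms. Both
  windows contribute $\lesssim 10^{-3}$ of the corresponding phase
  durations with the default settings.
* Hydroxide-exhaustion times computed here sit about 12% below the
  reference values for the cylindrical finite-rate configuration, while
  agreeing to 0.1% with the independent quasi-steady quadrature of the
  same equations; the difference is attributed to the reference's own
  numerical treatment, whose small-time asymptotics are not available to
  reproduce verbatim.
* Very large $\kappa$ with very fine meshes pushes the CO2-exhaustion
  event below the resolvable shell width; the lift cap handles the
  defaults and the documented sweep ranges, but $\kappa \gtrsim 10^3$ is
  outside the tested envelope (use Case 1 there instead, which it
  approaches).
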