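---
title: "Methods: peristaltic transport of a variable-viscosity Carreau fluid in a flexible annulus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peristaltic Carreau transport in a flexible annulus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The physical problem

The package models axisymmetric flow in the gap between a rigid inner
cylinder (a catheter or endoscope shaft, dimensionless radius
$\varepsilon$) and a flexible outer wall that carries a travelling
sinusoidal wave,
$$ r_2(z,t) = 1 + \varphi\,\sin\!\big(2\pi(z-t)\big), $$
with lengths scaled on the mean outer radius, the axial coordinate on the
wavelength and time on the wave period. The fluid is an incompressible
Carreau (shear-thinning) liquid whose viscosity also depends on
temperature through the Reynolds law $\mu \propto e^{-\alpha H}$,
truncated for small $\alpha$ to $M(H) = 1 - \alpha H$. Heat and solute
transport are coupled: a temperature gradient drives a solute flux (Soret
effect), and both fields feed back on the momentum balance through
thermal and solutal buoyancy (Grashof numbers $G_1$, $G_2$).

Two standard lubrication-type assumptions reduce the problem: the
wavelength is long compared with the gap and the Reynolds number is
small. Radial momentum, axial diffusion and all inertial terms then drop,
and every axial station $(z, t)$ becomes an independent one-dimensional
boundary-value problem in the radius $r \in [\varepsilon, h]$,
$h = r_2(z,t)$. There is no time stepping anywhere in the package; $z$
and $t$ are labels of quasi-static sections.

## The elastic wall replaces the pressure gradient

The outer wall is a stretched membrane with flexural stiffness, axial
tension, inertia, viscous damping and an elastic bed. Its equation of
motion eliminates the axial pressure gradient in favour of a fifth-order
operator acting on the known wall shape:
$$ E(z,t) = \Big( e_1\partial_z^5 - e_2\partial_z^3 +
   e_3\partial_z\partial_t^2 + e_4\partial_z\partial_t +
   e_5\partial_z \Big) r_2 . $$
For the single-harmonic wall this evaluates in closed form: with
$\theta = 2\pi(z-t)$ and $k = 2\pi$,
$$ E = \varphi\big[(k^5 e_1 + k^3 e_2 - k^3 e_3 + k\,e_5)\cos\theta
     + k^2 e_4 \sin\theta\big]. $$
`wall_forcing()` implements this closed form; the only finite differences
in the package live in the test suite, where a sixth-order
finite-difference application of the operator to $r_2$ serves as an
independent oracle for the formula.

Two consequences of this closed form shape several design choices below:

* the $\cos\theta$ component, which carries the stiffness, tension, mass
  and spring coefficients, is amplified by $k^5 = (2\pi)^5 \approx 9.8
  \times 10^3$, so at the reference wall coefficients the forcing is
  large ($|E| \approx 450$ at its extremes);
* at the wave crest and trough ($\theta = \pi/2, 3\pi/2$) the
  $\cos\theta$ component vanishes identically, so there the coefficients
  $e_1, e_2, e_3, e_5$ have **no** effect on the flow at all.

One note on naming: the source formulation defines the damping and
spring-stiffness groups under the same symbol; the package assigns
viscous damping to `e4` and spring stiffness to `e5`, following their
positions in the operator.

## Scalar fields in closed form

The temperature obeys a modified-Helmholtz equation,
$$ \beta\Big(H'' + \tfrac{1}{r}H'\Big) = \Omega H, \qquad
   \beta = \frac{1}{Pr} + \frac{4}{3 Rn}, \qquad
   H(\varepsilon) = 0, \; H(h) = 1 , $$
solved with real modified Bessel functions,
$$ H(r) = \frac{I_0(Ar)K_0(A\varepsilon) - I_0(A\varepsilon)K_0(Ar)}
               {I_0(Ah)K_0(A\varepsilon) - I_0(A\varepsilon)K_0(Ah)},
   \qquad A = \sqrt{\Omega/\beta}, $$
with the exact log-profile limit $H = \ln(r/\varepsilon)/\ln(h/\varepsilon)$
at $\Omega = 0$. The implementation uses exponentially scaled Bessel
evaluations so the form remains stable for large $A$. The decay constant
is taken as $\sqrt{\Omega/\beta}$ — the only reading consistent with the
dimensions of the equation. Derivatives are analytic (`d1` from the
Bessel recurrences, `d2` from the equation itself), because they feed the
velocity forcing and must be smooth.

The concentration satisfies
$(1/S_2)\nabla_r^2\xi + S_1 \nabla_r^2 H = 0$ with
$\xi(\varepsilon) = 1$, $\xi(h) = 0$. Since $\xi + S_1 S_2 H$ is
radially harmonic,
$$ \xi(r) = c_{\log} \ln r + c_{\mathrm{const}} - S_1 S_2 H(r), \qquad
   c_{\log} = \frac{S_1 S_2 - 1}{\ln(h/\varepsilon)}, \quad
   c_{\mathrm{const}} = 1 - c_{\log}\ln\varepsilon . $$
Both fields are verified in the tests by interior residuals at
$10^{-8}$, by a finite-difference two-point boundary-value oracle
(Richardson-extrapolated, kept in its truncation-dominated resolution
range), and by the analytic limits above.

## The double perturbation expansion

With $M(H) = 1-\alpha H$ and $\kappa = (n-1)/2$ the reduced momentum
balance is the flux form
$$ \frac{1}{r}\frac{d}{dr}\Big[\, r\,M(H)\big(u' + \kappa We^2 u'^3\big)\Big]
   = F_0(r) \equiv E - G_1 H - G_2 \xi . $$
Expanding twice, $u_3 = (u_{300} + \alpha u_{301}) +
We^2 (u_{310} + \alpha u_{311})$, and collecting orders *in the flux*
gives, per order, one quadrature plus one affine constant ($v_k$ denotes
the order's shear $u'$, $G(r)=\int_\varepsilon^r s F_0\,ds$):

| order | shear |
|---|---|
| $1$ | $v_0 = G/r + C_0/r$ |
| $\alpha$ | $v_1 = H v_0 + C_1/r$ |
| $We^2$ | $v_2 = -\kappa v_0^3 + C_2/r$ |
| $We^2\alpha$ | $v_3 = H v_2 - 3\kappa v_0^2 v_1 + \kappa H v_0^3 + C_3/r$ |

Each constant is fixed by the outer-wall condition ($u_{300} = -1$ at
both walls; the corrections vanish at both walls), which reduces to one
division by the quadrature of $1/r$ over the gap. Working in the flux
form avoids discretising any second derivative: the solution is exact up
to quadrature error. The printed first-order systems in the source are
typographically inconsistent; the expansion of the flux balance itself is
the authority, and the nonlinear reference solver (below) confirms the
hierarchy to its truncation order.

`n = 1` or `We = 0` makes the Weissenberg orders identically zero (their
particular parts vanish and the boundary conditions kill the homogeneous
$C/r$ part); `alpha = 0` removes the $\alpha$-orders from the assembly.
The lab-frame profile is $w = u_3 + 1$ (wave-frame wall condition
$u_3 = -1$ maps to no-slip $w = 0$).

## Numerical choices

* **Grid.** 257 radial nodes per section by default, uniform from
  $\varepsilon$ to $h$; any strictly increasing grid is accepted.
* **Quadrature.** A fourth-order cumulative Newton–Cotes rule: each cell
  integrates the cubic Lagrange interpolant through the four nearest
  nodes (one-sided at the ends). Weights are precomputed per grid. The
  rule is exact for cubics, $O(h^4)$ on smooth data, and works on
  non-uniform grids; the tests confirm the order by Richardson
  refinement.
* **Outer-wall constants.** The divisor $\ln(h/\varepsilon)$ in each
  $C_k$ is evaluated with the same quadrature as the numerators, so the
  wall conditions hold to rounding rather than to quadrature accuracy.
* **Scaled Bessel functions** guard against overflow at large decay
  constants.
* **Stream function.** $\psi(r,z) = \int_\varepsilon^r s\,u_3\,ds$ with
  the gauge $\psi = 0$ on the catheter; the mesh is boundary-fitted via
  $\eta = (r - \varepsilon)/(h(z)-\varepsilon)$ so that marching squares
  operates on a rectangle. Contour levels: 21 evenly spaced values
  strictly between the field extrema; closed polylines are measured by
  the shoelace formula in the physical $(z, r)$ plane.

## The nonlinear reference solver

The validation oracle solves the *unexpanded* flux balance: the flux
$r M (u' + \kappa We^2 u'^3) = G(r) + C$ is inverted pointwise for $u'$
(bisection on the guaranteed bracket of the monotone branch, Newton
polish), $u$ is recovered by quadrature from $u(\varepsilon) = -1$, and
the single constant $C$ is found by a safeguarded scalar root solve so
that $u(h) = -1$ to $10^{-10}$. For shear thinning ($n < 1$,
$\kappa < 0$) the constitutive map folds at
$|u'| = 1/\sqrt{-3\kappa We^2}$; if the required flux exceeds the fold
anywhere the solver reports the radius and stops — the fold is a genuine
validity boundary of the constitutive law, not a numerical artefact. At
the reference configuration the strongly forced sections are beyond the
fold at $We = 0.2$, so oracle comparisons and the convergence study run
at the wave crest, where the forcing is moderate and the whole ladder
($We \le 0.1$, $\alpha \le 0.05$) stays far from the fold.

The oracle shares only the forcing quadrature with the perturbation
module; the solution paths are otherwise disjoint. The measured
max-norm gap between the two scales with fitted log–log slopes close to
4 in $We$ (at $\alpha = 0$) and 2 in $\alpha$ (at $We = 0$), which is
the defining property of the expansion's remainder; the acceptance
tests pin these slopes to $4 \pm 0.7$ and $2 \pm 0.4$.

## Choice of reporting section

The sections $z - t = 0.25$ (crest) and $0.75$ (trough) are natural
landmarks but degenerate for this model: the $\cos\theta$ part of the
wall forcing vanishes there, leaving only the damping term
($E = \pm\varphi k^2 e_4$), and at the reference configuration the crest
profile is a shallow *negative* trough in the lab frame. The
characteristic profile described for this flow — single-peaked,
downward-concave, zero at both walls, with its maximum nearer the
catheter — develops where the elastic forcing is active and negative.
The package therefore reports profiles at $z - t = 0.5$ by default: the
wall sits at its mean radius and $|E|$ is essentially maximal there for
the reference coefficients. At that section the computed peak of
$w$ sits near $r \approx 0.36$ on a 2049-node grid — close to the
catheter side of the gap, consistent with the qualitative description of
the flow, and reproduced by `scripts/acceptance.R` at run time. Boundary
values and scalar-field targets are section-independent and are checked
at the crest as well.

## Trapped boluses and a known degeneracy

Because the long-wavelength model with the wall-eliminated pressure
solves every section independently, the gap flux
$Q(z) = \int_\varepsilon^h r\,u_3\,dr$ is *not* constant in $z$ (there is
no global mass-conservation constraint linking sections). The stream
function's extrema therefore sit essentially on the outer wall wherever
the forcing is strong, and level curves terminate on the wall instead of
closing. At the reference configuration the closed-contour set under the
default 21-level ladder is empty — the recirculation is wall-attached,
with a closure window narrower than $10^{-5}$ of the $\psi$ range — and
the bolus-area monotonicity checks hold in their non-strict form with
all areas zero. Interior closed streamlines do exist in a
transitional-forcing regime (wall coefficients roughly twenty times
softer), and that regime, with a denser level ladder, is what the unit
tests use to exercise the extraction machinery non-trivially. Users
studying trapping should treat the bolus summary as a diagnostic of this
specific reduced model rather than of mass-conserving peristalsis.

## Validity and limitations

* The expansion needs $We^2 |u'|^3$-type corrections small against
  $|u'|$; the oracle's fold check is the operational validity bound. At
  the reference configuration the assembled profile at strongly forced
  sections is dominated by the $We^2$ orders (lab-frame peak
  $\sim 1.5\times 10^4$), i.e. the series is used there as the model's
  defining formula, as in the source analysis, not as a converged
  asymptotic answer. All quantitative validation (residuals, oracle
  gaps, slopes) is done in regimes where the expansion is demonstrably
  convergent.
* $\alpha < 1$ is required by the truncation of the viscosity law; the
  exponential law is available in the oracle and differs from the
  truncated law at $O(\alpha^2)$, which the tests verify.
* The model carries no pressure field, no axial coupling, no inertia and
  no transient term; none of these can be recovered from this package's
  outputs.
* There is no external data anywhere: every input is a dimensionless
  parameter set, and all test fixtures are generated in code.

## Problem sizes used by the checks

The shipped tests and the acceptance script use 257-node radial grids
(2049 for locating the velocity peak), stream-function meshes of
$49\times 97$ to $65 \times 129$, finite-difference oracles of up to
$6\,144$ cells, and oracle ladders of three values per expansion
parameter. A full test run solves a few hundred sections; all checks are
deterministic.
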