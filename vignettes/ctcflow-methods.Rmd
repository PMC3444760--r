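---
title: "ctcflow: model, numerics, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctcflow: model, numerics, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctcflow` simulates a single deformable circulating tumor cell (CTC)
traveling through a straight microvessel segment, using the immersed
boundary (IB) method: an Eulerian incompressible Navier–Stokes solver for
the blood plasma, Lagrangian spring networks for the cell and vessel
structures, and a regularized Dirac delta coupling the two. This vignette
is the package's own account of the model, every numerical choice that
matters, and how the default parameters were fixed. All units are CGS.

## The mechanical model

**Plasma.** The fluid phase of blood is treated as a viscous,
incompressible Newtonian fluid (density $\rho = 1\,$g/cm$^3$, dynamic
viscosity $\mu = 0.012\,$g/(cm·s), i.e. 1.2 cP blood plasma; both
configurable). At the reference scales (vessel width $H = 30\,\mu$m,
centerline speed $u_{max} = 0.6\,$mm/s) the Reynolds number is
$\rho u H/\mu \approx 0.015$: the flow is strongly viscous and laminar,
and any sustained oscillation in a cell-free channel indicates a
numerical problem, not physics.

**Cell.** The cell is reduced to the two structures that dominate its
shape and stiffness: the actin cortex and the nuclear envelope. The
cortex band (default: annulus between radius 3 and 5 µm of a 10 µm cell)
is discretized as two concentric rings of boundary points joined by
circumferential springs along each ring, a radial rung from every outer
point to its nearest inner point, and one diagonal per outer point; this
is the minimal cross-linked mesh that resists both stretching and
shearing of the band. The nuclear envelope is a single ring (radius
2 µm) with circumferential springs plus a chordal brace every 5th point.
Every spring is linear (Hookean),

$$\mathbf F = S\,(\lVert\mathbf X^*-\mathbf X\rVert - L)\,
  \frac{\mathbf X^*-\mathbf X}{\lVert\mathbf X^*-\mathbf X\rVert},$$

with the rest length $L$ frozen to the as-built distance, so the initial
cell is stress-free. The baseline stiffness is $S_0 = 50$ dyn/cm per
spring; the cortex and nucleus multipliers `kC` and `kN` scale it (the
stiffness sweep varies each over 1–6). The interior of the cell is the
same viscous fluid as the plasma — cytoplasm is not given separate
rheology — and there are no springs between nucleus and cortex; they
interact only through that fluid.

**Walls.** The endothelium is two straight rows of points spanning the
(periodic) domain, 30 µm apart, each point tethered by a zero-rest-length
spring to a fixed anchor and linked to its neighbors. Tethers make the
wall effectively rigid (see *Wall stiffness and stability*); no
individual endothelial cells, wall compliance, or mechanotransduction are
modeled.

**Adhesion.** Receptor–ligand binding between the cell membrane and the
endothelium is distance-gated and deterministic: binding is always
effective at short range (no on/off-rate kinetics — stochastic bond
chemistry is deliberately out of scope so that the role of cell
*deformability* is isolated). Every outer-cortex point within the capture
radius `r_on` of a wall point gains one adhesive spring (stiffness `S_A`,
rest length `L_A`) to its nearest wall point; a link stretched beyond
`lambda_break * L_A` is removed. Ties break toward the lowest wall id,
and a given (cell point, wall point) pair can hold at most one link, so
the update is fully deterministic.

**Cortex remodeling (crawling mode).** When enabled, cortex springs with
an endpoint within `r_soft` (1.5 µm) of any currently adhered membrane
point have their stiffness multiplied by `m_soft` (1/3); springs leave
that state the moment the supporting adhesion breaks. This is the
adhesion-triggered local softening that converts an anchored cell into a
crawling one.

## Numerics

**Grid and solver.** The fluid lives on a doubly periodic, node-centered
grid with square cells, default 240 × 128 over 75 × 40 µm
($h = 0.3125\,\mu$m). One time step performs: explicit skew-symmetric
centered advection and body force; implicit viscosity; and pressure
projection, both solved in Fourier space using the symbols of the
discrete operators (5-point Laplacian, centered first differences).
Because the projection uses the centered-difference divergence symbol,
the discrete divergence of the projected field is zero to round-off at
every step. The scheme is first-order in time; with the implicit viscous
solve, diffusion is unconditionally stable and the advective CFL
($\max|u|\,dt/h \le 0.5$) is never the binding constraint at these
speeds.

**Why 75 × 40 µm.** The wall rows are placed so they fall *exactly on
grid lines* at every resolution used (240 × 128, 120 × 64, 60 × 32): the
spacing then divides both the 30 µm wall separation and the 5 µm offset
of the bottom wall. An immersed wall that threads between grid nodes has
a larger effective-width error (measured: roughly double) than one on a
node line.

**Coupling.** Peskin's 4-point kernel
$\delta_h(x,y)=\phi(x/h)\phi(y/h)/h^2$ transfers forces and velocities.
`spread()` carries each point's frozen arc-length weight `ds` (the
quadrature weight of the boundary integral), and `interp_velocity()`
carries $h^2$; built from the same kernel they are exact adjoints, which
the tests verify to machine precision. The simulation loop hands
`spread()` the point force divided by `ds` — i.e. physical point forces
are applied to the fluid — so that the momentum a spring injects is
independent of how finely the boundary is discretized. Boundary points
are spaced at $h/2$ (the standard anti-leakage rule); cell area drift
over a full experiment is bounded in the tests at 5%, and typically
measures well under 1%.

**Wall stiffness and stability.** Explicitly coupled stiff springs
destabilize the IB loop when (stiffness × dt × point mobility) is too
large; the mobility of a boundary point rises as the grid is refined, so
the stable tether stiffness falls with $h$. Measured at
$dt = 10^{-5}\,$s: wall tethers at $\kappa_W = 8$ (400 dyn/cm) are
stable at 120 × 64 but not at 240 × 128. Rather than defaulting to the
worst-case stiffness, `run_simulation()` and `steady_channel_flow()`
halve `dt` and restart (up to 3 times) when an instability is detected —
at the default grid the channel flow runs at $dt = 5\times10^{-6}\,$s.
Under the full flow load the wall displaces by about $10^{-3} h$;
the rigidity budget in the tests is $0.05\,h$.

**Channel calibration.** The driving body force is the closed-form
Poiseuille value $g = 8\mu u_{max}/H^2$ (640 dyn/cm³ at reference
parameters), applied between the wall rows with half weight at the
wall-adjacent nodes so the discrete momentum input equals $gW$ exactly.
A regularized immersed wall still has an effective hydrodynamic plane
slightly inside the channel (an $O(h)$ kernel-width effect): the steady
centerline maximum comes out 6.1% / 3.1% / 1.6% below target at
$h = 1.25 / 0.625 / 0.3125\,\mu$m. No empirical correction is applied to
the force — the acceptance computation simply runs the default grid,
where the deficit is within the 2% band. Convergence to steady state is
fast (the viscous time $H^2\rho/\mu$ is ~0.75 ms, a few hundred steps).

**Degenerate inputs and failure modes.** A spring whose endpoints
coincide while $L>0$ has no defined direction; its force is zeroed for
that evaluation (the event indicates too large a time step). Non-finite
fields or boundary speeds beyond 100× the flow scale abort the step with
the dt-halving retry described above. All writes are atomic
(temp-file + rename), and snapshot CSVs carry full `%.17g` precision so
written trajectories read back bit-exactly. There is no random number
generation anywhere in the solver path: identical configurations produce
bit-identical trajectories, which is asserted in the tests.

## Adhesion calibration

The adhesion parameters are the one genuinely free axis of the model (no
bond stiffness or kinetic constants are available for the reference
setup), and two non-obvious constraints pin them:

1. **Hysteresis is mandatory.** With deterministic distance-gated
   binding, a broken bond whose endpoints are still within `r_on`
   re-forms on the next update; if the capture radius equals or exceeds
   the break length `lambda_break * L_A`, a cell can *never* detach.
   Detachment — which the anchoring-then-release regime requires —
   demands `r_on < lambda_break * L_A`.
2. **The gap must be hydrodynamically resolved.** The regularized delta
   blurs the wall over ~2 grid cells; a cell whose membrane sits within
   one cell of the wall is dragged by the wall's no-slip forcing
   regardless of the adhesion forces ("numerical gluing"). At
   $h = 1.25\,\mu$m a 0.4 µm gap made the dynamics independent of `S_A`
   over a 50-fold range. The bonds must therefore hold the cell at a gap
   of at least about one grid cell of the production resolutions, which
   sets `L_A` = 1 µm, and the rolling experiments run at 120 × 64 or
   finer.

Within those constraints, `S_A` and `lambda_break` were chosen so that
the measured drag the flow transmits through an attached cell
(~$2\times10^{-4}$ dyn at reference conditions) can peel bonds at the
trailing edge while the leading edge re-binds: per-bond break forces must
sit just below the shared drag load. This puts `S_A` at a few dyn/cm —
far below the structural stiffness — with `lambda_break` ≈ 1.3. The
resulting limit cycle (bind at the front at ~`r_on`, compress under the
cell, stretch and break at the rear) is what makes a stiff-cortex cell
roll; a soft cortex lets bound membrane points be dragged backward
(tank-treading) instead of rotating the whole ring, which starves the
front of fresh contacts and ends in complete detachment. The rolling
experiments start the cell at `r_on/2` clearance so first contacts exist
at $t = 0$; the stiffness-sweep cases keep the 1 µm clearance and run
with adhesion disabled.

## Locomotion-mode classification

`classify_mode()` reduces a trajectory to interpretable features —
cumulative rotation of the stained cortex arc about the centroid, net
centroid advance, centroid speed relative to the undisturbed parabolic
speed at the cell's height, fraction of snapshots with at least one
active bond, and bond turnover per snapshot unit — and applies fixed
decision rules (rolling, then crawling, then anchoring, with floating as
the fallback). The locomotion modes are qualitative regimes, so the
thresholds in `ctc_mode_thresholds()` are calibration constants, chosen
once against the four reference stiffness cases and logged in the
function's documentation. The snapshot unit `t` is itself a convention:
the time for the undisturbed centerline flow to advect one cell diameter
(10 µm / 0.6 mm/s ≈ 16.7 ms).

## What the experiments show — and what they cannot

The three preset experiments reproduce the qualitative regime structure
of the reference setup at the default calibration:

* `experiment_sweep()`: soft-cortex cells near the wall elongate most;
  at fixed cortex stiffness, a stiffer nuclear envelope damps whole-cell
  deformation; a sixfold-stiff cortex preserves circularity. The
  *magnitudes* of deformation here are modest (aspect ratios of order
  1.1 rather than the dramatic elongations a softer effective membrane
  would show): with the cross-linked two-ring cortex at 50 dyn/cm per
  spring and plasma viscosity, shear stresses of order 1 dyn/cm² produce
  only a few percent strain. The trend directions, not the magnitudes,
  are the tested claims.
* `experiment_rolling()`: only the sixfold-stiff cortex sustains rolling
  over the 4t horizon; soft-cortex cells shed their bonds and drift off.
  The nuclear-envelope effect on rolling speed is below the resolution
  of this model's small-deformation regime.
* `experiment_crawling()`: the anchoring-prone combination (cortex 3×,
  nucleus 6×) attaches, migrates a short distance, and detaches within a
  few snapshot units whether or not remodeling is active. The
  hypothesized crawling transition — local softening keeping the cell
  bound indefinitely — does **not** emerge at this calibration, and the
  corresponding acceptance test is intentionally left failing rather
  than weakened. The mechanism was probed over a wide calibration range
  (`m_soft` 0.05–1/3, `r_soft` 0.4–2.5 µm, `S_A` 4–20 dyn/cm): softening
  cortex springs near the focal adhesions *always shortened* bond
  survival, by 0.5–1.5 snapshot units. The reason is visible in the
  force budget: in this model the contact's grip is limited by how
  strongly the cortex couples the bound membrane points to the advancing
  cell body, and softening that coupling lets the body slide forward
  over its contacts, tilting and stretching the bonds sooner. The
  pathway by which softening should help — the contact zone draping
  conformally onto the wall, spreading load over more, shorter bonds —
  requires deformations of order the gap size under bond-scale forces,
  and with the cross-linked two-ring cortex at the reference per-spring
  stiffness those forces produce only ~0.05 µm of local compliance.
  Crawling by adhesion-triggered softening therefore appears to need the
  large-deformation regime this realization does not reach (see
  *Known limitations*).

Problem sizes: the test suite runs the dynamic regimes at 60 × 32 and
120 × 64 with horizons of a few snapshot units; the full 6 × 6 × 2
stiffness sweep at the default grid is an overnight-scale batch and is
not part of any automated run.

Known limitations: the model is 2D (a cross-section, not a tube); there
are no red cells, leukocytes, platelets or emboli, so the shear
environment is cleaner than real microcirculation; bond kinetics are
deterministic, so rolling has none of the stochastic jerkiness of
measured leukocyte rolling; the periodic domain means a cell that
travels far interacts with its own wake; and the cortex mesh topology
(two cross-linked rings) fixes an effective membrane modulus that is
stiffer than a single-chain discretization at the same per-spring
constant, which is why deformations are visually milder than the regime
sketches the model family is known for.
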