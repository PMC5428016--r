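---
title: "Physical models behind the microfluidic sample trap design rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical models behind the microfluidic sample trap design rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstdesign)
```

Microfluidic sample traps (MSTs) are wells, recesses or chambers adjacent
to a channel that individually capture submicroliter 3D tissue samples —
single cells, spheroids, micro-dissected tissue — and keep them alive for
culture and assay. Four physical constraints govern whether a trap design
works: the sample must settle into the trap in reasonable time; applied
flow must be able to eject it *before* shear stress damages it; the tissue
core must stay oxygenated; and the finite nutrients in the loaded medium
must outlast the replenishment schedule. This vignette describes the models
`mstdesign` implements for each constraint, the choices made where the
design was genuinely open, and what the numerical defaults do and do not
capture.

## Sedimentation trapping

A spherical tissue of diameter $d$ and density $\rho_T$ settles in medium
of density $\rho_M$ and viscosity $\eta$ under the volume force
$F_V = (\rho_T - \rho_M) V_T \, g_{\mathrm{eff}}$. Unbounded, it reaches
the Stokes velocity

$$v_{\mathrm{Stokes}} = \frac{1}{18}\frac{\rho_T - \rho_M}{\eta}\, g_{\mathrm{eff}}\, d^2 .$$

Confinement in a trap of width $w$ comparable to $d$ increases drag by the
wall-correction factor

$$K(\lambda) = \frac{1 - 0.76\lambda^5}{1 - 2.1\lambda + 2.1\lambda^3 - 1.7\lambda^5 + 0.73\lambda^6},
\qquad \lambda = d/w,$$

the classical polynomial approximation for a sphere settling along the axis
of a long cylindrical conduit. The confined settling velocity is
$v_{\mathrm{set}} = v_{\mathrm{Stokes}} / K(\lambda)$ and the settling time
over the trap depth is $t = h / v_{\mathrm{set}}$.

Two numerical notes. First, the polynomial is a *drag enhancement* factor:
$K(0) = 1$ and $K$ grows steeply with confinement, so dividing by it slows
settling — consistent with the physics (drag increases with confinement),
which is why the package divides rather than multiplies by the bracketed
fraction. Second, the fit is only trusted for $\lambda < 0.9$;
`wall_correction_factor()` errors hard beyond that, and the fit is
non-monotone above $\lambda \approx 0.83$, a fit artifact near its validity
edge that no default workflow reaches. Bottom-wall retardation is
neglected, so computed settling times are upper bounds.

For a square trap with $w = h$ and a given tissue, the settling time is
proportional to $K(\lambda)/\lambda^2$. The minimizer,

```{r}
optimal_trap_ratio()
```

is a pure number — independent of scale, density contrast and viscosity —
and sits comfortably inside the $0.3 < d/w < 0.7$ band within which
settling stays near-minimal. That is the origin of the $w \approx 2d$
design rule.

## The operating window: ejection before damage

Applied channel flow does two things to a trapped tissue: above
$Q_{\mathrm{lift}}$ it ejects a non-adherent sample, and above
$Q_{\mathrm{shear}}$ it subjects the sample to shear stress beyond the
damage threshold $\tau_{\max}$ (1 Pa by default, a conservative
physiological level). For a cubic trap ($h = w$) holding a tissue with
$d/w = 0.5$:

$$Q_{\mathrm{shear}} = \frac{\tau_{\max}}{9.6\,\eta} w^3,
\qquad
Q_{\mathrm{lift}} = \sqrt{d}\, w^2 \sqrt{\tfrac{4}{3} g_{\mathrm{eff}}
\left(\tfrac{\rho_T}{\rho_M} - 1\right)} .$$

The 9.6 is a fitted hydraulic constant for this geometry; the package uses
it as given and warns when the formulas are applied to clearly non-cubic
traps. A healthy design has $Q_{\mathrm{lift}} < Q_{\mathrm{shear}}$ so
tissues can be flushed out unharmed; `operating_window()` computes both and
`classify_flow()` places any applied flow rate into `trapped_safe`,
`ejected_safe` or `damaging` (boundaries: the lift threshold itself already
ejects; the shear threshold itself already damages).

Because $Q_{\mathrm{shear}} \propto w^3$ falls faster than
$Q_{\mathrm{lift}} \propto w^2$ as a device is scaled down, the two curves
cross at the minimum trap width

$$w_{\min} = 61\, \frac{g_{\mathrm{eff}}\, \eta^2}{\tau_{\max}^2}
\left(\frac{\rho_T}{\rho_M} - 1\right),$$

about 12 µm for a 2% density excess in water. Below $w_{\min}$, flow
damages tissues before it can eject them — such devices must be unloaded
mechanically. The conventional coefficient 61 is the rounded value of the
exact crossing coefficient $9.6^2 \cdot 2/3 = 61.44$;
`minimum_trap_width(exact = TRUE)` returns the unrounded crossing, which
the test suite verifies against a bisection of
$Q_{\mathrm{shear}}(w) - Q_{\mathrm{lift}}(w)$ to machine precision.

The admissible *ranges* around the optimum ($1.1d < w < 3.3d$,
$0.6w < h < 1.1w$, $1.2d < w < 6.7d$ for settling, $w \le 1.4d$ for
guaranteed single-sample trapping) derive from full 3D hydrodynamic sweeps
rather than from these closed forms; `check_design()` encodes them as rule
constants and recomputes the analytically available rules live.

## Oxygen: the anoxia diameter

Oxygen reaches the tissue continuously through gas-permeable device walls
(PDMS passes oxygen more readily than water), so its worst case is an
oxygen-consuming sphere in effectively unbounded aqueous medium. Balancing
maximum uptake $q_{\max}\rho_{\mathrm{cell}}$ against the series
diffusion–solubility resistances of tissue and medium gives the maximum
viable diameter

$$d_{\max} = 2\sqrt{\frac{3}{q_{\max}\rho_{\mathrm{cell}}}
\left(\frac{1}{2 D_T c_{T,\mathrm{sat}}} + \frac{1}{D_M c_{M,\mathrm{sat}}}\right)^{-1}}
\approx 500\ \mu\mathrm{m}$$

for the typical (EMT6/Ro) oxygen parameters. Tissues above $d_{\max}$ will
develop anoxic cores regardless of trap design; `recommend_design()` warns.
Bonding the device to glass blocks the oxygen path through the floor and
substantially degrades supply; that 3D conjugate-diffusion effect is outside
this package's analytic scope, which is why the anoxia criterion here is the
conservative all-aqueous bound.

## Glucose: finite-nutrient depletion and replenishment

Nutrients that only exist in the loaded medium (glucose) are consumed with
Michaelis–Menten kinetics, $q(c) = q_{\max}\, c/(c + k_M)$ per cell. The
metabolic threshold is $c = k_M$: below it uptake falls under half-maximum.
The replenishment interval is the time until the *minimum* concentration in
the tissue first reaches $k_M$.

**Geometry reduction.** The real trap-plus-channel domain is reduced to a
tissue sphere of volume $V_T$ centred in a concentric medium shell of
volume $V_M$, with concentration and flux continuity at the interface and a
no-flux outer boundary (each trap's medium share exchanges nothing with its
neighbours' — the closed-system analogue of the periodic inlet/outlet
condition in a multi-trap channel). This is justified exactly where the
linear replenishment law is claimed to hold: outside the diffusion-limited
regime, transport is fast compared with uptake and the channel's actual
shape is immaterial. The zero-order Damköhler number
$Da_0 = t_{\mathrm{diff}}/t_{\mathrm{up}}$ with
$t_{\mathrm{diff}} = L^2/(8 D_M)$ and
$t_{\mathrm{up}} = c_0 V_M / (q_{\max}\rho_{\mathrm{cell}} V_T)$ guards the
reduction: `sweep_and_fit_replenishment()` excludes any sweep point with
$Da_0 \ge 1$ (using the shell thickness as diffusion length), and
`max_channel_length()` inverts $Da_0 = 1$ into the channel-length limit
$L_{\max} = \sqrt{8\, c_0 D_M (V_M/V_T) / (q_{\max}\rho_{\mathrm{cell}})}$.

**Discretization.** `depletion_time_pde()` uses a conservative finite-volume
method of lines in spherical radius: 100 uniform cells in the tissue and
100 geometrically stretched cells in the shell (the first shell cell
matches the tissue spacing, so the interface — which falls exactly on a
face — is resolved on both sides), distance-weighted harmonic-mean
diffusivities at faces, and no-flux closures at the centre and outer
boundary. Time integration is stiff-adaptive (`deSolve::lsodar` with a
banded Jacobian) with the stop condition implemented as a root function, so
the threshold crossing is located by the integrator itself rather than by
post-hoc interpolation. Tolerances default to `rtol = atol = 1e-8`. A
conservation audit (final inventory plus time-integrated uptake versus
initial stock) is attached to every result; it sits around $10^{-6}$
relative, and halving the grid spacing moves the threshold time by well
under 0.5%.

**Initial condition and partitioning.** Both tissue and medium start at
$c_0$ (11 mM for glucose, the experimental medium concentration), and
glucose is assigned partition coefficient 1 across the interface — a single
aqueous phase, so the continuity condition on concentration normalized by
saturation reduces to plain continuity. The literature table supplies no
glucose diffusion constants, so the package defaults to standard aqueous
and tissue values $D_M = 6.7\times10^{-6}$, $D_T = 1.1\times10^{-6}$
cm²/s, both user-overridable; in the uptake-limited regime the depletion
time is insensitive to their precise values, which is the regime the
Damköhler check enforces.

**The linear law.** Sweeping the medium-to-tissue volume ratio
$V_M/V_T$ over 12 log-spaced points in $[10, 1000]$ (with the reference
375 µm spheroid, the depletion-stressing geometry) and regressing

$$t = a\,\frac{c_0}{q_{\max}\rho_{\mathrm{cell}}}\,\frac{V_M}{V_T} + b$$

gives $a \approx 0.96$, $|b|$ under half an hour and $r^2 > 0.9999$. The
slope sits below 1 because the tissue core reaches $k_M$ slightly before
the pool as a whole is spent — the diffusion gradient across tissue and
shell gives the core a head start of order
$q_{\max}\rho_{\mathrm{cell}} R_T^2 / (6 D_T)$ in concentration. The
$V_M \ge 100\,V_T$ design rule comes straight from this law: a hundred-fold
medium volume sustains optimal metabolism for at least a day.

```{r, eval = FALSE}
fit <- sweep_and_fit_replenishment()
fit
#> <replenishment_fit: t = a tau (V_M/V_T) + b>
#>   a = 0.9591, b = 0.3488 h, r^2 = 1.000000, tau = 1007 s (glucose)
#>   fitted over V_M/V_T in [10, 1e+03] (12 points)
```

`replenishment_time()` evaluates the law as a conservative replenishment
interval; cells tolerate excursions past the threshold for a while, so real
schedules may stretch somewhat longer without visible viability loss.

## Validation against published devices

The packaged table `literature_devices()` transcribes 13 published MST
designs spanning single cells (16–20 µm) to 600 µm spheroids, with each
device's $V_M/V_T$ and experimental replenishment practice.
`evaluate_literature_table()` applies the fitted law and classifies each
device: perfused (supply always sufficient), replenished within the model
time, within 20% of it (brief dips below $k_M$), or under-replenished.
Under the default fit the tally is 5 perfused and exactly one
under-replenished device — the 600 µm-spheroid design whose daily schedule
is roughly half the modelled requirement; inverting the law at that
device's fixed medium volume gives a maximum spheroid diameter of about
500 µm for a 24 h schedule, in line with the published figure of 487 µm.
Classification depends on the fitted constants only through ratios of
order one, but per-device agreement inherits the model's idealizations
(typical EMT6/Ro kinetics for every cell line, spherical samples, nominal
$V_M$).

## What the defaults do and do not represent

The study conditions baked into the defaults are: water-like medium
(η = 1.0 mPa s, the value consistent with the published 12 µm minimum
width; ρ = 1000 kg/m³), gravity as the volume force, tissue density
1.02 g/cm³, cellular density 2.8×10⁵ cells/µL, τ_max = 1 Pa, typical
EMT6/Ro uptake kinetics, and the reference geometries (250 µm tissue in a
500 µm cubic trap for hydrodynamics; 375 µm spheroid for depletion
sweeps). Problem sizes — 200 radial cells, 12 sweep points — were chosen
so a full sweep-and-fit runs in seconds while grid refinement changes
results by less than half a percent.

Known limitations, inherited from the analytic scope:

* No flow-field solving: recirculation patterns, the pinning of samples
  upstream in the trap, and transitional-Reynolds lift are summarized by
  the two fitted critical-flow constants, not recomputed.
* The depletion geometry is radially symmetric, so the concentration
  minimum is always at the tissue centre; in a real trap the minimum
  shifts toward whichever side is farther from the channel, without
  materially changing the threshold time in the uptake-limited regime.
* Oxygen transport through device walls (and its degradation on glass
  bonding) is represented only by the conservative anoxia bound.
* No proliferation or death kinetics: the $k_M$ threshold marks where
  metabolism becomes limited, which is deliberately earlier than any
  viability loss.
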