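---
title: "A 1D pacemaker-driven model of lymph transport: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 1D pacemaker-driven model of lymph transport: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lymphchain` simulates lymph transport through a chain of collecting
lymphangions — the contractile segments of a lymphatic vessel bounded by
one-way secondary valves. The driver of transport is not a prescribed
trigonometric waveform but a *spatiotemporal activation field* constructed
from measurable pacemaking metrics: how many initiation sites a vessel has
per unit length, how fast a contraction wave conducts, and how often it
fires. This vignette explains the model, its assumptions, every tunable
parameter, the numerical scheme, and — importantly — what the shipped
defaults can and cannot claim about real vessels.

## 1. The activation field

Each pacemaker site fires once per contraction period and produces a
signal modelled as a bivariate Gaussian density in the space–time plane,
centred at the site position $\mu_z$ and firing time $\mu_t$:

$$
f(z,t) = \frac{1}{2\pi\sigma_z\sigma_t\sqrt{1-\rho^2}}
\exp\!\left[-\frac{1}{2(1-\rho^2)}\left(
\frac{(z-\mu_z)^2}{\sigma_z^2}
- \frac{2\rho\,(z-\mu_z)(t-\mu_t)}{\sigma_z \sigma_t}
+ \frac{(t-\mu_t)^2}{\sigma_t^2}\right)\right]
$$

The spreads encode the requirement that a contraction decays between any
two pacemakers within a period: with one decay spanning roughly four
standard deviations, $\sigma_z = L_\text{pacemaker}/8$ (two decays between
neighbouring sites, $L_\text{pacemaker} = 1/\text{sites per cm}$) and
$\sigma_t = T/4$ (one decay per period $T$).

The correlation $\rho$ carries the conduction speed $c$. The
conditional-mean ridge of a bivariate Gaussian has slope
$\rho\,\sigma_t/\sigma_z$ in the $t$–$z$ plane; equating that slope to
$1/c$ gives

$$\rho = \frac{\sigma_z}{c\,\sigma_t},$$

which reproduces both stated limits: fast conduction gives a symmetric,
near-synchronous pulse ($\rho \to 0$), slow conduction a strongly skewed,
crawling one. For the wild-type metrics (0.98 cm/s, 10 sites/cm,
period 7.23 s) this yields $\rho \approx 0.0071$; for the Connexin-45
knock-out metrics (0.063 cm/s, 11 sites/cm, 3.80 s),
$\rho \approx 0.19$. Signal direction (antegrade vs retrograde) is the
sign of $\rho$. $|\rho|$ is capped at 0.99 to keep the covariance positive
definite — a bound of the form $\sqrt{\sigma_z\sigma_t}$ is sometimes
quoted for this quantity but is dimensionally inconsistent for a
correlation coefficient, so the package does not use it.

Sites are placed evenly at the pacemaking distance, centred on the chain,
and all fire at mid-period; wave propagation is carried entirely by the
skew. Simultaneous firing is the minimal assumption given that phase
offsets between sites are not measurable from the available metrics. The
per-site signals, plus one periodic temporal image on each side (three
images in total; by the $\sigma_t = T/4$ rule the Gaussians decay within
one period, so three images are exact to machine precision), are summed
over all sites and normalized by the global maximum $\Gamma$, giving the
contraction parameter $t_\text{act}(z,t) \in [0,1]$ with maximum exactly 1.
$\Gamma$ is recomputed per scenario. Evaluation wraps time into $[0,T)$,
so the field is periodic by construction.

## 2. Wall mechanics

The wall interpolates between two measured mechanical states — the
*pre-twitch* (fully relaxed) and *peak-twitch* (maximally contracted)
pressure–diameter curves — with the activation as the weight, both states
evaluated at the pressure of the previous time step:

$$d = (d_\text{peak} - d_\text{pre})\,t_\text{act} + d_\text{pre},
\qquad
C = (C_\text{peak} - C_\text{pre})\,t_\text{act} + C_\text{pre},$$

where $C_s = \tfrac{\pi}{2} d_s\, (\partial d/\partial P)_s$ is the area
compliance of a circular lumen in state $s$. Interpolating the two state
compliances linearly is the model's rule; it coincides with the chain rule
of the interpolated diameter at the endpoints and approximates it in
between. This weighted-average construction avoids solving a nonlinear
active-plus-passive constitutive inverse problem at every node and step.

Each state is a saturating exponential
$d(P) = d_\max - (d_\max - d_\min)\,e^{-kP}$ — monotone, concave and
strain-stiffening, the familiar shape of rat mesenteric lymphatic
inflation data. **The shipped coefficients are calibrated stand-ins**, not
digitized measurements: the numeric pressure–diameter data behind the
reference curves are not published as numbers. The defaults anchor the
pre-twitch curve at the resting diameter $D_0 = 255\,\mu$m at the mean
operating pressure 3.75 cmH2O, and put the peak-twitch plateau at
$0.45\,D_0$ so that a fully activated node contracts its caliber by
roughly half. Users with their own inflation data can fit the family with
`curves_from_table()` or override any anchor in the configuration.

## 3. Valves

Secondary valves are lumped resistances with a sigmoidal dependence on the
trans-valvular pressure difference $\Delta p$ (upstream minus downstream):

$$
R_v = R_{v,\min} + R_{v,\max}\left(
\frac{1}{1+e^{\,s_o(\Delta p - p_o)}} +
\frac{1}{1+e^{-s_f(\Delta p - p_f)}} - 1\right),
\qquad s_o, s_f > 0,\; p_f < p_o .
$$

The sign of the opening slope is calibrated so that the valve is cheap to
pass when $\Delta p$ is favourable ($R_v \to R_{v,\min}$), expensive when
closed ($R_v = R_{v,\min}+R_{v,\max}$ on the plateau between the
thresholds), and fails (leaflet prolapse, resistance collapsing again)
only below $p_f$. As printed in the source lineage, the two-sigmoid form
with both slopes positive yields inverted limits
($R_{v,\min}+R_{v,\max}$ when open, $R_{v,\min}-R_{v,\max}$ when closed),
so this sign calibration is required to obtain the physiological one-way
behaviour. The default $p_f = -6$ cmH2O is far outside the simulated
operating range: failure never engages unless a user asks for it.

Default magnitudes are stand-ins too: $R_{v,\min} = 600$ and
$R_{v,\max} = 3.5\times 10^5$ cmH2O·s/cm³. $R_{v,\min}$ keeps the
open-valve drop negligible against the 0.5 cmH2O boundary head at the
simulated peak flows; $R_{v,\max}$ was set so the wild-type simulation's
cycle-averaged outflow lands at the reported scale (see §7). All six
parameters are per-valve configurable; the four valves are identical by
default.

## 4. The 1D fluid solver

Mass and momentum balance on each lymphangion (a straight elastic tube;
taper is not modelled):

$$
C\,\frac{\partial P}{\partial t} + \frac{\partial Q}{\partial z} = 0,
\qquad
\frac{\rho}{A}\frac{\partial Q}{\partial t} + \frac{\partial P}{\partial z}
= \frac{\tau}{A}
- (1+\delta_s)\frac{\rho}{A}\frac{\partial}{\partial z}\!\left(\frac{Q^2}{A}\right),
$$

with the friction closure $\tau = -2(\zeta+2)\mu\pi Q/A$ of the power-law
velocity profile
$u(r) = (Q/A)\,\tfrac{\zeta+2}{\zeta}\,[1-(r/r_i)^\zeta]$. The radial
coordinate in the profile is interpreted relative to the lumen radius, so
that $u$ vanishes exactly at the wall and its cross-sectional mean equals
$Q/A$ (verified by quadrature in the tests). $\delta_s$ defaults to
$1/(\zeta+1)$, making $1+\delta_s$ the momentum-flux correction factor of
that profile ($4/3$ for the parabolic $\zeta = 2$); it is exposed in the
configuration. For $\zeta = 2$ the steady rigid-tube momentum balance
reduces to the Hagen–Poiseuille law, which the test suite verifies to
better than 0.1%.

Discretization: backward Euler in time, central differences on a staggered
grid (pressures at nodes, flows at cell faces), valves as zero-length
resistive interfaces between the segment-end nodes (the boundary valves
see the inlet/outlet reservoirs). The wall is explicit — $d$, $A$ and $C$
are evaluated at the previous step's pressure and the new step's
activation — and the lumen area is advanced by the linearization
$A^{n+1} = A(P^n, t_\text{act}^{n+1}) + C\,(P^{n+1}-P^n)$, which makes the
discrete mass balance telescope exactly: at periodic steady state the
cycle-averaged flow is identical at all four valve planes (observed
residuals $\sim 10^{-12}$ relative). Eliminating the face flows from the
momentum equation leaves a tridiagonal pressure system per step, solved by
the Thomas algorithm; the valve resistances and the (small) convective
term are lagged and Picard-iterated to a relative tolerance of $10^{-8}$
on pressure and flow, with log-space under-relaxation of the valve
resistance engaged only if the iteration is slow. Lumen diameters are
clamped at 5% of $D_0$ to keep the friction term regular; the clamp is
never reached with the shipped scenarios.

A run advances whole contraction cycles and stops when successive
cycle-averaged outflows differ by less than 1% (at least 5 cycles,
at most 12 by default). With the reference grid — three 1 mm lymphangions,
$dz = 50\,\mu$m (63 nodes), $dt = 5$ ms — a wild-type run (1446 steps per
7.23 s cycle) converges in 5 cycles in under 10 s on one CPU; halving both
$dz$ and $dt$ changes the cycle-averaged outflow by well under 2%
(asserted in the tests on a shorter-period configuration chosen to keep
the suite fast).

## 5. Derived metrics

All metrics are computed over the last complete cycle. Ejection fraction
uses the *chain-averaged* lumen area series,
$EF = (A_{EDA}-A_{ESA})/A_{EDA}$ (control-volume weighted; per-lymphangion
EFs are also reported), and $FPF = f \times EF$ holds exactly by
construction. Wall shear stress is the friction traction over the
perimeter, $-2(\zeta+2)\mu Q/(Ad)$, negative during forward flow,
converted at 980.665 dyn/cm² per cmH2O. Its signal-to-noise ratio
compares the series at the chain midpoint against a trailing moving
average (window 5 samples = 25 ms by default, truncated at the series
start; the window is configurable and recorded in the report since the
reference definition leaves it open):
$SNR = \log\left[(\mathrm{RMS}(x)/\mathrm{RMS}(x-\hat x))^2\right]$.
Valvular energy loss is the jump of $\Phi = P + \tfrac{1}{2}\rho u^2$
across each valve (reservoir sides taken quiescent), reported as the
magnitude of the cycle mean. Activation integration (AI) is the
space–time mean of the normalized field scaled by 1000 — a "per-mille
activation duty" on the normalized $(z/L, t/T)$ domain, a convention the
report records because the quantity has no published normalization; under
it the wild-type field scores 187. The bottleneck trace marks, per
lymphangion and time step, the node carrying the largest flow magnitude
(ties broken upstream) and scores its stationarity as the modal-node
fraction.

## 6. Scenarios and what the presets emulate

Four presets encode the measured contractility of the two mouse lines:
`WT` (wild type) and `KO1`–`KO3` (Connexin-45 knock-out with antegrade,
alternating, and retrograde pacemaking signals respectively; the three KO
cases share their metrics and differ only in directionality). Boundary
pressures are 3.5/4 cmH2O — a 0.5 cmH2O adverse head the chain must pump
against. Runs are deterministic end to end: presets, sweep and CLI use no
random numbers, and reruns are bit-identical (asserted in the tests).

## 7. Calibration, and the honest limits of the construction

Two inputs exist only as figures in the source literature: the
pressure–diameter curves and the valve sigmoid's coefficients. The shipped
defaults are therefore *calibrated stand-ins*: the wall curves are
anchored as described in §2, and the single remaining free magnitude
($R_{v,\max}$) was set against one anchor — the reported wild-type
cycle-averaged flow of 5.44 µL/h; the shipped defaults give 5.76 µL/h. No
other quantity was tuned.

The construction also has a structural consequence worth stating plainly.
The decay rule $\sigma_z = L_\text{pacemaker}/8$ makes the activation
field a comb: nodes midway between pacemakers are essentially never
activated, so the *chain-average* activation duty cannot exceed
$\approx K\sqrt{2\pi}\,\sigma_z/L \approx 0.31$ at the systolic peak.
Chain-average quantities inherit that ceiling: the simulated wild-type
ejection fraction is $\approx 0.19$, not the $\approx 0.78$ reported from
experiments, and the simulated lumen-area reduction, peak velocities and
WSS excursions sit correspondingly lower. Likewise, with simultaneous
firing and between-site decay, signal directionality can only act within
$\pm\sigma_z$ of each site, so the three KO cases are hydraulically
nearly indistinguishable here, and the knock-out's higher contraction
frequency (15.8 vs 8.3 per minute) makes it out-pump the wild type —
the opposite of the measured contrast. Where the qualitative physics does
not depend on these gaps the model behaves as expected: the wild-type WSS
signal is smoother (higher SNR) than every knock-out's, its bottleneck
nodes are more stationary, valves rectify an oscillatory head into
non-negative net flow, and the activation-integration index separates
scenarios on the duty scale. Users who need the full experimental
contrast should supply activation fields with broader spatial support or
phase-offset firing — both are single-parameter changes in this
implementation — and their own constitutive data.

## 8. Numerical edge cases

Degenerate inputs fail loudly: non-positive contractility metrics,
$|\rho| \ge 1$, activation values outside $[0,1]$, non-divisible grids
($dz$ must divide the lymphangion length; $dt$ must divide the period),
crossing constitutive curves, non-positive valve resistances, and
truncated (sub-cycle) analysis windows all raise classed errors. An empty
pacemaker list is an error rather than a silent zero field; passive runs
are requested explicitly (`scenario = "passive"`). If the pacemaking
distance exceeds the chain length, a single midpoint site is placed with a
warning. Ties in the bottleneck argmax break towards the upstream node.
The all-zero WSS series has no defined SNR (error), and a series equal to
its filtered version reports `Inf`.
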