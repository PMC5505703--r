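---
title: "An agent-based model of interfollicular epidermal homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of interfollicular epidermal homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ifesim)
```

## The model

`ifesim` is a center-based, off-lattice simulator of the interfollicular
epidermis: the stratified tissue in which basal keratinocytes divide on the
basement membrane, detach, differentiate as they move upward, cornify into
the stratum corneum, and are finally shed at the surface. The package's
purpose is twofold: to reproduce tissue homeostasis (constant thickness,
roughly 3-day division and 28-day turnover periods), and to run the
adhesion-perturbation experiment in which the anchoring strength of
committed progenitors to the basement membrane is weakened
(`Kd` from 5.0 to 2.0) — the in-silico analogue of losing hemidesmosomal
collagen XVII. The homeostasis goals are met quantitatively; what the
perturbation does (and does not) produce at the printed parameter
magnitudes is examined candidly in the Limitations section.

### Mechanics

Each cell is a sphere of radius $R$ with position $x_i$; the basement
membrane is a monolayer of immobile spheres of radius $R_m$ on a laterally
periodic, undulated surface. Motion is overdamped:

$$\mu \dot x_i = -\partial_{x_i}\Big(\sum_{j \in \Omega_{LJ}} V_{LJ}(|x_i-x_j|)
  + \sum_{j \in \Omega_m} V_m(|x_i-x_j|)\Big),$$

where $\Omega_{LJ}$ contains the cells in contact with $i$ plus the nearest
membrane particle, and $\Omega_m$ the membrane anchor. The contact potential
is the shifted-truncated repulsive form

$$V_{LJ}(r) = \varepsilon\left[\tfrac12\left(\tfrac{d}{r}\right)^{12}
  - \left(\tfrac{d}{r}\right)^{6}\right] + \tfrac{\varepsilon}{2},
  \qquad r \le d = R_i + R_j,$$

zero beyond contact: purely repulsive with a continuous force that vanishes
at $r = d$. A literature variant of this potential circulates with the two
powers' signs interchanged, which is attractive under overlap and
contradicts the hard-core repulsion the model's physics requires; the
sign-corrected form above is the default, and the inverted one remains
available as `lj_form = "printed"` for comparison. With
`contact_cutoff_factor > 1` the unshifted potential (with its adhesive
tail) is used instead, truncated at the cutoff.

Membrane anchoring is kind-dependent, with $u = r - (R + R_m)$ the
displacement from rest:

* stem cells: $V_m = \tfrac{K_s}{2}u^2$, unbounded — stem cells can never
  leave the membrane;
* committed progenitors (daughters):
  $V_m = \tfrac{K_d}{2}\left[a u^2 - \tfrac{b}{2}u^4\right]$ for
  $r \le r^* = R + R_m + a/b$ and $0$ beyond. The potential is
  discontinuous at $r^*$ exactly as defined; $r^*$ lies inside the
  quartic's restoring region (the barrier top is at $u = \sqrt{a/b}$), so
  the force jumps from a finite restoring value to zero at the threshold.
  A progenitor whose nearest-membrane distance exceeds $r^*$ is immediately
  and irreversibly reclassified as suprabasal;
* suprabasal and cornified cells: $V_m = 0$.

The anchor always acts toward the *dynamically nearest* membrane particle;
no permanent anchor identity is stored. This allows lateral crawling along
the membrane and matches the neighborhood definition used for the contact
sum.

### Division

Every reproducible cell (stem cells and attached progenitors) carries a
deterministic cycle clock of period $T$; once the clock passes $T$ the cell
enters a stochastic division phase with Poisson rate $\gamma$, so
inter-division intervals are $T + \mathrm{Exp}(\gamma)$. At division start
the parent is deleted and two children are created at its exact position;
their overlap is permitted because their mutual contact force is replaced by
the elastic dumbbell $U = \tfrac{K'}{2}(|x_j - x_k| - l(t))^2$ with natural
length $l(t) = \alpha (t - t_0)$. When $l$ reaches $2R$ (after exactly
$2R/\alpha = 20$ time units at the defaults) the division completes, the
pair dissolves, and the realized axis (the normalized separation at
completion) is logged. The initial push direction at zero separation is a
uniformly random unit vector; isotropy at birth is the minimal assumption,
and the realized axis is re-measured at completion because the mechanics may
rotate the pair. A `division_axis = "in_plane"` option restricts the initial
push to the lateral plane so that newborns stay within the basal layer and
only crowding rotates pairs out of plane; it changes basal kinetics
surprisingly little, because any oblique displacement crosses the short
detachment leash $r^* - (R+R_m) = 0.23$ far more easily than the weak
anchor can restrain it (see Limitations).

Fate assignment is not part of the mechanical definition and was an open
design choice; the package uses the asymmetric rule **stem → (stem,
daughter)** and **daughter → (daughter, daughter)**. This pins the stem pool
to the membrane (their count is exactly conserved, which the tests assert)
while progenitors behave as a committed, expendable population — consistent
with stem cells being unable to leave the membrane and progenitors
detaching under crowding.

### Differentiation and calcium

Each suprabasal cell carries a differentiation degree $S$; at $S \ge S^*$
(threshold inclusive) it cornifies. The advancement of $S$ is
calcium-coupled: contact with a cornified cell imposes the excited calcium
level $c_{exc}$ (high calcium sits directly beneath the stratum corneum),
otherwise calcium decays exponentially at rate $k_{ca}$, and

$$\frac{dS}{dt} = s_{base}\,(1 + \lambda_{ca}\, c).$$

This excite-and-decay law is deliberately minimal: it implements exactly the
two asserted couplings (contact-triggered excitation; calcium-accelerated
differentiation) and nothing else. The upstream reaction-diffusion calcium
dynamics of earlier work are not reproduced; anything beyond the verbal
coupling would be invented physics. Consequences of the simplification:
calcium is bounded in $[0, c_{exc}]$, is top-weighted under the cornified
layer by construction, and carries no lateral wave dynamics.

Cornified cells are mechanically ordinary (same contact potential, no
anchor, no division). Desquamation removes *exposed* cornified cells — those
with no higher cell center within lateral contact range — stochastically at
rate `desq_rate`. Exposure-based stochastic removal was chosen over
deterministic top-layer culling to avoid lock-step removal artifacts. The
rule itself is a calibration device: the tissue needs a cell sink with a
tunable rate, and the removal capacity (exposed cells × rate) must exceed
the division flux or the cornified stack grows without bound; the default
rate 0.05 per time unit is safely supercritical at the default patch size
(a rate of 0.02 sits at the capacity margin and lets the cornified stack
creep upward indefinitely — the symptom that fixed this default).

## Parameters and calibration

The mechanical and kinetic constants default to
$\mu = 1$, $R = 1.4$, $R_m = 1$, $\varepsilon = 1$, $K_s = 25$,
$K_d = 5$, $a = 0.0868$, $b = 0.376$, $K' = 5$, $\gamma = 0.00813$,
$\alpha = 0.14$ (model units). The remaining constants are simulator
plumbing with the following rationale:

* `T_cycle = 100` — the cycle period is not fixed by the mechanical
  constants; 100 time units combined with $1/\gamma \approx 123$ gives a
  mean inter-division interval of 223 units and a convenient day mapping.
* `day_unit = (T_cycle + 1/gamma)/3` — *defined*, not measured: the mean
  inter-division interval is calibrated to 3 days. All day-denominated
  output uses this mapping.
* `S_star = 1`, `c_exc = 1`, `lam_ca = 3`, `k_ca = 0.1` — surrogate
  calcium/differentiation scales; only the product structure matters, and
  `s_base` absorbs the overall rate.
* `s_base` — tuned by `calibrate_turnover()` so the mean
  birth-to-desquamation time is 28 days. Turnover is, to good approximation,
  affine in `1/s_base` (the viable-layer transit dominates), so a secant
  iteration converges in one or two simulation evaluations. The shipped
  default 0.00039 already lands within a few percent of 28 days at the
  default patch size.
* `desq_rate = 0.05` — held fixed during calibration (see above); the
  effective turnover knob is `s_base`.

With these choices a homeostatic 20 × 20 patch (100 membrane sites,
undulation amplitude 1, wavelength 10) carries roughly 470–500 cells:
~50 basal (about 20 of them stem), ~410 suprabasal, and a thin cornified
cap of ~15–30 cells, at a stationary thickness ≈ 22 length units
(≈ 8 cell diameters).

## The synthetic initial condition

There is no external input data. The fixtures stage generates (i) the
membrane monolayer on a regular grid with the product-of-sines undulation
$z = A\sin(2\pi x/\lambda)\sin(2\pi y/\lambda)$ (amplitude and wavelength
are free choices — the tissue literature only requires "undulated" — and a
flat membrane is supported for unit fixtures), and (ii) one basal cell per
membrane site at anchoring rest distance, stem with probability
`stem_fraction = 0.2` (the stem/progenitor ratio is not constrained by the
model definition; 20% stems keeps a realistic minority stem pool), with
cycle clocks uniform in $[0, T)$ to desynchronize the first division wave.
Burn-in from this packing produces the stratified steady state; the tissue
overshoots around day 30 and settles by day ≈ 45, which is why the
protocol default is a 50-day burn-in. Ensemble members vary the random seed
and the undulation phase, giving each run a different membrane shape.

What the generator does *not* emulate: real basal-membrane geometry
(rete-ridge statistics), cell-size heterogeneity, apoptosis, and any
signalling beyond the calcium surrogate. Passing tests therefore demonstrate
internal consistency of the model and its published parameter regime, not
fidelity to any particular tissue section.

## The perturbation experiment

`run_protocol()` burns in, then forks each run into a control arm
($K_d = 5$) and a perturbed arm ($K_d = 2$), both continuing from the same
saved RNG state so the arms differ only by the adhesion strength (with
$K_d$ unchanged the two arms are bit-identical — a test asserts this).
Thickness is recorded on a column grid (pitch one cell diameter, thickness =
top of highest cell minus local membrane surface per column, averaged over
occupied columns) and each series is normalized to its value at the switch,
so ratios start at exactly 1. Five-member ensembles are summarized
pointwise by mean and standard error, and `transient_metrics()` reports the
peak ratio, its timing, the final ratio and the recovery fraction
$(peak - final)/(peak - 1)$.

The intended mechanism is that weakening $K_d$ releases part of the
standing crowd of attached progenitors — a detachment pulse that swells the
suprabasal compartment before division flux, set by basal occupancy,
refills the layer and the excess clears: transient hypertrophy rather than
a new set point. The post-switch horizon of 30 days covers about one
turnover period. Whether the model as defined actually delivers this
transient at the printed parameter magnitudes is a measured result, not an
assumption; see Known limitations for what the ensembles show.

## Numerics and reproducibility

* **Integrator** — explicit Euler at `dt = 0.01`, first-order and consistent
  with the overdamped equation; the stiffest spring satisfies
  $K_s\,dt/\mu = 0.25 < 0.5$, enforced at parameter validation. Total
  potential descent under pure mechanics is asserted in the tests.
* **Displacement cap** — per-step displacements are capped at
  `max_step_disp = 0.7` ($R/2$) as a guard against pathological overlaps;
  in healthy states the cap never engages.
* **Degenerate overlaps** — exactly coincident non-partner cells are
  separated along a deterministic id-derived direction of length $10^{-6}$;
  a deterministic direction (rather than a random draw) keeps the rare
  branch from desynchronizing the RNG stream shared by the two engine
  paths.
* **Neighbor search** — a periodic cell-list grid at the contact cutoff;
  the nearest-membrane lookup uses an expanding lateral window with an
  exclusion bound, validated against exhaustive search in the tests.
* **RNG** — a single R random stream drives everything (seeding, division
  sampling, axes, desquamation), consumed in documented ascending-id order.
  The fused C++ loop and the R-level operation functions draw identically,
  and a test pins their trajectories against each other bit-for-bit. The
  protocol fork captures `.Random.seed`, giving both arms the same
  post-switch stream.
* **Tie-breaks** — nearest-membrane ties resolve to the lowest particle id;
  cornification uses the inclusive threshold $S \ge S^*$; division starts
  are processed in ascending cell id within a step.

## Problem sizes used by the shipped analyses

The packaged tests and the acceptance script run: the five-seed protocol on
the 20 × 20 patch with a 50-day burn-in and 30-day follow-up per arm; a
75-day homeostatic run for the stem-lineage division-period estimate
(≥ 200 intervals from cells born in the first 63 days, so neither horizon
truncation nor detachment censoring biases the mean — stem cells are the
only lineage never censored by leaving the basal layer); and an 85-day run
for the turnover estimate (lifetimes of cells
born between days 30 and 45). These sizes were chosen as the smallest at
which the ensemble statistics are stable; larger patches only tighten the
standard errors.

## Known limitations

* **The adhesion perturbation is mechanically inert at the printed
  magnitudes.** The quartic anchor's maximal restoring force is
  $K_d \max_u u(a - b u^2) \approx 0.077$ at $K_d = 5$ over a leash of only
  $r^* - (R+R_m) = 0.23$, while contact and division-dumbbell forces are
  $O(1)$: a dividing pair drags a child across the detachment window
  regardless of the anchor, so first detachment occurs within a day of
  birth at every $K_d \le 5$ and the detachment flux equals the division
  flux. Consequently the $K_d\!: 5 \to 2$ switch changes ensemble-mean
  thickness by less than the ensemble noise (a few percent), and the
  response to $K_d$ is monotone *increasing* with leverage appearing only
  an order of magnitude above the homeostatic value (at $K_d = 50$ the
  basal pool and thickness grow measurably). The transient
  thinning-free hypertrophy reported for this class of perturbation would
  require either a substantially deeper or longer-ranged progenitor anchor
  or additional biology (for example, delaminated progenitors that keep
  dividing suprabasally) that the model's stated equations do not contain;
  the package implements the equations as given and reports what they do.
  The perturbation pipeline and its metrics remain fully functional and
  are exercised by the test suite, where the transient-hypertrophy check
  documents this model-level finding by failing honestly.
* The calcium surrogate has no spatial dynamics beyond contact excitation;
  quantitative statements about the cornified-boundary geometry are out of
  scope.
* The quartic anchor's force discontinuity at $r^*$ is part of the model
  definition and is excluded from gradient-consistency checks at exactly
  that point.
* A 20 × 20 patch holds only ~100 basal cells; stem-pool statistics in much
  larger tissues (drift, clonal competition) are outside the model's fate
  rule, which conserves the stem count exactly.
* Thickness is a column-maximum estimator; it tracks the tallest cell per
  column and is insensitive to subsurface porosity.
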