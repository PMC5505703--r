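# ifesim

An agent-based simulator of interfollicular epidermal homeostasis, built for
studying how basal-layer adhesion shapes tissue architecture. Cells are
overdamped spheres above an immobile, undulated basement-membrane particle
monolayer in a laterally periodic box. Stem cells are bound to the membrane
by a harmonic anchor; committed progenitors by a quartic anchor with a
finite detachment threshold; division follows a deterministic cell-cycle
phase plus a Poisson waiting time and is resolved mechanically by a growing
elastic dumbbell; detached cells differentiate under a calcium-coupled
clock, cornify at a threshold, and desquamate from the surface.

The package exists for audiences who want (i) a tested, reusable
implementation of this class of epidermis model, and (ii) its headline
computational experiment: weakening the progenitor-membrane adhesion
(`Kd` 5.0 → 2.0, the in-silico analogue of losing hemidesmosomal collagen
XVII from the basal niche) and measuring the epidermal-thickness response
across a five-member ensemble, control and perturbed arms side by side.

## The model in brief

Overdamped motion under pairwise potentials,

$$\mu \dot x_i = -\partial_{x_i}\Big(\textstyle\sum_{j\in\Omega_{LJ}} V_{LJ}(|x_i - x_j|) + \sum_{j\in\Omega_m} V_m(|x_i - x_j|)\Big),$$

with a shifted-truncated repulsive contact potential
$V_{LJ}(r) = \varepsilon[\tfrac12 (d/r)^{12} - (d/r)^6] + \varepsilon/2$
for $r \le d = R_i + R_j$, and kind-dependent membrane anchoring
($u = r - (R+R_m)$):

| kind | $V_m(r)$ | consequence |
|---|---|---|
| stem | $\tfrac{K_s}{2} u^2$ | never leaves the membrane |
| progenitor | $\tfrac{K_d}{2}[a u^2 - \tfrac b2 u^4]$ for $r \le r^{*}$, else 0 | detaches past $r^* = R + R_m + a/b \approx 2.631$ |
| suprabasal / cornified | 0 | free to stratify |

Division: cycle period $T$, then Poisson rate $\gamma$; children are created
coincident and pushed apart by $U = \tfrac{K'}{2}(|x_j-x_k| - \alpha(t-t_0))^2$
until their natural distance reaches $2R$. Differentiation: $S$ grows at
$s_{base}(1 + \lambda_{ca} c)$, with calcium $c$ excited by contact with
cornified cells; $S \ge S^*$ cornifies; exposed cornified cells shed at rate
`desq_rate`. Defaults: $\mu=1$, $R=1.4$, $R_m=1$, $\varepsilon=1$, $K_s=25$,
$K_d=5$, $a=0.0868$, $b=0.376$, $K'=5$, $\gamma=0.00813$, $\alpha=0.14$;
the day mapping is calibrated so the mean inter-division interval
$T + 1/\gamma$ equals 3 days, and `s_base` is calibrated so mean
birth-to-desquamation time is 28 days. See the methods vignette
(`vignettes/epidermis-model.Rmd`) for every choice and its rationale.

## Worked example

Burn a 20 × 20 patch (100 membrane sites) into homeostasis and look at it:

```r
library(ifesim)
p  <- model_params()
st <- burn_in(p, membrane_spec(), days = 50, seed = 11)
st
#> ifesim tissue: t = 3716.69, box 20 x 20, 492 cells (stem 23, daughter 29,
#>   suprabasal 422, cornified 18), 3 active pairs, 3059 events
measure_thickness(st, p)
#> [1] 22.51081
```

About 50 basal cells (a fifth of them stem) support ~440 differentiating
and cornified cells at a stationary thickness of ≈ 22 length units (≈ 8
cell diameters), with a mean division period of ≈ 2.8 days and a mean
birth-to-desquamation time of ≈ 28–29 days. The adhesion perturbation
experiment:

```r
runs <- run_protocol(p, membrane_spec(), seeds = 1:5,
                     burn_days = 50, post_days = 30, Kd_perturbed = 2.0)
per <- ensemble_average(lapply(runs, `[[`, "perturbed"))
ctl <- ensemble_average(lapply(runs, `[[`, "control"))
range(ctl$mean_ratio)
#> [1] 0.9541088 1.0013063
transient_metrics(per)$peak_ratio
#> [1] 1.000108
```

Read: the control arm holds its thickness to within a few percent over 30
days (homeostasis), and the weakened-adhesion arm is statistically
indistinguishable from it. That null is itself a documented finding: the
printed quartic anchor exerts at most ~0.08 force units over a detachment
leash of 0.23, so it cannot compete with O(1) contact and division forces,
and the `Kd` switch has no mechanical leverage at or below its homeostatic
value. The methods vignette's Limitations section walks through the
analysis; the corresponding transient-hypertrophy check in the test suite
fails honestly rather than being weakened.

A command-line interface wraps the same pipeline:

```sh
exec/ifesim simulate --seed 1 --days 40 --out out/
exec/ifesim fig1f --seeds 1,2,3,4,5 --out out/fig1f/
exec/ifesim axis-stats --events out/events.csv --out out/
```

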