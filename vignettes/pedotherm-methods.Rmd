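---
title: "Methods: partitioning plantar foot heating during walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning plantar foot heating during walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedotherm)
```

## The scientific problem

Plantar skin temperature rises by several degrees Celsius during a
half-hour walk, and elevated or poorly regulated foot temperature is a
recognised correlate of tissue complications such as ulceration in
diabetic feet. Two classes of mechanism drive the rise: *mechanical*
factors — the net work dissipated by foot structures at every ground
contact, which appears as heat — and *physiological* factors — skin blood
flow (capillaries and arteriovenous anastomoses), sweating, conduction and
convection, which both deliver and remove heat and vary over the activity.
`pedotherm` implements a pipeline that quantifies the temperature rise from
thermal images, characterises its temporal shape, and partitions it into
those two contributions under a first-law thermodynamic model.

## Regional extraction and the whole-foot average

Thermal frames are pixel matrices of surface temperature (°C). The plantar
surface is divided by a label mask into five regions — hallux, MTP
(metatarsophalangeal / ball), midfoot, arch, heel — produced by manual
segmentation upstream; the package deliberately provides no
auto-segmentation, accepting masks as inputs. Per region we report the
arithmetic mean temperature and pixel area. The whole-foot temperature at
each time point is the area-weighted average

$$T_{foot}(t) = \frac{\sum_r A_r(t)\, T_r(t)}{\sum_r A_r(t)},$$

recomputed from that frame's own areas (re-segmentation between photos may
change $A_r$). Because the weights are relative, physical pixel size
cancels and areas are plain pixel counts. The weighted mean is always
bounded by the regional extremes, and with equal areas it reduces to the
arithmetic mean — both properties are tested. If a region is missing at a
time point, the default policy drops it there and renormalizes the
remaining weights with a warning; a strict mode errors instead.

## Temporal models and their comparison

Each regional (or whole-foot) series over the 30-min walk, sampled every
5 min, is fit with two models:

* a line, $T = m\,t + b$ — the shape expected if a constant per-stride
  heat input alone drove the response;
* a six-parameter generalized logistic (Richards) curve,
  $$T(t) = A + \frac{K - A}{\left(C + Q e^{-B t}\right)^{1/\nu}},$$
  an S-shaped family able to capture the plateauing that physiological
  regulation produces.

The logistic is fit by Levenberg–Marquardt damped least squares. Positivity
of $B$, $\nu$, $C$ and $Q$ is enforced by optimizing those parameters on
the log scale, which also keeps the power base positive. Defaults:
initialization $A=\min T$, $K=\max T$, $C=Q=\nu=1$, $B=0.1\,\mathrm{min}^{-1}$
(magnitudes near those observed for plantar regions); convergence by the
optimizer's relative tolerances ($10^{-12}$) or 500 iterations, with a
`converged` flag always reported rather than silent failure. An optional
multi-start grid over $B \in \{0.05, 0.1, 0.2, 0.5\}$ and
$\nu \in \{0.1, 1, 5\}$ keeps the best of all starts, so it can never end
worse than the default start. During iteration, parameter excursions that
overflow the power term are absorbed by a residual guard rather than
crashing the optimizer.

The six-parameter form is structurally non-identifiable — a joint rescaling
of $C$ and $Q$ can be traded against $K - A$ — so recovery is judged on the
*curve*, never on raw coefficients: tests require the fitted curve to match
a noiseless generating curve within $10^{-3}$ °C on a dense grid.

Models are compared by MSE and residual standard deviation, defined on
residual degrees of freedom:
$SS_{res} = \sum (obs - pred)^2$, $MSE = SS_{res}/(n-p)$,
$S_{res} = \sqrt{MSE}$, with $p = 2$ and $p = 6$. This denominator
convention is adopted because it makes $MSE = S_{res}^2$ hold exactly,
which published linear-model criteria pairs for all five regions satisfy
at their printed precision; no single denominator convention reproduces
the corresponding non-linear pairs, so we do not attempt to infer one.
With the 7-point design and $p = 6$ the logistic has a single residual
degree of freedom: its MSE is defined but heavily penalised, which is the
conservative choice for declaring the logistic the winner. Exactly equal
MSEs are reported as a tie; undefined criteria make the comparison
inconclusive rather than defaulting to either model.

## The thermodynamic partition

Over one stride the foot returns to its initial mechanical state, so under
the First Law the net work done by foot structures is dissipated as heat.
With net per-stride work $W_{stride}$ (kJ; negative = net dissipation),
foot mass $m_{foot}$ and composite specific heat $c_{foot}$:

$$\Delta T_{stride} = \frac{-W_{stride}}{m_{foot}\, c_{foot}}, \qquad
  \Delta T_{mech}(t) = \Delta T_{stride} \cdot strides(t).$$

The default stride schedule is constant cadence,
$strides(t) = N_{total}\, t / t_{end}$; a custom non-decreasing cumulative
count is accepted for non-constant cadence. The physiological contribution
is defined as the residual

$$\Delta T_{phys}(t) = \Delta T_{exp}(t) - \Delta T_{mech}(t),$$

so the conservation identity
$\Delta T_{mech} + \Delta T_{phys} = \Delta T_{exp}$ holds at machine
precision at every time point by construction — an invariant the emitted
tables are tested against row by row.

Reference inputs (literature-derived means for healthy adults walking
30 min at 1.25 m/s): $W_{stride} = -0.0034$ kJ with a ±1 SD interval of
$(-0.0071, 0.00023)$ kJ; 1,674 strides; $m_{foot} = 1.17$ kg
($0.0145 \times 80.42$ kg body mass by standard segment anthropometry);
$c_{foot} = 1.96$ kJ kg$^{-1}$ K$^{-1}$, bounded by bone (1.31) and blood
(3.62). These give $\Delta T_{mech}(30\,\mathrm{min}) \approx 2.48$ °C;
against an observed whole-foot rise of 3.50 °C the physiological residual
is $\approx 1.0$ °C.

Two unit notes, made deliberately as package design choices. First, the
composite specific heat is entered per unit mass (kJ kg$^{-1}$ K$^{-1}$)
even though such constants are sometimes quoted as kJ/K for a whole
segment: only the per-mass reading, divided by $m_{foot}c_{foot}$,
reproduces the ~2.5 °C estimate, and it keeps the mixture rule
$c_{foot} = \sum_i f_i c_i$ (mass fractions $f_i$ summing to 1) dimensionally
consistent. The mixture is mass-weighted — the standard rule — and its
convexity guarantees a result between the bone and blood endpoints.
Second, the sign convention treats negative net work (dissipation) as
heating, carried by the minus sign in $\Delta T_{stride}$.

Bound envelopes re-evaluate the mechanical curve at the work bounds
(mean $c$) and at the specific-heat bounds (mean $W$); each pair brackets
the mean curve, and the least-negative work bound yields a slightly
negative (cooling) curve — that bound is dominated by an outlying
participant in the source work data and is retained as an honest envelope,
not as a physical prediction. The mechanical estimate neglects losses to
sound and proximal tissue transfer, so it should be read as an upper bound
on mechanical heating.

## Burn-threshold extrapolation

Skin held above 43.3 °C may develop first-degree burns over time. The
package extrapolates when a foot heated at the mechanical rate would cross
that threshold. Because the source description of this extrapolation is
ambiguous about what the mechanical curve is added to, both readings are
exposed as modes, neither privileged: `mechanical_only` (temperature rises
from a supplied baseline at the constant mechanical rate; crossing at
$(43.3 - T_0)/\text{rate}$) and `experimental_then_mechanical` (follow a
measured temperature curve to its end, then extend at the mechanical
rate). The whole-foot baseline of any given cohort is a required input —
it is not a universal constant and is never assumed. From a 30.0 °C
baseline the mean mechanical rate (2.48 °C per 30 min) crosses the
threshold at ≈161 min; the steepest work bound at ≈78 min; at 1.25 m/s
those correspond to roughly 12 and 5.8 km of walking. Degenerate cases are
defined, not errors: baseline at or above threshold crosses at 0 min; a
non-positive rate never crosses (`Inf`). Crossing time is strictly
decreasing in both rate and baseline, a tested property. Cumulative
thermal-dose damage models (Arrhenius/CEM43) are out of scope.

## The synthetic-data generator

No raw thermal images are distributed, so a seeded generator stands in for
the study conditions and makes every stage testable end to end. Its
defaults *are* those conditions: 8 participants, samples every 5 min over
30 min, five regions whose ground-truth curves are the generalized-logistic
coefficient sets observed per region in healthy adults (hallux warming
most, arch least). Free defaults, chosen once as field-plausible values and
documented here rather than tuned: additive i.i.d. Gaussian temporal noise
of SD 0.2 °C per sample (no within-series noise estimate exists to copy;
0.2 °C sits well below the 2–6 °C regional rises), per-participant random
offsets of SD 0.5 °C applied jointly to $A$ and $K$ (shifting level,
preserving shape, mimicking between-participant baseline spread), region
pixel areas (60, 180, 120, 100, 140 for hallux, MTP, midfoot, arch, heel)
proportional to plausible plantar shares, ambient background 22 °C, and
zero per-pixel spatial noise by default so frame-derived means equal the
series exactly.

Frames lay regions out as abstract stacked rectangular blocks, not
foot-shaped outlines: the area-weighted average depends only on areas and
means, so geometry adds nothing but cost. Random streams are split
hierarchically (cohort → participant → region/frame) by an integer mixing
function, so identical seeds give byte-identical cohorts and adding a
participant never perturbs earlier participants' data.

What passing tests on synthetic cohorts do and do not show: they verify
the pipeline's numerics — extraction, weighting, fitting, comparison,
partition — under a known truth; they do not validate the logistic as the
true physiological law, nor the i.i.d. noise model (real series have
serially correlated, possibly heteroscedastic errors from re-shoeing and
camera repositioning), nor any spatial texture of real thermograms.

## Problem sizes and numerical choices

The test-suite simulation study uses 200 seeded cohorts of 8 participants
(noise SD 0.2 °C) for the model-comparison property — on cohort-mean
series, where averaging 8 participants reduces the effective noise to
$0.2/\sqrt{8} \approx 0.07$ °C, mirroring how the regional curves are
summarised before fitting — and observes the logistic winning in ≈98% of
region-cohort comparisons, satisfying the ≥95% acceptance bound. Recovery
and oracle checks run at the study's own scale (7 time points, 5 regions).
Linear fits are checked against closed-form normal equations to $10^{-10}$
relative; the mechanical curve against an explicit per-stride accumulation
loop to $10^{-12}$; decomposition conservation to machine epsilon.

## Known limitations

* The partition inherits every assumption of the first-law model: all net
  stride work becomes foot heat, uniformly distributed over a single
  thermal mass with one composite specific heat.
* The physiological term is a residual; it absorbs any error in the
  mechanical inputs along with genuine physiology.
* The burn extrapolation is a threshold crossing, not a damage integral,
  and extrapolates a 30-min mechanical rate to 3+ hours.
* The exact tissue inventory behind the composite specific heat mean is
  not published; only the bone/blood endpoints bound it, and the mixture
  rule here is the standard mass-weighted one.
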