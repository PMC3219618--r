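---
title: "Speed, sensitivity and bistability of inducible auto-activation circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed, sensitivity and bistability of inducible auto-activation circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autocircuit)
```

## The model and its assumptions

The package models a transcription factor (TF) that must be activated —
by covalent modification such as phosphorylation, or by ligand binding —
before it can act, and whose active form activates transcription of its
own gene. The signal enters only through the steady-state activated
fraction θ ∈ [0, 1] of TFs; the activation step itself (e.g. a sensor
kinase and phosphotransfer) is deliberately not modelled, because it is
fast (seconds) compared with transcription and translation (minutes) and
is specific to each system. The deterministic dynamics of the total TF
concentration $x$ are

$$\frac{dx}{dt} = \frac{b}{V}\,g(\theta x) - \beta x, \qquad
  g(\hat x) = \alpha\,\frac{1/f + (\hat x/K)^n}{1 + (\hat x/K)^n},$$

and the stochastic model is the master equation for the TF copy number
$N$ with production $N \to N + b$ at rate $g(\theta N/V)$ and decay
$N \to N - 1$ at rate $\beta N$ (`build_generator`).

Assumptions worth keeping in mind:

* **No explicit mRNA and no delays.** Each transcript is translated
  instantly $b$ times (the burst size). Transcription, translation and
  folding delays are ignored; on the tens-of-minutes induction scale this
  mainly shifts times, not the structure of the results.
* **Fast promoter binding.** The operator occupancy is equilibrated, so
  the transcription rate is the Hill function of the instantaneous active
  TF concentration. Slow operator kinetics can produce a *different* kind
  of bimodality (one peak per binding state); that mechanism is outside
  this model.
* **First-order loss.** β lumps degradation and dilution by growth;
  growth-physiology feedback on the rates is not modelled.

## Parameters, units, defaults

| parameter | meaning | shipped default (`fig4`/`fig5`) |
|---|---|---|
| `alpha_max` | maximal transcription rate | 1 min⁻¹ |
| `fold` (f) | maximal/basal promoter ratio | scanned (≥ 1) |
| `hill_n` (n) | Hill coefficient | scanned (> 0, continuous) |
| `K` | operator dissociation constant | 20 copies per cell volume |
| `beta` (β) | degradation/dilution rate | 0.025 min⁻¹ (≈ 28 min doubling) |
| `burst` (b) | proteins per transcript | 5 |
| `volume` (V) | cell volume | 1 (so concentrations are copy numbers) |

Only the combination $c = b\alpha/(\beta V K)$, together with $(f, n)$,
fixes the *shape* of the dimensionless response; the remaining freedom
sets absolute copy numbers and times. The defaults are typical enterobacterial
values: one transcript per minute at full activation, a five-protein
burst, dilution-dominated loss at a ~28-minute doubling time, and an
operator that half-saturates at 20 active copies, giving $c = 10$ and an
induced level of ≈ 180–230 copies across the fold-change range. The
`fig3` preset instead uses $K = 50$ ($c = 4$) so that the large-fold
threshold sits at $\theta_c = 1/c = 0.25$. These choices were made once,
to reproduce the qualitative behaviour the analyses target, and are not
tuned thereafter; every number below is recomputed from them at run time.

## Bistability and the regime classification

Steady states solve $h(w) = c\,\theta$ with $w = \theta x^*/K$ and
$h(w) = w(1+w^n)/(1/f + w^n)$. The turning points of $h$ follow from a
quadratic in $w^n$, which yields the exact boundary: $h$ is monotone —
one steady state for every input — iff $f \le f_c(n) = ((n+1)/(n-1))^2$
(`critical_fold`). Above $f_c$ a bistable window
$\theta \in [m_1/c,\, m_2/c]$ exists, where $m_1 < m_2$ are the values of
$h$ at its turning points.

`classify_regime` labels a parameter set **I** when no bistable window
exists for any θ (that is, $f \le f_c$: this part of the classification
is independent of $c$), **III** when the window includes saturating input
($m_1 \le c \le m_2$), and **II** otherwise. A design choice deserves a
note: with small $c$ the mathematical window can lie wholly above
$\theta = 1$; such sets are reported as II (a window exists, the circuit
is simply not driven into it by a physical input). Under this convention
the I/(II,III) boundary is a property of $(f, n)$ alone, which is what
makes the phase diagram's boundary curve universal; the II/III boundary
does depend on $c$. Tests cross-check both statements against dense
sign-scans of the drift, which know nothing of $h$.

Root finding for `steady_states` uses a 400-point logarithmic sign scan
of the drift on $[0,\ 1.05\,b\alpha/(\beta V)]$ — production is bounded,
so the interval is known a priori — followed by bracketed bisection to
$10^{-13}$; stability comes from the sign of the drift's derivative at
the root. Degenerate tangency cases (exactly at a fold bifurcation) are
resolved by the scan as the nearest odd multiplicity.

## Sensitivity: two measures and their conventions

`smax_closed_form` implements the exact maximal log–log slope of the
active-TF response,
$S_{\max} = (1+\sqrt f)/((n+1)-(n-1)\sqrt f)$, attained where
$w = f^{-1/2n}$; it is 1 without feedback, diverges as $f \uparrow f_c$,
and for $n = 1$ reduces to $(1+\sqrt f)/2$ — ultrasensitivity with no
molecular cooperativity. Two conventions matter:

* $S_{\max}$ is the maximum over the *whole* response relation. For
  $n = 1$ the maximising input is exactly $\theta = 1/c$, so when
  $c < 1$ the maximum would sit beyond the physical range θ ≤ 1 and a
  numerically measured slope on [0, 1] stays below the closed form. The
  numeric oracle (`smax_numeric`, centred differences on a geometric
  2000-point grid with parabolic refinement) is therefore validated on
  circuits with $c = 10$, where the maximum is comfortably interior.
* The average slope `sbar` uses the switching domain where the response
  rises from 10% to 90% **of its maximum value** (not of its dynamic
  range above basal; the alternative is available via
  `range_above_basal = TRUE`). For a basal-included Hill promoter run to
  saturation this gives the closed form
  $\bar S = 2n\ln 3 / \ln\!\big(9(0.9 - 1/f)/(0.1 - 1/f)\big)$
  (`sbar_hill`), i.e. $(n/2)\,\varphi(f)$ with $\varphi \to 1$ from
  below — the prefactor $n/2$, not $n$, is forced by the numeric oracle,
  which is the authority wherever the two could disagree. The form is
  defined for $f > 10$, where the 10% threshold exceeds the basal level.

$\bar S$ of the auto-activation circuit stays finite (≈ 1.4 at $c = 10$)
as $f \to \infty$ because the limiting response is threshold-linear
(`large_f_limits`: off below $\theta_c = 1/c$, active TF
$K(c\theta - 1)$ above), not step-like, while $S_{\max}$ diverges.

## Exact induction times from the master equation

The induction protocol: the circuit relaxes to stationarity with the
signal absent (θ = 0); at $t = 0$ the signal saturates (θ = 1); the
induction time is the first time the copy number reaches
$N_{th} = \lceil \tfrac12 \langle N\rangle_{\theta=1} \rceil$, half the
induced stationary mean. The stochastic mean is the default threshold
reference (a `"deterministic"` option exists); at the copy numbers of
interest the two differ by well under 5%, and initial states already at
or above $N_{th}$ contribute zero waiting time, consistent with reading
the induction time as a *waiting* time.

The mean is computed exactly: the stationary vector at θ = 0 and θ = 1
comes from a sparse linear solve of the generator null space (truncation
$n_{\max} = \max(4 x^* V, 20b)$, doubled until the top burst band holds
less than $10^{-8}$ mass; the cap reflects production rather than killing
it, preserving conservation), and the conditional mean hitting times
$h(N)$ solve the banded first-passage system with absorbing set
$\{N \ge N_{th}\}$ under the θ = 1 generator. Second moments solve the
same system with right-hand side $2h$, giving the CV
(`induction_time_distribution`). All solves are exact up to truncation
and solver tolerance; they are validated against an independent
direct-method SSA (`sample_induction_times`, compiled core, per-replicate
RNG substreams `seed + r`) at $10^4$ replicates, and the SSA itself
against matrix-exponential transient propagation.

Two regimes emerge. With basal rate $\alpha/f \gg \beta$ the initial
pool of TFs is large, induction proceeds through many accumulation steps,
and the stochastic mean tracks the deterministic one (within ~2% at
$f = 4$ under the default conditions). With $\alpha/f \lesssim \beta$
the cell typically holds no TF when the signal arrives, the first
transcription event (mean wait $f/\alpha$) becomes rate limiting, the
mean induction time detaches from the deterministic prediction by
factors, and the distribution becomes approximately exponential
(CV → 1): slow and unpredictable. The same zero-state trapping produces
a stationary peak at $N = 0$; for $n = 1$, a bimodal stationary law
requires $\alpha/f < \beta$ — a necessity the tests probe with a
200-set random parameter sweep. Note the converse fails at large
$c K V$: with hundreds of copies maintained, the on-state essentially
never decays back to zero and the zero peak carries negligible mass even
when $\alpha/f < \beta$.

`detect_bimodality` counts local maxima after width-3 smoothing, treats
$N = 0$ as a peak iff $p(0) > p(1)$, and requires each peak's basin to
hold at least $10^{-4}$ probability — guarding against grid-level
wiggles being read as modes.

## Phase maps and the admissible region

The grid analyses use $n \in [1, 4]$ (33 points) and
$f \in [1, 10^3]$ (41 log-spaced points): fine enough that the
closed-form bistability boundary is resolved within one cell, coarse
enough that the ~1350 first-passage solves of the induction map finish
in under half a minute. `induction_map` exploits that induction time
increases along the fold axis to stop solving a row once it exceeds the
time cutoff. `admissible_region` intersects, cell by cell: regime I,
$S_{\max} \ge 3$, mean induction ≤ 50 min, $f \ge 10$. The sensitivity
cutoff and fold floor are judgement calls (the time limit of 50 min is
the one the analysis is built around); all three are arguments, and the
fold floor is what pinches the region at $f_c(n) = f_{\min}$, i.e.
$n \approx 1.93$ for $f_{\min} = 10$. Under the shipped defaults the
region spans Hill coefficients ≈ 1–1.84 and caps the fold change at
37.6 — auto-activating signalling circuits that must be monostable,
sensitive and fast are pushed to low cooperativity and moderate fold
change, which is what the curated two-component systems show.

## What the synthetic conditions do and do not establish

Everything above is computed on model-generated conditions, not measured
data. Passing tests establish internal correctness — closed forms agree
with independent numerics, exact solves agree with simulation, the
region logic is a true intersection — under the model's idealisations:
no mRNA stage, no delays, equilibrated operator, constant θ after the
switch, a single well-mixed cell. They do not establish that any
particular organism's circuit sits at the shipped parameter values; the
presets are representative, and every analysis accepts user parameters
via `circuit_params`, config files, or the CLI.

## Numerical choices, degenerate inputs, limitations

* ODE induction times use `deSolve::lsodar` (stiff-capable, terminating
  root function at the threshold crossing; rtol $10^{-10}$). In regime
  III the trajectory from the basal state converges to the low branch
  and can never cross half of the induced level: reported as `Inf` with
  a flag rather than an error.
* `fold = 1` removes the feedback: induction time 0 (the steady state
  does not move), sensitivity exactly 1, stationary law exactly the
  constant-rate burst birth–death (Poisson for $b = 1$ — a test anchor,
  as is the flux-balance mean $b\alpha/\beta$).
* First-passage and stationary solves are exact linear algebra; their
  cost grows with the copy-number scale ($n_{\max}$), so very large
  $c K V$ (≫ 10⁴ copies) becomes slow — use the deterministic module
  there, where it is accurate anyway.
* The SSA uses its own Mersenne–Twister streams; results are independent
  of (and do not disturb) R's global RNG state, at the cost of not being
  reproducible via `set.seed` alone — seeds are explicit arguments
  everywhere, and stochastic CLI commands require one.
* Known limitation: `smax_numeric` requires a strictly positive,
  single-valued, monotone curve; it refuses bistable branches rather
  than silently differentiating across a fold point.
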