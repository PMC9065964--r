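---
title: "Windows of opportunity: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windows of opportunity: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woo)
```

## The establishment problem

In many harsh environments — tidal flats, arid savannas, shellfish
beds — young organisms can only establish during short benign intervals,
*windows of opportunity* (WoO). The organism's state is its tolerance
$T$ to an environmental stressor $E(t)$. From inception it develops
tolerance from an initial value $T_0$ at rate $\lambda$, either linearly
($T(t) = T_0 + \lambda t$) or exponentially
($T(t) = T_0 e^{\lambda t}$). The rules of the model are deliberately
stark:

* the organism dies instantly at the first moment its tolerance falls
  below the environment ($T < E$, strict);
* it is established, permanently, once its tolerance exceeds the
  harshest condition it will still face ($T \ge E_{\mathrm{high}}$).

All stochasticity lives in the environment; tolerance growth is
deterministic given $(T_0, \lambda)$. This isolates the interaction
between the two timescales of the problem — how fast the organism
hardens versus how long benign spells last.

## Closed-form theory for dichotomous environments

For a two-level environment alternating between $E_{\mathrm{low}}$ and
$E_{\mathrm{high}}$, the organism must close the gap
$\delta = E_{\mathrm{high}} - T_0$ within one benign window of length
$\tau_{\mathrm{low}}$, giving the critical linear growth rate

$$\lambda_{\mathrm{crit}} = \frac{\delta}{\tau_{\mathrm{low}}},$$

implemented in `critical_growth_rate()`. Its inverse,
`required_window()`, gives the critical window length
$\tau_{\mathrm{crit}} = \delta / \lambda$ (linear) or
$\log(E_{\mathrm{high}}/T_0)/\lambda$ (exponential); `Inf` when
$\lambda = 0$ and the gap is positive.

Under dichotomous Markov noise (DMN) — the random telegraph process with
transition rates $k_{\mathrm{low}}$, $k_{\mathrm{high}}$ — window
lengths are exponential,
$P(\tau_{\mathrm{low}}) = k_{\mathrm{low}}
e^{-k_{\mathrm{low}}\tau_{\mathrm{low}}}$, so the probability that a
window is an opportunity is the tail mass

$$P_{\mathrm{WoO}} = e^{-k_{\mathrm{low}} \tau_{\mathrm{crit}}}.$$

On the regular-dichotomous critical boundary,
$\tau_{\mathrm{crit}} = \langle\tau_{\mathrm{low}}\rangle =
1/k_{\mathrm{low}}$, this is always $1/e \approx 0.368$, regardless of
the other parameters — the single most useful reference value of the
framework.

Four regimes partition parameter space (`classify_regime()`): (i)
$T_0 \ge E_{\mathrm{high}}$, always establish; (ii)
$E_{\mathrm{high}} > T_0 \ge E_{\mathrm{avg}}$, variability destroys
opportunities; (iii) $E_{\mathrm{avg}} > T_0 > E_{\mathrm{low}}$,
variability creates opportunities; (iv) $T_0 \le E_{\mathrm{low}}$,
never establish. Ties follow the printed inequalities; when the
variance collapses entirely ($E_{\mathrm{low}} = E_{\mathrm{avg}} =
E_{\mathrm{high}} = T_0$) regime i wins, so a zero-variance column of an
occurrence diagram is 1 where $T_0 \ge E_{\mathrm{avg}}$ and 0
elsewhere. Establishment at exact equality $T = E_{\mathrm{high}}$
succeeds — the marginal organism with $\lambda = \lambda_{\mathrm{crit}}$
is defined as successful — and death requires strictly $T < E$.

`p_establishment()` extends $P_{\mathrm{WoO}}$ to a horizon by
compounding over the expected number of windows,
$N = \mathrm{horizon} / (1/k_{\mathrm{low}} + 1/k_{\mathrm{high}})$,
$P_{\mathrm{est}} = 1 - (1 - P_{\mathrm{WoO}})^N$. This is a minimal
reconstruction — it treats the window count as fixed at its mean — and
is documented as such; treat it as indicative, not exact.

## Signal generators and their parameters

**Regular dichotomous** (`generate_regular_dichotomous()`): a square
wave starting benign at $t = 0$; phases are half-open, sample $i$ covers
$[i\,dt, (i+1)\,dt)$, so arithmetic on window durations is unambiguous.

**DMN** (`generate_dmn()`): per step of length $dt$ the probability of
leaving the current state is $k\,dt$, the first-order discretization of
exponential waiting times. Sojourns are drawn as
$1 + \mathrm{Geometric}(k\,dt)$ steps — the exact distribution of that
per-step Bernoulli scheme — rather than stepwise, for speed. The
initial state is drawn from the stationary distribution
($P(\mathrm{low}) = k_{\mathrm{high}}/(k_{\mathrm{low}} +
k_{\mathrm{high}})$) because the theory concerns long-run stationary
dynamics. We require $k\,dt < 1$ (error) and warn above $k\,dt = 0.1$,
beyond which the geometric visibly departs from the exponential; the
discrete window mean is exactly $1/k$ at any $dt$.

**Correlated Gaussian (OU-type)** (`generate_oun()`): the recursion
$E_{t+dt} = E_t + r(\mu - E_t)\,dt + \varepsilon R$ with standard-normal
$R$. Two conventions for the mean-reversion rate $r$ are provided:

* `drift = "hasselmann"` (default): $r = 1 - 1/\langle\tau\rangle$.
  This is the printed form of the Hasselmann-style recursion in the
  literature this package follows. Note its peculiar geometry: it is a
  random walk at $\langle\tau\rangle = 1$, non-stationary below, and its
  correlation time $1/r$ *shrinks* toward 1 as $\langle\tau\rangle$
  grows.
* `drift = "relaxation"`: the textbook OU rate $r = 1/\langle\tau\rangle$,
  under which $\langle\tau\rangle$ *is* the correlation time and
  increasing it reddens the signal.

Because the reddening/whitening analyses of this package (the `fig5`
preset and the $f_{\mathrm{WoO}}$ ordering checks) require a period
parameter that actually lengthens the correlation time — and because the
default form cannot even be simulated at the common choice
$\langle\tau\rangle = 1$ — those experiments use the relaxation
convention explicitly. Everything else honours the default. Both modes
agree on the AR(1) structure $E_{n+1} = a E_n + (1-a)\mu +
\varepsilon R$ with $a = 1 - r\,dt$.

`scale_epsilon()` makes signals with different periods comparable in
magnitude: the stationary variance of the AR(1) recursion is
$\varepsilon^2/(1 - a^2)$, so
$\varepsilon = \sqrt{\sigma^2(E)\,(1 - a^2)}$ pins it at a target
$\sigma^2(E)$. This scaling is derived here from the AR(1) form and is
validated in the test suite by re-simulating $10^5$-step series and
checking the sample variance, rather than assumed. Non-stationary
combinations ($|a| \ge 1$) are refused with an explicit error.

When the start value is not overridden, `generate_oun()` starts at $\mu$
and discards a burn-in of ten relaxation times ($10/(r\,dt)$ steps) so
that sample moments estimate stationary moments.

## Windows, attempts and $f_{\mathrm{WoO}}$

`extract_benign_windows()` returns maximal runs of samples with
$E < T_0$; windows touching either series boundary are flagged censored
and excluded from duration statistics by default, since truncation
biases the exponential fit.

`simulate_attempt()` incepts an organism at a window's opening sample
(inception only in benign conditions, one attempt per window — windows
are the unit of analysis throughout) and walks forward: death at the
first sample with $T < E$; establishment at the first sample, before the
last, where $T$ reaches the maximum of the *remaining* series — beyond
that point death is impossible, which makes the outcome well defined on
a finite series. An organism alive at the final sample that never
cleared that bar is *censored* and counted as not attainable — a
conservative choice; the censored count is reported alongside.
Comparisons carry an absolute tie tolerance of $10^{-9}$ so the marginal
organism at $\lambda = \lambda_{\mathrm{crit}}$ establishes despite
round-off in $t = i\,dt$ arithmetic; on a DMN trajectory the attempt
outcome then agrees *exactly* with the analytic rule
$\tau \ge \tau_{\mathrm{crit}}$, which the test suite verifies
window-by-window.

On continuous signals the number of potential windows varies wildly with
the period, so the establishment measure is the *fraction of attainable
windows* $f_{\mathrm{WoO}}$ (`fraction_attainable_windows()`):
per replicate trajectory, the fraction of windows whose attempt
establishes; aggregated across replicates as a mean with a 10–90%
interdecile range. Replicates without any window contribute no fraction
and are counted separately — when the variance is too small to create
windows at all, the result is an explicit "no potential windows" state,
not a zero. `fwoo_curve()` evaluates a $\lambda$ grid with common
random numbers (the same trajectories for every $\lambda$), which makes
$f_{\mathrm{WoO}}$ exactly monotone in $\lambda$ replicate by replicate
and gives clean ordering comparisons across periods and variances.

## Default study conditions

The experiment presets (`woo_preset()`, `run_experiment()`) freeze the
package's reference conditions:

* DMN experiments: $E_{\mathrm{low}} = 0$, $E_{\mathrm{high}} = 1$,
  $k_{\mathrm{low}} = 0.1$, $k_{\mathrm{high}} = 0.2$, $dt = 0.01$,
  $10^4$ steps; organism $T_0 = 1/6$ (so $\delta = 5/6$), linear growth.
  The $P_{\mathrm{WoO}}(\lambda)$ curves are drawn for gaps
  $\delta \in \{1/3, 5/6, 4/3\}$ over a logarithmic $\lambda$ grid
  spanning $10^{-2}$–$10^{0.5}$ (the exact curve grids are a
  presentation choice).
* Correlated-Gaussian experiments: $\mu = 1$, $\sigma^2(E) = 0.5$,
  $dt = 0.01$, 1000 steps, 1000 replicate signals; periods varied by a
  factor 10 ($\langle\tau\rangle \in \{0.1, 1, 10\}$) at fixed variance
  and variances by a factor 2 ($\sigma^2 \in \{0.25, 0.5, 1\}$) at fixed
  period; $T_0 = 1/6$. With $\mu = 1$ and $\sigma^2 = 0.25$ the
  threshold $T_0$ sits $1.67\sigma$ below the mean, which produces the
  episodic, high-spread behaviour expected at low variance.
* Occurrence diagram: period 10, $\lambda = 0.05$, $T_0 = 0.5$ over
  $E_{\mathrm{avg}} \in [0, 1]$, $\sigma^2 \in [0, 0.5]$. The mapping
  from $(E_{\mathrm{avg}}, \sigma^2)$ to a dichotomous envelope is the
  symmetric two-point signal $E_{\mathrm{avg}} \pm \sigma$ with equal
  occupancy and $\langle\tau_{\mathrm{low}}\rangle =
  \langle\tau\rangle/2$ — the simplest signal with the requested mean
  and variance; both the mapping and the fixed $T_0$ are conventions of
  this package.

A single master seed spawns counter-based child seeds per replicate
(`child_seeds()`), so replicate $r$ is reproducible independently of how
many replicates run or in what order; identical configuration and seed
give byte-identical CSV outputs.

## Test problem sizes and statistical tolerances

Monte-Carlo checks in the test suite are sized so that their tolerance
bands are multi-sigma statements rather than coin flips: window-law
recovery uses $10^4$ completed windows ($5\%$ band on a mean with
standard error $\approx 1\%$); variance recovery of the scaled OU signal
uses $10^5$ steps at $dt = 0.05$–$0.1$, where the effective number of
independent samples puts the $10\%$ band at $2.5$–$3\sigma$;
$f_{\mathrm{WoO}}$ orderings use 200 replicates of 1000 steps with
common random numbers. The simulation-versus-theory agreement checks
use three binomial standard errors at $n = 2000$ windows per cell.

## What the synthetic environments do and do not capture

The generators reproduce the statistical skeleton of environmental
forcing: two-point occupancy, exponential window lengths, tunable
correlation time and variance. They do not contain deterministic cycles
(tides, seasons), trends, skewed or heavy-tailed marginals, or
multi-stressor structure; a passing test therefore shows that the
method's logic is correct under the stated noise models, not that any
particular field system satisfies them. Likewise the organism has no
demographic stochasticity, density dependence, tolerance decay, or
propagule limitation, and extinction-side transitions (the reverse
direction of the establishment transition) are out of scope.

## Known limitations

* `p_establishment()` is a mean-field stand-in (see above).
* The default drift convention degenerates at
  $\langle\tau\rangle \le 1$; the package refuses those combinations
  rather than silently switching convention.
* Censoring treatment of attempts at the series end is conservative;
  with short series and slow growers $f_{\mathrm{WoO}}$ is biased
  downward relative to an infinite-horizon definition.
* The occurrence diagram inherits the two-point envelope convention;
  other mappings from $(E_{\mathrm{avg}}, \sigma^2)$ to a signal would
  shift regime boundaries quantitatively, not qualitatively.

## A worked configuration

```{r worked}
organism <- tolerance_model(T0 = 1/6, lambda = 0.1)
delta <- tolerance_threshold(organism$T0, E_high = 1)
tau_crit <- required_window(organism, E_high = 1)
c(delta = delta, tau_crit = tau_crit,
  p_woo = p_woo_analytic(0.1, tau_crit))

dmn <- dmn_params(0, 1, k_low = 0.1, k_high = 0.2, dt = 0.01,
                  n_steps = 2e5)
monte_carlo_p_woo(dmn, organism, n_windows = 2000, seed = 1)$estimate
```
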