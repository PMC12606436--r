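---
title: "Methods: two-sex polygenic adaptation under sex-specific stabilizing selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sex polygenic adaptation under sex-specific stabilizing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `twosexsel`, the units and
defaults, the numerical choices behind the simulator and the analytic
predictions, and the problem sizes the package is designed around. All code
chunks are illustrative and not evaluated when the vignette is built; the
package's test suite exercises every claim made here.

## Model

A highly polygenic quantitative trait is expressed in both sexes of a diploid,
randomly mating population of size $N$ ($N$ females and $N$ males). Allele $i$
has per-copy effects $a_{i,f}$ and $a_{i,m}$ on the female and male trait and
population frequency $x_i$. Phenotypes are

$$z_f = \tilde F_f + \sum_i 2 a_{i,f} x_i, \qquad
  z_m = \tilde F_m + \sum_i 2 a_{i,m} x_i,$$

where $\tilde F_f$, $\tilde F_m$ collect the contributions of fixed alleles
(the *fixed backgrounds*). Each sex experiences Gaussian stabilizing selection
towards its own optimum $O_f$, $O_m$ with a common width parameter $V_S$ and
sex-specific *selection shares* $\gamma_f^2 + \gamma_m^2 = 1$: the effective
strength of selection through females is $\gamma_f^2 / V_S$ (equivalently,
fitness width $V_{S,f} = V_S / (2\gamma_f^2)$), and likewise for males. The
default is equal shares, $\gamma_f = \gamma_m = 1/\sqrt 2$.

### Units

All phenotypic quantities are expressed in units of
$\delta = \sqrt{V_S / (2N)}$, the scale of drift-induced fluctuations of the
population mean. The default $V_S = 2N$ makes $\delta = 1$, so trait values
are in $\delta$ units and variances in $\delta^2$ units throughout. The
overall scaled magnitude of an allele is
$a^2 = a_f^2\gamma_f^2 + a_m^2\gamma_m^2$, which equals the scaled selection
coefficient $2Ns_e$ acting on it in $\delta^2$ units.

### Allele-frequency dynamics

The expected per-generation frequency change of an allele, given the
distances $D_f = \bar z_f - O_f$, $D_m = \bar z_m - O_m$ of the sex means
from their optima, is

$$E[\Delta x] =
  -\left(\frac{a_f D_f \gamma_f^2}{V_S} + \frac{a_m D_m \gamma_m^2}{V_S}\right)
   x(1-x)
  -\left(\frac{a_f^2\gamma_f^2}{V_S} + \frac{a_m^2\gamma_m^2}{V_S}\right)
   \left(\tfrac12 - x\right) x(1-x),$$

a directional term proportional to the displacement of the means and a
stabilizing (underdominant-like) term pushing frequencies towards the nearer
boundary. With the sign convention used by `expected_delta_x()`, the
directional term reads
$(a_f D'_f \gamma_f^2 + a_m D'_m \gamma_m^2)\,x(1-x)/V_S$ with
$D' = O - \bar z$ the displacement *towards* the optimum. The stabilizing
coefficient reduces to $a^2/V_S$ in overall-magnitude units, which is the
single-sex small-effect limit; this fixes the coefficients as
$\gamma^2 / V_S$ (not $2\gamma^2 / V_S$).

### Wright–Fisher scheme

`step_generation()` advances one generation per allele:

1. compute $p = x + E[\Delta x]$, clamped to $[0, 1]$;
2. draw the next count from $\mathrm{Binomial}(2N, p)$ (Hardy–Weinberg /
   linkage-equilibrium approximation: frequencies evolve independently given
   the means);
3. fold fixed alleles into the backgrounds ($\tilde F_f \mathrel{+}= 2a_f$)
   and drop them together with lost alleles;
4. add $\mathrm{Poisson}(2NU)$ new mutations at frequency $1/(2N)$, where $U$
   is the per-gamete mutation rate on the trait.

This free-recombination, allele-frequency-only scheme is the standard
approximation for highly polygenic traits: it neglects linkage disequilibrium
and identity disequilibrium, both of which are $O(1/N)$ corrections for the
parameter regimes targeted here. It is *not* an individual-based simulator:
family structure, dominance, and epistasis are outside its scope.

## Mutation model

New mutations have squared overall magnitude $a^2 \sim$
Exponential(`mean_sq`) and an independent *sex-bias angle* $\phi_a$ with
$a_f = a\cos\phi_a/\gamma_f$, $a_m = a\sin\phi_a/\gamma_m$. Two architectures
are used throughout: `mean_sq = 1` (*approximately infinitesimal*; almost all
segregating alleles are nearly neutral) and `mean_sq = 16` (*multigenic*;
a substantial fraction of variance from strongly selected alleles).

The default angle density `h_r` is a three-class mixture indexed by the
shared fraction $r$: with probability $r$ the mutation affects both sexes
equally ($\phi_a = \pi/4$ or $5\pi/4$), otherwise it is female- or
male-specific with equal probability (angles on the axes). Direction cosines
for these atoms are stored exactly (e.g. $\cos\phi = \pm\sqrt{1/2}$ or $0$)
so that shared draws satisfy $a_f = a_m$ and sex-specific draws are exactly
zero in the other sex at the floating-point level. Arbitrary discrete angle
densities are supported and are symmetrised so that $h(\phi) = h(\phi+\pi)$.
Under `h_r` with equal selection shares, the expected equilibrium intersex
correlation is $r_{fm} = r$ and the shared variance is $B = r\,V_{A,*}$.

### Calibration of the mutation rate

At mutation–selection–drift balance the overall genic variance is

$$V_{A,O} = 2NU \int_0^\infty v(a)\, g(a)\, da, \qquad
  v(a) = 4a\, D_+(a/2),$$

with $D_+$ Dawson's integral and $g$ the magnitude density. $v(a) \to 2a^2$
for nearly neutral alleles and saturates at $4$ for strongly selected ones.
`calibrate_U()` inverts this (linear in $U$) relation for a target variance
$V_{A,*}$:

```{r}
library(twosexsel)
p <- model_params(N = 1000)
calibrate_U(mutation_model(mean_sq = 1), p, target_VA = 40)   # 0.0134
calibrate_U(mutation_model(mean_sq = 16), p, target_VA = 40)  # 0.0047
```

**Numerical choices.** Dawson's function is evaluated in-package through the
substitution $t = x - u$, giving
$D_+(x) = \int_0^x e^{u(u-2x)}\,du$ with integrand bounded by 1 — stable for
all magnitudes without asymptotic switchovers (tests cross-check it against
values frozen from an independent implementation to $10^{-10}$). The
architecture average $E[v(a)]$ is integrated over $s = a^2$, where the
exponential density is exact, which handles the heavy-tailed multigenic case
accurately.

## Statistics

`compute_moments()` evaluates, per recorded generation: the sex means and
their average/difference, sex-specific additive variances
$V_{A,f} = \sum 2a_f^2 x(1-x)$, the intersex covariance
$B = \sum 2 a_f a_m x(1-x)$ and correlation $r_{fm}$, third moments
$\mu_{3}$, the dimorphism $SD_\pm = \bar z_f - \bar z_m$, and
within/between-sex variance components. Average/difference coordinates
$k_a = (k_f + k_m)/2$, $k_d = (k_f - k_m)/2$ diagonalise the dynamics when
$\gamma^2 = 1/2$. `aggregate_replicates()` averages replicate trajectories on
a common time grid with 95% normal CIs ($1.96 \cdot \mathrm{SEM}$);
`equilibrium_fluctuation_stats()` estimates stationary fluctuation moments
from thinned equilibrium samples.

## Analytic predictions

* **Drift-induced dimorphism** (`drift_sd_prediction()`): with coinciding
  optima and $r_{fm} < 1$ the stationary distribution of the sex means gives
  $V[\bar z] = \delta^2$, $V[\bar z_{f/m}] = 2\delta^2$,
  $\mathrm{Cov}[\bar z_f, \bar z_m] = 0$, $V[SD_\pm] = 4\delta^2$, and
  $E[SD] = E|SD_\pm| = 2\sqrt{2/\pi}\,\delta \approx 1.596\,\delta$ —
  independent of $V_{A}$ and of $r_{fm}$. `scaled_sd()` expresses $E[SD]$ in
  phenotypic standard deviations.

* **Constant-variance (Lande) trajectories** (`lande_trajectories()`): after
  a shift $(\Lambda_f, \Lambda_m)$, with constant variances the distances
  decay as $D_a(t) = \Lambda_a e^{-t (V_{A,a}+B)/(2V_S)}$ and
  $D_d(t) = \Lambda_d e^{-t (V_{A,a}-B)/(2V_S)}$, so dimorphism builds as
  $SD_\pm(t) = 2\Lambda_d(1 - e^{-t V_{A,a}(1-r_{fm})/(2V_S)})$. A non-zero
  cross-variance $V_{A,d}$ couples the coordinates; that case is solved by
  eigendecomposition. The rapid-phase lengths
  (`adaptation_timescales()`) satisfy $t_d / t_a = (1+r_{fm})/(1-r_{fm})$ at
  equal shift sizes.

* **Moment-driven recursion** (`breeder_step()`,
  `predict_breeder_trajectory()`): the exact one-generation expected change
  of the distances given the current second and third moments,
  $E[\Delta D] = \frac{1}{2V_S}\,\Gamma\,(\mu_3 - G D)$ with
  $\Gamma = \mathrm{diag}(2\gamma_f^2, 2\gamma_m^2)$. Integrated over a
  *simulated* moment series, it isolates how much of any departure from the
  constant-variance prediction is explained by the evolution of the moments
  themselves (e.g. the transient dip of $r_{fm}$ after a discordant shift
  under the multigenic architecture). At equilibrium moments (zero skew,
  $V_{A,d} = 0$) it reduces exactly to the linear recursion underlying the
  exponential trajectories.

* **Background equilibration** (`equilibration_decay()`): after adaptation,
  the displacement of the *fixed backgrounds* from their expected value
  relaxes at the neutral rate $1/(2N)$, crossing $\delta$ at
  $t \approx 2N\ln(\Lambda/\delta)$.

## Experiments

`run_scenario()` drives the figure-level experiments: `equilibrium_sd`,
`concordant_shift`, `discordant_shift`, `divergent_then_convergent`, and
`transient_rfm`. Shift magnitudes are specified as multiples of $\sqrt{V_S}$
(coefficients 0.15 / 0.25 / 0.5, i.e. 1.06 / 1.77 / 3.54 phenotypic standard
deviations when $V_{A,*} = 40$, see `relative_shift_in_sd_units()`). Default
problem sizes follow the study design: $N = 1000$, $V_{A,*} = 40$ for shift
experiments (burn-in $10N$) or $V_{A,*} = 9$ for equilibrium-fluctuation
experiments (burn-in $100N$, samples thinned every $N/10$ generations —
roughly one autocorrelation time of the mean), 25 replicates. A resource
guard refuses configurations whose total replicate-generations exceed a
budget. Runs are deterministic given the master seed: replicate $i$ uses
`replicate_seed(seed, i)`, recorded in the JSON manifest.

Typical costs on one CPU: about 0.2 ms per generation at $V_{A,*} = 40$
(roughly 400 segregating alleles) and 0.1 ms at $V_{A,*} = 9$; a 25-replicate
shift experiment with a $10N$ burn-in takes on the order of a minute.

```{r}
res <- run_scenario("discordant_shift", architecture = "infinitesimal",
                    r = 0.5, shift_coeff = 0.25, replicates = 25, seed = 3)
head(res$aggregate[, c("t", "phase", "SDpm_mean", "SDpm_ci", "rfm_mean")])
head(res$prediction)          # constant-variance overlay
head(res$prediction_breeder)  # moment-driven overlay
```

A thin command-line front end with `simulate`, `stats`, `theory`, and
`experiment` subcommands is installed under `exec/twosexsel` (YAML configs;
see the script header for options).

## Design decisions and limitations

* The stabilizing-selection coefficients in the expected frequency change are
  $\gamma^2/V_S$, fixed by the requirement that the stabilizing term reduce
  to $a^2/V_S$ in overall-magnitude units (see above).
* Frequencies are propagated under Hardy–Weinberg and linkage equilibrium;
  the fixed backgrounds absorb fixations so that means remain exact.
* Selection response enters through the *expected* frequency change only;
  the full sex-specific selection model (separate gamete pools per sex) is
  approximated to the leading order in $1/V_S$, consistent with the analytic
  theory being tested.
* CIs in aggregates are normal-theory; equilibrium fluctuation statistics
  should be estimated from samples spanning many autocorrelation times
  ($\approx 2V_S / (V_A(1-r_{fm}))$ generations for the slowest,
  sex-difference mode — long exactly when $r_{fm}$ is high).
* `2NU \le 1` triggers a warning: with fewer than one mutation per
  generation entering the population, the trait is effectively monogenic and
  the polygenic approximations degrade.
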