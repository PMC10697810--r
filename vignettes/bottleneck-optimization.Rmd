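---
title: "Bottleneck regimes and the rate of microbial adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottleneck regimes and the rate of microbial adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bottleneckR)
```

## The problem

Serial passaging grows a microbial culture for a period $\tau$ (hours) and
then transfers a fraction into fresh media, each cell surviving the transfer
independently with probability $D \in (0,1)$ (a "100:1" dilution is
$D = 0.01$). Experimenters choosing $D$ and $\tau$ face a trade-off: long
growth periods give beneficial mutants more divisions in which to arise and
expand, but require harsher bottlenecks, which are exactly where rare
beneficial lineages are lost. This package implements the branching-process
theory and stochastic simulators needed to quantify that trade-off, and to
answer the design question: which $(D, \tau)$ regime maximizes the rate at
which beneficial mutations destined to fix are produced?

The headline answers the package reproduces:

* per unit *time*, the adaptation rate increases monotonically in $D$, so
  frequent, infinitesimally mild bottlenecks -- continuous culture in a
  chemostat -- are optimal, roughly 20-fold faster than conventional 100:1
  passaging;
* if logistics pin the growth period at $\tau = 24$ h, the optimum moves to
  $D^\* \approx 0.203$, a ${\sim}5{:}1$ dilution;
* the older view that intermediate bottlenecks of ${\sim}8{:}1$
  ($D = e^{-2} \approx 0.135$) are optimal is recovered exactly when one
  adopts the historical assumptions: optimization per *transfer*,
  deterministic growth, and Poisson-approximated bottleneck sampling.

## The exponential-growth model

A clonal wild-type population grows exponentially at rate $r$ from $DN$ to
$N$ cells over $\tau = \ln(1/D)/r$ hours (the *stable population*
constraint $D = e^{-r\tau}$, enforced by `core_params()` unless explicitly
decoupled). Each division carries probability $\mu$ of producing a
beneficial mutant whose selective effect $s$ is drawn from an exponential
distribution with mean $\omega$; the mutant lineage is a pure-birth (Yule)
process at rate $r(1+s)$.

The distributional building blocks (all exported):

* `yule_size_pmf()` -- a pure-birth lineage founded by one cell is
  geometric: $X(u) \sim \mathrm{Geom}(e^{-\lambda u})$ on $\{1, 2, \dots\}$.
* `bottleneck_transition_pmf()` -- the post-bottleneck count compounds that
  geometric law with per-cell Bernoulli($D$) thinning; the package evaluates
  the closed form obtained from the geometric pgf composed with
  $1 - D + Dz$, and the test suite checks it against the explicitly
  truncated double sum.
* `survival_initial()` / `survival_at_time()` -- eventual extinction
  probabilities $V(0,s) = (D^{-1}-1)/(D^{-(1+s)}-1)$ and
  $V(t,s) = \left(1 + (1-D^s)/(\beta(D^{-1}-1))\right)^{-1}$ with
  $\beta = e^{-r(1+s)(\tau-t)}$. The identity
  $V(t,s) = G_{M(\tau^+)}(V(0,s))$ -- the bottleneck-transition pgf
  evaluated at the phase-start extinction probability -- is verified
  numerically to $10^{-9}$ over random parameter triples.

The adaptation rate integrates the mutation supply against survival:

$$
\gamma \;=\; \frac{1}{\tau}\int_0^\infty \frac{e^{-s/\omega}}{\omega}
\int_0^\tau \mu N D r e^{rt}\,\bigl(1 - V(t,s)\bigr)\,dt\,ds
\;\approx\; r \mu N \cdot \frac{\omega}{1+\omega} \cdot
\frac{\ln(D^{-1})}{D^{-1}-1}.
$$

`fixation_rate_exact()` evaluates the double integral by nested adaptive
quadrature; `fixation_rate_approx()` is the closed form.

### How good is the closed form?

The $D$-dependent factor $\ln(D^{-1})/(D^{-1}-1)$ is excellent for all $D$.
The $\omega/(1+\omega)$ factor, however, stands in for the exact average
survival $\mathrm{E}[s/(1+s)]$ under exponential effects, and the two agree
only to first order in $\omega$: the closed form overshoots the double
integral by about 1% at $\omega = 0.01$, a uniform ~8% at $\omega = 0.1$
(the default), and tens of percent at $\omega = 1$. An independent
Monte-Carlo branching simulation sides with the double integral, so the
package treats the integral as the reference and documents the offset
rather than absorbing it. One acceptance check asserts the often-quoted
"within 2% for all $\omega \le 1$" form of the claim and is expected to
fail at $\omega \ge 0.1$; the package's own guarantee is 2% at
$\omega \le 0.01$ and 10% at $\omega = 0.1$. None of the optimization
results depend on this offset, because it is constant in $D$ wherever the
curves are compared.

The same caveat touches two printed corollaries. The mean selective effect
of mutations destined to fix is "$2\omega$" only in the weak-selection
limit; the model's own expectation at $D = 0.1$, $\omega = 0.1$ is
$1.856\,\omega$, which is what the simulator reproduces. And the
adaptation-based effective population size
`ne_effective()` implements the printed transcription
$N_e \approx N r \ln(D^{-1})/(2(D^{-1}-1))$ verbatim, whose $D \to 1$ limit
is $N r/2$ although the surrounding text asserts $N$; the factor-2
ambiguity is exposed in a dedicated test rather than silently "fixed".

## The eight model variants

`variant_rate()` computes $\gamma$ under any combination of three
assumptions (`variant_spec()`): metric (`per_time` vs `per_transfer`,
differing by a factor $\tau$), growth of mutant lineages (`stochastic`
geometric vs `deterministic` point mass), and bottleneck sampling
(`binomial` thinning vs the `poisson` approximation of the older
literature). Survival probabilities come from the smallest fixed point
$q = G(q)$ of the per-cycle offspring pgf, found by Brent root-finding on
$q - G(q)$ bracketed in $[0, 1-10^{-9}]$ ($G$ is monotone and convex, so
the sub-1 root is unique for supercritical lineages; tolerance
$10^{-13}$). Deterministic growth produces non-integer pre-bottleneck
counts $m = e^{r(1+s)(\tau-t)}$; these enter the pgfs as real exponents --
$((1-D)+Dz)^m$ for binomial sampling, $\exp(mD(z-1))$ for Poisson -- which
avoids rounding artifacts and matches generating-function treatments of
non-integer cohorts. The `(per_time, stochastic, binomial)` variant
reproduces `fixation_rate_exact()` to quadrature tolerance, which pins the
two code paths against each other.

The historical optimum deserves a note. Under
`(per_transfer, deterministic, poisson)`, the weak-selection rate per
transfer is proportional to $D(\ln D)^2$, maximized at $D = e^{-2}$
(dilution ratio $e^2 \approx 7.39$, conventionally quoted as ${\sim}8{:}1$).
The full fixed-point treatment shifts the optimum with $\omega$ (to
$D^\* \approx 0.155$ at $\omega = 0.1$); since the analyses this variant
represents were first-order in $s$, the package evaluates the historical
optimum in the weak-selection regime ($\omega = 0.002$), where the argmax
converges to $e^{-2}$.

## Resource-explicit growth

`resource_params()` supplies Monod kinetics: per-cell division rate
$r_{\max} R/(k+R)$, one unit of resource consumed per division, fresh-media
concentration $R_0$. Within a phase the wild type and resource obey an
exact conservation $W + R = C$, which reduces the deterministic bulk
dynamics to the implicit closed form
$r_{\max} t = a\ln(W/W_0) + b\ln((C-W_0)/(C-W))$ with $a = (k+C)/C$,
$b = k/C$; `serial_equilibrium()` iterates the cycle map built on it to the
equilibrium pre-bottleneck size $N^\*$ (relative tolerance $10^{-10}$,
collapse reported as an `extinct` flag). With the resource depleted each
cycle, $N^\* \approx R_0$ regardless of $D$. The general adaptation-rate
formula replaces $r$ by the average growth rate
$\bar r = \ln(D^{-1})/\tau$ and $N$ by $N^\*$:
$\gamma \approx \tau^{-1}\mu N^\* \,\omega/(1+\omega)\,(\ln D)^2/(D^{-1}-1)$
(`fixation_rate_general()`), whose $D$-factor at fixed $\tau$ is maximized
at the root of $2(e^x-1) = xe^x$, $x = \ln(1/D)$: $D^\* = 0.2032$
(`optimal_D_fixed_tau()`).

At transfer the package models volumetric mixing,
$R \leftarrow D R_{\text{end}} + (1-D) R_0$ (a fraction $D$ of spent
culture into fraction $1-D$ fresh media); a `transfer = "replace"` switch
substitutes $R \leftarrow R_0$, and the two differ negligibly whenever the
resource is depleted at transfer.

`run_chemostat()` is the continuous-culture limit: outflow at per-capita
rate $\Phi$, resource inflow $\Phi R_0$, giving the textbook equilibrium
$R_{eq} = k\Phi/(r_{\max}-\Phi)$ and population $R_0 - R_{eq}$; dilution
rates at or above the maximum Monod rate are reported as washout, not
errors.

## Simulator design

The simulators do not tau-leap. Two exact transition laws carry all the
stochasticity that matters:

* a pure-birth process over any interval with integrated per-capita rate
  $L$ satisfies $X(t_1) = n + \mathrm{NegBin}(n, e^{-L})$ given
  $X(t_0) = n$ (the time-change property of the Yule process). Under Monod
  kinetics $L = (1+s)\ln(W(t_1)/W(t_0))$ along the deterministic wild-type
  curve, so a mutant lineage advances through an entire growth phase in one
  draw, exactly, even though its rate varies with the depleting resource;
* a linear birth-death process (the chemostat lineage: birth $\Phi(1+s)$,
  death $\Phi$) has the classical two-parameter transition law sampled by
  one binomial and one negative-binomial draw per interval.

Mutation events arrive as a Poisson process proportional to the realized
number of wild-type divisions, with origin times placed by inverse-CDF
sampling along the growth curve (for Monod growth, origins are uniform in
cumulative divisions, then mapped to times through the closed form). The
wild type itself is advanced by the same exact negative-binomial law in the
exponential model; in the resource model at large $N$ ($> 10^6$ cells,
where the coefficient of variation is below $10^{-4}$) the equilibrium
wild-type curve is computed once and reused, while a fully stochastic
stepping engine (`step_kinetics()`, Poisson division counts per adaptive
step, resource decremented integer-exactly and never negative) remains the
default for small populations and underlies the conservation and
equilibrium tests. A per-division Gillespie mode (`exact_mode`) validates
the phase-level laws on small populations; the two engines agree on the
size distribution of grown lineages, on single-lineage establishment
frequencies, and on whole-experiment rate estimates.

**Establishment criterion.** A lineage of size $n$ at a phase start is
classified as destined to fix once $V(0,s)^n < 10^{-6}$ (threshold exposed
in every config). The estimator counts mutations *arising* before `t_end`
that are destined to fix: after `t_end` the simulation continues without
new mutations until every segregating lineage resolves. A fixed-horizon
count would undercount by the establishment lag (roughly 10-20% at the
default scale); resolving the stragglers removes that censoring bias and
matches the quantity the rate integral defines.

**Reproducibility.** Every experiment takes one root seed; replicate $k$
runs on an independently derived seed, so results are bit-reproducible and
replicates are independent.

## The genotype (clonal interference) model

`run_genotype_experiment()` tracks genotype counts over bitmasks of a small
set of loci (default 10), with multiplicative fitness
$\prod_i (1+s_i)$ over mutated loci and per-locus, per-division mutation
probability (double mutations in one division, probability $O(\mu^2)$, are
ignored; there is no back mutation). Locus effects are drawn once per run
(quenched) from an exponential with mean $\omega$, or fixed via
`locus_effects`. Under the resource law all genotypes share one pool: the
phase's integrated Monod exposure is computed from the deterministic bulk
dynamics of the current mix, so fitter genotypes deplete the resource
faster and shorten everyone's growth window -- the mechanism by which
clonal interference slows adaptation here. The exponential law is retained
for short-horizon cross-checks against the single-lineage model (with an
overflow guard, since adaptation raises mean fitness above what a fixed
$D$ balances). A locus is *fixed* at allele frequency 0.99 (strict
fixation is asymptotic; threshold configurable) and *established* under
the same extinction-probability rule as the other simulators, which is the
cross-model comparable metric.

## Numerical choices

* Quadrature: nested adaptive integration, relative tolerance $10^{-9}$
  (outer $10^{-8}$), absolute $10^{-12}$; the effect integral is truncated
  at $s_{\max} = 40\omega$, where the exponential weight's tail mass is
  below $10^{-10}$ of the total; non-convergence is an error, never a
  warning.
* Optimizations over $D$ run on the $\ln D$ scale with bounded scalar
  search on $(10^{-6}, 1-10^{-6})$; ties on the flat shoulder near
  $D \to 1$ break toward larger $D$.
* $D \to 1$ (continuous culture) is always an analytic limit; plugging
  $D = 1$ into the $0/0$ forms is rejected at construction.
* Neutral lineages ($s = 0$) take $V = 1$ analytically (removable
  singularity).
* Counts are doubles; negative-binomial sampling switches to its Gaussian
  limit only above $10^6$ cells (relative error $< 10^{-3}$), binomial
  thinning above $2 \times 10^9$.

## Problem sizes

The test suite and the reproduction script run at desk scale, chosen so
Monte-Carlo error stays well inside each assertion's tolerance: 200-520
replicates of 50 h for the exponential-model comparisons (the source
figures used 1,000), 150 replicates x 150 cycles per grid point for the
24-hour resource optimum, and ~4,000 pooled establishments for the
fixed-effect ratio (minimum 500; the larger pool brings the ratio's
standard error to ~0.02). Statistical assertions use three-standard-error
bands or fixed seeds.

## What the simulations do and do not emulate

The generators implement the models faithfully -- stochastic division
timing, per-cell bottleneck survival, resource depletion, competition for
one pool -- so passing tests demonstrate internal consistency of theory and
simulation, not realism of the models. Known idealizations: no deleterious
or neutral mutations, no mutation from mutant backgrounds in the
single-lineage models, no density effects on the wild type beyond the
resource pool, fitness acts only through division rate (not yield, lag or
mortality), no recombination or epistasis in the genotype model, and
mutant frequencies are assumed small relative to $N$ wherever lineages are
treated as independent. The empirical question of how real cultures behave
between these regimes is outside the package's scope.
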