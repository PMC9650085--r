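---
title: "Modelling heteroplasmy, bottlenecks and the evolution of evolvability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heteroplasmy, bottlenecks and the evolution of evolvability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odnaevo)
```

## The scientific question

Mitochondria and plastids carry their own genomes (oDNA) in populations of
tens to thousands of copies per cell. A new, potentially beneficial oDNA
variant necessarily first appears as a minority type inside a cell — a
heteroplasmic state — and heteroplasmy itself often carries a fitness cost,
because mixed oDNA populations can compromise bioenergetic function. The
cost creates a *fitness valley* between the two homoplasmic optima: a
population adapted to one environment cannot reach the other optimum by
gradual enrichment of the new type without passing through penalised mixed
states. Germline "bottlenecks" — any mechanism that inflates
daughter-to-daughter variance in heteroplasmy — are a candidate route
across that valley: they turn modest within-cell heteroplasmy into
between-cell variance that selection can act on.

`odnaevo` is a two-scale stochastic simulator for this question: a
cell-level inheritance model (mutation and segregation kernels acting on
the mutant fraction $h$) nested in a population-level selection model. On
top sit an evolvable layer (the kernel parameters themselves heritable and
mutable), a three-type extension with dysfunctional oDNA, and an
experiment harness for replicate-averaged parameter sweeps.

## The inheritance model

Each cell carries $n$ oDNA copies (default 100) summarised by its mutant
fraction $h \in [0,1]$. A daughter's $h$ is her mother's transformed by two
normal perturbation kernels in fixed order, mutation then segregation,
each clamped to $[0,1]$:

$$h' = g_\sigma(g_\mu(h)).$$

*Mutation* ($g_\mu$): a draw from
$N\!\left(h + \mu(1-2h),\ \sqrt{\mu/n}\right)$. Per-molecule switching at
rate $\mu$ in both directions gives the drift towards $1/2$, and treating
the $n$ molecules as independent binomial switchers gives proportion
variance $\approx \mu/n$. We use the square-root (variance $\mu/n$) form by
default; a literal reading in which $\mu/n$ is the standard deviation is
available via `kernel_params(mut_sd = "linear")`. The square-root form is
the one consistent with the segregation kernel, where the analogous spread
term must be a variance (see below).

*Segregation* ($g_\sigma$): a draw from
$N\!\left(h,\ \sqrt{\sigma h(1-h)}\right)$ — the classical drift-variance
form. Parameterised this way, $\sigma$ *is* the per-generation normalised
heteroplasmy variance $V'(h) = V(h)/(h(1-h))$ for near-normal heteroplasmy
distributions, and is interpretable as the inverse of an effective
bottleneck size. `normalised_variance()` implements the $V'(h)$
diagnostic; for $h=0.5$ and $10^5$ draws it recovers $\sigma$ to within a
few percent on the raw kernel. Note that clamping biases the *clamped*
diagnostic low once $\sqrt{\sigma/4}$ is no longer small against the
distance to the boundaries (about $-12\%$ at $\sigma = 0.3$, $h = 0.5$);
the `clamp = FALSE` argument exposes the raw variates for moment checks.

Two structural properties follow and are enforced exactly. With $\mu = 0$
the mutation kernel is the identity, so a homoplasmic population has no
variance source whatsoever: segregation variance $\sigma h(1-h)$ vanishes
at $h \in \{0,1\}$, making homoplasmy absorbing. And values clamped to the
boundary are treated as exactly homoplasmic downstream — no tolerance
band.

## Fitness and selection

Each generation, the $N$ mothers (default 20) each produce
$N_\mathrm{off}$ daughters (default 2) by the kernels above; the next
generation of $N$ cells is drawn from the $N \times N_\mathrm{off}$
daughters with replacement, with probability proportional to fitness
(roulette-wheel selection). Mothers die each generation; there is no
selection among mothers before reproduction.

Fitness is sigmoidal and strictly inside $(0,1)$:

$$f(h; E, \epsilon) = \frac{1}{1 + e^{-2\,(f_E(h) + f_\epsilon(h))}},$$

with performance part $f_E(h) = -h$ in environment A (wildtype favoured)
and $+h$ in environment B (mutant favoured). Note the two environments are
*not* mirror images: the best attainable fitness is $1/2$ at $h=0$ in A
and $1/(1+e^{-2}) \approx 0.88$ at $h=1$ in B. The admixture penalty
$f_\epsilon$ has three shapes (`fitness_spec()`):

* **step** (default): $0$ at $h \in \{0, 1\}$, $-\epsilon$ at any mixed
  state — even slight heteroplasmy pays the full cost, the strongest form
  of the valley;
* **smooth**: $4\epsilon(h - \tfrac12)^2 - \epsilon$, agreeing with the
  step shape at $h \in \{0, \tfrac12, 1\}$;
* **threshold**: no cost up to a mutant fraction `threshold_h` (default
  0.2), $-\epsilon$ beyond it, modelling threshold-effect phenotypes in
  mtDNA disease where the phenotype appears only beyond a mutant load. We
  exempt the homoplasmic mutant $h = 1$ by default, matching the step
  variant's homoplasmy exemption; `exempt_mutant_homoplasmy = FALSE`
  penalises it instead, since either reading of "fitness constant until a
  given mutant proportion" is defensible.

$\epsilon \ge 0$ sets the valley depth. Empirical values are not
available, so sweeps scan it; $\epsilon$ larger than the performance gain
at small $h$ ($\epsilon > h$) is what makes leaving the wildtype optimum
initially deleterious.

Environment schedules (`env_schedule()`): a **switch** imposes environment
B from $t = 0$ on an A-adapted population (the adaptation experiments); a
**static** schedule never changes; an **oscillating** schedule flips every
$\tau$ generations, starting in B so that $t=0$ imposes the novel
environment (generation $t$ sees the start environment when
$\lfloor t/\tau \rfloor$ is even). *Adaptation time* is the first
generation at which the *population mean* $h$ strictly exceeds 0.75;
changing the threshold rescales times without reordering parameter
settings, which the test suite checks. Runs that never adapt are recorded
as censored and enter grid averages at $t_{\max}+1$, with censored counts
reported per pixel so fully-censored pixels are identifiable.

## The evolvable layer

To ask whether bottlenecking is itself an evolvable strategy, each cell
carries its own $(\mu_i, \sigma_i)$, both starting at 0. Daughters' $h$
values are transmitted with their *mother's* parameters; each daughter
then inherits the parameters perturbed by independent zero-mean normal
variates of standard deviation $\delta$ (the parameter-mutation rate,
default 0.005), clamped to $\mu_i \in [0, 0.2]$ and $\sigma_i \in [0, 1]$.
The $\sigma$ ceiling of 1 reflects its normalised-variance character; the
additive-normal perturbation is the simplest imperfect-inheritance model
consistent with parameters that "can themselves mutate", and is a design
choice — the quantitative outcomes below are sensitive to it. Selection
never sees the parameters directly; they hitchhike with the adaptive
success of the lineages carrying them.

## The dysfunctional-oDNA extension

For generality a third, purely deleterious oDNA class is supported:
off-target mutation converts functional molecules (either type) to a
dysfunctional class at rate $\mu_D = \alpha\mu$. The cell state becomes
$(h, h_D)$ with $h = m/(w+m)$ the mutant fraction among functional
molecules and $h_D = d/(w+m+d)$ the dysfunctional load. By the same
binomial moment-matching as the base kernels, one generation of conversion
gives $h_D$ a mean increment $\mu_D(1-h_D)$ with spread
$\sqrt{\mu_D(1-h_D)/n}$ — vanishing at $h_D = 1$, so total dysfunction is
absorbing — while the marginal kernel of $h$ is unchanged, because
conversion samples wildtype and mutant proportionally. Segregation
perturbs each coordinate independently with variance
$\sigma x (1-x)$; treating the two coordinates as uncorrelated is a
modelling choice. Fitness becomes $f_E(h) - h_D$ inside the sigmoid
(purely detrimental load); cells with $h_D = 1$ are non-viable and receive
fitness 0, and a run terminates flagged "extinct" if a whole daughter pool
is non-viable. With $\alpha = 0$ the extension reduces *exactly* — same
seeds, same trajectories — to the base model, which the suite asserts.

## Numerical and reproducibility choices

* Every stochastic routine draws from R's global RNG; run functions call
  `set.seed()` once with their configured seed, so trajectories are
  bitwise reproducible.
* Draws whose scale parameter is exactly zero are *skipped*, not drawn
  with `sd = 0`. Besides a small speed gain, this makes reduced models
  consume identical RNG streams, so the reduction equivalences
  ($\alpha = 0$ tri-state $\equiv$ base; $\delta = 0$ evolvable $\equiv$
  base with $\mu = \sigma = 0$) hold exactly rather than only in
  distribution.
* Replicate $r$ of sweep pixel $(i,j)$ under root seed $s$ uses
  `pixel_seed(s, i, j, r)` $= (s + 1299709\,i + 7907\,j + 104729\,r)
  \bmod (2^{31}-1)$, so any single sweep entry can be reproduced in
  isolation.
* Clamp-then-compare: homoplasmy tests use exact equality with 0 and 1
  after clamping; there is no epsilon band anywhere.
* Ties and degenerate inputs: `roulette_select()` requires a positive
  total weight (guaranteed by the sigmoid in the base model; the
  dysfunctional extension handles the all-zero case as extinction);
  `normalised_variance()` refuses homoplasmic founders, where the
  normalisation is undefined.

## What the simulations show — and problem sizes

The package's own test suite and acceptance script run at the default
study conditions ($N = 20$, $N_\mathrm{off} = 2$, $n = 100$,
$t_{\max} = 500$), with replicate counts of 10 for adaptation checks and
20–50 for evolutionary means; unit tests use shorter horizons (60–300
generations) where only mechanics are at stake. At these sizes the full
suite runs in well under a minute of simulation time; single 500-generation
runs take ~0.1 s (base) to ~0.5 s (evolvable).

Reproduced behaviours include: no adaptation ever at $\mu = 0$ (analytic);
a small bottleneck ($\sigma = 0.02$) carrying most replicates across a
deep valley ($\epsilon = 0.8$, $\mu = 0.005$) that is impassable without
segregation; mean adaptation time non-increasing in $\sigma$;
bottleneck-adapted populations concentrated at the homoplasmic optimum
while mutation-only populations stall in a heterogeneous intermediate
state near $h = 1/2$; and more segregation strength evolving under
fluctuating than static environments.

## Known limitations

* **$\delta$ sensitivity.** With the default $\delta = 0.005$, evolved
  segregation strength under an oscillating environment
  ($\tau = 100$, $\epsilon = 0.2$) averages $\approx 0.12$ after 500
  generations; parameter evolution is drift-dominated at this scale, and
  the $\epsilon$-dependence of evolved parameters is correspondingly
  flat. With $\delta = 0.01$–$0.02$ the same experiment yields evolved
  $\sigma \approx 0.28$–$0.44$, the range reported for normalised
  heteroplasmy variance in several empirical systems. The perturbation
  kernel and its scale are the least-constrained parts of the model, and
  quantitative conclusions about evolved parameter magnitudes should be
  read with that in mind.
* **Compensation direction.** In this implementation, when $\mu$ is fixed
  and only $\sigma$ evolves, evolved $\sigma$ *increases* with the fixed
  $\mu$: segregation is selected both for adaptation and as a
  heteroplasmy purifier, and both benefits grow with the heteroplasmy
  that mutation supplies.
* **Coarse graining.** The kernels pool all microscopic mechanisms
  (copy-number reduction, turnover, stochastic divisions) into two
  moment-matched normals; there is no molecule-level discreteness, no
  explicit germline development, no recombination or paternal leakage,
  and no mechanistic model of why admixture is costly.
* **Synthetic conditions.** All inputs are simulated under the stylised
  two-environment, single-locus world above; passing tests certify the
  model's internal behaviour, not quantitative agreement with any
  particular organism's oDNA dynamics.

## A worked example

```{r example, fig.width = 7, fig.height = 4}
cfg <- sim_config(kernel = kernel_params(mu = 0.005, sigma = 0.02),
                  fitness = fitness_spec(epsilon = 0.8), seed = 1)
traj <- run_simulation(cfg)
glance(traj)
autoplot(traj)
```

A deep valley ($\epsilon = 0.8$) at a low mutation rate is crossed within
~50 generations once a modest bottleneck ($\sigma = 0.02$) is present;
rerun with `sigma = 0` to watch the same population stay pinned at
$h = 0$ for all 500 generations.
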