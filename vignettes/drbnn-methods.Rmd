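---
title: "Dose-response association mapping with Bayesian neural networks: models and methods"
author: "drbnn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response association mapping with Bayesian neural networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drbnn)
```

## The problem

In cell-based pharmacogenomic studies a compound is applied to cell
lines (for example lymphoblastoid cell lines) across $k$ increasing
concentrations, and a quantitative response — viability, ATP content,
expression — is measured at each dose. Association mapping then asks
which of $p$ genotyped SNPs (coded additively as 0/1/2 copies of the
minor allele) drive the response profile. Testing the full $k$-vector of
responses per individual is substantially more powerful than collapsing
the curve to a summary such as the IC50, but the standard multivariate
linear test only detects *marginal* (single-locus) effects. When loci
act through gene–gene interaction (epistasis), two questions arise: how
much does a single-locus multivariate scan still see, and can a more
flexible model detect interacting loci directly without enumerating
pairs? `drbnn` implements both tools — a per-SNP MANOVA scan and a
Bayesian neural network (BNN) with automatic relevance determination —
together with the two-locus simulation models and the closed-form
marginal-effect analysis needed to study them.

## Simulation models

The baseline mean curve is a unit-asymptote hill-slope function of the
concentration $x_k$,
$$\mu_k = 1 - \frac{1}{1 + x_k^{-1.5}},$$
evaluated on a six-point grid. Two grids are supported, because the
natural reading of the study grid, $x = 10^{-4}\cdot\{0.03125, 0.0625,
0.10, 0.25, 0.5, 1.25\}$, puts every concentration far below the unit
IC50 so that $\mu_k \approx 1$ at all doses (a nearly flat curve, within
$10^{-3}$ of 1); dropping the $10^{-4}$ factor (`defaultDoseGrid(unitScale
= TRUE)`) yields a realistically sloping curve from $0.9945$ down to
$0.4171$. The default is the literal grid; since every analysis
standardizes each dose column, the two choices are nearly equivalent for
power purposes and the flag exists mainly for realistic display.

Responses for individual $i$ at dose $k$ are generated as
$$y_{ik} = \mu_k\,\bigl(m(S_{1i}, S_{2i}) + \epsilon_{ik}\bigr),$$
with the noise-free multiplier $m$ given by one of three two-locus
architectures in terms of the minor-allele counts $S_1, S_2 \in
\{0,1,2\}$ and an effect size $\theta \in [0,1]$:

| model | multiplier $m(S_1, S_2)$ |
|---|---|
| additive | $1 + \frac{\theta}{2} S_1 - \frac{\theta}{2} S_2$ |
| additive + interaction | $1 + \frac{\theta}{2} S_1 - \frac{\theta}{2} S_2 + \frac{\theta}{2} S_1 S_2$ |
| interaction only | $1 + \frac{\theta}{2} S_1 S_2$ |

One locus increases and the other decreases the response. Genotypes are
drawn as Binomial(2, MAF) — Hardy–Weinberg proportions, no linkage
disequilibrium, loci independent. The default study conditions are 2000
individuals and 998 background SNPs with MAFs uniform on $[0.01, 0.5]$,
plus the two causal loci placed (and recorded in truth metadata) at the
first two columns.

Two conventions deserved explicit decisions:

* **Noise scale.** The generating description $\epsilon \sim N(0, 0.1)$
  is ambiguous between variance $0.1$ and standard deviation $0.1$. The
  package default is **sd = 0.1** (`noiseIsSd = TRUE`), because only
  that reading reproduces the reported behaviour of the methods under
  study: with variance $0.1$ the multivariate scan's power to detect
  both causal loci at $\theta = 0.05$, MAF $0.3$, $n = 2000$, $p = 1000$
  is only about $0.6$, while with sd $0.1$ it is essentially 1 — the
  "good power across parameter combinations" regime. The literal
  variance reading remains available via `noiseIsSd = FALSE`.
* **Noise sharing.** $\epsilon_{ik}$ is drawn independently per
  individual *and per dose column*. The generating notation indexes the
  observation by dose but the noise term carries no dose index; we chose
  independent-per-dose noise, the variant under which the multivariate
  test's gain from combining doses is conservative (a shared
  $\epsilon_i$ would be absorbed into the response correlation).

Because these defaults are the simulator's definition of the study
conditions, they are fixed once here and not tuned per experiment.

What the generator deliberately does **not** emulate: linkage
disequilibrium and population structure, covariates (batch, growth
conditions), missing or imputed genotypes, more than two causal loci,
and non-Gaussian measurement error. Passing tests therefore demonstrate
correctness of the methods under idealized genetics, not robustness to
the confounding structure of real cell-line panels.

## The MANOVA comparator

For each marker the $k$ dose responses are regressed jointly on the
additively coded genotype plus an intercept (and optional numeric
covariates) by least squares, and the genotype coefficient vector is
tested with Wilks' lambda. For this single-degree-of-freedom hypothesis
the Rao F transform is exact,
$$F = \frac{1 - \Lambda}{\Lambda}\cdot\frac{n - k - 1}{k}
  \sim F_{k,\,n-k-1} \text{ under } H_0,$$
and all four classical multivariate statistics give identical p-values
(the Pillai trace is offered as an alternative statistic label). The
genotype is treated as a 1-df numeric covariate, matching the linear
coding of the model being tested, rather than as a 2-df factor.
Selection uses Bonferroni: marker $j$ is called when $p_j <
\alpha/p_\mathrm{tested}$ with $\alpha = 0.05$ by default. Monomorphic
or collinear markers are skipped with a warning and excluded from both
testing and the Bonferroni denominator. The implementation is a direct
cross-product computation (fast enough for thousands of markers at $n =
2000$), validated in the test suite against `stats::lm` +
`anova.mlm` to $10^{-10}$ and against the univariate F test at $k = 1$.

## The Bayesian neural network

The network has one hidden layer of $H = 10$ logistic units,
$$h_j(x) = \mathrm{logit}^{-1}\!\bigl(a_j + x^\top w_j\bigr), \qquad
  f_k(x) = \alpha_k + \sum_{j=1}^{H} h_j(x)\,\beta_{kj},$$
with one output per dose. Responses are standardized per dose column and
given an independent Gaussian likelihood with mean $f_{ik}(x_i)$ and
unit variance; there is no free noise-variance parameter. With small
hidden weights the logistic is locally affine, so the network nests the
linear model MANOVA tests (verified to $O(\lVert w\rVert^2)$ in the test
suite); with larger weights it represents interactions without
enumerating pairs.

The prior is the automatic relevance determination (ARD) hierarchy: all
hidden-layer weights fanning out of input SNP $j$ share a scale,
$$w_{jh} \sim N(0, \sigma_j^2), \qquad
  \sigma_j^2 \sim \mathrm{InvGamma}(3, 1),$$
so an input only obtains large weights by inflating its own
$\sigma_j^2$, and the posterior of $\sigma_j^2$ measures the SNP's
relevance. Output weights share a single scale $\tau^2 \sim
\mathrm{InvGamma}(0.1, 0.1)$. Biases receive a fixed broad $N(0, 5^2)$
prior (the source framework leaves this open; broad-and-proper is the
conservative choice). The ARD scales are kept as explicitly sampled
parameters — not marginalized — because the selection procedure needs
their posterior draws; sampling uses the unconstrained coordinates
$\log\sigma_j^2$, $\log\tau^2$ with the Jacobian folded into the
target density.

### Sampling

The posterior is explored with Hamiltonian Monte Carlo: identity mass
matrix, leapfrog integration (step size 0.02, 20 steps), partial
momentum refresh $p \leftarrow \gamma p + \sqrt{1-\gamma^2}\,\xi$ with
persistence $\gamma = 0.75$, 375 iterations with the first 25 discarded
as burn-in, and Metropolis correction with momentum negation on
rejection — the combination required for the persistent-momentum
variant to leave the target invariant. Gradients are exact analytic
backpropagation, validated against central finite differences to
relative error $10^{-5}$.

**Annealing.** Burn-in uses an annealing temperature decaying
geometrically from $T_0 = 1000$ to 1 at the last burn-in iteration. What
the temperature should act on was a genuinely open design point, and the
obvious choice fails: dividing the log-likelihood by $T$ flattens the
data term so thoroughly that the early chain decouples from the data,
wanders into saturated-weight configurations whose curvature exceeds the
step-size stability limit, and — once $T$ reaches 1 — rejects every
trajectory thereafter (we observed chains permanently frozen at
acceptance $\approx 0.06$ in half of the replicates). The package
instead applies the temperature to the **Metropolis test**: proposals
always follow the exact posterior dynamics, but during burn-in a move is
accepted with probability $\exp(-\Delta H / T_t)$. Early iterations can
cross energy barriers, the kernel is exactly posterior-invariant from
the end of burn-in onward, and all recovery replicates pass. With this
scheme acceptance rates on the study conditions run at roughly
0.25–0.7.

Two practical notes on fixed-settings HMC. First, a fixed trajectory
length can resonate with a target's period (at half the period of a
Gaussian coordinate the trajectory degenerates to a sign flip); the test
suite picks non-resonant lengths for its Gaussian checks, and the
persistence mechanism mitigates this on real targets. Second, a stuck
chain (50+ consecutive rejections) is reported as a warning with a
tuning hint rather than an error, since it is a tuning symptom, not a
programming failure.

### Scoring SNPs

The selection rule turns ARD posteriors into probabilities: a null
reference threshold is the 95th percentile of $\sigma_j^2$ draws pooled
across all inputs — either from the primary run (`pooled`, cheap, valid
when causal inputs are sparse) or from a re-run on row-permuted
responses (`permutation`, assumption-free). The posterior probability of
involvement for SNP $j$ is the fraction of post-burn-in draws with
$\sigma_j^2$ above the threshold, and a SNP is called causal when that
probability exceeds 0.4. Both the quantile and the null mode are
configurable; the concrete construction instantiates a framework whose
original description specifies only the comparison concept and the 0.4
cut-off.

## Marginal effects of two-locus models

Why does a marginal-effect method retain power on a purely interactive
architecture? Write $p_{xy}$ for the proportion of individuals with $x$
minor alleles at $S_1$ and $y$ at $S_2$, and consider the
$S_1$-aggregated mean response at a fixed $S_2$ level, e.g. under the
additive model $E[y] = \beta_1 S_1 + \beta_2 S_2$:
$$\mu_A(S_2{=}1) = \beta_1 (p_{11} + 2p_{21}) +
                   \beta_2 (p_{01} + p_{11} + p_{21}).$$
`marginalEffect()` implements these closed forms for all three
architectures and both weighting conventions — the joint-weight form
above (`as_printed`) and the textbook conditional expectation that
divides by the column mass (`conditional`); the two differ exactly by
that factor, so all magnitude comparisons are invariant to the choice.
Every closed form is verified against `bruteForceMarginal()`, a direct
enumeration over $S_1$, to $10^{-12}$ — the enumeration is the
authority, and one consequence is worth stating: at the simulation
effect sizes $\beta_1 = \beta_3 = \theta/2$, $\beta_2 = -\theta/2$ the
correct $S_2{=}1$ marginal under the additive-plus-interaction model is
$-\tfrac{\theta}{2}(p_{01} - p_{11} - 3p_{21})$ (at $\theta = 0.04$,
MAFs 0.2: $-0.00128$), not the slightly different expression sometimes
quoted from hand simplification.

Two findings follow and are reproduced by `buildMarginalTables()`:

* **Attenuation.** At $S_2 = 0$ the interaction contributes nothing and
  $\mu_{AI} = \mu_A$ exactly. At $S_2 \in \{1,2\}$ the interaction term
  opposes the negative $S_2$ main effect, so $\lvert\mu_{AI}\rvert <
  \lvert\mu_A\rvert$ — the second locus becomes harder to see. This
  inequality is **regime-dependent**, not universal: under
  Hardy–Weinberg genotype frequencies it holds at $S_2=1$ exactly when
  the $S_1$ MAF is below $1/3$ (and at $S_2=2$ below $1/2$), and for
  arbitrary strictly positive tables it can reverse. The package
  therefore computes the relation column from the actual magnitudes
  (`eq`/`lt`/`gt`) instead of asserting a fixed symbol, and the test
  suite demonstrates both the low-MAF regime where attenuation holds and
  a MAF-0.45 example where it flips — which is also the regime where the
  scan's power on the interacting model degrades.
* **Induced marginals.** The purely interactive model has $\mu_I = 0$ at
  $S_2 = 0$ but $\mu_I = \tfrac{\theta}{2}\, s\,(p_{1s} + 2p_{2s})
  \neq 0$ at $S_2 = s > 0$ whenever those cells have mass: the discrete
  genotype coding manufactures marginal effects out of a model that
  nominally has none. This is why the single-locus scan detects at
  least one locus of a purely epistatic pair in the majority of
  replicates at moderate MAF.

## Power harness

`runPowerSweep()` estimates, per $(\theta, \mathrm{MAF})$ cell and
method, the probability of detecting both causal loci and at least one,
as the fraction of replicate datasets in which the causal column is in
the method's selected set — background false positives do not disqualify
a detection. Replicate seeds are derived from the base seed and the
cell's parameter values (not its grid position) through a counter-based
hash, so every cell's result is independent of which other cells are in
the sweep and the whole table is bit-reproducible. The full-scale study
grid ($5\ \theta \times 7$ MAF $\times$ 100 replicates $\times$ 3 models
with 375-iteration chains) is cluster-scale; the package's tests and
acceptance script run single cells at 10–20 replicates with $n = 2000$
and $p = 1000$ (MANOVA) or $p = 50$ (BNN), sizes chosen so the whole
suite completes on one desktop CPU while still estimating power with
binomial standard error $\le 0.11$.

## Numerical choices and degenerate inputs

* Wilks' lambda is computed as $1/(1 + h^\top E^{-1} h)$ with $E$ the
  residual cross-product matrix; a singular $E$, a monomorphic marker,
  or a marker collinear with covariates raises a structured
  degenerate-marker condition that scans catch and log.
* Standardization refuses constant response columns (no variance to
  scale) with an explicit error.
* Leapfrog trajectories with non-finite gradients or coordinates are
  flagged divergent and rejected as proposals rather than propagating
  NaNs.
* The inverse-gamma prior terms are evaluated in log-scale coordinates,
  $a\log b - \log\Gamma(a) - a u - b e^{-u}$ with $u = \log\sigma^2$
  (Jacobian included), which is finite for all real $u$ — there are no
  positivity boundaries for the sampler to hit.
* Ties and near-ties in the relation columns are resolved with an
  absolute tolerance of $10^{-12}$ on the magnitude difference.
* File readers validate the genotype domain {0,1,2} and numeric
  responses and report the offending line; the VCF importer restricts to
  biallelic sites, determines the minor allele from the sample allele
  frequency, and refuses missing genotypes rather than imputing.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
d <- simulateDataset(
  simulationDesign(nIndividuals = 2000, nBackgroundSnps = 48, seed = 11),
  geneticModelSpec("additive", theta = 0.05, causalMaf = 0.3))

scan <- manovaScan(d, normalizeResponses(responses(d)))
selectedMarkers(scan)

ps <- bnnSample(d, settings = hmcSettings(seed = 11))
imp <- scoreSnps(ps, nullReference(ps, "pooled"), cutoff = 0.4)
head(imp[order(-imp$posterior_probability), ])
```

## Known limitations

* The sampler uses the study's fixed tuning (no step-size or mass
  adaptation, single chain); badly scaled problems outside the intended
  regime can mix slowly, and the package reports rather than repairs a
  stuck chain.
* The pooled null reference assumes causal inputs are sparse; with many
  true signals it inflates the threshold and the permutation mode should
  be used.
* The 0.4 probability cut-off is a decision rule, not an
  error-rate-calibrated threshold; no FDR control is claimed.
* Only two causal loci, additive coding and one hidden layer are
  supported — deeper epistatic networks are out of scope.
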