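---
title: "MMMC models for social-network and group dependences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MMMC models for social-network and group dependences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmmmc)
```

## The problem

School-based adolescent surveys collect an individual outcome (here a
continuous, standardized measure such as academic attainment), individual
covariates (sex, ethnic group, age), group memberships (school, area of
residence) and friendship nominations. Each of these structures induces
dependence among responses, and each literature has historically modelled
its own: multilevel models handle schools and areas but ignore networks;
network autocorrelation models handle the network but can only absorb
groups as fixed effects. This package implements the joint treatment: the
network enters a multilevel model as one or more additional
*classifications* of the population, so the relative share of variation at
the individual, network, school and area levels is directly estimable.

## From nominations to classifications

Nomination data arrive as adjacency lists (each ego names up to a capped
number of friends per sex; in-sample alters only are retained, which
creates *sample isolates*). `parse_adjacency_list()` builds the binary
nomination matrix $D$ ($d_{ij} = 1$ iff $i$ nominates $j$; zero diagonal),
and `symmetrize()` the undirected $D^*$ ($d^*_{ij} = \max(d_{ij},
d_{ji})$) used for clique analysis.

Three network classifications are supported:

* **Ego-nets.** One random effect per individual-as-network-member;
  individual $i$'s response loads, with equal weights $1/n_i$, on the
  effects of the $n_i$ alters $i$ nominates (the ego is excluded from
  their own ego-net). Under equal weights this weight matrix *is* the
  row-standardized $D$, which is deliberate: the multiple-membership
  ego-net model and the network disturbances model then use literally the
  same weight information and are directly comparable.
* **Clique-2 and clique-3.** Maximal completely connected subgroups
  (Luce–Perry cliques) of $D^*$, enumerated by Bron–Kerbosch (via igraph)
  with a canonical ordering so runs are byte-identical. When both enter
  one model, the clique-2 classification holds maximal dyads only and
  clique-3 the cliques of size $\ge 3$ — a partition of the maximal clique
  set. Cliques of minimum size 4 are typically too rare in sampled
  networks to model separately and are not split out.
* **School and area.** Single-membership classifications (one weight
  of 1 per row).

Weighting schemes: `equal` ($1/n_i$; nonzero rows sum to exactly 1),
`unit` (all memberships weight 1), and `inv_sqrt` ($1/\sqrt{n_i}$). The
sensitivity schemes are applied to network classifications only — for a
single-membership classification all three coincide. Isolates keep
all-zero weight rows under every scheme, which is statistically harmless:
they simply receive no network random effect. Duplicate nominations
collapse to a single tie.

## The MMMC model and its sampler

$$y_i = \mathbf{x}_i'\boldsymbol\beta + \sum_k \sum_{j \in k(i)}
w^{(k)}_{ij} u^{(k)}_j + e_i, \qquad
u^{(k)} \sim N(0, \sigma^2_k I), \quad e_i \sim N(0, \sigma^2_e),$$

with random effects independent across classifications a priori. Priors:
flat on $\boldsymbol\beta$; Gamma($a$, $b$) on each precision with the
conventional diffuse default $a = b = 0.001$ (configurable). Defaults are
a 20 000-draw chain with 2 000 burn-in; the examples and tests in this
package use shorter chains (3 000–8 000 draws, 800–1 000 burn-in), which
the interweaving move below makes sufficient for the effective sample
sizes reported alongside every summary.

Each Gibbs sweep draws:

1. $\boldsymbol\beta \mid \cdot \sim N(\hat{\boldsymbol\beta}_{\text{OLS}}(r),
   \sigma^2_e (X'X)^{-1})$ for the current partial residual $r$;
2. each block $u^{(k)}$ jointly from its multivariate Normal conditional
   with sparse precision $Z_k'Z_k/\sigma^2_e + I/\sigma^2_k$, via a
   permuted sparse Cholesky factorisation whose symbolic analysis is
   reused across iterations (a single-site Gauss–Seidel-style update is
   also implemented as a cross-check; both target the same posterior);
3. $1/\sigma^2_k \sim \text{Gamma}(a + K_k/2,\; b + u^{(k)\prime}u^{(k)}/2)$;
4. $1/\sigma^2_e \sim \text{Gamma}(a + n/2,\; b + \text{SSR}/2)$.

**Interweaving.** Network variance components in sparse sampled networks
are weakly identified: each effect is informed by roughly one nomination,
so the centered draws (2)–(3) leave $u^{(k)}$ and $\sigma^2_k$ strongly
coupled and the variance chain moves as a random walk. After step (3) the
sampler therefore applies an ancillarity–sufficiency interweaving move:
writing $u^{(k)} = \sigma_k z$, it redraws $\sigma_k$ from its conditional
given $z$ (a one-dimensional slice sampler on $\log \sigma_k$, stepping-out
variant) and rescales the block. This is an additional valid MCMC move on
the same posterior; on generator-default data it raises the ego-net
variance ESS by more than an order of magnitude.

Structurally empty effect columns (individuals never nominated, in the
ego-net classification) are dropped before sampling — they are prior-only
and would merely slow variance mixing — while the user-facing weight
matrix keeps all columns so the identity with row-standardized $D$ holds.

Starting values: $\boldsymbol\beta$ at OLS, variance components at an
equal split of $\mathrm{var}(y)$. Results at the chain lengths used here
are insensitive to these choices; the summaries' ESS column is the
diagnostic to watch.

**DIC.** Deviance $D(\theta) = n \log(2\pi\sigma^2_e) + \sum_i (y_i -
\mu_i)^2 / \sigma^2_e$ with $\mu_i$ the full fitted mean;
$\mathrm{DIC} = 2\bar D - D(\bar\theta)$ and $p_D = \bar D -
D(\bar\theta)$, where the plug-in $\bar\theta$ uses posterior means of
*all* parameters, including every random effect (the convention of the
standard multilevel MCMC software). Alternative plug-ins are out of scope.

## Variance partition with average weights

A multiple-membership component contributes $\sigma^2_k \sum_j w_{ij}^2$
to individual $i$'s variance, so raw components across classifications of
a standardized response sum to more than 1 and are not comparable.
Averaging over individuals (isolates included as zeros) gives the factor
$f_k = n^{-1}\sum_i \sum_j w_{ij}^2$ — under equal weights, the mean of
$1/n_i$ — and the average contribution $A_k = \sigma^2_k f_k$. Shares are
reported against the factor-adjusted total $\sigma^2_e + \sum_k A_k$
rather than the raw sum, because the raw sum systematically exceeds 1 for
MM models; both totals are printed so the "adjusted total $\approx$ 1"
diagnostic for a standardized response stays visible. For single
membership $f_k = 1$ exactly.

## Network autocorrelation models

For comparison, maximum-likelihood fits of the network effects model
$(I - \rho_1 W_1) y = X\beta + \epsilon$, the network disturbances model
$y = X\beta + \delta$, $\delta = \rho_2 W_2 \delta + \epsilon$, and the
combined model with both transforms. $\beta$ and $\sigma^2$ are profiled
analytically (OLS/GLS; ML $\hat\sigma^2 = \mathrm{RSS}/n$, with the
$(n-p)$-divisor alternative also reported as `sigma2_df`), and the profile
likelihood is maximised over $\rho$ on the open interval $(-1, 1)$ — the
admissible region for a row-standardized $W$, whose eigenvalues have
modulus at most 1; positivity of $\det(I - \rho W)$ is verified at every
evaluation and a boundary optimum is flagged. A coarse grid brackets the
optimum before golden-section refinement, guarding against a secondary
mode; the combined model starts from the two one-parameter fits and uses
L-BFGS-B. Log-determinants use sparse LU factorisations. Standard errors
come from the inverse numerical observed information of the full
$(\rho, \beta, \sigma^2)$ likelihood, and $\mathrm{AIC} = 2k - 2\ell$ with
$k = p + \#\rho + 1$.

The MM-vs-ND workflow (`run_mm_vs_nd()`) mirrors the standard comparison:
schools enter both models as fixed indicator variables (reference: the
first school in sort order), the network enters both random parts through
the same row-standardized matrix, and the output is a side-by-side
coefficient table with DIC (MCMC) and AIC (ML).

## The synthetic generator

Since comparable nomination data sets are typically restricted-access,
every stage is exercised on simulated populations whose defaults emulate
the structure such a study exhibits: 968 individuals in 10 near-equal
schools; 13 areas with each school mapped to a home area and a 3%
crossing rate, so areas are uneven and nearly nested in schools; 52%
female, 17% black; age Normal(14.76, 1.5²) truncated to [10, 19] and
centred before model use. Out-degrees come from a Poisson whose mean is
calibrated so non-isolates average 1.8 nominations, thinned to a 39%
isolate fraction in expectation — thinning emulates out-of-sample
nominations rather than modelling an explicit superpopulation network,
since the analysis only ever sees the in-sample restriction — and capped
at 10 (5 per sex). Alters are drawn with a log-odds preference for
same-school (3) and same-sex (0.7) alters, chosen so the large majority
of ties stay within school, as in school-based sampling. Generating
response parameters default to the magnitudes typical of fitted
standardized-attainment models (individual ≈ 0.87, network ≈ 0.15,
school/area ≈ 0.03–0.05, $\rho$ = 0.10).

Responses are simulated under the MMMC model ($y = X\beta + \sum_k Z_k
u_k + e$, then standardized, with the truth recorded on both scales — the
centring is absorbed into the intercept and components divide by the
realized variance) or under the autocorrelation models via
$(I-\rho W)^{-1}$ solves.

What the generator does *not* emulate: degree heterogeneity beyond
Poisson thinning, transitivity/clustering beyond what homophily induces,
selection (network formation depending on the outcome), measurement error
in nominations, and longitudinal co-evolution. Passing recovery tests on
these data therefore show the estimators are correct for the model they
fit, not that real friendship data satisfy that model.

## Numerical choices and degenerate inputs

* Node order is the order of first appearance; all matrices are indexed
  internally by position with ids preserved on I/O. Cliques are sorted
  canonically (members by node order, cliques lexicographically).
* Out-of-sample alters are dropped with a count recorded in
  `attr(net, "n_dropped")`; a flag errors instead. Self-nominations are
  always removed; duplicate egos are an error naming the id.
* Equal-scheme rows sum to 1 exactly (the weights are constructed as
  $1/n_i$, not normalised floating sums); zero rows stay exactly zero.
* An all-zero weight matrix classification triggers a warning and
  contributes nothing; a rank-deficient fixed design is an error.
* $(I - \rho W)$ singular or with non-positive determinant raises an
  error naming $\rho$.
* All simulation, fitting and workflow functions take explicit seeds and
  are bit-reproducible; grid and comparison workflows attach a manifest
  (seed, chain settings, problem sizes) to their output.

## Known limitations

* **Prior sensitivity of weakly identified components.** On
  generator-default data the marginal likelihood for the ego-net variance
  is nearly flat over a wide interval, so the diffuse Gamma(0.001, 0.001)
  precision prior — whose density diverges at zero variance — pulls the
  posterior for that component toward zero relative to the likelihood
  peak. Interval estimates remain calibrated (the recovery tests check
  95% credible-interval coverage), but point estimates of network
  variance components from sparse sampled networks should be read
  together with their intervals, and the prior hyperparameters are
  exposed precisely so users can assess sensitivity. Relatedly, the
  factor-adjusted shares need not total exactly 1 for a standardized
  response; no correction is attempted.
* Continuous responses only; no random slopes, no correlated random
  effects across classifications, no binary-response autocorrelation
  models, no multiplex or longitudinal networks.
* The network is assumed exogenous to the response: these are
  variance-decomposition models, not models of selection or influence.
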