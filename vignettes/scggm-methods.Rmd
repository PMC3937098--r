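---
title: "Sparse conditional Gaussian graphical models for gene networks under SNP perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse conditional Gaussian graphical models for gene networks under SNP perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scggm)
```

## The model

`scggm` estimates a gene network jointly with the genetic variants
that directly perturb it.  Expression traits $y \in \mathbb{R}^p$
conditional on genotypes $x \in \mathbb{R}^q$ follow a conditional
Gaussian graphical model (CGGM)

$$
p(y \mid x) \;=\; \frac{1}{Z(x)}
  \exp\!\left(-\tfrac12 y^\top \Lambda y - x^\top \Theta y\right),
\qquad
\log Z(x) = \tfrac12 x^\top \Theta \Lambda^{-1} \Theta^\top x
          + \tfrac{p}{2}\log 2\pi - \tfrac12 \log\det\Lambda .
$$

$\Lambda$ ($p \times p$, positive definite) is the precision matrix of
expression conditional on genotype: its nonzero off-diagonals are
conditional-dependence edges of the gene network.  $\Theta$
($q \times p$) holds direct SNP-to-gene interaction weights: a
nonzero entry makes the SNP a direct eQTL of that gene, over and
above anything transmitted through the network.  Completing the
square shows the conditional distribution is Gaussian with mean
$B^\top x$ and covariance $\Sigma$, where

$$
B = -\Theta\Lambda^{-1}, \qquad \Sigma = \Lambda^{-1}.
$$

$B$ collects *total* SNP effects — direct perturbations plus their
propagation through the network — which is what a per-gene regression
would estimate.  Separating $\Theta$ (sparse, mechanistic) from $B$
(denser, phenomenological) is the point of the parameterization.

**Sign convention.** We fix the interaction term as
$-x^\top\Theta y$, so $B = -\Theta\Lambda^{-1}$.  The opposite
convention merely flips the sign of $\Theta$ and leaves every support
statement, penalty and fitted conditional mean unchanged; we state it
once here and use it everywhere, including the simulators.

**Preprocessing.** The zero-mean form above assumes each expression
trait is mean-centered and each genotype column is standardized to
mean 0, variance 1.  `scggm()` applies both by default.  A constant
genotype column is an error rather than silently dropped: it carries
no signal and dropping it would desynchronize SNP identifiers.
Data sets with fewer than two samples are rejected.

## Estimation

Both parameter blocks are estimated at once by the convex program

$$
\min_{\Lambda \succ 0,\, \Theta}\;
  \ell(\Lambda, \Theta)
  + \lambda_{\text{net}} \|\Lambda\|_{1,\text{off}}
  + \lambda_{\text{perturb}} \|\Theta\|_1 ,
$$

where $\ell$ is the *per-sample* negative log-likelihood
$$
\ell = \tfrac12\operatorname{tr}(\Lambda S_{yy})
+ \sum_{ij} \Theta_{ij} (S_{xy})_{ij}
+ \tfrac12\operatorname{tr}(\Theta\Lambda^{-1}\Theta^\top S_{xx})
- \tfrac12\log\det\Lambda + \tfrac{p}{2}\log 2\pi ,
$$
with $S_{xx} = X^\top X/n$, $S_{yy} = Y^\top Y/n$,
$S_{xy} = X^\top Y/n$ the sufficient statistics (the middle term is
the sample average of $x^\top\Theta y$).  Dividing by
$n$ makes penalty scales comparable across sample sizes, so a
cross-validation grid transfers between studies; this matches the
common graphical-lasso convention.  The diagonal of $\Lambda$ is not
penalized.  The $-\log\det\Lambda$ term diverges at the boundary of
the positive-definite cone and acts as a barrier, so no explicit
constraint is needed.

Two limits connect the joint fit to classical sparse methods and are
used as internal baselines: a very large $\lambda_{\text{perturb}}$
forces $\Theta = 0$ and leaves a graphical-lasso-style network
estimate from $S_{yy}$ alone; a very large $\lambda_{\text{net}}$
forces $\Lambda$ diagonal and leaves per-gene lasso-style regressions.
`fit_two_stage()` combines the two as the decoupled alternative that
the joint estimator is compared against.

### The solver

The objective is smooth-plus-L1, so we use an accelerated
proximal-gradient scheme with two Nesterov sequences:

1. gradient step from the extrapolated point, then elementwise
   soft-thresholding (`prox_l1`; the $\Lambda$ diagonal is skipped),
   with the $\Lambda$ block symmetrized;
2. backtracking line search (step halved, factor 0.5) on the
   composite quadratic upper bound; a trial $\Lambda$ that fails a
   Cholesky factorization is treated as objective $+\infty$ and the
   step is halved — positive definiteness is maintained by rejection,
   never by eigenvalue projection, so accepted iterates are exact;
3. monotone restart: if the accelerated step would increase the
   objective, momentum is dropped and the iteration repeats from the
   current iterate (a plain proximal step cannot increase the
   objective, so one restart always suffices);
4. the step size is allowed to grow back by one backtracking factor
   per iteration, so a single conservative line search does not
   permanently slow the fit.

Accepted objectives are therefore non-increasing — asserted on every
test fit.  Initialization is $\Lambda^{(0)} = I$, $\Theta^{(0)} = 0$;
by convexity the optimum does not depend on it.  Convergence is
declared when the relative objective change stays below `tol`
(default $10^{-6}$) for three consecutive accepted iterations; the
momentum ramp-up can stall the objective for an iteration or two long
before the optimum, and the three-in-a-row rule makes the stopping
test robust to that plateau at negligible cost.  `max_iter` defaults
to 2000.  `scggm_kkt_residual()` reports the maximum violation of the
subgradient optimality condition, which the test-suite checks against
an independent quasi-Newton reference solver.

### Penalty selection

`scggm_cv()` performs $k$-fold cross-validation (default grids are
log-spaced over $[10^{-3}, 1]$, appropriate for standardized inputs).
Folds are contiguous blocks of a seeded random permutation, so fold
assignment is reproducible.  Each training block is centered and
standardized, and its statistics are reused to transform the held-out
block — never the other way around.  The CV error is the mean squared
error of the conditional-mean prediction $B^\top x$ per sample and
per gene; held-out negative predictive log-likelihood is available
via `metric = "loglik"`.  Squared prediction error was chosen as the
default because it matches the package's test-set metric; any
positive rescaling of either metric preserves the selected pair.
Ties break toward the larger $\lambda_{\text{net}} +
\lambda_{\text{perturb}}$, i.e. the sparser model.  Paths over the
grid are warm-started from the previous solution, which saves
iterations without changing solutions beyond the stopping tolerance.

Prediction-error CV is conservative about network edges: the
conditional mean depends on $\Lambda$ only through $B$, so when few
genes are directly perturbed the selected $\lambda_{\text{net}}$ can
be large and the reported network sparse.  This is a property of the
selection criterion, not of the estimator; users who care primarily
about network recovery should inspect the CV surface
(`autoplot(cv)`) or use the predictive-likelihood metric.

## Inference on the fitted model

* `indirect_effects()` solves $B\Lambda = -\Theta$ by Cholesky-based
  triangular solves (explicit inversion is used only when $\Sigma$
  itself is requested).  Effects propagate only within connected
  components of the network: with a block-diagonal $\Lambda$, $B$ has
  exact zeros across blocks, and with a diagonal $\Lambda$ the
  support of $B$ equals that of $\Theta$.
* `decompose_effects()` returns
  $B_k = -\Theta_{\cdot k} (\Lambda^{-1})_{k\cdot}$ for every
  directly perturbed gene $k$; the components sum to $B$ exactly (to
  $10^{-10}$ in tests).  The indexing — column of $\Theta$ times row
  of $\Lambda^{-1}$ — is forced by the dimensions of the outer
  product.
* `decompose_covariance()` reports
  $S_{yy} = \Lambda^{-1} + B^\top S_{xx} B + R$.  At the unpenalized
  maximum-likelihood solution the moment-matching property of
  log-linear models makes $R$ vanish; under the L1 penalty the
  identity holds only approximately, and
  `relative_residual_norm` quantifies the sparsity bias.  Both
  behaviors are verified in the acceptance tests.
* `effect_types()` labels SNP–gene pairs *direct* (both $\Theta$ and
  $B$ entries nonzero) or *indirect* ($B$ nonzero, $\Theta$ zero).
  Support everywhere in the package means absolute value above
  $10^{-8}$: the L1 solutions have exact zeros in theory, but
  serialized floating-point artifacts require a tolerance, and
  $10^{-8}$ sits well below any effect size the simulators generate.

## Synthetic data: what it emulates, what it does not

The generators reproduce the statistical structure the estimator
assumes, so end-to-end tests exercise exactly the regime the model is
designed for.

* **Module networks** (`sim_module_network`): genes are partitioned
  into modules (default 3); gene pairs are connected with probability
  `p_within = 0.2` inside a module and `p_between = 0.01` between
  modules; edge weights are drawn from $U(0.4, 0.8)$; $\Lambda^*$ is
  the graph Laplacian of the weight matrix (negated weights
  off-diagonal, incident sums on the diagonal) plus
  `diag_jitter = 0.1` on the diagonal.  A Laplacian is positive
  semidefinite by construction, so the jitter makes $\Lambda^*$
  positive definite with smallest eigenvalue at least the jitter;
  the row-sum identity $\Lambda^* \mathbf{1} = \delta\,\mathbf{1}$ is
  asserted in tests.
* **Scale-free networks** (`sim_scalefree_network`): node degrees are
  drawn from a discrete power law $P(k) \propto k^{-\gamma}$
  (default $\gamma = 2.5$), repaired to a graphical sequence by
  decrementing the largest degrees until the Erdős–Gallai condition
  holds (checked with igraph), realized as a simple graph
  (Havel–Hakimi) and randomized by degree-preserving rewiring; the
  Laplacian construction is as above.
* **Direct perturbations** (`sim_direct_perturbations`): the
  module design perturbs one randomly chosen gene per module, hit by
  each SNP with probability `perturb_prob = 0.05`; the uniform design
  makes every SNP–gene pair an eQTL with that probability; the
  hub-extra design adds one extra eQTL for every gene with more than
  20 network neighbors.  Effect sizes are $U(0.6, 1.0)$ with random
  signs.
* **Genotypes** (`sim_genotypes`): two haplotypes per sample from a
  first-order Markov chain along the SNPs (allele copied from the
  left neighbor with probability `ld_decay = 0.5`, else a fresh
  Bernoulli draw at the site's frequency, uniform in $[0.1, 0.5]$),
  summed to $\{0,1,2\}$; constant columns are resampled.  This
  emulates minor-allele-frequency filtering and local LD — nothing
  more.  There is no population structure, no recombination-rate
  variation, no Hardy–Weinberg violation; conclusions about such
  effects cannot be drawn from these tests.
* **Expressions** (`sim_expressions`): rows drawn from
  $N(B^{*\top} x_i, \Lambda^{*-1})$ via the Cholesky factor of
  $\Lambda^*$.  The pleiotropic regression design
  (`sim_regression_design`) instead sets $Y = XB^* + E$ with a
  module-shared eQTL support in $B^*$ — the misspecified case where
  the truth is sparse in the regression parameterization rather than
  the graphical one.

The default study condition used throughout the tests and the
acceptance script is $n = 300$ training samples (plus 43 held out
where prediction error is reported), $p = 30$ genes in 3 modules and
$q = 60$ SNPs, with five-fold CV on a $3\times3$ grid; the
scalability check runs a single fit at $p = 500$, $q = 1000$,
$n = 300$, `tol = 1e-4` on a scale-free network.  These sizes keep a
complete run on a single CPU within minutes while leaving the
support-recovery signal far above the prevalence baseline.  All
generators are pure functions of their parameters and seed; every
numeric default above was fixed once as a realistic, well-conditioned
regime and is exposed as an argument rather than hidden in code.

Passing these tests shows the estimator recovers structure when the
generating process matches the model class (or the pleiotropic
regression variant).  It does not show robustness to confounding,
batch effects, non-Gaussian expression noise, or discrete dominance
effects in genotypes — real-data phenomena the generators
deliberately do not emulate.

## Evaluation choices

* Precision–recall curves rank all candidate entries by absolute
  value; tied values enter as one group, making the curve
  deterministic.  For symmetric network matrices only the strict
  upper triangle is ranked — self-edges are not network claims.  The
  area is computed by trapezoid over recall with a flat extension to
  recall 0.  The prevalence (fraction of true entries among
  candidates) is reported alongside as the random-ranking baseline.
* Prediction error is the mean squared error per sample and per gene.
  The normalization is a declared package convention; any positive
  scaling preserves method ordering.

## Network analyses

Weighted degree is the sum of absolute off-diagonal precision entries
per gene.  The power-law diagnostic fits ordinary least squares to
$\log_{10} P(\text{degree} \ge d)$ against $\log_{10} d$ at the
observed distinct positive degrees — the cumulative distribution
needs no binning choice, which is why it is used.  Hub modules are
genes with at least `min_neighbors` neighbors together with those
neighbors; eQTL hotspots are the `top_k` SNPs by count of directly
perturbed genes; both use the $10^{-8}$ support threshold and
deterministic ID-based tie-breaks.  cis/trans labels come from
windowed interval overlap (1-based inclusive, touching counts;
default window 20 kb, configurable because linkage extents are
data-specific).  Gene-set enrichment is the upper hypergeometric tail
(one-sided Fisher's exact test) computed in log space via
`stats::phyper`; the gene universe must be supplied explicitly
because it materially changes p-values and no default is defensible.
Raw p-values are reported without multiple-testing correction.

## Numerical contract and limitations

* Symmetry of $\Lambda$ is enforced to $10^{-12}$ at model
  construction; positive definiteness is defined by Cholesky success.
* Model archives store matrix entries as `%.17g` strings inside JSON,
  so save/load round-trips are bit-exact and two runs with the same
  configuration and seed produce byte-identical archives.
* The solver is first-order: for very ill-conditioned $S_{yy}$ or
  penalties near zero at $n < p + q$ it may need many iterations;
  there is no proximal-Newton path.  The unpenalized fit requires
  $n$ large enough for the MLE to exist.
* Estimates carry no standard errors or selection-adjusted inference;
  support statements are subject to the usual instability of L1
  selection, and cross-validated penalties optimize prediction, not
  support recovery.
* Genotypes are treated as numeric dosages; dominance and epistasis
  are out of scope, as are directed or causal network claims beyond
  conditional dependence.
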