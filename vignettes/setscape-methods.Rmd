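---
title: "Methods: exploring multi-trait coadaptation along a range expansion"
author: "setscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exploring multi-trait coadaptation along a range expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a species expands its range, populations meet a succession of new
environments and respond by shifting many interrelated traits at once.
Scanning one trait or one locus at a time misses this *coadaptation*: the
joint, directional change of whole blocks of traits driven by a common
environmental pressure. `setscape` implements an exploratory, two-layer
analysis of this process. The first layer turns genotypes into
population-genetic features: per-population allele frequencies,
population-specific F~ST~, per-trait GWAS effect sizes, and
trait/gene-environment correlations. The second layer integrates them:
a correspondence-analysis map of populations amid their SNPs, traits and
environments; a drift tree of the populations; per-edge polygenic
selection parameters; and a PCA of the selection-on-edge-by-trait (SET)
matrix whose components *are* the coadaptations, with environmental
factor loadings identifying their likely drivers.

All heavy inputs can be simulated: the package ships a forward simulator
of one-dimensional stepping-stone colonization under polygenic
environmental selection, which doubles as the test bed for every claim
the package makes.

## Population-specific F~ST~

For population $i$ and locus $l$, let $\tilde M_{W,l}^{i}$ be the
unbiased within-population probability that two *distinct* sampled
alleles match, $\sum_a n_a(n_a-1)/(n(n-1))$, and let $\tilde M_l^B$ be
the between-population matching probability averaged over all
$K(K-1)/2$ population pairs. The estimator is a ratio of sums over loci,

$$\widehat{\mathrm{psF}}_{ST}^{\,i} \;=\;
\frac{\sum_l \left(\tilde M_{W,l}^{i}-\tilde M_l^B\right)}
     {\sum_l \left(1-\tilde M_l^B\right)},$$

never a mean of per-locus ratios (single-locus ratios are wildly
unstable when $\tilde M_l^B\to 1$). Under a pure colonization history,
each founder event inflates drift, so younger populations carry larger
psF~ST~ and the values order the populations chronologically. Negative
values are legal (a population more diverse than the pair average).
Standard errors come from a bootstrap over loci (default 200 resamples);
an asymptotic variance formula is deliberately not offered, because the
bootstrap makes no assumption about the locus-wise dependence structure.

The same matching quantities give a per-locus global index,
$(\overline{\tilde M_{W,l}}-\tilde M_l^B)/(1-\tilde M_l^B)$, used only to
pick the most differentiated SNP of each gene (`top_snp_per_gene()`),
with ties broken by locus id for reproducibility.

## Correspondence analysis of the composite table

`build_composite_table()` binds three variable blocks into one
nonnegative populations × columns table:

* SNP columns: minor-allele frequencies, used as-is. Orienting to the
  pooled minor allele (`minor_allele_orientation()`) is an ad hoc proxy
  for the derived allele when no outgroup is available; a pooled
  frequency of exactly 0.5 keeps the incoming orientation so results are
  deterministic.
* trait and environment columns: min–max scaled to $[0,1]$ across
  populations. CA requires nonnegative "mass", and min–max scaling makes
  heterogeneous units commensurable with frequencies; constant columns
  are dropped because they carry no profile information.
* every environment additionally contributes a sign-reversed copy
  ($1-$scaled value). Genes and traits that correlate *negatively* with
  an environment then plot near its reversed copy, so both signs of
  association can be read off one map. Traits are not duplicated — their
  sign structure is recovered later through the SET PCA loadings.

Missing cells are mean-imputed within column (and counted in a message);
imputation at the ordination stage is preferable to dropping whole
populations. SNP columns are *not* reweighted against the (much shorter)
trait/environment blocks: the SNP block is supposed to dominate the
geometry so that population positions reflect genome-wide structure, and
traits/environments are read as annotations of that structure.

The decomposition itself is classical: with correspondence matrix
$P=X/n$, row masses $r$, column masses $c$, the SVD of
$D_r^{-1/2}(P-rc^{\top})D_c^{-1/2}$ yields principal coordinates
$D_r^{-1/2}U\Sigma$ and $D_c^{-1/2}V\Sigma$ and total inertia
$\sum_k\sigma_k^2=\chi^2/n$ — an identity the tests verify against an
independent $\chi^2$ computation. Axis signs are fixed by making the
largest-magnitude column coordinate positive. Populations are annotated
with psF~ST~ and an age scalar in $[0,1]$ (0 = smallest psF~ST~ =
oldest); a constant psF~ST~ vector degenerates to 0.5 for every
population.

## The admixture graph and per-edge selection

### Drift covariance and tree fitting

`drift_covariance()` estimates
$W_{ij}= \mathrm{mean}_l\,
(q_{il}-\bar q_l)(q_{jl}-\bar q_l)/(\bar q_l(1-\bar q_l))$ with
$\bar q_l$ the unweighted across-population mean. Centering at $\bar q$
biases the absolute entries but cancels exactly in the drift distances
$d_{ij}=W_{ii}+W_{jj}-2W_{ij}$, which are all the tree fit consumes.
`fit_tree()` takes the neighbor-joining topology of $d$ and refits all
branch lengths by nonnegative least squares of path distances, so
noiseless additive distances are reproduced exactly and negative NJ
branches cannot occur. Rooting is never automatic: the root population
is a scientific choice (typically guided by psF~ST~ and diagnostics), so
`fit_tree()` requires it. Internal nodes are labelled `a1, a2, ...` in
preorder; edges are named `parent-child`.

`add_migration_edges()` optionally adds admixture edges greedily: each
round scores every (source node, target node) pair by the drop in
residual sum of squares between the observed and graph-implied
(doubly centered) covariances, with the weight fitted by 1-D
optimization over $(0.001, 0.5)$. This is a deliberately simple
device — no likelihood, no search over topologies — sufficient for the
colonization-style histories the package targets; users with a full
migration-graph inference can import its output through
`read_treemix_output()` instead.

### Standardized per-edge polygenic selection

For a trait with significant GWAS loci, the population polygenic score
is $Z_i = 2\sum_j \beta_j q_{ij}$ and the additive variance scale is
$V_A = 4\sum_j \beta_j^2\,\bar q_j(1-\bar q_j)$. Under pure drift the
scores evolve approximately as a Brownian motion on the graph with
per-edge variance $V_A c_e$. `estimate_edge_selection()` reconstructs
ancestral scores $\hat z$ by generalized least squares under that model
(admixture children are tied to the weighted mixture of their two
parents) and reports, for every tree edge,

$$\alpha_e = \frac{\hat z_{\mathrm{child}}-\hat z_{\mathrm{parent}}}
  {\sqrt{V_A\, v_e}},$$

where $v_e$ is the *exact null variance of that GLS contrast*: the
contrast is a linear functional $a_e^{\top}z$ of the leaf scores, and
$v_e = a_e^{\top} T a_e$ with $T$ the leaf covariance implied by the
fitted graph. The naive alternative — dividing by $\sqrt{V_A c_e}$ —
looks natural but is miscalibrated: GLS shrinks ancestral estimates
toward their neighbors, and numerical experiments during design showed
its null SD is ≈ 0.7 on colonization-shaped (caterpillar) trees, with
strong edge-to-edge heterogeneity. With the exact contrast variance,
every $\alpha_e$ is standard normal under drift (given the graph), so
values of $|\alpha|\gtrsim 2$ flag frequency shifts of trait-associated
alleles beyond drift, comparably across edges and traits. The sign
gives the direction of trait change along the edge. Edges of
(near-)zero drift length get $\alpha=0$; the telescoping identity
$\sum_{e\in\mathrm{path}} \alpha_e\sqrt{V_A v_e}
 = \hat z_{\mathrm{leaf}}-\hat z_{\mathrm{root}}$ holds along any
root-to-leaf path.

GWAS itself (`gwas_scan()`) is ordinary least squares of the trait on
dosage with population-membership indicators absorbing structure,
two-sided t tests, and Benjamini–Hochberg q-values at a default
$\alpha=0.05$. A mixed-model kinship correction is out of scope; with
population indicators, power comes from within-population dosage
variance only, which is the conservative choice in strongly structured
samples.

## SET matrix, PCA and environmental loadings

Binding the per-trait $\alpha$ vectors column-wise gives the SET matrix
(edges × traits); traits with no significant GWAS loci are omitted and
reported. `set_pca()` centers the columns and, by default, scales them
to unit variance before the SVD: although $\alpha$ is nominally on a
common N(0,1) null scale, traits under strong selection have much
larger spread, and standardization keeps one dramatic trait from owning
every component. The flag `standardize = FALSE` restores covariance
PCA. Trait loadings are orthonormal right singular vectors with a
deterministic sign convention; edge scores are the projections, and
`pc_edge_scores()` reproduces them as the loading-weighted combination
of the per-trait $\alpha$ values — the quantity mapped onto the graph
as the red/blue (increase/decrease) edge coloring.

The loading of an environmental variable on component $k$ is the sum of
conditional loadings through every trait:
$\mathrm{load}(E,k)=\sum_t \mathrm{load}(t,k)\, r(t,E)$, with $r$ the
among-population trait–environment Pearson correlation. Missing
correlations count as zero (and are tallied). A sign-reversed
environment needs no duplicated column here: its loading is exactly the
negative of the original's.

## The colonization simulator

`sim_params()` defaults encode the study scenario: $K=25$ linearly
arrayed demes; deme 1 ancestral with $N_e=10^5$; every 10 generations
1% of the source deme founds the next vacant deme, which jumps to its
capacity $N_e=10^4$ within that generation; the run ends at generation
260, the 25th deme having been founded at generation 240. Ancestral
polymorphism is drawn from the equilibrium spectrum
$f(q)\propto q^{-1}(1-q)^{-1}$ truncated to
$[1/(2N_e),\,1-1/(2N_e)]$ — uniform on the logit scale, which is also
how it is sampled. Two environmental factors act on disjoint blocks of
15 traits: a local patch (value 1 on demes 5–10) and a cline (0 through
deme 14, then rising linearly to 1). Each trait sums 10 monogenic
latent traits; each derived causal allele shifts its latent trait by
$2\gamma_G q$ per deme with $\gamma_G=-1$ (only the sign is
scientifically constrained — derived alleles lower the traits — so the
magnitude is set to 1 and becomes the unit of the trait scale). The
parameter $\gamma_E\le 0$ records the complementary sign convention
that high environmental values favour those derived alleles; the
frequency-level dynamics use only this sign structure, not a magnitude.

Selection follows a cost-of-adaptation model: the derived allele has
coefficient $s$ (default 0.01) where the environment is 1 and
$1/(1+s)-1$ (≈ $-s$) where it is 0, linearly interpolated for
intermediate environments, applied as the genic update
$q'=q(1+s_{\mathrm{eff}})/(1+q s_{\mathrm{eff}})$. Drift is binomial at
each deme's size; founding draws $2\times\mathrm{round}(0.01 N_e)$
binomial allele copies (frequency-level founding rather than
individual-based emigration, consistent with simulating frequencies
and mean traits throughout). New mutations enter at frequency 0.01 in
one uniformly chosen occupied deme — neutral ones at Poisson rate 5 per
generation and 3 adaptive ones per generation, each targeting a
uniformly chosen latent trait. The pool of ancestral neutral loci
defaults to 12,000 so that roughly 10,000 remain polymorphic for
observation, and the Poisson rate of 5 yields comfortably more than 500
surviving new neutral loci over 260 generations; the per-generation
adaptive count of 3 makes multiple causal alleles per latent trait
available, of which the observation step reports one.

Observation mimics SNP discovery and sampling: uniform subsets of the
pooled-polymorphic loci (10,000 initial-neutral, 500 new-neutral by
default), plus one surviving adaptive locus per latent trait — the one
with the highest across-deme frequency variance, ties broken at
random — and 50 diploid individuals per deme with dosages drawn
$\mathrm{Binomial}(2,q)$ per locus (Hardy–Weinberg and linkage
equilibrium within demes). Individual trait values are genotypic values
from the sampled dosages at *all* surviving causal loci (observed or
not) plus normal noise; the noise SD defaults to half the SD of the
genotypic values, and both it and every count above are configurable.

What the simulator does **not** emulate — and therefore what passing
tests cannot certify about real data: linkage and LD between loci,
two-dimensional geography, back-migration between established demes,
demographic stochasticity beyond the founding step, genotyping error,
ascertainment bias in SNP discovery, and pleiotropy (trait blocks share
selection pressure, never loci). Results on real datasets additionally
depend on the accuracy of the population assignment, which the package
takes as given.

## Numerical choices and conventions

* Minor-allele tie at pooled frequency exactly 0.5: keep the incoming
  orientation.
* Genepop populations are labelled `pop1..popK` in block order unless
  names are supplied; multiallelic loci error by default and are
  dropped under a flag; missing genotypes are excluded pairwise and
  never imputed at the I/O layer.
* TreeMix-format export writes `round(freq × n)` allele counts and
  `0,0` for missing cells; the vertices/edges reader accepts the
  documented whitespace dialect and validates the graph invariants.
* CA and SET-PCA axis signs: largest-magnitude loading positive.
* Zero-mass CA rows/columns and zero-variance standardized SET columns
  are dropped with warnings, not errors.
* GLS edge weights floor the drift length at $10^{-8}\times$ the
  maximum edge length to keep the system well posed; such edges report
  $\alpha=0$.
* All randomness flows through R's RNG: one seed (argument or
  `set.seed()`) reproduces a run end to end; the command-line tools log
  their seed.

## Problem sizes used by the test-suite

The packaged checks run the scenario at reduced size so the whole suite
stays fast: the chronological-ordering and selection-recovery checks
use $K=10$ demes ($N_e$ 2000/1000), 2000 ancestral neutral loci, 110
generations, selection $s=0.05$ concentrated on demes 3–5, 3 traits per
environmental factor with 5 latent traits each, and 20 replicates; the
null-calibration check uses $K=8$ neutral demes, a 3000-locus pool and
200 scoring loci of unit effect over 20 replicates. The GWAS
parameter-recovery check injects causal mutations at frequency 0.2 (not
the default 0.01) with 150 individuals sampled per deme, because with
population indicators in the model the scan can only ever recover loci
that segregate *within* demes — alleles still at their initial 1%
frequency are invisible to any structure-corrected association test, so
that scenario probes the machinery, not the sweep dynamics. These sizes
were
chosen once, as the smallest configurations in which the underlying
effects (founder-driven psF~ST~ gradients, mid-sweep causal alleles,
drift-calibrated contrasts) are comfortably expressed; the full-scale
defaults remain those stated above.

## Known limitations

The tree fit assumes a colonization-like, tree-dominated history; dense
migration violates both the NJ step and the Brownian approximation.
$\alpha$ is calibrated *given* the fitted graph — uncertainty in the
topology and branch lengths is not propagated. GWAS effect sizes enter
the polygenic scores as point estimates; winner's-curse inflation of
$\hat\beta$ at the significance threshold biases $V_A$ upward and
$|\alpha|$ correspondingly downward, which is conservative. The
environmental loadings inherit whatever confounding is present in the
among-population trait–environment correlations; they identify
candidate drivers, not causes.
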