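---
title: "Codon-model selection scans and phylogenetic regression of brain size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection scans and phylogenetic regression of brain size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phydnds)
```

This vignette documents the models the package fits, the assumptions behind
them, the numerical choices in the implementation, and what the synthetic
data used by the test suite does and does not establish about real data.

## The two-stage analysis

Stage one asks whether a protein-coding gene evolved under positive
selection anywhere in its sequence across a clade. Stage two asks whether
the *strength* of selection on the gene, summarized per species, predicts a
species trait — here brain size, in absolute form and relative to body
size.

### Codon substitution model

Both stages rest on a continuous-time Markov model on the 61 sense codons
of the standard genetic code (Goldman–Yang form). The instantaneous rate
from codon $i$ to codon $j$ is

$$q_{ij} = \pi_j \,\kappa^{[\text{transition}]}\, \omega^{[\text{nonsynonymous}]}$$

for codons differing at exactly one nucleotide position, and 0 otherwise;
$\pi$ are equilibrium codon frequencies, $\kappa > 0$ the
transition/transversion rate ratio, and $\omega = dN/dS$ the
nonsynonymous/synonymous rate ratio, the selection parameter of interest.
The chain is time-reversible, which the implementation exploits by
symmetrizing the generator and eigendecomposing once per parameter value;
every transition matrix is then a single matrix product.

Assumptions inherited from this model family: sites evolve independently;
the alignment is a correct orthologous, frame-preserving alignment with no
recombination across the tree; codon frequencies are at equilibrium and
shared across branches; and synonymous sites are (approximately) neutral so
that $\omega$ isolates selection on the protein.

*Codon frequencies.* The default is F3x4 — products of position-specific
nucleotide frequencies, renormalized over sense codons — because it is the
conventional default for this analysis when nothing else is stated; F61
(observed codon proportions, pseudo-count 1) and uniform frequencies are
available. Frequencies are estimated empirically from each gene's cleaned
alignment and held fixed during optimization.

### Site models and the positive-selection test

The site models let $\omega$ vary over alignment columns through a finite
mixture, constant across branches:

* **M0** — one class, a single $\omega$;
* **M1a** — $\omega_0 \in (0,1)$ (purifying) and $\omega_1 = 1$ (neutral),
  with proportions $p_0, p_1$;
* **M2a** — adds $\omega_2 \ge 1$ with proportion $p_2$.

Positive selection is inferred when M2a fits significantly better than M1a:
the statistic $-2[\ell(\text{M1a}) - \ell(\text{M2a})]$ is referred to a
chi-square with 2 degrees of freedom (the parameter-count difference), with
small negative values — which arise when the extra class collapses onto its
boundary — treated as estimates of zero. Because the null places $p_2$ and
$\omega_2$ on the boundary of the parameter space, the chi-square reference
is conservative; the test suite verifies this empirically (the type-I error
stays below the nominal level). Nominal p-values are adjusted across genes
by Benjamini–Hochberg.

### Branch model and root-to-tip dN/dS

The free-ratio model gives every branch its own $\omega$, constant across
sites. Each branch length, in expected substitutions per codon, is
decomposed into nonsynonymous and synonymous distances

$$dN = t\,\rho_N/f_N, \qquad dS = t\,\rho_S/f_S,$$

where $\rho_N, \rho_S$ are the proportions of substitution flux through
nonsynonymous/synonymous changes under the branch's fitted matrix and
$f_N, f_S$ are the same proportions evaluated at $\omega = 1$ (mutational
opportunity). This decomposition satisfies $dN/dS = \omega$ exactly, which
the tests assert to $10^{-10}$.

A species' root-to-tip dN/dS is the **ratio of the sums**: sum the
per-branch $dN$, and separately the per-branch $dS$, along the unique path
from the root to the species' tip (terminal branch included), then divide.
Summing before dividing matters — the quotient of sums is a flux-weighted
mediant and differs from the mean of per-branch ratios. Species on shared
internal branches receive identical addends from them, which makes the
measure comparable across species. A gene in which more than half of the
species have a zero or undefined ratio (no synonymous change on the path)
carries too little signal to regress on; such genes are flagged and routed
to an exclusion report rather than fitted. The 50% threshold
operationalizes a qualitative "most species" rule and is configurable.
Because branch dN/dS estimates sit at a small positive bound (not exactly
zero) when no substitution of a kind is inferred, summed distances below a
numerical-zero tolerance (`zero_tol`, default $10^{-5}$ substitutions per
site) are treated as zero before the ratio is formed.

### PGLS with Pagel's lambda

Species values are not independent; residual covariance is modeled as
$\sigma^2 V_\lambda$ where $V$ is the Brownian-motion covariance (shared
root-to-MRCA path length) from the input tree and $\lambda \in [0,1]$
multiplies the off-diagonals. Four model formulas are fitted per gene, all
variables natural-log transformed:

1. `log(brain) ~ log(dN/dS)`
2. `log(brain) ~ log(dN) + log(dS)`
3. `log(brain) ~ log(body) + log(dN/dS)`
4. `log(brain) ~ log(body) + log(dN) + log(dS)`

Coefficients are the closed-form GLS estimates; standard errors use the
residual variance at $n - p$ degrees of freedom with two-sided t tests.
$\lambda$ is profiled by maximum likelihood (ML criterion, not REML — the
profile is also used to *average* $\lambda$, and ML keeps the weights
comparable across formulas). The profile is evaluated on a 101-point
uniform grid plus a bounded 1-D optimization; the likelihood-weighted
average uses weights $\propto \exp(\ell_i - \max \ell)$, normalized after
subtracting the maximum for numerical stability. When the profile spans
less than 2 log-units it is flagged *flat* — at the sample sizes typical of
candidate-gene studies (around 20 species) the data often carry almost no
information about $\lambda$ — and the default `"auto"` mode then uses the
averaged $\lambda$ in place of an ML estimate of exactly zero. Fixed
$\lambda = 0$ and $\lambda = 1$ companion runs are always emitted so the
sensitivity of conclusions to $\lambda$ is visible.

FDR families for the regression p-values group the same formula and the
same coefficient across genes (the intercept is not adjusted), so the
family size equals the number of genes fitted for that formula. This
partition reproduces published adjusted/nominal pairs checked in the test
suite and is configurable through `fdr_by_family()`.

Sensitivity analyses: `exclusion_rerun()` repeats everything with a fixed
species set removed — by default the two phyletic dwarfs (*Callithrix
jacchus*, *Microcebus murinus*), lineages whose secondary brain-size
reductions can reverse the expected selection–size relationship — and
`sensitivity_loo()` refits the model dropping one species at a time,
reporting which omissions flip significance.

## Numerical and design choices

* **Parameterization.** Branch lengths are optimized in raw generator time
  so a class's rate matrix depends only on its own $\omega$; reported
  branch lengths are converted to expected substitutions per codon — for
  site models under the mixture-averaged rate, for the free-ratio model
  under each branch's own rate. The per-branch normalization (rather than a
  tree-wide average) is the convention under which a branch length reads as
  that branch's substitutions per codon, and it leaves root-to-tip dN/dS
  unchanged since the $dN$/$dS$ decomposition is scale-consistent by
  construction.
* **Optimizer.** A short coordinate warmup (per-edge Newton steps on cached
  directional partials, with a damped/over-relaxed line search along the
  sweep direction) is followed by joint bounded quasi-Newton (`nlminb`)
  over all parameters, with analytic branch-length gradients and exact
  class-local finite differences for the globals. Mixture proportions are
  not optimizer coordinates: for a fixed per-class site-likelihood matrix
  their profile likelihood is concave and an inner EM solves it directly,
  which removes the flattest ridge of the M2a surface. Bounds:
  $\omega \in [10^{-6}, 999]$, $\kappa \in [0.01, 100]$,
  $\omega_0 \in (0,1)$, $\omega_2 \ge 1$ (so M1a is properly nested in
  M2a). Convergence is declared when a full pass improves the
  log-likelihood by less than `tol` (default $10^{-8}$); non-convergence is
  flagged on the fit, never raised as an error. Richer models warm-start
  from simpler ones (M0 to M1a to M2a; M0 to free-ratio), which both speeds
  the fits and enforces likelihood nesting up to optimizer tolerance, and
  M2a additionally takes seeded random restarts of the global parameters
  (default 3; branch lengths stay warm).
* **Underflow.** Pruning partials are rescaled per node and per pattern
  when any entry falls below $10^{-130}$, with log-scalers accumulated;
  mixtures are combined by log-sum-exp.
* **Branch omegas without signal.** A branch with no inferred synonymous
  change drives its $\omega$ to the upper bound (999); this is recorded
  (`omega_at_bound`) and such branches contribute what the likelihood
  supports to the root-to-tip sums rather than aborting the fit.
* **Degenerate regressions.** A zero-variance predictor or fewer species
  than coefficients + 2 skips the gene-formula pair with an explicit record
  instead of producing a spurious fit; species with zero/undefined
  root-to-tip ratios are dropped from log-scale regressions with a warning.
* **Stop codons and missing data.** In-frame stops are masked as missing
  with a warning (curated alignments should not contain them; the
  column-cleaning step removes those columns anyway). Coverage is computed
  per species over all codon columns *before* column removal, and species
  strictly below 70% coverage are excluded.
* **PHYLIP dialect.** Reading is relaxed (names of any length,
  whitespace-delimited, sequential or interleaved, with parse errors that
  name the offending line and taxon); writing is strict sequential PHYLIP
  with 10-character names, and write–read–write round-trips are
  byte-identical.

## The synthetic-data generator

`simulate_alignment()` draws root codons from $\pi$, assigns each site a
class by the mixture proportions, and evolves states branch by branch by
exact sampling from the branch's transition matrix — only endpoint states
matter for likelihood-based analyses, so no event-level simulation is
needed. `simulate_traits()` adds
$\log(\text{brain}) = \beta_0 + \beta_1 \log(\text{ratio}) + \varepsilon$
with $\varepsilon \sim N(0, \sigma^2 V_{\lambda})$, and body size with its
own intercept and correlated phylogenetic noise. `make_study_fixture()`
bundles a pure-birth tree (rescaled to mean root-to-tip length 0.5
substitutions per codon — divergent enough for identifiable $\omega$
without saturation) with three genes: a nearly neutral gene (M1a,
$\omega_0 = 0.1$, $p_0 = 0.8$), a positive-selection gene (M2a,
$\omega_2 = 6$ at 2% of sites, echoing the scale of fitted
positive-selection classes in real candidate-gene scans), and a gene whose
per-branch $\omega$ (log-normal around 0.25) is coupled to the trait
through slope $\beta_1 = 2$ with $\sigma^2 = 0.04$ and $\lambda = 1$.
Everything is seeded; identical seeds give byte-identical outputs.

What the simulations emulate: site-class mixtures, per-branch rate
variation, phylogenetically correlated traits with a known coupling, and
missing-data/coverage structure when injected. What they do not emulate:
alignment error, recombination, selection on synonymous sites,
context-dependent mutation (CpG), indels, or gene-tree/species-tree
discordance. Passing the test suite therefore demonstrates that the
estimators recover the parameters of their own generative model and that
the test statistics are calibrated under it — not that those assumptions
hold for any particular empirical alignment.

## Problem sizes used by the test suite

Validation experiments are sized for a desk-scale run while keeping each
property meaningful: brute-force likelihood cross-checks use 3–4 taxa and
up to 5 codons (exact enumeration over interior states); single-ratio
recovery uses 20 taxa by 500 codons over 5 seeds (tolerance $\pm 0.05$);
the type-I-error experiment simulates 100 parametric-bootstrap null
alignments of 8 taxa by 100 codons from a fitted nearly neutral model,
fitting both M1a and M2a warm-started at the generating values (the
conservativeness of the boundary null does not depend on alignment size);
PGLS confidence-interval coverage uses 200 replicates at 23 species with
$\lambda$ fixed at its generating value of 1 (coverage is a property of
the GLS core; adding $\lambda$ estimation noise would test a different
quantity); and the end-to-end fixture runs use 8–10 taxa and 120–250
codons. The acceptance script repeats the same computations at the same or
smaller sizes, all driven by a single seed.

## Known limitations

* Likelihoods match other implementations of the same models only up to
  optimizer and frequency-model conventions; published per-gene tables are
  reproduced through their printed values (the deposited alignments are not
  bundled), and refits of the deposited data would be expected to agree
  within tolerance, not bit-exactly.
* The free-ratio model is parameter-rich (two parameters per branch);
  on short branches $\omega$ estimates are unstable and may hit bounds.
  Root-to-tip sums inherit that noise, though summing along paths averages
  much of it out.
* Bayes-empirical-Bayes identification of *which* sites are under
  selection is not implemented; the scan tests only for the presence of a
  positive-selection class.
* $\lambda$ profiling at 20-odd species is weakly informative by nature;
  conclusions should be read alongside the fixed-$\lambda$ companion runs.
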