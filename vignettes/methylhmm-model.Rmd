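---
title: "A hidden Markov model of DNA methyltransferase processivity and substrate preference"
author: "dnmtHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hidden Markov model of DNA methyltransferase processivity and substrate preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data and the question

Hairpin-bisulfite PCR reads the methylation state of both strands of a
single DNA molecule at every CpG of a short locus. Each molecule therefore
yields a *double-stranded methylation pattern*: two aligned binary strings
over the locus's CpG sites. One strand is the template ("parent") present
before DNA replication, the other is the newly synthesized daughter — but
the assay does not reveal which is which. A CpG site read jointly on both
strands is a *dyad*: fully methylated (M), hemimethylated (H, with an
orientation — which strand carries the methyl), or unmethylated (U).

Shortly after replication the daughter strand is unmethylated everywhere;
methyltransferases then act on the molecule. DNMT1 preferentially
methylates daughter CpGs whose parent partner is methylated (maintenance),
and the DNMT3s methylate CpGs regardless of the partner state (de novo).
Two enzymatic properties shape the resulting patterns:

* **substrate preference** — the ratio of the maintenance probability to
  the de novo probability (the *hemi-preference ratio*), and
* **processivity** — the tendency to stay associated with the DNA and act
  at successive sites, visible as runs of same-orientation hemimethylated
  dyads where an enzyme was absent (or present) for a stretch of sites.

This package infers both from a collection of double-stranded patterns,
in a Bayesian framework that also handles bisulfite measurement errors
and the unknown strand orientation.

## The hidden Markov model

### Association chains

Three independent two-state Markov chains run along the molecule, one per
enzyme process: DNMT1 on the daughter strand, the DNMT3s on the parent
strand, and the DNMT3s on the daughter strand. Each chain has a per-bp
*reassociating* probability $r$ (unassociated $\to$ associated over 1 bp)
and a per-bp *dissociating* probability $d$. Over one bp an associated
molecule stays associated either *processively* (never dissociating,
probability $1-d$) or through a *dissociation–reassociation* event
(falling off and rebinding at the next position, probability $d\,r$), so
the per-bp transition matrix is

$$T \;=\; \begin{pmatrix} 1-r & r \\ d(1-r) & 1-d+d\,r \end{pmatrix},$$

with state order (unassociated, associated). At $d = 1$ the two rows
coincide and association is independent from site to site — the
"no processivity" limit. Between CpG sites $L$ bp apart the chain evolves
by $T^L$ (computed by exponentiation-by-squaring; $L$ is the difference
of the CpG cytosines' genomic coordinates, and $L = 0$ is rejected).

Derived quantities, per process:

* mean association tract length $1/d$ bp — a tract ends at *any*
  dissociation, so this deliberately excludes dissociation–reassociation
  events that merely mimic processivity in outcome. (The dwell time of
  the chain's associated *state* is the longer $1/(d(1-r))$, because
  instantaneous rebinding keeps the state alive.)
* mean non-association tract (gap) length $1/r$ bp;
* average association level $f = r / (r + d(1-r))$, the stationary law of
  $T$; at $d = 1$ this reduces to $f = r$.

The joint hidden state at a site is the triple $(s_1, s_{3p}, s_{3d})$ of
association indicators, indexed $0\ldots7$ with $s_1$ as the most
significant bit. Because the chains are independent, the joint $L$-bp
transition matrix is the Kronecker product of the three marginal ones,
and the chain is assumed at equilibrium entering the region (each chain
starts from its stationary law; nothing in the data identifies a
non-equilibrium start).

### Emissions

Given the hidden triple and the site's *pre-replication methylation
density* $m_i$ (the probability that the parent CpG was methylated before
replication), a dyad is generated as:

1. pre-replication parent state $z \sim \mathrm{Bernoulli}(m_i)$;
2. no active demethylation: if $z = 1$ the post-replication parent CpG is
   methylated; if $z = 0$ it is methylated only by an associated
   parent-strand DNMT3, which methylates with probability 1;
3. the daughter CpG is methylated by associated DNMT1 with probability
   $\mu_1$ (if $z = 1$; maintenance) or $\delta_1$ (if $z = 0$; de novo),
   and by associated daughter-strand DNMT3s with $\mu_3$ / $\delta_3$;
   simultaneous association combines as independent attempts (noisy-OR),
   the minimal assumption when no combination rule is specified, and one
   that reproduces every constrained variant exactly.

The substrate (hemimethylated vs unmethylated) is judged on the
*pre-replication* state $z$, not on the concurrently modified parent
strand: a dyad unmethylated before replication whose parent and daughter
are both methylated de novo counts as two de novo events, with total
probability $(1-m_i)\,\delta_1$ for the DNMT1 part. This generative order
is forced by the model's accounting of double-de-novo events.

Bisulfite conversion then corrupts each strand independently: a truly
unmethylated cytosine reads methylated with probability $c$ (failure of
conversion) and a truly methylated cytosine reads unmethylated with
probability $e$ (inappropriate conversion). Unread sites (`?`) are
marginalized per strand. Setting `errors_off` makes the observed emission
identical to the error-free one.

### Orientation and likelihood

Which ascertained strand is the parent is unknown; both assignments are
mixed with prior probability 1/2. The pattern likelihood is computed by
the forward algorithm over the 8 joint states (scaled at every site for
numerical stability; impossible observations yield $-\infty$), once per
orientation. Forward–backward smoothing gives per-site posterior state
marginals; a k-best Viterbi-style dynamic program enumerates the top-k
(orientation, hidden path) explanations, with ties broken first by
orientation (strand A as parent first) and then by lexicographic path
order. The cost is linear in molecules and sites.

## Model variants

* `in_vivo_default` — the parsimonious in vivo model: $\mu_3 = \delta_3
  = 1$ (association of the daughter-strand DNMT3s is synonymous with
  methylation), $\mu_1, \delta_1$ free.
* `dnmt3_hemi` — to estimate the DNMT3 hemi-preference ratio the roles
  are swapped: DNMT1 is constrained to pure maintenance and $\mu_3,
  \delta_3$ are freed. The source text for the constraint values is
  incomplete; this package reads it as $\mu_1 = 1, \delta_1 = 0$,
  consistent with DNMT1 being the primary maintenance enzyme. Without
  some such constraint the DNMT1 and daughter-strand DNMT3 chains are
  exchangeable and unidentifiable.
* `in_vitro_dnmt1` — purified-DNMT1 experiments: both DNMT3 chains are
  disabled ($r = 0$, $d = 1$), only DNMT1 parameters are estimated.

## Inference

All free parameters are probabilities. Priors default to uniform(0, 1);
any parameter can instead get a Beta prior or be fixed. Following common
practice for this assay, the failure-of-conversion probability $c$ is
fixed (default 0.003, configurable) and the inappropriate-conversion
probability $e$ is estimated, shared across sites and strands (it varies
little across CpGs in this data type). Site densities $m_i$ are sampled
with uniform priors by default (one per site), or plugged in
(`fix_site_densities`) as the empirical per-site methylation frequency or
a user-supplied vector.

The sampler is component-wise random-walk Metropolis on the logit scale
(the logit Jacobian $\log p(1-p)$ is included), with per-component
proposal scales adapted toward a ~40% acceptance rate during burn-in
only. One additional joint multivariate-normal proposal per iteration,
with covariance estimated from the burn-in draws (Haario-style adaptive
Metropolis, frozen after burn-in), traverses the correlated posterior
ridges that single-coordinate moves cross slowly. Starting values are
data-driven — empirical site frequencies for $m_i$, moderate values for
the rest — jittered per chain on the logit scale, with prior-draw
restarts if the posterior density is zero (bounded retries, then an
error).

Posterior summaries follow the conventions of the original analyses:
median and 80% credible interval (10- and 90-percentiles, type-7
quantiles; 80% rather than 95% to blunt heavy tails). Hemi-preference
ratios get a one-sided 80% interval — the 20-percentile as a lower bound
and no upper bound — because small de novo probabilities cannot be
excluded, hence neither can arbitrarily large ratios; draws with
$\delta = 0$ to machine precision yield $+\infty$ and are handled by
quantiles on the extended half-line (interpolation touching $\infty$
returns $\infty$). Convergence is monitored by split-chain potential
scale reduction and an initial-positive-sequence effective sample size,
with flags at $\hat R > 1.1$ or ESS < 100.

Default chain settings (`mcmc_control()`: 2 chains × 6000 iterations,
2000 burn-in, thin 4) are desk-scale choices for a ~170-molecule locus,
not values taken from any prior analysis; raise them for final analyses.

## The simulator

`simulate_patterns()` is the generative dual of the likelihood: hidden
chains from stationary starts stepped by $T^L$, pre-replication states
from the site densities, dyads by the emission law, per-strand error
flips, and a random A/B strand labelling to mimic unknown parentage. An
optional PCR-crossover artifact replaces a molecule with a
single-breakpoint hybrid of two independently simulated molecules
(uniform breakpoint); double crossovers are not injected. A truth sidecar
(orientation, hidden paths, pre-replication states, crossover flags) is
kept separate so simulated pattern files are format-identical to real
ones.

Auto-generated loci draw CpG spacings uniformly from 4–10 bp (median
about 7 bp, typical of the dense CpG islands this assay targets). The
ready-made `fmr1_regime_params()` encodes a densely methylated
inactive-X-like regime: $d_1 = 0.002$, $r_1 = 0.12$, $\mu_1 = 0.99$,
$\delta_1 = 0.02$, nearly inactive DNMT3s, $e = 0.02$, $c = 0.003$, and a
flat site density of 0.88 — the density value is chosen once so that the
implied stationary dyad-class fractions (82.6% M, 6.2% H, 11.2% U) and
overall methylation density (~86%) match published summaries of such
loci.

What the simulator does *not* emulate: PCR amplification kinetics and raw
bisulfite reads (errors act as per-CpG flips), molecular contamination,
site-to-site density heterogeneity (densities are constant under the
ready-made regime, though any vector may be supplied), and multiple
enzyme passes per replication round — the processivity modeled here is
the cumulative one. Passing tests on simulated data therefore validate
the estimator under the model's own assumptions, not those features of
real data.

## Identifiability at desk scale

With per-site densities free, the posterior for a ~200-molecule dataset
has a near-flat ridge linking the de novo probability $\delta_1$, the
error rate $e$, the maintenance probability $\mu_1$ and the densities
$m_i$: profile log-likelihood varies by under 1.5 units while $\delta_1$
moves from 0.02 to 0.10 with the others compensating. These parameters
are then only jointly identified; marginal 80% intervals for $\delta_1$
and $e$ need not cover generating values at any realistic number of
molecules. The package's parameter-recovery study (see
`tests/testthat/test-acceptance.R`) therefore conditions on the
generator's density profile, under which all enzymatic parameters are
identified (the large-sample maximum-likelihood estimate returns the
truth) and 80% intervals show near-nominal coverage. Real-data fits
default to sampling the densities; interpret $\delta_1$, $e$ and the
hemi-preference ratio there with the ridge in mind — exactly why the
ratio is reported with a one-sided interval.

The DNMT3 chains at such loci carry almost no events, so their
dissociation probabilities stay at their priors — reproduced in the
recovery study as a distributional check against uniform(0, 1).

## Numerical and testing choices

* Forward pass in scaled linear space; transition powers by repeated
  squaring; all row sums and emission normalizations tested to 1e-12.
* Likelihoods verified against brute-force enumeration over all
  $2 \times 8^S$ (orientation, path) configurations for up to 5 sites,
  with emissions recomputed independently in the test oracle.
* The compiled likelihood core (used inside MCMC) is tested for exact
  agreement with the plain-R reference implementation.
* Desk-scale problem sizes in the test suite: 200 random-parameter oracle
  comparisons; 20 recovery replicates of 200 molecules × 22 CpGs with
  2 × 1500 MCMC iterations each — sizes chosen to keep the default suite
  in the tens of minutes on one core.
* The adjacent-site permutation test is a reconstruction (statistic:
  same-orientation adjacent-hemi pair count; null: within-molecule
  site-order permutation, preserving dyad composition and breaking
  adjacency), since the original's supplementary details are not
  available; treat its p-values as those of this reconstruction.

## Limitations

No multi-pass methylation, no active demethylation, no tetramer-binding
extensions for DNMT3A, no site-specific error rates, and no handling of
contaminant or duplicate molecules (assumed removed upstream). The
crossover model injects single breakpoints only. Loci must have at least
two CpGs with strictly increasing coordinates.
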