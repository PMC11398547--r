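---
title: "Rule-based modeling of multi-particle complexes on a hard-core boson Fock space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based modeling of multi-particle complexes on a hard-core boson Fock space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfock)
```

## The model

polyfock models well-mixed populations of particles that bind into
complexes — dimers, polymer chains and rings, branched trees — using an
operator algebra over *excitation modes*. Three kinds of hard-core boson
fields carry the state:

* a **particle** field has one mode per internal index $i \in \{1..N\}$;
  the index gives outwardly identical particles an identity, which is what
  lets pre-existing particles join into complexes;
* a **site** field decorates a particle field: mode $a_i$ is excited when
  the binding site of particle $i$ is occupied;
* a **bond** field has one mode per index pair, excited when two sites are
  joined. Bonds may be symmetric ($I_{ij} = I_{ji}$, stored with $i<j$) or
  directed ($J_{ij} \ne J_{ji}$).

A *microstate* is the set of excited modes; the vacuum is the empty set.
Four mode operators act on each mode: creation, annihilation, presence and
absence, with creation/annihilation nilpotent (occupancy 0 or 1). A
*reaction rule* is a product of mode operators summed over indices, e.g.
the homopolymer bond-formation rule
$R_3 = \sum_{i \ne j} \hat J_{ij}\,\hat a_i\,\hat b_j\,\bar A_i \bar A_j$:
it requires both particles present, occupies the outgoing site of $i$ and
the incoming site of $j$, and creates the directed bond. A rule *instance*
is one index binding; an instance is **eligible** on a state iff every
factor is (create/absence need their mode unexcited, annihilate/presence
excited). Eligibility is what enforces chemistry: a bonded particle cannot
be annihilated (its site-absence factor fails), an occupied site cannot be
bonded again.

The transition generator of the microstate master equation is
$W = \sum_l r_l \sum_i (R_{li} - \grave R_{li})$, where the depletion
operator $\grave R$ is derived factor-wise (create $\to$ absence,
annihilate $\to$ presence; presence/absence fixed) and carries the
probability outflow. Columns of $W$ sum to zero by construction.

## Module map

| concern | entry points |
|---|---|
| model text format, fixtures | `parse_model`, `render_model`, `builtin_fixture` |
| modes, instances, operators | `compile_model`, `apply_rule_instance`, `instantiate_rules`, `derive_depletion` |
| explicit small-N matrices | `operator_matrix`, `field_matrix`, `macrostate_vector` |
| master equation | `enumerate_reachable`, `build_generator`, `propagate`, `macrostate_distribution`, `build_macro_generator` |
| stochastic simulation | `run_ssa`, `eligible_rules`, `gillespie_step`, `replay_state` |
| species census | `microstate_to_complexes`, `classify_topology`, `trajectory_census`, `ensemble_stats` |
| macro (species-count) master equation | `omega_coefficient`, `homopolymer_reactions`, `species_flux_projector`, `homopolymer_macro_rhs`, `integrate_homopolymer_macro` |
| equilibrium analytics | `eq_params`, `monomer_equilibrium`, `homopolymer_bulk`, `isotropic_bulk`, `branched_bulk`, `exact_partition_oracle`, `detailed_balance_rates` |
| Wick engine | `labeled_product`, `enumerate_contractions`, `count_schemes_by_topology`, `factory_apply_vacuum`, `factory_gallery_check` |

## Numerical choices

**Reachable subspace instead of the full space.** The full Fock space has
dimension $2^{|\mathcal M|}$ with $|\mathcal M|$ polynomial in $N$.
`enumerate_reachable` takes the BFS closure of the initial state under the
rule instances (cap: $2\times 10^5$ states); restricted to this set the
generator gives identical dynamics.

**Matrix exponential by uniformization.** `propagate` evaluates
$e^{tW}\psi$ as a Poisson-weighted series in the stochastic matrix
$I + W/\Lambda$ ($\Lambda = \max_s |W_{ss}|$), truncated when the Poisson
tail drops below `tol` ($10^{-12}$ per step). This never forms $e^{tW}$
densely, preserves positivity, and degrades gracefully on deliberately
truncated (leaky) generators, where the lost mass is the reported
truncation flux.

**Exact lumping for symmetric models.** All fixture rule sets are
invariant under permutations of the mode indices, so the microstate chain
is strongly lumpable with respect to the species-census partition.
`build_macro_generator` builds the lumped generator from representative
microstates — the monomer at $N = 20$ collapses from $2^{20}$ microstates
to 21 labels — and *verifies* lumpability by re-expanding up to `verify`
extra representatives per label, erroring on any mismatch rather than
assuming symmetry.

**SSA.** `run_ssa` implements the eligibility-driven Gillespie loop. The
waiting time is inverse-CDF exponential in the summed eligible rate; the
instance is selected by cumulative-rate search in lexicographic instance
order (a measure-zero tie is broken toward the lower id — a documented
choice, not derived from anything). Two eligibility modes exist: `naive`
rescans every instance per step (the reference), `indexed` maintains a
per-instance unsatisfied-condition counter updated through the
mode-to-instance incidence index; both produce bitwise-identical
trajectories, which the suite asserts on randomized models. Randomness
comes from R's Mersenne–Twister stream seeded with the recorded seed; we
use R's generator rather than a counter-based one because it is part of
R's reproducibility contract across platforms and releases, which is the
property the trajectory metadata needs.

**Canonical species labels.** A complex is a connected component of the
particle–bond graph. Topology kinds are structural: path $\to$ chain-$x$,
all-degree-2 cycle $\to$ ring-$x$, other acyclic $\to$ tree, unicyclic
$\to$ grove. For models with one particle field and at most one bond
field the kind-size tag is already a species label; otherwise the label
carries a canonical string computed by iterative color refinement with
individualization and lexicographic tie-breaking, where edge colors
include the bond field, both site ports, and direction. This collapses
ring rotations and mirror images to one label while keeping genuinely
distinct port structures apart — e.g. the two alternating-bond even-chain
species of the isotropic homopolymer stay distinct, and a path-shaped
complex of the branched system is tagged `chain-2[...]` with its
port-colored canonical string rather than conflated with the homopolymer
2-chain. Components above 40 vertices fall back to a strong (but not
canonical) invariant; nothing in the shipped systems approaches that.

**Species-count master equation.** At the macro level a rule drives a
family of species reactions, each with reactant vector $q$, product vector
$p$, and a multiplicity $\sigma$ = number of distinct product microstates
per reactant microstate (for the homopolymer: joins $\sigma = 2$ for both
unequal- and equal-length pairs, circularization 1; splits 2 and 1, ring
cutting $x$ — the package recomputes all of these by brute-force
enumeration in its acceptance suite rather than trusting the list). The
flux into a state is $\sigma\,\Omega(n,q,p)$ with
$\Omega(n,q,p) = \prod_k \binom{n_k + q_k - p_k}{q_k} 1[n_k \ge p_k]$,
and the depletion of a state is $\sigma\,\Omega(n,q,q)$ — derived from
the microstate-level definition of the depletion operator, which
reproduces the $n_{\text{chain}}^2$ and $n_{\text{link}}$ totals exactly.
(The species-level normalization printed elsewhere as $N_{\vec p}$
disagrees with this for joins; we treat the microstate definition as
authoritative, and the suite cross-checks the two independent
implementations `homopolymer_macro_rhs` and `species_flux_projector`
against each other term by term.) Truncation at chain length `xmax` keeps
join channels whose product is too long as pure depletion, so lost
probability is visible as a mass deficit instead of being silently
renormalized away.

**Self-bonds.** Whether a directed bond $J_{ii}$ (a 1-ring) exists is
ambiguous in the source systems; the homopolymer fixture exposes
`allow_self` (default `FALSE`). The macro master equation as usually
written includes the 1-circularization channel, so the consistency
experiment between the two (acceptance criterion 7) runs the SSA with
`allow_self = TRUE`, making both routes describe the same world; the
σ-census targets use the default and are insensitive to the flag.

## Equilibrium analytics

With $\lambda = e^{\beta\mu}$ per mode, the monomer macrostate law is
Binomial$(N, \lambda/(1+\lambda))$, Poisson with mean $V\lambda'$
($\lambda' = N\lambda/V$) in the large-$N$ limit. Effective parameters
$\mu' = \mu + k_BT\log(N/V)$ and $\epsilon'$ absorb mode-count entropy;
the two $\log V$ sign conventions for $\epsilon'$ (homodimer-like vs
homopolymer) are stored per system because the two systems renormalize
differently. The polymer control parameter is
$\eta = e^{\beta(\mu'-\epsilon')}$.

For the directed homopolymer ($0<\eta<1$):
$\log Z/V = e^{\beta\epsilon'}\eta/(1-\eta) - \log(1-\eta)/V$, chain
concentrations $\propto e^{\beta\epsilon'}\eta^x$, ring concentrations
$\propto \eta^x/(xV)$, particle concentration diverging as
$e^{\beta\epsilon'}/\delta^2$, $\delta = 1-\eta$. The chain-length
distribution is geometric on $x \ge 1$; its mean is $1/(1-\eta)$ and its
variance $\eta/(1-\eta)^2$. The widely quoted mean $\eta/(1-\eta)$ is the
mean *excess* length (bonds per chain), $\sum_x (x-1)P(x)$; the package
returns both (`chain_length_mean`, `chain_length_excess_mean`) rather than
silently picking one, and the acceptance suite verifies the excess mean by
series summation. The isotropic variant (alternating symmetric bonds $I$,
$J$; even rings only, the 2-ring with symmetry factor 2, longer even rings
$4x$) diverges with coefficient $\tfrac32 e^{\beta\epsilon'}$ — the 3/2
against the directed system comes from the doubled even-chain species.
The branched system solves the tree recursion $\xi = \eta(1+\xi)^2$,
$\xi = (1-2\eta-\sqrt{1-4\eta})/(2\eta)$, defined for $\eta \le 1/4$, with
grove (ringed) species suppressed by $1/V$.

Every closed form is exercised against an independent route: certified
truncated summation of the defining species series (geometric tail below
$10^{-12}$ of the partial sum), fixed-point iteration for $\xi$, and — at
small $N$ — `exact_partition_oracle`, which enumerates all structurally
valid microstates and evaluates the Gibbs measure directly. Divergent
regimes ($\eta \ge 1$, $\eta > 1/4$) raise typed errors rather than
returning infinities.

`detailed_balance_rates` bridges statics and dynamics: with
$r_\text{create}/r_\text{annihilate} = e^{\beta\mu}$ and
$r_\text{bind}/r_\text{unbind} = e^{-\beta\epsilon}$ the stationary state
of the rule-built generator is exactly the Gibbs state, which the suite
checks to $10^{-8}$ by comparing the stationary vector with the oracle.

## The Wick engine

The factory representation builds the sum-over-complexes state by ordered
exponentials, $|{\rm sum}\rangle = e^{F_2}e^{F_1}|0\rangle$; the gallery
representation lists one creation operator per species. The engine
verifies their equivalence two independent ways:

1. **Combinatorially.** A factory term $F_2^p F_1^q/(p!q!)$ is a
   productive-ordered labeled product: $2p$ presence slots left of $q$
   creation slots. Contraction schemes pair slots — homodimer creations
   accept at most one contraction; homopolymer creations accept one per
   port (the non-central case), so complete schemes form a directed graph
   of in/out-degree $\le 1$ whose components are exactly labeled chains
   and rings. Only fully contracted residuals survive on the vacuum. The
   homodimer count $q!/(q-2p)!$ makes the closed form
   $(q-2p\ \text{monomers},\ p\ \text{dimers})$ with coefficient exactly 1
   (checked for $p \le 3$, $q \le 8$); homopolymer coefficients come out
   as 1 per species multiset after the ring rotation factor.
2. **By explicit matrices.** On small-$N$ spaces ($2^M$, $M \le 20$)
   the ordered exponentials terminate exactly (nilpotency), and
   `factory_gallery_check` demands integer equality coordinate by
   coordinate — homodimer $N=4$ and homopolymer $N=3$ in the suite.

Scheme enumeration is exhaustive recursion with guards ($p\le4$,
$q\le10$; full expansions capped at $2\times10^5$ schemes).

## What the generators emulate — and what a green test does not establish

The stochastic experiments use a stated world chosen once: ensembles of
500 trajectories, 50 (or 16) grid points, and unit per-instance rates for
the monomer ($N=20$), homodimer ($N=4$) and homopolymer ($N=3$)
comparisons — the reference experiments print no rate values, so these
defaults are the package's own, picked to put all species at comparable
abundances within a few relaxation times. The macro-equation experiment
uses $N = 60$, rates $(2/N, 1, 0.5, 1)$ and `xmax = 6`, putting typical
total occupancy far below $N$ (the regime where the species-count
equation's $\sigma_1 \approx N$ approximation is valid) while keeping
chains long enough to exercise joining, circularization and truncation.
Agreement is asserted within three standard errors at $\ge 90\%$ of grid
points, pooled over species.

A green ensemble test establishes consistency between two implementations
of the same stochastic law under permutation-symmetric, well-mixed,
zero-dimensional kinetics with time-independent rates. It does not probe
spatial effects, rate laws outside detailed balance conventions, large-$N$
scaling beyond the sizes run, or model files with features the fixtures
do not exercise. The synthetic model files are the fixtures themselves;
there is no external data.

## Known limitations

* The macro-level machinery (`homopolymer_reactions` and relatives) is
  specific to the homopolymer; other systems get micro-level treatment
  only.
* Canonical labels above the 40-vertex guard are not canonical (flagged
  by a `big:` prefix); trajectory post-processing at realistic sizes never
  reaches it.
* The SSA rescans eligibility in $O(|\mathcal R|)$ (`naive`) or updates it
  incrementally (`indexed`); neither removes the $O(N^2)$ instance count
  of bond rules, so very large $N$ needs a sparser instance
  representation than this package provides.
* No tau-leaping, hybrid ODE/SSA, moment closures, or spatial transport.
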