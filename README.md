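# polyfock

Rule-based modeling of multi-particle complexes — dimerization, polymer
chains and rings, branched assemblies — on a hard-core boson Fock space,
for people who study stochastic biochemical kinetics and equilibrium
self-assembly (complex formation in systems biology, polymerization
kinetics, biophysical models of macromolecular assembly).

## The idea

A system is described by excitation **modes**: particle modes $A_i$
($i = 1..N$ internal indices, which give outwardly identical particles an
identity), site modes ($a_i$ excited = binding site of particle $i$
occupied), and bond modes ($J_{ij}$ excited = a bond joins two sites).
A microstate is the set of excited modes. Four nilpotent mode operators —
creation $\hat A_i$, annihilation $\check A_i$, presence $\bar A_i$,
absence $\tilde A_i$ — build everything else. A reaction rule is an
indexed operator product with a rate, e.g. bond formation in the directed
homopolymer,

$$R_3 = \sum_{i\neq j} \hat J_{ij}\, \hat a_i\, \hat b_j\, \bar A_i \bar A_j ,$$

and the microstate master equation generator is
$W = \sum_l r_l \sum_i (R_{li} - \grave R_{li})$ with depletion operators
$\grave R$ derived factor-wise. From four such rules the homopolymer
generates chains and rings of every length; the package gives you

* **exact propagation** $\psi(t) = e^{tW}\psi(0)$ on the reachable
  subspace (uniformization; exact lumping over the species census for
  permutation-symmetric models),
* an eligibility-driven **Gillespie simulator** (naive rescan and
  incremental index, bitwise-identical trajectories),
* a **species census** of trajectories via canonical labeling of complex
  topologies (chains, rings, trees, groves, generic colored graphs),
* the species-count (macro) **master equation** for the homopolymer with
  $\sigma$ multiplicities and $\Omega$ occupancy coefficients, truncated
  at a chain length with the truncation flux reported,
* **equilibrium analytics**: effective chemical potentials, partition
  function densities and critical scaling for the directed, isotropic and
  branched homopolymers, with an exact small-$N$ enumeration oracle,
* a brute-force **Wick contraction engine** verifying the factory/gallery
  equivalence both combinatorially and by explicit matrices.

## Worked example

Homodimerization at $N = 4$: four monomers can bind pairwise. Simulate,
census the trajectory, and compare with the exact master equation.

```r
library(polyfock)

spec <- builtin_fixture("homodimer", 4)   # rules r1..r4, all rates 1
fm   <- compile_model(spec)
fm
#> <fock_model> N = 4 | 14 modes, 20 rule instances

## stochastic trajectory from the vacuum
traj <- run_ssa(fm, tmax = 3, seed = 1)
trajectory_census(traj, times = c(1, 2, 3), fm)
#>      chain-1 chain-2
#> [1,]       3       0
#> [2,]       3       0
#> [3,]       0       2
```

`chain-1` counts free monomers, `chain-2` dimers: at $t=1$ this
trajectory holds three free monomers; by $t=3$ they have paired into two
dimers. The exact equilibrium from the rule-built generator:

```r
sp   <- enumerate_reachable(fm, init = integer(0))   # 43 microstates
W    <- build_generator(fm, sp)                      # columns sum to 0
psi0 <- numeric(43); psi0[1] <- 1
psi  <- propagate(W, psi0, times = 50)               # ~stationary
round(macrostate_distribution(psi[, 1], sp, census_labeler(fm)), 3)
#>           chain-1:1 chain-1:1|chain-2:1           chain-1:2
#>               0.093               0.279               0.140
#> chain-1:2|chain-2:1           chain-1:3           chain-1:4
#>               0.140               0.093               0.023
#>           chain-2:1           chain-2:2               empty
#>               0.140               0.070               0.023
```

The label `chain-1:1|chain-2:1` reads "one free monomer and one dimer";
with all rates 1 that mixed macrostate is the most likely at
equilibrium.

Equilibrium analytics tie dynamics to statics: with rates from
`detailed_balance_rates` the stationary vector of `W` equals the Gibbs
state `exact_partition_oracle` computes by enumeration (the suite checks
this to 1e-8). For polymers:

```r
p <- eq_params(N = 100, V = 1, system = "homopolymer",
               mu_prime = log(0.5), eps_prime = 0)   # eta = 0.5
b <- homopolymer_bulk(p)
c(b$chain_length_excess_mean, b$chain_length_var)
#> [1] 1 2
```

— at $\eta = 1/2$ a chain carries on average one bond
(excess length $\eta/(1-\eta) = 1$) with length variance
$\eta/(1-\eta)^2 = 2$.

And the Wick engine reproduces the worked contraction count for the
$p=2,\,q=5$ factory term (both contractions on one $F_2$ factor:
$(5\cdot4)\times(4\cdot1)/2! = 40$):

```r
count_schemes_by_topology(2, 5, "homodimer", "same_F2_double")
#> [1] 40
factory_gallery_check("homodimer", 4)$equal
#> [1] TRUE
```

## Command line

A thin CLI ships in `inst/cli/polyfock`:

```sh
polyfock fixtures --name homopolymer --N 20 --out model.txt
polyfock validate model.txt
polyfock simulate --model model.txt --tmax 5 --runs 10 --seed 1 --out traj/
polyfock census --model model.txt --traj traj/ --times 0:5:0.5 --stats --out counts.tsv
polyfock equilibrium --system branched --mu -3 --eps 0 --N 100 --out eq.tsv
```

See `vignettes/polyfock-methods.Rmd` for the model, the numerical
choices (uniformization, lumping verification, canonical labeling,
truncation accounting) and the package's design decisions.
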