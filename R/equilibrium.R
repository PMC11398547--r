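## equilibrium_analytics: effective chemical potentials, Poisson macrostate
## laws, polymer partition-function densities, chain-length statistics,
## critical scaling, and the exact small-N enumeration oracle.

#' Equilibrium parameter bundle
#'
#' Collects the bare parameters and derives the renormalized quantities:
#' per-mode fugacity `lambda = e^(beta mu)`, effective fugacity
#' `lambda' = (N/V) lambda`, effective chemical potential
#' `mu' = mu + kBT log(N/V)`, effective interaction energy `eps'`
#' (`eps - kBT log V` for the homodimer/isotropic/branched convention,
#' `eps + kBT log V` for the homopolymer — the two sign conventions are kept
#' per system, as each system's renormalization demands), the polymer
#' control parameter `eta = e^(beta (mu' - eps'))` (Boltzmann weight of one
#' particle with a dangling bond) and its distance to criticality `delta`
#' (`1 - eta`, or `1/4 - eta` for the branched system).
#'
#' @param mu Bare chemical potential.
#' @param eps Bare interaction energy (ignored for the monomer).
#' @param N Mode count.
#' @param V Volume.
#' @param beta Inverse temperature (kBT = 1 by default).
#' @param system One of `"monomer"`, `"homodimer"`, `"homopolymer"`,
#'   `"isotropic"`, `"branched"`.
#' @param mu_prime,eps_prime Optional direct overrides of the effective
#'   parameters (then `mu`/`eps` may be omitted).
#' @return An `eq_params` list.
#' @export
eq_params <- function(mu = NULL, eps = NULL, N, V = 1, beta = 1,
                      system = c("monomer", "homodimer", "homopolymer",
                                 "isotropic", "branched"),
                      mu_prime = NULL, eps_prime = NULL) {
  system <- match.arg(system)
  eps_sign <- if (system == "homopolymer") +1 else -1
  if (is.null(mu_prime)) {
    stopifnot(!is.null(mu))
    mu_prime <- mu + log(N / V) / beta
  } else if (is.null(mu)) mu <- mu_prime - log(N / V) / beta
  if (is.null(eps_prime)) {
    if (!is.null(eps)) eps_prime <- eps + eps_sign * log(V) / beta
  } else if (is.null(eps)) eps <- eps_prime - eps_sign * log(V) / beta
  lambda <- exp(beta * mu)
  eta <- if (!is.null(eps_prime)) exp(beta * (mu_prime - eps_prime)) else NA_real_
  structure(list(mu = mu, eps = eps, N = N, V = V, beta = beta,
                 system = system, lambda = lambda,
                 lambda_prime = (N / V) * lambda,
                 mu_prime = mu_prime, eps_prime = eps_prime,
                 eta = eta,
                 delta = if (system == "branched") 0.25 - eta else 1 - eta),
            class = "eq_params")
}

#' Monomer gas in equilibrium
#'
#' Finite N: binomial macrostate law with per-mode excitation probability
#' `lambda / (1 + lambda)` and `Z = (1 + lambda)^N`. Large N at fixed
#' `lambda'`: Poisson with mean `V lambda'` and `log Z = V lambda'`.
#'
#' @param params An [eq_params()].
#' @return List: `Z`, `pmf` (over n = 0..N), `mean_count`, `concentration`,
#'   and the Poisson limit (`poisson_mean`, `logZ_poisson`).
#' @export
monomer_equilibrium <- function(params) {
  lam <- params$lambda; N <- params$N
  p <- lam / (1 + lam)
  list(Z = (1 + lam)^N,
       pmf = setNames(dbinom(0:N, N, p), 0:N),
       mean_count = N * p,
       concentration = N * p / params$V,
       poisson_mean = params$V * params$lambda_prime,
       logZ_poisson = params$V * params$lambda_prime)
}

#' Effective chemical potentials of the homodimer species
#'
#' `mu'_M = mu'`; `mu'_D = 2 mu' - eps' - kBT log 2`, the log term being the
#' dimer's two-fold symmetry. Both depend on (mu, eps, N, V) only through
#' (mu', eps'): the system is exactly renormalizable.
#'
#' @param params An [eq_params()] (homodimer convention).
#' @return data.frame over species `monomer`, `dimer`: `mu_prime`,
#'   `lambda_prime`, `n_internal` (mode counts N and N(N-1)/2).
#' @export
homodimer_effective_potentials <- function(params) {
  b <- params$beta
  muM <- params$mu_prime
  muD <- 2 * params$mu_prime - params$eps_prime - log(2) / b
  data.frame(species = c("monomer", "dimer"),
             mu_prime = c(muM, muD),
             lambda_prime = exp(b * c(muM, muD)),
             n_internal = c(params$N, params$N * (params$N - 1) / 2),
             stringsAsFactors = FALSE)
}

#' Effective potentials of homopolymer chains and rings
#'
#' `mu'_Cx = x (mu' - eps') + eps'` and
#' `mu'_Rx = x (mu' - eps') - kBT log x - kBT log V`; equivalently
#' fugacities `lambda'_Cx = e^(beta eps') eta^x` and
#' `lambda'_Rx = eta^x / (x V)` (ring concentrations scale as 1/V).
#'
#' @param params An [eq_params()] (homopolymer convention).
#' @param x Polymer length (vectorized), `x >= 1`.
#' @return data.frame with chain and ring potentials and fugacities per x.
#' @export
homopolymer_species_potentials <- function(params, x) {
  stopifnot(all(x >= 1))
  b <- params$beta
  muC <- x * (params$mu_prime - params$eps_prime) + params$eps_prime
  muR <- x * (params$mu_prime - params$eps_prime) - log(x) / b -
    log(params$V) / b
  data.frame(x = x, mu_prime_chain = muC, mu_prime_ring = muR,
             lambda_prime_chain = exp(b * muC),
             lambda_prime_ring = exp(b * muR))
}

## geometric-tail-certified truncation point for sum of eta^x terms
series_xmax <- function(eta, tol = 1e-12) {
  stopifnot(eta > 0, eta < 1)
  max(64L, ceiling(log(tol * (1 - eta)) / log(eta)) + 8L)
}

#' Bulk equilibrium of the directed homopolymer
#'
#' Log partition function density, particle concentration and chain-length
#' statistics, either in closed form or by certified truncated summation of
#' the defining species series (`route = "series"`, the independent check).
#' The chain-length distribution is geometric, `P(x) proportional to eta^x`
#' on `x >= 1`; `chain_length_mean` is its mean `1/(1-eta)` and
#' `chain_length_excess_mean` the mean number of bonds per chain
#' `eta/(1-eta)` (which also equals the variance-matching geometric
#' parameterization quoted in critical-scaling arguments);
#' `chain_length_var` is `eta/(1-eta)^2`.
#'
#' @param params An [eq_params()] with `0 < eta < 1`.
#' @param route `"closed"` or `"series"`.
#' @param tol Series tail tolerance.
#' @return List: `logZ_V`, `concentration`, `chain_length_mean`,
#'   `chain_length_excess_mean`, `chain_length_var`,
#'   `divergence_coefficient` (of `1/delta^2` in the concentration).
#' @export
homopolymer_bulk <- function(params, route = c("closed", "series"),
                             tol = 1e-12) {
  route <- match.arg(route)
  eta <- params$eta; b <- params$beta; V <- params$V
  if (is.na(eta) || eta >= 1)
    stop("partition function diverges: eta must lie in (0, 1), got ", eta)
  ee <- exp(b * params$eps_prime)
  if (route == "closed") {
    logZ_V <- ee * eta / (1 - eta) - log(1 - eta) / V
    conc <- ee * eta / (1 - eta)^2 + (eta / (1 - eta)) / V
    mean_x <- 1 / (1 - eta)
    excess <- eta / (1 - eta)
    var_x <- eta / (1 - eta)^2
  } else {
    xs <- seq_len(series_xmax(eta, tol))
    chain_terms <- ee * eta^xs
    ring_terms <- eta^xs / (xs * V)
    logZ_V <- sum(chain_terms) + sum(ring_terms)
    conc <- sum(xs * chain_terms) + sum(eta^xs) / V
    w <- eta^xs / sum(eta^xs)
    mean_x <- sum(xs * w)
    excess <- sum((xs - 1) * w)
    var_x <- sum((xs - mean_x)^2 * w)
  }
  list(logZ_V = logZ_V, concentration = conc,
       chain_length_mean = mean_x, chain_length_excess_mean = excess,
       chain_length_var = var_x,
       divergence_coefficient = ee)
}

#' Bulk equilibrium of the isotropic homopolymer
#'
#' Two alternating symmetric bond classes: odd chains are a single species,
#' even chains come in two species (I/J exchange), rings exist only at even
#' length (the 2-ring with symmetry factor 2, longer even rings with 4x).
#' The concentration divergence coefficient is `3/2 e^(beta eps')`, a
#' factor 3/2 above the directed homopolymer.
#'
#' @inheritParams homopolymer_bulk
#' @return List: `logZ_V`, `concentration`, `divergence_coefficient`.
#' @export
isotropic_bulk <- function(params, route = c("closed", "series"),
                           tol = 1e-12) {
  route <- match.arg(route)
  eta <- params$eta; b <- params$beta; V <- params$V
  if (is.na(eta) || eta >= 1)
    stop("partition function diverges: eta must lie in (0, 1), got ", eta)
  ee <- exp(b * params$eps_prime)
  if (route == "closed") {
    logZ_V <- ee * (eta + 2 * eta^2) / (1 - eta^2) +
      (eta^2 / 4 - log(1 - eta^2) / 4) / V
    conc <- ee * eta * (1 + 4 * eta + eta^2) / (1 - eta^2)^2 +
      (eta^2 / 2) * (1 + 1 / (1 - eta^2)) / V
  } else {
    xs <- seq_len(series_xmax(eta, tol))
    odd <- xs[xs %% 2 == 1L]; even <- xs[xs %% 2 == 0L]
    chain_terms <- c(ee * eta^odd, 2 * ee * eta^even)
    chain_sizes <- c(odd, even)
    ring_sizes <- even
    ring_terms <- ifelse(ring_sizes == 2L, eta^2 / (2 * V),
                         eta^ring_sizes / (2 * ring_sizes * V))
    logZ_V <- sum(chain_terms) + sum(ring_terms)
    conc <- sum(chain_sizes * chain_terms) + sum(ring_sizes * ring_terms)
  }
  list(logZ_V = logZ_V, concentration = conc,
       divergence_coefficient = 1.5 * ee)
}

#' Bulk equilibrium of the branched directed homopolymer
#'
#' Trees (rooted at a particle with free site c) and groves (trees hanging
#' off a central ring). `xi`, the partition function of a tree with one
#' dangling bond, satisfies `xi = eta (1 + xi)^2`; the closed solution is
#' `xi = (1 - 2 eta - sqrt(1 - 4 eta)) / (2 eta)`, defined for
#' `0 < eta <= 1/4`. Near `delta = 1/4 - eta -> 0` the concentration scales
#' as `e^(beta eps')/(2 sqrt(delta)) + 1/(8 V delta)`.
#'
#' @param params An [eq_params()] with `0 < eta <= 1/4`.
#' @param route `"closed"`, or `"series"` (fixed-point iteration of the
#'   tree recursion plus grove series, the independent check).
#' @param tol Convergence/tail tolerance for the series route.
#' @return List: `xi`, `logZ_V`, `concentration`,
#'   `tree_coefficient` (of `delta^(-1/2)`), `grove_coefficient`
#'   (of `(V delta)^(-1)`).
#' @export
branched_bulk <- function(params, route = c("closed", "series"),
                          tol = 1e-14) {
  route <- match.arg(route)
  eta <- params$eta; b <- params$beta; V <- params$V
  if (is.na(eta) || eta <= 0 || eta > 0.25)
    stop("the partition function is not defined for eta > 1/4 (eta = ",
         eta, ")")
  ee <- exp(b * params$eps_prime)
  if (route == "closed") {
    s <- sqrt(1 - 4 * eta)
    xi <- (1 - 2 * eta - s) / (2 * eta)
    logZ_V <- ee * xi - log(1 - 4 * eta) / (2 * V)
    dxi <- (2 * eta / s - 1 + s) / (2 * eta^2)       # d xi / d eta
    conc <- ee * eta * dxi + 2 * eta / ((1 - 4 * eta) * V)
  } else {
    fixed_point_xi <- function(e, max_iter = 1e6L) {
      ## converges to the smaller root for e < 1/4; at the tangent point
      ## e = 1/4 convergence is O(1/n), so cap the iterations
      xi <- 0
      for (it in seq_len(max_iter)) {
        xin <- e * (1 + xi)^2
        if (!is.finite(xin) || abs(xin - xi) < tol) break
        xi <- xin
      }
      xi
    }
    series_logZ <- function(e) {
      xi <- fixed_point_xi(e)
      y <- 2 * e * (1 + xi)
      xs <- seq_len(if (y < 1) series_xmax(y, 1e-12) else 4096L)
      ee * xi + sum(y^xs / xs) / V
    }
    xi <- fixed_point_xi(eta)
    logZ_V <- series_logZ(eta)
    ## concentration = (1/beta) d logZ/V / d mu' = eta d(logZ/V)/d eta
    h <- 1e-6 * eta
    conc <- eta * (series_logZ(eta + h) - series_logZ(eta - h)) / (2 * h)
  }
  list(xi = xi, logZ_V = logZ_V, concentration = conc,
       tree_coefficient = ee / 2, grove_coefficient = 1 / 8)
}

#' Exact partition-function oracle by microstate enumeration
#'
#' Enumerates every structurally valid microstate (the closure of the
#' vacuum under the model's reversible rules), evaluates
#' `H(s) = sum_terms sign * coef * (# excited modes of the term's field)`
#' with `coef` values taken from `params` by name (`mu`, `eps`), and returns
#' the exact Gibbs measure.
#'
#' @param fm Compiled model (with `[hamiltonian]` terms).
#' @param params An [eq_params()] supplying `mu`, `eps`, `beta`.
#' @param cap Reachable-state cap.
#' @return List: `Z`, `space`, `prob` (aligned with `space$states`),
#'   `energy`.
#' @export
exact_partition_oracle <- function(fm, params, cap = 2e5) {
  terms <- fm$spec$hamiltonian
  if (length(terms) == 0L) stop("model has no hamiltonian terms")
  space <- enumerate_reachable(fm, init = integer(0), cap = cap)
  coefs <- c(mu = params$mu, eps = params$eps)
  md <- fm$modes
  energy <- vapply(space$states, function(s) {
    H <- 0
    for (tm in terms) {
      cnt <- sum(md$field[s] == tm$field)
      H <- H + tm$sign * coefs[[tm$coef]] * cnt
    }
    H
  }, 1)
  w <- exp(-params$beta * energy)
  Z <- sum(w)
  list(Z = Z, space = space, prob = w / Z, energy = energy)
}

#' Detailed-balance rates for a fixture model
#'
#' Per-instance rates making the rule-built generator's stationary state the
#' Gibbs state of the model's Hamiltonian: particle creation over
#' annihilation `= e^(beta mu)`, bond creation over annihilation
#' `= e^(-beta eps)`.
#'
#' @param fm Compiled model (fixture-style reversible rule pairs).
#' @param params An [eq_params()] supplying `mu`, `eps`, `beta`.
#' @return Named numeric vector of rates by rule name, suitable for
#'   [builtin_fixture()]'s `rates` argument.
#' @export
detailed_balance_rates <- function(fm, params) {
  out <- numeric(0)
  for (r in fm$spec$rules) {
    kinds <- vapply(r$factors, function(fa)
      paste(fm$fields[[fa$field]]$kind, fa$op), "")
    rate <-
      if ("particle create" %in% kinds) exp(params$beta * params$mu)
      else if ("particle annihilate" %in% kinds) 1
      else if ("bond create" %in% kinds) exp(-params$beta * params$eps)
      else if ("bond annihilate" %in% kinds) 1
      else 1
    out[r$name] <- rate
  }
  out
}
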