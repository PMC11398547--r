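test_that("monomer equilibrium matches the enumeration oracle", {
  params <- eq_params(mu = log(0.5), N = 3, system = "monomer")
  eqm <- monomer_equilibrium(params)
  expect_equal(eqm$Z, 3.375)   # (1 + 1/2)^3, verified by enumeration below
  fm <- compile_model(builtin_fixture("monomer", 3))
  oracle <- exact_partition_oracle(fm, params)
  expect_equal(oracle$Z, eqm$Z)
  expect_equal(eqm$mean_count, 3 * 0.5 / 1.5)
  ## mu -> -Inf: point mass at the vacuum
  p0 <- eq_params(mu = -Inf, N = 3, system = "monomer")
  eq0 <- monomer_equilibrium(p0)
  expect_equal(eq0$Z, 1)
  expect_equal(unname(eq0$pmf["0"]), 1)
})

test_that("homodimer species potentials renormalize exactly", {
  p1 <- eq_params(N = 10, V = 2, beta = 1, system = "homodimer",
                  mu_prime = 0, eps_prime = 0)
  tab <- homodimer_effective_potentials(p1)
  expect_equal(tab$mu_prime, c(0, -log(2)))
  ## changing (N, V) at fixed (mu', eps') leaves both outputs unchanged
  p2 <- eq_params(N = 1000, V = 37, beta = 1, system = "homodimer",
                  mu_prime = 0, eps_prime = 0)
  expect_equal(homodimer_effective_potentials(p2)$mu_prime, tab$mu_prime)
  expect_equal(tab$n_internal, c(10, 45))
})

test_that("homopolymer species fugacities follow eta powers", {
  params <- eq_params(N = 50, V = 4, beta = 1, system = "homopolymer",
                      mu_prime = log(0.3), eps_prime = 0.2)
  tab <- homopolymer_species_potentials(params, 1:6)
  eta <- params$eta
  expect_equal(tab$lambda_prime_chain, exp(0.2) * eta^(1:6))
  expect_equal(tab$lambda_prime_ring, eta^(1:6) / ((1:6) * 4))
  ## x = 1 chain is the free monomer
  expect_equal(tab$lambda_prime_chain[1], exp(params$mu_prime))
  ## ring concentration scales as 1/V
  params2 <- eq_params(N = 50, V = 8, beta = 1, system = "homopolymer",
                       mu_prime = log(0.3), eps_prime = 0.2)
  tab2 <- homopolymer_species_potentials(params2, 1:6)
  expect_equal(tab2$lambda_prime_ring * 8, tab$lambda_prime_ring * 4)
  expect_error(homopolymer_species_potentials(params, 0), "x >= 1")
})

test_that("homopolymer bulk closed forms equal their defining series", {
  for (eta in c(0.2, 0.5, 0.9)) {
    params <- eq_params(N = 100, V = 3, system = "homopolymer",
                        mu_prime = log(eta), eps_prime = 0)
    closed <- homopolymer_bulk(params)
    series <- homopolymer_bulk(params, "series")
    for (f in names(closed))
      expect_equal(closed[[f]], series[[f]], tolerance = 1e-10, label = f)
  }
  params <- eq_params(N = 100, V = 1, system = "homopolymer",
                      mu_prime = log(0.5), eps_prime = 0)
  bulk <- homopolymer_bulk(params)
  expect_equal(bulk$chain_length_excess_mean, 1)
  expect_equal(bulk$chain_length_var, 2)
  expect_error(homopolymer_bulk(eq_params(N = 10, V = 1,
    system = "homopolymer", mu_prime = 0.1, eps_prime = 0)), "diverges")
})

test_that("isotropic bulk matches its series and carries the 3/2 factor", {
  params <- eq_params(N = 100, V = 2, system = "isotropic",
                      mu_prime = log(0.99), eps_prime = 0)
  closed <- isotropic_bulk(params)
  series <- isotropic_bulk(params, "series")
  expect_equal(closed$logZ_V, series$logZ_V, tolerance = 1e-10)
  expect_equal(closed$concentration, series$concentration, tolerance = 1e-8)
  dir_params <- eq_params(N = 100, V = 2, system = "homopolymer",
                          mu_prime = log(0.99), eps_prime = 0)
  ratio <- closed$divergence_coefficient /
    homopolymer_bulk(dir_params)$divergence_coefficient
  expect_equal(ratio, 1.5)
  expect_error(isotropic_bulk(eq_params(N = 10, V = 1, system = "isotropic",
    mu_prime = 0.2, eps_prime = 0)), "diverges")
})

test_that("branched trees satisfy the self-similar recursion", {
  p25 <- eq_params(N = 10, V = 1, system = "branched",
                   mu_prime = log(0.25), eps_prime = 0)
  expect_equal(branched_bulk(p25)$xi, 1)
  for (eta in seq(0.01, 0.25, by = 0.02)) {
    pp <- eq_params(N = 10, V = 1, system = "branched",
                    mu_prime = log(eta), eps_prime = 0)
    xi <- branched_bulk(pp)$xi
    expect_lt(abs(xi - eta * (1 + xi)^2), 1e-12)
  }
  ## xi ~ eta as eta -> 0
  tiny <- eq_params(N = 10, V = 1, system = "branched",
                    mu_prime = log(1e-5), eps_prime = 0)
  expect_equal(branched_bulk(tiny)$xi / 1e-5, 1, tolerance = 1e-3)
  ## closed form vs fixed-point series
  pmid <- eq_params(N = 10, V = 2, system = "branched",
                    mu_prime = log(0.18), eps_prime = 0.4)
  c1 <- branched_bulk(pmid); c2 <- branched_bulk(pmid, "series")
  expect_equal(c1$xi, c2$xi, tolerance = 1e-10)
  expect_equal(c1$logZ_V, c2$logZ_V, tolerance = 1e-10)
  expect_equal(c1$concentration, c2$concentration, tolerance = 1e-6)
  expect_error(branched_bulk(eq_params(N = 10, V = 1, system = "branched",
    mu_prime = log(0.3), eps_prime = 0)), "not defined")
})

test_that("the enumeration oracle reproduces hand partition functions", {
  params <- eq_params(mu = 0.2, eps = 0.5, N = 2, system = "homodimer")
  fm <- compile_model(builtin_fixture("homodimer", 2))
  oracle <- exact_partition_oracle(fm, params)
  lam <- exp(0.2)
  expect_equal(oracle$Z, 1 + 2 * lam + lam^2 + lam^2 * exp(-0.5))
  ## beta = 0: every structurally valid microstate weighs 1
  p0 <- eq_params(mu = 0.7, eps = -0.3, N = 2, beta = 0, system = "homodimer")
  expect_equal(exact_partition_oracle(fm, p0)$Z, 5)
})

test_that("detailed-balance rates make W stationary at the Gibbs state", {
  params <- eq_params(mu = 0.4, eps = -0.9, N = 3, system = "homodimer")
  fm0 <- compile_model(builtin_fixture("homodimer", 3))
  rates <- detailed_balance_rates(fm0, params)
  expect_equal(unname(rates["r1"] / rates["r2"]), exp(0.4))
  expect_equal(unname(rates["r3"] / rates["r4"]), exp(0.9))
  fm <- compile_model(builtin_fixture("homodimer", 3, rates = as.list(rates)))
  sp <- enumerate_reachable(fm, init = integer(0))
  W <- build_generator(fm, sp)
  p <- stationary_of(W)
  oracle <- exact_partition_oracle(fm, params)
  expect_lt(max(abs(p - oracle$prob)), 1e-8)
  ## mu = 0 gives symmetric creation/annihilation
  r0 <- detailed_balance_rates(fm0, eq_params(mu = 0, eps = 1, N = 3,
                                              system = "homodimer"))
  expect_equal(unname(r0["r1"]), unname(r0["r2"]))
})

test_that("species sectors factorize as N grows at fixed lambda'", {
  lambda_prime <- 0.4   # V = 1
  tv <- vapply(c(2, 4, 8), function(N) {
    params <- eq_params(mu = log(lambda_prime / N), eps = 0.5,
                        N = N, system = "homodimer")
    fm <- compile_model(builtin_fixture("homodimer", N))
    oracle <- exact_partition_oracle(fm, params)
    lab <- census_labeler(fm)
    joint <- macrostate_distribution(oracle$prob, oracle$space, lab)
    counts <- lapply(names(joint), parse_census_label)
    m <- vapply(counts, function(cc) if ("chain-1" %in% names(cc))
      cc[["chain-1"]] else 0L, 1L)
    d <- vapply(counts, function(cc) if ("chain-2" %in% names(cc))
      cc[["chain-2"]] else 0L, 1L)
    ## sector-factorized reference: product of Poisson laws at the species'
    ## effective fugacities
    pt <- homodimer_effective_potentials(params)
    lamM <- pt$lambda_prime[1]; lamD <- pt$lambda_prime[2]
    ref <- dpois(m, lamM) * dpois(d, lamD)
    sum(abs(as.numeric(joint) - ref)) / 2 + (1 - sum(ref))/2
  }, 1)
  expect_true(all(diff(tv) < 0))
  expect_lt(tv[3], tv[1] / 2)
})

test_that("SSA at detailed-balance rates reproduces the exponential chain-length law", {
  ## eta = 0.3 with e^(beta eps') = 3, N = 12 >> typical occupancy
  N <- 12
  eps <- log(3)           # V = 1, homopolymer convention: eps' = eps
  mu_prime <- log(0.3) + eps
  params <- eq_params(mu = mu_prime - log(N), eps = eps, N = N,
                      system = "homopolymer")
  fm0 <- compile_model(builtin_fixture("homopolymer", N))
  rates <- detailed_balance_rates(fm0, params)
  fm <- compile_model(builtin_fixture("homopolymer", N, rates = as.list(rates)))
  n_runs <- 120
  c1 <- numeric(n_runs); c2 <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    traj <- run_ssa(fm, 12, seed = 1000 + r)
    cc <- microstate_to_complexes(fm, replay_state(traj, length(traj$times)),
                                  check = FALSE)
    c1[r] <- if ("chain-1" %in% names(cc)) cc[["chain-1"]] else 0
    c2[r] <- if ("chain-2" %in% names(cc)) cc[["chain-2"]] else 0
  }
  ## <c_{x+1}> / <c_x> ~ eta: test c2 - eta c1 = 0 within 3 SE
  d <- c2 - params$eta * c1
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(n_runs) + 1e-12)
})
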