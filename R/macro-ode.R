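## Macro-level (species-count) master equation machinery: the combinatorial
## occupancy coefficient Omega, rule-derived species reactions with their
## product-microstate multiplicities sigma, the flux projector, and the
## truncated homopolymer macrostate master equation.

#' Occupancy coefficient for species reactions
#'
#' `Omega(n, q, p) = prod_k choose(n_k + q_k - p_k, q_k) * 1[n_k >= p_k]`:
#' the number of ways the reactant multiset `q` can be drawn when the state
#' reached after the reaction is `n` (with `p` the product multiset).
#'
#' @param n,q,p Equal-length nonnegative integer vectors over species.
#' @return Nonnegative number.
#' @export
omega_coefficient <- function(n, q, p = rep(0L, length(n))) {
  stopifnot(length(q) == length(n), length(p) == length(n),
            all(q >= 0), all(p >= 0))
  if (any(n < p)) return(0)
  prod(choose(n + q - p, q))
}

## --- homopolymer species bookkeeping --------------------------------------
## species vector layout: chains c_1..c_xmax then rings r_1..r_xmax

hp_species_names <- function(xmax)
  c(paste0("chain-", seq_len(xmax)), paste0("ring-", seq_len(xmax)))

hp_zero <- function(xmax) setNames(integer(2 * xmax), hp_species_names(xmax))

hp_key <- function(n) paste(n, collapse = ",")

hp_mass <- function(n, xmax) sum(seq_len(xmax) * (n[seq_len(xmax)] +
                                                  n[xmax + seq_len(xmax)]))

#' Species reactions of the nonequilibrium homopolymer
#'
#' The gallery of species-specific reactions the four homopolymer rules
#' drive, truncated at chain/ring length `xmax`, each with its
#' product-microstate multiplicity `sigma`: monomer creation (`sigma ~ N`),
#' monomer annihilation (`sigma = 1`), chain joining (`sigma = 2` for both
#' unequal and equal lengths), circularization (`sigma = 1`), chain
#' splitting (`sigma = 2` unequal, `1` equal), and ring cutting
#' (`sigma = x`). Joins whose product exceeds `xmax` are kept as truncated
#' reactions: they deplete but produce nothing inside the support.
#'
#' @param rates Numeric `c(r1, r2, r3, r4)` (per-instance rates).
#' @param N Mode count (enters only through the creation multiplicity).
#' @param xmax Truncation length.
#' @param allow_self Include 1-circularization / 1-ring cutting (self-bond
#'   `J(i,i)`); matches the fixture's `allow_self` flag.
#' @return List of reactions `list(rate, sigma, q, p, truncated, name)` with
#'   `q`, `p` full-length species count vectors.
#' @export
homopolymer_reactions <- function(rates, N, xmax, allow_self = TRUE) {
  stopifnot(length(rates) == 4, xmax >= 1)
  r1 <- rates[1]; r2 <- rates[2]; r3 <- rates[3]; r4 <- rates[4]
  z <- hp_zero(xmax)
  cx <- function(x) { v <- z; v[x] <- v[x] + 1L; v }
  rx <- function(x) { v <- z; v[xmax + x] <- v[xmax + x] + 1L; v }
  out <- list()
  add <- function(rate, sigma, q, p, truncated = FALSE, name = "") {
    out[[length(out) + 1L]] <<- list(rate = rate, sigma = sigma, q = q, p = p,
                                     truncated = truncated, name = name)
  }
  add(r1, N, z, cx(1), name = "create")
  add(r2, 1, cx(1), z, name = "annihilate")
  for (x in seq_len(xmax)) for (y in x:xmax) {
    q <- cx(x) + cx(y)
    sigma <- 2                        # both unequal and equal joins: sigma = 2
    if (x + y <= xmax)
      add(r3, sigma, q, cx(x + y), name = sprintf("join-%d+%d", x, y))
    else
      add(r3, sigma, q, z, truncated = TRUE,
          name = sprintf("join-%d+%d(trunc)", x, y))
  }
  for (x in seq_len(xmax)) if (x >= 2 || allow_self)
    add(r3, 1, cx(x), rx(x), name = sprintf("circularize-%d", x))
  for (x in seq_len(xmax)) for (y in x:xmax) {
    if (x + y > xmax) next
    add(r4, if (x == y) 1 else 2, cx(x + y), cx(x) + cx(y),
        name = sprintf("split-%d+%d", x, y))
  }
  for (x in seq_len(xmax)) if (x >= 2 || allow_self)
    add(r4, x, rx(x), cx(x), name = sprintf("cut-ring-%d", x))
  out
}

#' Flux projector of a species-reaction gallery
#'
#' For a macrostate `n`, returns the components of `|J(n)>`: for each
#' reaction, a reaction term `sigma * Omega(n, q, p)` attached to the state
#' `n + q - p` (the state whose probability feeds `dP(n)/dt`) and a
#' depletion term `-sigma * Omega(n, q, q)` attached to `n` itself.
#'
#' @param reactions Reaction list (e.g. [homopolymer_reactions()]); `q` and
#'   `p` must not overlap.
#' @param n Species count vector.
#' @return data.frame with columns `state` (key string), `coef`, `reaction`.
#' @export
species_flux_projector <- function(reactions, n) {
  states <- character(0); coefs <- numeric(0); names_ <- character(0)
  for (rc in reactions) {
    if (any(rc$q > 0 & rc$p > 0)) stop("overlapping q and p in reaction ",
                                       rc$name)
    if (!rc$truncated) {
      w <- rc$rate * rc$sigma * omega_coefficient(n, rc$q, rc$p)
      if (w > 0) {
        states <- c(states, hp_key(n + rc$q - rc$p))
        coefs <- c(coefs, w); names_ <- c(names_, rc$name)
      }
    }
    wd <- rc$rate * rc$sigma * omega_coefficient(n, rc$q, rc$q)
    if (wd > 0) {
      states <- c(states, hp_key(n)); coefs <- c(coefs, -wd)
      names_ <- c(names_, paste0(rc$name, "-depletion"))
    }
  }
  data.frame(state = states, coef = coefs, reaction = names_,
             stringsAsFactors = FALSE)
}

#' Right-hand side of the truncated homopolymer macrostate master equation
#'
#' Direct term-by-term implementation of the macrostate master equation for
#' the homopolymer (chain joining with factor 2 for unequal lengths,
#' equal-length joining, circularization, the three reverse processes with
#' multiplicities 2, 1, x, and the depletion coefficient
#' `N r1 + r2 c1 + r3 nchain^2 + r4 nlink`), truncated at length `xmax`.
#' Deliberately implemented independently of [species_flux_projector()] so
#' the two routes can be cross-checked.
#'
#' @param P Named numeric vector: state key (see below) -> probability. Keys
#'   are comma-joined count vectors `c_1..c_xmax, r_1..r_xmax`.
#' @param rates `c(r1, r2, r3, r4)`.
#' @param N Mode count.
#' @param xmax Truncation length.
#' @param allow_self Include the 1-circularization channel.
#' @return Named numeric vector `dP/dt` over the union of support and
#'   one-reaction neighbors, with attribute `"truncation_flux"`: the total
#'   probability flux through join reactions whose product exceeds `xmax`.
#' @export
homopolymer_macro_rhs <- function(P, rates, N, xmax, allow_self = TRUE) {
  stopifnot(xmax >= 1)
  r1 <- rates[1]; r2 <- rates[2]; r3 <- rates[3]; r4 <- rates[4]
  acc <- new.env(parent = emptyenv())
  bump <- function(key, val) {
    cur <- if (exists(key, envir = acc, inherits = FALSE))
      get(key, envir = acc) else 0
    assign(key, cur + val, envir = acc)
  }
  trunc_flux <- 0
  xmin_ring <- if (allow_self) 1L else 2L
  for (key in names(P)) {
    p0 <- P[[key]]
    if (p0 == 0) next
    n <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    cxv <- n[seq_len(xmax)]; rxv <- n[xmax + seq_len(xmax)]
    nchain <- sum(cxv)
    nlink <- sum((seq_len(xmax) - 1) * cxv + seq_len(xmax) * rxv)
    ## depletion (outflow from this state)
    depl <- N * r1 + r2 * cxv[1] + r3 * nchain^2 + r4 * nlink
    if (!allow_self) depl <- depl - r3 * cxv[1]    # no 1-circularization
    bump(key, -depl * p0)
    ## outflows feed the corresponding targets (push-forward of each term)
    flow <- function(target_n, w) bump(hp_key(target_n), w * p0)
    ## creation
    m <- n; m[1] <- m[1] + 1L; flow(m, N * r1)
    ## annihilation of a free monomer
    if (cxv[1] >= 1) { m <- n; m[1] <- m[1] - 1L; flow(m, r2 * cxv[1]) }
    ## joins
    for (x in seq_len(xmax)) for (y in x:xmax) {
      w <- if (x == y) r3 * 2 * choose(cxv[x], 2) else r3 * 2 * cxv[x] * cxv[y]
      if (w == 0) next
      if (x + y <= xmax) {
        m <- n; m[x] <- m[x] - 1L; m[y] <- m[y] - 1L
        m[x + y] <- m[x + y] + 1L
        flow(m, w)
      } else trunc_flux <- trunc_flux + w * p0
    }
    ## circularization
    if (xmin_ring <= xmax) for (x in xmin_ring:xmax) if (cxv[x] >= 1) {
      m <- n; m[x] <- m[x] - 1L; m[xmax + x] <- m[xmax + x] + 1L
      flow(m, r3 * cxv[x])
    }
    ## splits
    if (xmax >= 2) for (xy in 2:xmax) if (cxv[xy] >= 1) {
      for (x in seq_len(xy %/% 2)) {
        y <- xy - x
        w <- r4 * (if (x == y) 1 else 2) * cxv[xy]
        m <- n; m[xy] <- m[xy] - 1L; m[x] <- m[x] + 1L; m[y] <- m[y] + 1L
        flow(m, w)
      }
    }
    ## ring cutting
    if (xmin_ring <= xmax) for (x in xmin_ring:xmax) if (rxv[x] >= 1) {
      m <- n; m[xmax + x] <- m[xmax + x] - 1L; m[x] <- m[x] + 1L
      flow(m, r4 * x * rxv[x])
    }
  }
  keys <- ls(acc)
  out <- setNames(vapply(keys, get, 1, envir = acc), keys)
  attr(out, "truncation_flux") <- trunc_flux
  out
}

#' Sparse generator of a species-reaction network
#'
#' BFS over count vectors reachable from `init` under `reactions`, bounded
#' by a total particle mass `amax` (transitions crossing the bound deplete
#' but are not followed, and their lost mass shows up as a probability
#' deficit that [propagate()] reports).
#'
#' @param reactions Reaction list ([homopolymer_reactions()]).
#' @param xmax Truncation length (for the mass computation).
#' @param amax Total-particle cap of the enumerated support.
#' @param init Initial count vector (default: empty).
#' @param cap Maximum number of states.
#' @return List `(keys, states, W)` with sparse generator `W`.
#' @export
macro_reaction_generator <- function(reactions, xmax, amax, init = NULL,
                                     cap = 2e5) {
  if (is.null(init)) init <- hp_zero(xmax)
  index <- new.env(parent = emptyenv())
  states <- list(init); keys <- hp_key(init)
  assign(keys[1], 1L, envir = index)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  src <- 0L
  while (src < length(states)) {
    src <- src + 1L
    n <- states[[src]]
    for (rc in reactions) {
      w <- rc$rate * rc$sigma * omega_coefficient(n, rc$q, rc$q)
      if (w == 0) next
      m <- n - rc$q + rc$p
      keep <- !rc$truncated && hp_mass(m, xmax) <= amax
      ii <- c(ii, src); jj <- c(jj, src); xx <- c(xx, -w)
      if (keep) {
        key <- hp_key(m)
        if (!exists(key, envir = index, inherits = FALSE)) {
          if (length(states) + 1L > cap) stop("macro state cap exceeded")
          states[[length(states) + 1L]] <- m
          keys <- c(keys, key)
          assign(key, length(states), envir = index)
        }
        tgt <- get(key, envir = index)
        ii <- c(ii, tgt); jj <- c(jj, src); xx <- c(xx, w)
      }
    }
  }
  n <- length(states)
  list(keys = keys, states = states,
       W = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)))
}

#' Integrate the homopolymer macrostate master equation
#'
#' Builds the truncated reaction network, propagates the count-vector
#' distribution by uniformization, and returns species mean counts.
#'
#' @param rates `c(r1, r2, r3, r4)`.
#' @param N Mode count.
#' @param xmax Truncation length.
#' @param times Output time grid.
#' @param amax Total-particle cap (default 6 times the quasi-stationary
#'   monomer load `N r1 / r2`, at least 12).
#' @param allow_self Include self-bond channels.
#' @return List: `mean` (times x species matrix), `mass` (retained
#'   probability per time; `1 - mass` is the accumulated truncation flux),
#'   `n_states`.
#' @export
integrate_homopolymer_macro <- function(rates, N, xmax, times,
                                        amax = NULL, allow_self = TRUE) {
  if (is.null(amax)) amax <- max(12, ceiling(6 * N * rates[1] / max(rates[2], 1e-9)))
  rx <- homopolymer_reactions(rates, N, xmax, allow_self = allow_self)
  gen <- macro_reaction_generator(rx, xmax, amax)
  psi0 <- numeric(length(gen$states)); psi0[1] <- 1
  psi <- suppressWarnings(propagate(gen$W, psi0, times))
  counts <- do.call(rbind, gen$states)           # states x species
  means <- t(psi) %*% counts                     # times x species
  list(mean = as.matrix(means), mass = colSums(psi),
       n_states = length(gen$states), times = times)
}
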