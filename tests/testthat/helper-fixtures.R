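## Shared fixtures and small utilities for the test suite. All inputs are
## generated programmatically.

## build a homopolymer microstate containing the given chains (each a vector
## of particle indices, bonded head-to-tail) and rings
hp_state <- function(fm, chains = list(), rings = list()) {
  ex <- list()
  link <- function(i, j) {
    ex[[length(ex) + 1L]] <<- list(field = "a", idx = i)
    ex[[length(ex) + 1L]] <<- list(field = "b", idx = j)
    ex[[length(ex) + 1L]] <<- list(field = "J", idx = c(i, j))
  }
  for (ch in chains) {
    for (i in ch) ex[[length(ex) + 1L]] <- list(field = "A", idx = i)
    if (length(ch) > 1L)
      for (k in seq_len(length(ch) - 1L)) link(ch[k], ch[k + 1L])
  }
  for (rg in rings) {
    for (i in rg) ex[[length(ex) + 1L]] <- list(field = "A", idx = i)
    nxt <- c(rg[-1L], rg[1L])
    for (k in seq_along(rg)) link(rg[k], nxt[k])
  }
  build_state(fm, ex)
}

## count eligible instances of `rule` whose product census satisfies `pred`
count_channels <- function(fm, state, rule, pred) {
  ids <- instantiate_rules(fm, rule)$inst
  n <- 0L
  for (id in ids) {
    t_ <- apply_rule_instance(fm, id, state)
    if (!is.null(t_) && pred(microstate_to_complexes(fm, t_))) n <- n + 1L
  }
  n
}

## parse a census label ("chain-1:2|chain-2:1" or "empty") into counts
parse_census_label <- function(lab) {
  if (lab == "empty") return(setNames(integer(0), character(0)))
  parts <- strsplit(lab, "|", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  setNames(vapply(kv, function(x) as.integer(x[2]), 1L),
           vapply(kv, `[[`, "", 1))
}

## exact species-mean time traces from a labels x times probability matrix
species_means_from_P <- function(P, species) {
  sapply(species, function(spn) {
    w <- vapply(rownames(P), function(lab) {
      cc <- parse_census_label(lab)
      if (spn %in% names(cc)) cc[[spn]] else 0L
    }, 1L)
    colSums(P * w)
  })
}

## fraction of (time, species) grid points where an ensemble mean trace is
## within 3 standard errors of an exact trace. When every run shows the
## same count the empirical SE degenerates to 0; there the model-implied
## standard error of a mean count, sqrt(mean/n) (counts are Poisson-like),
## stands in -- observing 0 of n runs of a species with tiny positive
## expectation is consistent, not a failure.
frac_within_3se <- function(ens_mean, ens_sd, n_runs, exact) {
  se <- ens_sd / sqrt(n_runs)
  se0 <- sqrt(pmax(exact, 0) / n_runs)
  se_eff <- ifelse(se > 0, se, se0)
  dev <- abs(ens_mean - exact)
  mean(ifelse(se_eff > 0, dev <= 3 * se_eff, dev <= 1e-9))
}

## stationary distribution of a small generator
stationary_of <- function(W) {
  n <- nrow(W)
  A <- rbind(as.matrix(W), rep(1, n))
  qr.solve(A, c(numeric(n), 1))
}
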