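## master_equation: reachable state spaces, the rule-built generator W,
## matrix-exponential propagation, macrostate projection.

#' Enumerate the microstates reachable from an initial state
#'
#' Breadth-first closure of the initial microstate under all rule instances,
#' in deterministic order (BFS layer by layer, instances in lexicographic
#' order). This replaces the full `2^M` space: the generator restricted to
#' the reachable set gives identical dynamics for any state supported on it.
#'
#' @param fm Compiled model.
#' @param init Initial microstate (default: the model's `[init]` state).
#' @param cap Maximum number of states to enumerate before erroring.
#' @return A `state_space`: list with `states` (list of microstates), `keys`,
#'   and a hashed `index` environment mapping key -> position.
#' @export
enumerate_reachable <- function(fm, init = NULL, cap = 2e5) {
  if (cap <= 0) stop("cap must be positive")
  if (is.null(init)) init <- build_state(fm)
  index <- new.env(parent = emptyenv(), size = 1024L)
  states <- vector("list", 256L)
  keys <- character(256L)
  n <- 1L
  k0 <- paste0("s", paste(init, collapse = ","))
  states[[1L]] <- init; keys[1L] <- k0
  assign(k0, 1L, envir = index)
  head_ <- 1L
  while (head_ <= n) {
    s <- states[[head_]]
    for (id in eligible_instance_ids(fm, s)) {
      t_ <- apply_rule_instance(fm, id, s)
      key <- paste0("s", paste(t_, collapse = ","))
      if (!exists(key, envir = index, inherits = FALSE)) {
        n <- n + 1L
        if (n > cap)
          stop("reachable-state cap exceeded: more than ", cap, " states")
        if (n > length(states)) {
          length(states) <- 2L * length(states)
          length(keys) <- length(states)
        }
        states[[n]] <- t_; keys[n] <- key
        assign(key, n, envir = index)
      }
    }
    head_ <- head_ + 1L
  }
  structure(list(states = states[seq_len(n)], keys = keys[seq_len(n)],
                 index = index),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space>", length(x$states), "microstates\n")
  invisible(x)
}

state_space_lookup <- function(space, s) {
  key <- paste0("s", paste(s, collapse = ","))
  if (!exists(key, envir = space$index, inherits = FALSE)) return(NA_integer_)
  get(key, envir = space$index)
}

#' Build the microstate transition generator W
#'
#' `W = sum_l r_l sum_i (R_li - R`_li)`: for every instance eligible on every
#' state, the instance rate is added at (target, source) and subtracted from
#' the (source, source) diagonal, so every column sums to zero exactly.
#'
#' @param fm Compiled model.
#' @param space A [enumerate_reachable()] state space closed under the rules.
#' @return Sparse generator matrix (columns indexed by source state).
#' @export
build_generator <- function(fm, space) {
  n <- length(space$states)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (src in seq_len(n)) {
    s <- space$states[[src]]
    ids <- eligible_instance_ids(fm, s)
    if (length(ids) == 0L) next
    tgt <- vapply(ids, function(id)
      state_space_lookup(space, apply_rule_instance(fm, id, s)), 1L)
    if (anyNA(tgt))
      stop("state space is not closed under the rules (source state ", src, ")")
    r <- fm$inst_rate[ids]
    ii <- c(ii, tgt, src)
    jj <- c(jj, rep(src, length(ids) + 1L))
    xx <- c(xx, r, -sum(r))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Propagate a probability vector, psi(t) = exp(tW) psi(0)
#'
#' Action of the matrix exponential computed by uniformization (Poisson-
#' weighted power series of the stochastic matrix `I + W/lambda`), which
#' never forms `exp(tW)` densely and preserves probability and positivity.
#'
#' @param W Sparse generator (columns sum to zero).
#' @param psi0 Initial probability vector (must sum to 1 within 1e-9).
#' @param times Nondecreasing vector of times.
#' @param tol Poisson-tail truncation tolerance per step.
#' @return Matrix with one column per requested time; attribute `"times"`.
#' @export
propagate <- function(W, psi0, times, tol = 1e-12) {
  if (abs(sum(psi0) - 1) > 1e-9) stop("psi0 is not normalized")
  if (is.unsorted(times)) stop("times must be nondecreasing")
  n <- length(psi0)
  lambda <- max(-Matrix::diag(W), 0)
  out <- matrix(NA_real_, n, length(times))
  v <- psi0
  tprev <- 0
  if (lambda > 0) P <- W / lambda   # used as I + W/lambda via v + P v
  for (k in seq_along(times)) {
    dt <- times[k] - tprev
    if (dt > 0 && lambda > 0) {
      a <- lambda * dt
      mmax <- max(10L, as.integer(qpois(1 - tol, a)) + 5L)
      w <- dpois(0:mmax, a)
      acc <- w[1] * v
      u <- v
      for (m in seq_len(mmax)) {
        u <- u + as.numeric(P %*% u)
        acc <- acc + w[m + 1] * u
      }
      v <- acc
    }
    tprev <- times[k]
    out[, k] <- v
  }
  tot <- colSums(out)
  if (any(abs(tot - 1) > 1e-8 + 1e-6 * max(abs(tot))))
    warning("propagated mass deviates from 1 by ", max(abs(tot - 1)),
            " (truncated state space?)")
  attr(out, "times") <- times
  out
}

#' Project microstate probabilities onto macrostates
#'
#' Sums probabilities over microstates sharing a label.
#'
#' @param psi Probability vector aligned with `space`, or a matrix of such
#'   columns (as returned by [propagate()]).
#' @param space The state space.
#' @param labeler Function mapping a microstate to a label string (e.g. a
#'   species count vector rendered canonically; see [census_labeler()]).
#' @return Named numeric vector (or a labels x times matrix).
#' @export
macrostate_distribution <- function(psi, space, labeler) {
  labs <- vapply(space$states, labeler, "")
  ulab <- sort(unique(labs))
  f <- factor(labs, levels = ulab)
  if (is.matrix(psi)) {
    out <- apply(psi, 2, function(col) tapply(col, f, sum))
    rownames(out) <- ulab
    attr(out, "times") <- attr(psi, "times")
    out
  } else {
    tapply(psi, f, sum)
  }
}

#' Exactly lumped macrostate generator
#'
#' For models whose rules are invariant under permutations of mode indices
#' (all fixtures here), the microstate chain is strongly lumpable with
#' respect to the census partition: every microstate with the same species
#' label has the same total rate into each target label. This builds the
#' lumped generator by BFS over labels using representative microstates,
#' which makes systems like the monomer at N = 20 (microstate space 2^20)
#' exactly tractable.
#'
#' Lumpability is verified numerically: for each label, up to `verify`
#' distinct representatives encountered during the BFS are re-expanded and
#' their label-flux compared (error if they disagree).
#'
#' @param fm Compiled model.
#' @param labeler Microstate -> label function.
#' @param init Initial microstate (default: model init).
#' @param cap Maximum number of labels.
#' @param verify Extra representatives to cross-check per label.
#' @return List with `labels`, sparse `W` (lumped generator), and `init`
#'   (index of the initial label).
#' @export
build_macro_generator <- function(fm, labeler, init = NULL, cap = 1e4,
                                  verify = 2L) {
  if (is.null(init)) init <- build_state(fm)
  index <- new.env(parent = emptyenv())
  labels <- character(0)
  reps <- list()          # representatives per label (up to verify + 1)
  queue <- list(init)
  l0 <- labeler(init)
  labels[1] <- l0; reps[[1]] <- list(init)
  assign(l0, 1L, envir = index)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  flux_of <- function(s) {
    ids <- eligible_instance_ids(fm, s)
    if (length(ids) == 0L) return(list(lab = character(0), rate = numeric(0),
                                       states = list()))
    tgts <- lapply(ids, function(id) apply_rule_instance(fm, id, s))
    labs <- vapply(tgts, labeler, "")
    rate <- fm$inst_rate[ids]
    agg <- tapply(rate, factor(labs, levels = unique(labs)), sum)
    list(lab = names(agg), rate = as.numeric(agg), states = tgts, labs = labs)
  }
  src <- 0L
  while (src < length(labels)) {
    src <- src + 1L
    fx <- flux_of(reps[[src]][[1]])
    for (k in seq_along(fx$lab)) {
      lab <- fx$lab[k]
      if (!exists(lab, envir = index, inherits = FALSE)) {
        if (length(labels) + 1L > cap) stop("macro-label cap exceeded")
        labels <- c(labels, lab)
        reps[[length(labels)]] <- list(fx$states[[match(lab, fx$labs)]])
        assign(lab, length(labels), envir = index)
      } else if (verify > 0L) {
        pos <- get(lab, envir = index)
        if (length(reps[[pos]]) <= verify) {
          cand <- fx$states[[match(lab, fx$labs)]]
          if (!any(vapply(reps[[pos]], identical, TRUE, y = cand)))
            reps[[pos]] <- c(reps[[pos]], list(cand))
        }
      }
      tgt <- get(lab, envir = index)
      if (tgt != src) {
        ii <- c(ii, tgt, src); jj <- c(jj, src, src)
        xx <- c(xx, fx$rate[k], -fx$rate[k])
      }
    }
  }
  n <- length(labels)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  if (verify > 0L) {
    for (pos in seq_len(n)) {
      for (alt in reps[[pos]][-1]) {
        fx <- flux_of(alt)
        keep <- fx$lab != labels[pos]
        v <- numeric(n)
        v[vapply(fx$lab[keep], function(l) get(l, envir = index), 1L)] <-
          fx$rate[keep]
        ref <- as.numeric(W[, pos]); ref[pos] <- 0
        if (max(abs(v - ref)) > 1e-9)
          stop("census partition is not lumpable for this model (label '",
               labels[pos], "')")
      }
    }
  }
  list(labels = labels, W = W, init = get(labeler(init), envir = index))
}
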