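## wick_engine: brute-force enumeration of contraction schemes of
## productive-ordered factory products, topology classification of the
## residual normally ordered terms, and the factory/gallery equivalence
## check by explicit small-N matrices.
##
## A labeled product F2^p F1^q (productive ordered: all compound presence
## operators left of all creation operators) is encoded as p "bond factors"
## -- each carrying two presence slots (homodimer: two interchangeable
## a-side slots; homopolymer: an a-side and a b-side slot joined by a
## directed bond) -- plus q labeled creation slots. A contraction scheme
## pairs presence slots with creation slots: each presence slot at most
## once; each creation slot accepts at most one contraction total
## (homodimer) or at most one per side (homopolymer, where the contraction
## products are not central and may be contracted again).

#' Construct a labeled productive-ordered factory product
#'
#' @param system `"homodimer"` or `"homopolymer"`.
#' @param p Number of bond (F2) factors.
#' @param q Number of creation (F1) factors.
#' @param allow_self For the homopolymer: admit both slots of one factor
#'   contracting the same creation slot (a 1-ring).
#' @return A `labeled_product` description.
#' @export
labeled_product <- function(system = c("homodimer", "homopolymer"), p, q,
                            allow_self = FALSE) {
  system <- match.arg(system)
  stopifnot(p >= 0, q >= 0)
  structure(list(system = system, p = p, q = q, allow_self = allow_self),
            class = "labeled_product")
}

## recursive enumeration of schemes. A scheme is a p x 2 integer matrix:
## row k = (a-slot target, b-slot target) of factor k, 0 = uncontracted.
## `complete_only` prunes to fully contracted schemes.
enum_schemes <- function(prod, complete_only = FALSE, max_schemes = 2e5) {
  p <- prod$p; q <- prod$q
  homod <- prod$system == "homodimer"
  out <- list()
  used_a <- logical(q)   # per-creation a-side (or total, homodimer) usage
  used_b <- logical(q)   # per-creation b-side usage (homopolymer only)
  assign_mat <- matrix(0L, max(p, 1L), 2L)
  recurse <- function(slot) {       # slot runs over 1..2p (factor, side)
    if (length(out) >= max_schemes)
      stop("contraction-scheme enumeration guard exceeded (", max_schemes, ")")
    if (slot > 2L * p) {
      out[[length(out) + 1L]] <<- if (p > 0) assign_mat[seq_len(p), , drop = FALSE]
        else matrix(0L, 0L, 2L)
      return()
    }
    k <- (slot + 1L) %/% 2L
    side <- if (slot %% 2L == 1L) 1L else 2L
    if (!complete_only) recurse(slot + 1L)        # leave slot uncontracted
    for (m in seq_len(q)) {
      if (homod) {
        if (used_a[m]) next                       # total capacity 1
      } else {
        if (side == 1L && used_a[m]) next         # a-port already taken
        if (side == 2L && used_b[m]) next         # b-port already taken
        if (!prod$allow_self && side == 2L && assign_mat[k, 1L] == m) next
      }
      if (homod) used_a[m] <<- TRUE
      else if (side == 1L) used_a[m] <<- TRUE else used_b[m] <<- TRUE
      assign_mat[k, side] <<- m
      recurse(slot + 1L)
      assign_mat[k, side] <<- 0L
      if (homod) used_a[m] <<- FALSE
      else if (side == 1L) used_a[m] <<- FALSE else used_b[m] <<- FALSE
    }
  }
  if (q == 0L && p > 0L && complete_only) return(list())
  recurse(1L)
  out
}

## census of the residual term of one scheme: which creation slots remain
## bare, and (homopolymer) the chain/ring structure of the contraction graph
scheme_residual <- function(prod, scheme) {
  p <- prod$p; q <- prod$q
  n_contr <- sum(scheme > 0L)
  uncontracted_slots <- 2L * p - n_contr
  if (prod$system == "homodimer") {
    full_factors <- sum(scheme[, 1] > 0L & scheme[, 2] > 0L)
    touched <- unique(scheme[scheme > 0L])
    list(n_contractions = n_contr,
         open_presence_slots = uncontracted_slots,
         dimers = full_factors,
         monomers = q - length(touched))
  } else {
    ## directed multigraph on creation slots: edge a-target -> b-target for
    ## every fully contracted factor; partially contracted factors leave
    ## open presence slots
    keep <- scheme[, 1] > 0L & scheme[, 2] > 0L
    edges <- scheme[keep, , drop = FALSE]
    open_ <- uncontracted_slots
    census <- contraction_graph_census(q, edges)
    c(list(n_contractions = n_contr, open_presence_slots = open_),
      census)
  }
}

## classify components of a functional-style digraph (out-degree and
## in-degree at most 1): chains and rings by length
contraction_graph_census <- function(q, edges) {
  nxt <- integer(q); prv <- integer(q)
  for (r in seq_len(nrow(edges))) {
    nxt[edges[r, 1]] <- edges[r, 2]
    prv[edges[r, 2]] <- edges[r, 1]
  }
  visited <- logical(q)
  chains <- integer(0); rings <- integer(0)
  for (v in seq_len(q)) {
    if (visited[v] || prv[v] != 0L) next          # start at chain heads
    len <- 0L; u <- v
    while (u != 0L && !visited[u]) { visited[u] <- TRUE; len <- len + 1L; u <- nxt[u] }
    chains <- c(chains, len)
  }
  for (v in seq_len(q)) {                         # remaining are rings
    if (visited[v]) next
    len <- 0L; u <- v
    while (!visited[u]) { visited[u] <- TRUE; len <- len + 1L; u <- nxt[u] }
    rings <- c(rings, len)
  }
  list(chains = sort(chains), rings = sort(rings))
}

#' Enumerate all contraction schemes of a factory product
#'
#' Exhaustive Wick expansion: every admissible pairing of presence slots
#' with creation slots, each with its residual normally ordered term
#' (uncontracted presence slots vanish on the vacuum).
#'
#' @param prod A [labeled_product()].
#' @param max_schemes Enumeration guard.
#' @return List of `list(scheme =, residual =)`.
#' @export
enumerate_contractions <- function(prod, max_schemes = 2e5) {
  lapply(enum_schemes(prod, complete_only = FALSE, max_schemes = max_schemes),
         function(sch) list(scheme = sch, residual = scheme_residual(prod, sch)))
}

#' Count contraction schemes by topology class
#'
#' @param p,q Factor counts (guarded to `p <= 4`, `q <= 10`).
#' @param system `"homodimer"` or `"homopolymer"`.
#' @param topology One of `"uncontracted"` (no contractions),
#'   `"single"` (exactly one), `"same_F2_double"` (exactly two, both slots
#'   of one bond factor), `"split_double"` (exactly two, on different
#'   factors), `"fully_contracted"`.
#' @param allow_self Passed to [labeled_product()].
#' @return Integer count of distinct schemes.
#' @export
count_schemes_by_topology <- function(p, q, system = "homodimer",
                                      topology, allow_self = FALSE) {
  if (p > 4 || q > 10) stop("guard exceeded: need p <= 4, q <= 10")
  prod <- labeled_product(system, p, q, allow_self)
  complete_only <- identical(topology, "fully_contracted")
  schemes <- enum_schemes(prod, complete_only = complete_only)
  if (complete_only) return(length(schemes))
  sum(vapply(schemes, function(sch) {
    k <- sum(sch > 0L)
    switch(topology,
      uncontracted = k == 0L,
      single = k == 1L,
      same_F2_double = k == 2L && any(sch[, 1] > 0L & sch[, 2] > 0L),
      split_double = k == 2L && !any(sch[, 1] > 0L & sch[, 2] > 0L),
      stop("unknown topology tag '", topology, "'"))
  }, TRUE))
}

#' Apply a factory term to the vacuum, combinatorially
#'
#' Evaluates `F2^p/p! F1^q/q! |0>` by Wick enumeration: only fully
#' contracted residuals survive on the vacuum. For the homodimer the result
#' is the single macrostate `(q - 2p monomers, p dimers)` with coefficient
#' 1 when `q >= 2p` and 0 otherwise. For the homopolymer the result is a
#' table of chain/ring multisets with their scheme counts and gallery
#' coefficients (`count * prod(x^r_x) * prod(c_x! r_x!) / (p! q!)`, which is
#' 1 per distinct species multiset).
#'
#' @param p,q Factor counts.
#' @param system `"homodimer"` or `"homopolymer"`.
#' @param allow_self Homopolymer self-contraction flag.
#' @return For the homodimer: `list(monomers, dimers, coefficient)`.
#'   For the homopolymer: data.frame `(species, schemes, coefficient)`.
#' @export
factory_apply_vacuum <- function(p, q, system = "homodimer",
                                 allow_self = FALSE) {
  prod <- labeled_product(system, p, q, allow_self)
  schemes <- enum_schemes(prod, complete_only = TRUE)
  if (system == "homodimer") {
    if (q < 2 * p || length(schemes) == 0L)
      return(list(monomers = NA_integer_, dimers = NA_integer_,
                  coefficient = 0))
    ## every complete scheme leaves the same species content
    coef <- length(schemes) * factorial(q - 2 * p) / factorial(q)
    return(list(monomers = q - 2L * p, dimers = p, coefficient = coef))
  }
  if (length(schemes) == 0L)
    return(data.frame(species = character(0), schemes = integer(0),
                      coefficient = numeric(0)))
  keys <- vapply(schemes, function(sch) {
    cen <- scheme_residual(prod, sch)
    paste0("c[", paste(cen$chains, collapse = ","), "]r[",
           paste(cen$rings, collapse = ","), "]")
  }, "")
  tab <- table(keys)
  coef <- vapply(names(tab), function(k) {
    m <- regmatches(k, regexec("^c\\[([0-9,]*)\\]r\\[([0-9,]*)\\]$", k))[[1]]
    ch <- as.integer(strsplit(m[2], ",")[[1]])
    ri <- as.integer(strsplit(m[3], ",")[[1]])
    mult <- prod(factorial(table(ch))) * prod(factorial(table(ri)))
    tab[[k]] * prod(ri) * mult / (factorial(p) * factorial(q))
  }, 1)
  data.frame(species = names(tab), schemes = as.integer(tab),
             coefficient = as.numeric(coef), row.names = NULL,
             stringsAsFactors = FALSE)
}

## e^F v by truncated series; exact because factory operators are nilpotent
## on a finite mode set
expm_apply <- function(F_, v, max_terms = 200L) {
  acc <- v
  term <- v
  for (k in seq_len(max_terms)) {
    term <- as.numeric(F_ %*% term) / k
    if (all(term == 0)) return(acc)
    acc <- acc + term
  }
  stop("exponential series did not terminate (operator not nilpotent?)")
}

#' Factory/gallery equivalence by explicit matrices
#'
#' Computes the factory state `e^(F2) e^(F1) |0>` on the explicit small-N
#' Fock space and compares it, coordinate by coordinate, with the gallery
#' sum state `e^(sum_k Ghat_k) |0>` built from the species creation
#' operators (monomers and dimers for the homodimer; chains `Chat_x` and
#' rings `Rhat_x` of every length for the homopolymer, the ring operator
#' carrying its 1/x rotational-symmetry factor). Exact integer equality is
#' expected.
#'
#' @param system `"homodimer"` or `"homopolymer"`.
#' @param N Mode count (small: the space is `2^M` with `M = 2N + C(N,2)` or
#'   `3N + N(N-1)`).
#' @param allow_self Homopolymer self-bond flag.
#' @return `list(equal =, max_dev =, factory =, gallery =)`.
#' @export
factory_gallery_check <- function(system = c("homodimer", "homopolymer"), N,
                                  allow_self = FALSE) {
  system <- match.arg(system)
  spec <- builtin_fixture(if (system == "homodimer") "homodimer" else
    "homopolymer", N, allow_self = allow_self)
  fm <- compile_model(spec)
  F1 <- template_matrix(fm, "r1")
  F2 <- template_matrix(fm, "r3")
  v0 <- vacuum_vector(fm)
  factory <- expm_apply(F2, expm_apply(F1, v0))
  G <- gallery_operator(fm, system, allow_self)
  gallery <- expm_apply(G, v0)
  dev <- max(abs(factory - gallery))
  list(equal = dev == 0, max_dev = dev, factory = factory, gallery = gallery)
}

## sum of species creation operators for the gallery sum state
gallery_operator <- function(fm, system, allow_self = FALSE) {
  N <- fm$N
  dim <- fock_dim(fm)
  G <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(dim, dim))
  if (system == "homodimer") {
    for (i in seq_len(N))
      G <- G + composite_creation_matrix(fm, mode_id(fm, "A", i))
    if (N >= 2) for (i in seq_len(N - 1)) for (j in (i + 1):N)
      G <- G + composite_creation_matrix(fm, c(
        mode_id(fm, "A", i), mode_id(fm, "A", j),
        mode_id(fm, "a", i), mode_id(fm, "a", j),
        mode_id(fm, "I", i, j)))
    return(G)
  }
  ## homopolymer: chains and rings over all distinct index tuples
  tuples <- function(x) {
    if (x == 1) return(lapply(seq_len(N), identity))
    out <- list()
    rec <- function(pref) {
      if (length(pref) == x) { out[[length(out) + 1L]] <<- pref; return() }
      for (i in setdiff(seq_len(N), pref)) rec(c(pref, i))
    }
    rec(integer(0))
    out
  }
  for (x in seq_len(N)) {
    for (tp in tuples(x)) {
      modes <- vapply(tp, function(i) mode_id(fm, "A", i), 1L)
      if (x > 1) {
        modes <- c(modes,
                   vapply(tp[-x], function(i) mode_id(fm, "a", i), 1L),
                   vapply(tp[-1], function(i) mode_id(fm, "b", i), 1L),
                   mapply(function(i, j) mode_id(fm, "J", i, j),
                          tp[-x], tp[-1]))
      }
      G <- G + composite_creation_matrix(fm, modes)
    }
    ring_min <- if (allow_self) 1L else 2L
    if (x >= ring_min) {
      for (tp in tuples(x)) {
        nxt <- c(tp[-1], tp[1])
        modes <- c(vapply(tp, function(i) mode_id(fm, "A", i), 1L),
                   vapply(tp, function(i) mode_id(fm, "a", i), 1L),
                   vapply(tp, function(i) mode_id(fm, "b", i), 1L),
                   mapply(function(i, j) mode_id(fm, "J", i, j), tp, nxt))
        G <- G + composite_creation_matrix(fm, unique(modes)) / x
      }
    }
  }
  G
}
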