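## Explicit operator matrices on the 2^M-dimensional small-N Fock space.
##
## Basis: lexicographic microstate basis indexed by the excitation bit
## pattern; basis vector 1 + sum(2^(mode-1)) corresponds to the microstate
## with exactly those modes excited. Guarded to M <= 20 modes.

MAX_MATRIX_MODES <- 20L

#' Dimension of the explicit Fock space
#' @param fm Compiled model.
#' @return `2^M` where `M` is the total mode count (error if `M > 20`).
#' @export
fock_dim <- function(fm) {
  if (fm$n_modes > MAX_MATRIX_MODES)
    stop("explicit Fock space too large: ", fm$n_modes, " modes (guard ",
         MAX_MATRIX_MODES, ")")
  2L^fm$n_modes
}

#' Basis index of a microstate
#' @param fm Compiled model.
#' @param s Microstate (sorted integer vector of mode ids).
#' @return Integer basis index in `1..2^M`.
#' @export
basis_index <- function(fm, s) as.integer(1 + sum(2^(s - 1)))

#' The vacuum basis vector
#' @param fm Compiled model.
#' @return Dense numeric vector with a single 1 at the vacuum.
#' @export
vacuum_vector <- function(fm) {
  v <- numeric(fock_dim(fm)); v[1] <- 1; v
}

## sources: all required-set bits set, required-clear bits clear;
## target = source XOR flip. All masks are mode-id vectors.
masked_map_matrix <- function(fm, req1 = integer(0), req0 = integer(0),
                              flip = integer(0)) {
  dim <- fock_dim(fm)
  m1 <- as.integer(sum(2^(req1 - 1)))
  m0 <- as.integer(sum(2^(req0 - 1)))
  fl <- as.integer(sum(2^(flip - 1)))
  B <- 0:(dim - 1L)
  src <- B[bitwAnd(B, m1) == m1 & bitwAnd(B, m0) == 0L]
  tgt <- bitwXor(src, fl)
  Matrix::sparseMatrix(i = tgt + 1L, j = src + 1L, x = 1,
                       dims = c(dim, dim))
}

#' Explicit matrix of a single mode operator
#'
#' @param fm Compiled model (total mode count at most 20).
#' @param op `"create"`, `"annihilate"`, `"presence"` or `"absence"`.
#' @param field Field name.
#' @param i,j Mode indices (see [mode_id()]).
#' @return A sparse 0/1 matrix on the `2^M` microstate basis.
#' @export
operator_matrix <- function(fm, op, field, i, j = NULL) {
  op <- match.arg(op, FACTOR_OPS)
  m <- mode_id(fm, field, i, j)
  switch(op,
    create = masked_map_matrix(fm, req0 = m, flip = m),
    annihilate = masked_map_matrix(fm, req1 = m, flip = m),
    presence = masked_map_matrix(fm, req1 = m),
    absence = masked_map_matrix(fm, req0 = m))
}

#' Explicit matrix of a field operator (sum over modes)
#'
#' @inheritParams operator_matrix
#' @return Sparse matrix `sum_i op_i` over all modes of `field`.
#' @export
field_matrix <- function(fm, op, field) {
  op <- match.arg(op, FACTOR_OPS)
  ms <- fm$field_modes[[field]]
  if (is.null(ms)) stop("unknown field '", field, "'")
  out <- NULL
  for (m in ms) {
    mm <- switch(op,
      create = masked_map_matrix(fm, req0 = m, flip = m),
      annihilate = masked_map_matrix(fm, req1 = m, flip = m),
      presence = masked_map_matrix(fm, req1 = m),
      absence = masked_map_matrix(fm, req0 = m))
    out <- if (is.null(out)) mm else out + mm
  }
  out
}

#' Explicit matrix of one rule instance
#'
#' Equals the product of the instance's factor matrices (factors touch
#' distinct modes, so the product order is immaterial).
#'
#' @param fm Compiled model.
#' @param inst Instance id.
#' @return Sparse 0/1 matrix.
#' @export
instance_matrix <- function(fm, inst) {
  ci <- fm$conds_by_inst[[inst]]
  fi <- fm$flips_by_inst[[inst]]
  masked_map_matrix(fm,
                    req1 = fm$cond_mode[ci][fm$cond_req[ci]],
                    req0 = fm$cond_mode[ci][!fm$cond_req[ci]],
                    flip = fm$flip_mode[fi])
}

#' Explicit matrix of a whole rule template, `sum_i R_li`
#'
#' @param fm Compiled model.
#' @param name Rule template name.
#' @return Sparse matrix (rates not included).
#' @export
template_matrix <- function(fm, name) {
  ids <- instantiate_rules(fm, name)$inst
  out <- NULL
  for (k in ids) {
    mm <- instance_matrix(fm, k)
    out <- if (is.null(out)) mm else out + mm
  }
  if (is.null(out)) Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0),
                                         dims = rep(fock_dim(fm), 2)) else out
}

#' Creation matrix for a composite (multi-mode) excitation
#'
#' Product of creation operators for `modes`: maps a basis state with all
#' `modes` unexcited to the state with them excited, and kills anything else.
#'
#' @param fm Compiled model.
#' @param modes Integer vector of mode ids.
#' @return Sparse 0/1 matrix.
#' @export
composite_creation_matrix <- function(fm, modes)
  masked_map_matrix(fm, req0 = modes, flip = modes)

#' Macrostate basis vector |n> for a single particle field
#'
#' Built literally as `Ahat^n |0> / n!` on the explicit space.
#'
#' @param fm Compiled model.
#' @param field Particle field name.
#' @param n Occupation number.
#' @return Dense numeric vector.
#' @export
macrostate_vector <- function(fm, field, n) {
  v <- vacuum_vector(fm)
  if (n == 0) return(v)
  Ahat <- field_matrix(fm, "create", field)
  for (k in seq_len(n)) v <- as.numeric(Ahat %*% v)
  v / factorial(n)
}
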