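## fock_core: modes, microstates, rule instantiation, operator application.
##
## A microstate is the set of excited modes, stored as a sorted integer vector
## of mode ids. The zero vector (an annihilated state) is the sentinel NULL;
## the vacuum is integer(0) and is a valid state.

op_requires_excited <- c(create = FALSE, annihilate = TRUE,
                         presence = TRUE, absence = FALSE)
op_flips <- c(create = TRUE, annihilate = TRUE, presence = FALSE, absence = FALSE)

#' Compile a model into an executable form
#'
#' Enumerates the mode universe (lexicographic: field declaration order, then
#' indices) and every mode-specific rule instance, precomputing the
#' eligibility conditions and excitation flips each instance carries. All
#' simulation and master-equation machinery operates on the compiled model.
#'
#' @param spec A [model_spec()].
#' @return A `fock_model` object (list with mode table, instance tables and
#'   per-mode incidence index).
#' @export
compile_model <- function(spec) {
  validate_model(spec)
  N <- spec$N
  fld <- character(); ii <- integer(); jj <- integer(); kind <- character()
  for (f in spec$fields) {
    if (f$kind != "bond") {
      fld <- c(fld, rep(f$name, N)); ii <- c(ii, seq_len(N))
      jj <- c(jj, rep(NA_integer_, N)); kind <- c(kind, rep(f$kind, N))
    } else {
      if (f$symmetric) {
        pr <- which(upper.tri(matrix(0, N, N), diag = f$allow_self),
                    arr.ind = TRUE)
        pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
      } else {
        pr <- as.matrix(expand.grid(j = seq_len(N), i = seq_len(N)))[, 2:1,
                                                                     drop = FALSE]
        colnames(pr) <- c("row", "col")
        if (!f$allow_self) pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
      }
      fld <- c(fld, rep(f$name, nrow(pr)))
      ii <- c(ii, as.integer(pr[, 1])); jj <- c(jj, as.integer(pr[, 2]))
      kind <- c(kind, rep("bond", nrow(pr)))
    }
  }
  modes <- data.frame(field = fld, i = ii, j = jj, kind = kind,
                      stringsAsFactors = FALSE)
  keys <- ifelse(is.na(modes$j), paste0(modes$field, ":", modes$i),
                 paste0(modes$field, ":", modes$i, ",", modes$j))
  mode_ids <- setNames(seq_len(nrow(modes)), keys)
  fields <- setNames(spec$fields, vapply(spec$fields, `[[`, "", "name"))

  fm <- list(spec = spec, N = N, modes = modes, n_modes = nrow(modes),
             mode_ids = mode_ids, fields = fields,
             field_modes = split(seq_len(nrow(modes)), modes$field))
  class(fm) <- "fock_model"

  ## instantiate all templates
  inst_rate <- numeric(); inst_template <- integer(); inst_label <- character()
  cond_inst <- integer(); cond_mode <- integer(); cond_req <- logical()
  flip_inst <- integer(); flip_mode <- integer(); flip_add <- logical()
  inst_binding <- list()
  n_inst <- 0L
  for (ti in seq_along(spec$rules)) {
    tmpl <- spec$rules[[ti]]
    binds <- template_bindings(fm, tmpl)
    for (b in binds) {
      ops <- binding_ops(fm, tmpl, b)
      if (is.null(ops)) next                       # conflicting ops at i = j
      n_inst <- n_inst + 1L
      inst_rate[n_inst] <- tmpl$rate
      inst_template[n_inst] <- ti
      inst_label[n_inst] <- paste0(tmpl$name, "(", paste(b, collapse = ","), ")")
      inst_binding[[n_inst]] <- b
      cond_inst <- c(cond_inst, rep(n_inst, length(ops$mode)))
      cond_mode <- c(cond_mode, ops$mode)
      cond_req <- c(cond_req, op_requires_excited[ops$op])
      fl <- op_flips[ops$op]
      if (any(fl)) {
        flip_inst <- c(flip_inst, rep(n_inst, sum(fl)))
        flip_mode <- c(flip_mode, ops$mode[fl])
        flip_add <- c(flip_add, ops$op[fl] == "create")
      }
    }
  }
  fm$n_inst <- n_inst
  fm$inst_rate <- inst_rate
  fm$inst_template <- inst_template
  fm$inst_label <- inst_label
  fm$inst_binding <- inst_binding
  fm$cond_inst <- cond_inst; fm$cond_mode <- cond_mode; fm$cond_req <- cond_req
  fm$flip_inst <- flip_inst; fm$flip_mode <- flip_mode; fm$flip_add <- flip_add
  fm$conds_by_inst <- split(seq_along(cond_inst), factor(cond_inst,
                                                         levels = seq_len(n_inst)))
  fm$flips_by_inst <- split(seq_along(flip_inst), factor(flip_inst,
                                                         levels = seq_len(n_inst)))
  fm$conds_by_mode <- split(seq_along(cond_inst), factor(cond_mode,
                                                         levels = seq_len(fm$n_modes)))
  fm
}

## all index bindings of a template satisfying its constraint
template_bindings <- function(fm, tmpl) {
  vars <- unique(unlist(lapply(tmpl$factors, `[[`, "vars")))
  N <- fm$N
  if (length(vars) == 1L) {
    lapply(seq_len(N), function(i) setNames(i, vars))
  } else if (length(vars) == 2L) {
    g <- expand.grid(a = seq_len(N), b = seq_len(N))
    g <- g[order(g$b, g$a), ]                       # lexicographic (v1, v2)
    g <- g[, c("b", "a")]
    keep <- switch(tmpl$constraint,
                   "none" = rep(TRUE, nrow(g)),
                   "all-distinct" = g[, 1] != g[, 2],
                   "i<j" = g[, 1] < g[, 2])
    g <- g[keep, , drop = FALSE]
    lapply(seq_len(nrow(g)), function(r) setNames(as.integer(g[r, ]), vars))
  } else stop("templates with >2 index variables are not supported")
}

## resolve one binding to a deduplicated (op, mode id) table; NULL if the
## binding makes two conflicting operators touch the same mode, or references
## a mode that does not exist (e.g. a disallowed self-bond)
binding_ops <- function(fm, tmpl, b) {
  op <- character(); mode <- integer()
  for (fa in tmpl$factors) {
    idx <- unname(b[fa$vars])
    f <- fm$fields[[fa$field]]
    if (f$kind == "bond") {
      if (idx[1] == idx[2] && !f$allow_self) return(NULL)
      if (f$symmetric) idx <- sort(idx)
      key <- paste0(fa$field, ":", idx[1], ",", idx[2])
    } else key <- paste0(fa$field, ":", idx[1])
    m <- fm$mode_ids[[key]]
    if (is.null(m)) return(NULL)
    op <- c(op, fa$op); mode <- c(mode, m)
  }
  keep <- !duplicated(paste(op, mode))
  op <- op[keep]; mode <- mode[keep]
  if (anyDuplicated(mode)) return(NULL)
  list(op = op, mode = mode)
}

#' Look up a mode id
#'
#' @param fm A compiled model.
#' @param field Field name.
#' @param i,j Indices (j only for bond fields; symmetric bonds are
#'   canonicalized to i < j automatically).
#' @return Integer mode id.
#' @export
mode_id <- function(fm, field, i, j = NULL) {
  f <- fm$fields[[field]]
  if (is.null(f)) stop("unknown field '", field, "'")
  key <- if (is.null(j)) paste0(field, ":", i) else {
    ij <- c(i, j)
    if (f$symmetric) ij <- sort(ij)
    paste0(field, ":", ij[1], ",", ij[2])
  }
  m <- fm$mode_ids[[key]]
  if (is.null(m)) stop("no such mode: ", key)
  m
}

#' Build a microstate from a list of excitations
#'
#' @param fm A compiled model.
#' @param excitations List of `list(field =, idx =)` entries (as in the
#'   `[init]` section), or `NULL` for the model's own initial state.
#' @return Sorted integer vector of excited mode ids (the vacuum is
#'   `integer(0)`).
#' @export
build_state <- function(fm, excitations = NULL) {
  if (is.null(excitations)) excitations <- fm$spec$init
  if (length(excitations) == 0L) return(integer(0))
  ids <- vapply(excitations, function(e)
    mode_id(fm, e$field, e$idx[1], if (length(e$idx) > 1L) e$idx[2]), 1L)
  sort(unique(ids))
}

#' Apply a single mode operator to a microstate
#'
#' Creation on an excited mode, annihilation/presence on an unexcited mode,
#' and absence on an excited mode all yield the zero vector, encoded `NULL`.
#'
#' @param fm Compiled model.
#' @param op `"create"`, `"annihilate"`, `"presence"` or `"absence"`.
#' @param mode Integer mode id (see [mode_id()]).
#' @param s Microstate (sorted integer vector), or `NULL`.
#' @return The resulting microstate, or `NULL` for the zero vector.
#' @export
apply_operator <- function(fm, op, mode, s) {
  if (is.null(s)) return(NULL)
  op <- match.arg(op, FACTOR_OPS)
  if (mode < 1L || mode > fm$n_modes) stop("invalid mode id ", mode)
  exc <- mode %in% s
  switch(op,
    create = if (exc) NULL else sort(c(s, mode)),
    annihilate = if (exc) s[s != mode] else NULL,
    presence = if (exc) s else NULL,
    absence = if (exc) NULL else s)
}

#' Is a rule instance eligible on a microstate?
#'
#' True iff every factor is eligible: create/absence need their mode
#' unexcited, annihilate/presence need it excited; equivalently,
#' [apply_rule_instance()] would not return `NULL`.
#'
#' @param fm Compiled model.
#' @param inst Instance id (position in `fm$inst_label`).
#' @param s Microstate.
#' @return Logical.
#' @export
is_eligible <- function(fm, inst, s) {
  ci <- fm$conds_by_inst[[inst]]
  req <- fm$cond_req[ci]
  exc <- fm$cond_mode[ci] %in% s
  all(exc == req)
}

#' Apply a rule instance to a microstate
#'
#' Applies every factor; factors within one instance touch distinct modes so
#' the application order is immaterial.
#'
#' @inheritParams is_eligible
#' @return The product microstate, or `NULL` if any factor annihilates the
#'   state.
#' @export
apply_rule_instance <- function(fm, inst, s) {
  if (is.null(s)) return(NULL)
  if (!is_eligible(fm, inst, s)) return(NULL)
  fi <- fm$flips_by_inst[[inst]]
  add <- fm$flip_mode[fi][fm$flip_add[fi]]
  rm_ <- fm$flip_mode[fi][!fm$flip_add[fi]]
  sort(c(s[!(s %in% rm_)], add))
}

## ids of all instances eligible on state s (core inner loop, vectorized)
eligible_instance_ids <- function(fm, s) {
  if (fm$n_inst == 0L) return(integer(0))
  excited <- logical(fm$n_modes)
  excited[s] <- TRUE
  bad <- excited[fm$cond_mode] != fm$cond_req
  unsat <- tabulate(fm$cond_inst[bad], nbins = fm$n_inst)
  which(unsat == 0L)
}

#' Enumerate the mode-specific instances of one rule template
#'
#' One instance per index binding satisfying the template's constraint, in
#' deterministic lexicographic order.
#'
#' @param fm Compiled model.
#' @param name Rule template name.
#' @return A data.frame with columns `inst` (instance id), `label`, and one
#'   column per index variable.
#' @export
instantiate_rules <- function(fm, name) {
  ti <- which(vapply(fm$spec$rules, `[[`, "", "name") == name)
  if (length(ti) != 1L) stop("unknown rule template '", name, "'")
  ids <- which(fm$inst_template == ti)
  if (length(ids) == 0L)
    return(data.frame(inst = integer(0), label = character(0)))
  bind <- do.call(rbind, lapply(fm$inst_binding[ids], function(b)
    as.data.frame(as.list(b))))
  cbind(data.frame(inst = ids, label = fm$inst_label[ids],
                   stringsAsFactors = FALSE), bind)
}

#' Derive the depletion form of a rule template
#'
#' Factor-wise map create -> absence, annihilate -> presence, presence and
#' absence fixed; rate and index constraint preserved. The depletion operator
#' is diagonal and carries the probability outflow matching its reaction
#' operator in the master-equation generator.
#'
#' @param tmpl A [rule_template()].
#' @return The depletion `rule_template`.
#' @export
derive_depletion <- function(tmpl) {
  map <- c(create = "absence", annihilate = "presence",
           presence = "presence", absence = "absence")
  factors <- lapply(tmpl$factors, function(fa)
    rule_factor(map[[fa$op]], fa$field, fa$vars))
  rule_template(paste0(tmpl$name, "_depl"), factors, tmpl$rate, tmpl$constraint)
}

#' @export
print.fock_model <- function(x, ...) {
  cat("<fock_model> N =", x$N, "|", x$n_modes, "modes,",
      x$n_inst, "rule instances\n")
  invisible(x)
}
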