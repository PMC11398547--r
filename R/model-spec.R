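#' polyfock: Fock-space rule-based modeling of multi-particle complexes
#'
#' Particles, binding sites and bonds are hard-core boson excitation modes;
#' reaction rules are products of mode-specific creation (`+`), annihilation
#' (`-`), presence (`?`) and absence (`~`) operators. The package builds exact
#' microstate master equations from rules, runs an eligibility-driven Gillespie
#' algorithm, classifies the complexes in a trajectory (chains, rings, trees,
#' groves), evaluates equilibrium partition-function analytics for polymer
#' systems, and brute-forces Wick contraction combinatorics to verify the
#' factory/gallery equivalence.
#'
#' @importFrom methods as new
#' @importFrom stats rexp runif setNames dpois qpois sd dbinom
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

FACTOR_OPS <- c("create", "annihilate", "presence", "absence")
OP_GLYPH <- c(create = "+", annihilate = "-", presence = "?", absence = "~")
CONSTRAINTS <- c("none", "all-distinct", "i<j")

#' Declare a field
#'
#' A field is a family of hard-core boson modes. `particle` fields have one
#' mode per internal index `1..N`; `site` fields decorate a particle field
#' with one mode per index (occupied when the particle's site is engaged in a
#' bond); `bond` fields have one mode per index pair and connect two site (or
#' particle) fields.
#'
#' @param name Short identifier.
#' @param kind One of `"particle"`, `"site"`, `"bond"`.
#' @param host For sites: name of the particle field carrying the site.
#' @param endpoints For bonds: character vector of two site/particle field
#'   names, the two ends of the bond.
#' @param symmetric For bonds: if `TRUE` the index pair is unordered and
#'   stored with `i < j`.
#' @param allow_self For bonds: whether the pair `(i, i)` is an admissible
#'   mode (self-bond).
#' @return A `field_spec` object.
#' @export
field_spec <- function(name, kind, host = NULL, endpoints = NULL,
                       symmetric = FALSE, allow_self = FALSE) {
  kind <- match.arg(kind, c("particle", "site", "bond"))
  if (kind == "site" && is.null(host))
    stop("site field '", name, "' needs a host particle field")
  if (kind == "bond" && (is.null(endpoints) || length(endpoints) != 2L))
    stop("bond field '", name, "' needs exactly two endpoints")
  structure(list(name = name, kind = kind, host = host,
                 endpoints = endpoints,
                 symmetric = isTRUE(symmetric),
                 allow_self = isTRUE(allow_self)),
            class = "field_spec")
}

#' A single operator factor of a rule
#'
#' @param op One of `"create"`, `"annihilate"`, `"presence"`, `"absence"`
#'   (the hat / check / bar / tilde decorations).
#' @param field Field name the operator acts on.
#' @param vars Character vector of 1 or 2 index-variable names (e.g. `"i"`).
#' @return A `rule_factor` object.
#' @export
rule_factor <- function(op, field, vars) {
  op <- match.arg(op, FACTOR_OPS)
  structure(list(op = op, field = field, vars = as.character(vars)),
            class = "rule_factor")
}

#' A reaction rule template
#'
#' A rule template is an indexed product of mode operators with a per-instance
#' rate; instantiating it over `1..N` yields one mode-specific rule per index
#' binding satisfying `constraint`.
#'
#' @param name Rule identifier.
#' @param factors List of [rule_factor()] objects.
#' @param rate Nonnegative per-instance rate.
#' @param constraint One of `"none"`, `"all-distinct"` (`i != j`), `"i<j"`.
#' @return A `rule_template` object.
#' @export
rule_template <- function(name, factors, rate = 1,
                          constraint = c("none", "all-distinct", "i<j")) {
  constraint <- match.arg(constraint)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("rule '", name, "': rate must be a nonnegative number")
  structure(list(name = name, factors = factors, rate = as.numeric(rate),
                 constraint = constraint),
            class = "rule_template")
}

#' Assemble and validate a model
#'
#' @param N Number of modes per particle field (one global `N`).
#' @param fields List of [field_spec()] objects.
#' @param rules List of [rule_template()] objects.
#' @param hamiltonian Optional list of Hamiltonian terms for equilibrium
#'   analysis, each `list(coef = <name>, sign = +1/-1, field = <field>)`,
#'   read as `sign * coef * sum_i F_presence_i`.
#' @param init List of initial excitations, each `list(field = <name>,
#'   idx = <integer vector of 1 or 2 indices>)`.
#' @return A validated `model_spec` object.
#' @export
model_spec <- function(N, fields, rules = list(), hamiltonian = list(),
                       init = list()) {
  spec <- structure(list(N = as.integer(N), fields = fields, rules = rules,
                         hamiltonian = hamiltonian, init = init),
                    class = "model_spec")
  validate_model(spec)
  spec
}

field_arity <- function(f) if (f$kind == "bond") 2L else 1L

field_by_name <- function(spec, name) {
  for (f in spec$fields) if (f$name == name) return(f)
  NULL
}

#' Validate a model specification
#'
#' Checks field cross-references, rule factor arities, rates, operator
#' conflicts within a rule, and initial-state mode validity.
#'
#' @param spec A `model_spec`.
#' @return `spec`, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(spec) {
  if (is.na(spec$N) || spec$N < 1L) stop("N must be a positive integer")
  nms <- vapply(spec$fields, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate field name: ", nms[duplicated(nms)][1])
  for (f in spec$fields) {
    if (f$kind == "site") {
      h <- field_by_name(spec, f$host)
      if (is.null(h) || h$kind != "particle")
        stop("site field '", f$name, "' references unknown particle field '",
             f$host, "'")
    }
    if (f$kind == "bond") {
      for (e in f$endpoints) {
        ef <- field_by_name(spec, e)
        if (is.null(ef) || ef$kind == "bond")
          stop("bond field '", f$name,
               "' endpoint '", e, "' is not a declared site or particle field")
      }
    }
  }
  for (r in spec$rules) {
    seen <- character()
    for (fa in r$factors) {
      f <- field_by_name(spec, fa$field)
      if (is.null(f))
        stop("rule '", r$name, "' references undeclared field '", fa$field, "'")
      if (length(fa$vars) != field_arity(f))
        stop("rule '", r$name, "': factor on '", fa$field,
             "' has arity ", length(fa$vars), ", expected ", field_arity(f))
      key <- paste(fa$field, paste(fa$vars, collapse = ","))
      prev <- seen[key]
      if (!is.na(prev) && prev != fa$op)
        stop("rule '", r$name, "': conflicting operators on mode ",
             key)
      seen[key] <- fa$op
    }
    if (r$rate < 0) stop("rule '", r$name, "': negative rate")
  }
  for (e in spec$init) {
    f <- field_by_name(spec, e$field)
    if (is.null(f)) stop("init references undeclared field '", e$field, "'")
    if (length(e$idx) != field_arity(f))
      stop("init excitation ", e$field, "(", paste(e$idx, collapse = ","),
           "): wrong arity")
    if (any(e$idx < 1L | e$idx > spec$N))
      stop("init excitation ", e$field, "(", paste(e$idx, collapse = ","),
           "): index out of 1..N")
    if (f$kind == "bond" && !f$allow_self && e$idx[1] == e$idx[2])
      stop("init excitation ", e$field, ": self-pair not allowed")
  }
  invisible(spec)
}

## ---------------------------------------------------------------------------
## Text format
## ---------------------------------------------------------------------------

strip_line <- function(x) sub("\\s+$", "", sub("^\\s+", "", sub("#.*$", "", x)))

parse_factor_token <- function(tok, line_no) {
  m <- regmatches(tok, regexec("^([+?~-])([A-Za-z_][A-Za-z0-9_]*)\\(([^)]*)\\)$",
                               tok))[[1]]
  if (length(m) == 0)
    stop("line ", line_no, ": malformed factor '", tok, "'")
  op <- c("+" = "create", "-" = "annihilate",
          "?" = "presence", "~" = "absence")[m[2]]
  vars <- strip_line(strsplit(m[4], ",")[[1]])
  rule_factor(op, m[3], vars)
}

#' Parse the plain-text model format
#'
#' The format is line oriented with `#` comments and four sections:
#' \preformatted{
#' [params]       N = <int>
#' [fields]       A : particle
#'                a : site on A
#'                I : bond(a--a)          # symmetric
#'                J : bond(a->b) self     # directed, (i,i) admitted
#' [rules]        bind : 0.5 : ?A(i) ?A(j) +a(i) +a(j) +I(i,j) | i<j
#' [hamiltonian]  -mu : ?A(i)
#' [init]         A(2) A(3) A(5) A(7)
#' }
#' Factor glyphs: `+` create, `-` annihilate, `?` presence, `~` absence.
#' Rule constraint suffixes: `| i<j` or `| i!=j`.
#'
#' @param text A single string (or character vector of lines).
#' @return A validated [model_spec()].
#' @seealso [render_model()] for the inverse.
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  section <- NULL
  N <- NA_integer_
  fields <- list(); rules <- list(); ham <- list(); init <- list()
  for (ln in seq_along(lines)) {
    raw <- strip_line(lines[[ln]])
    if (raw == "") next
    if (grepl("^\\[[a-z]+\\]$", raw)) {
      section <- sub("\\]", "", sub("\\[", "", raw))
      if (!section %in% c("params", "fields", "rules", "hamiltonian", "init"))
        stop("line ", ln, ": unknown section [", section, "]")
      next
    }
    if (is.null(section)) stop("line ", ln, ": content before any section")
    if (section == "params") {
      m <- regmatches(raw, regexec("^N\\s*=\\s*([0-9]+)$", raw))[[1]]
      if (length(m) == 0) stop("line ", ln, ": expected 'N = <int>'")
      N <- as.integer(m[2])
    } else if (section == "fields") {
      m <- regmatches(raw, regexec(
        "^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", raw))[[1]]
      if (length(m) == 0) stop("line ", ln, ": malformed field declaration")
      name <- m[2]; rhs <- m[3]
      if (rhs == "particle") {
        fields[[length(fields) + 1L]] <- field_spec(name, "particle")
      } else if (grepl("^site on ", rhs)) {
        fields[[length(fields) + 1L]] <-
          field_spec(name, "site", host = strip_line(sub("^site on ", "", rhs)))
      } else {
        m2 <- regmatches(rhs, regexec(
          "^bond\\(([A-Za-z_][A-Za-z0-9_]*)(--|->)([A-Za-z_][A-Za-z0-9_]*)\\)( self)?$",
          rhs))[[1]]
        if (length(m2) == 0) stop("line ", ln, ": malformed field '", rhs, "'")
        fields[[length(fields) + 1L]] <-
          field_spec(name, "bond", endpoints = c(m2[2], m2[4]),
                     symmetric = m2[3] == "--",
                     allow_self = m2[5] == " self")
      }
    } else if (section == "rules") {
      parts <- strsplit(raw, ":", fixed = TRUE)[[1]]
      if (length(parts) != 3) stop("line ", ln, ": expected 'name : rate : factors'")
      name <- strip_line(parts[1])
      rate <- suppressWarnings(as.numeric(strip_line(parts[2])))
      if (is.na(rate)) stop("line ", ln, ": unreadable rate")
      body <- strip_line(parts[3])
      constraint <- "none"
      if (grepl("|", body, fixed = TRUE)) {
        bits <- strsplit(body, "|", fixed = TRUE)[[1]]
        body <- strip_line(bits[1])
        con <- strip_line(bits[2])
        constraint <- switch(con, "i<j" = "i<j", "i!=j" = "all-distinct",
                             stop("line ", ln, ": unknown constraint '", con, "'"))
      }
      toks <- strsplit(body, "\\s+")[[1]]
      factors <- lapply(toks, parse_factor_token, line_no = ln)
      rules[[length(rules) + 1L]] <- rule_template(name, factors, rate, constraint)
    } else if (section == "hamiltonian") {
      m <- regmatches(raw, regexec(
        "^([+-]?)([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*\\?([A-Za-z_][A-Za-z0-9_]*)\\([^)]*\\)$",
        raw))[[1]]
      if (length(m) == 0) stop("line ", ln, ": malformed hamiltonian term")
      ham[[length(ham) + 1L]] <- list(coef = m[3], sign = if (m[2] == "-") -1 else 1,
                                      field = m[4])
    } else if (section == "init") {
      toks <- strsplit(raw, "\\s+")[[1]]
      for (tok in toks) {
        m <- regmatches(tok, regexec(
          "^([A-Za-z_][A-Za-z0-9_]*)\\(([0-9, ]+)\\)$", tok))[[1]]
        if (length(m) == 0) stop("line ", ln, ": malformed init entry '", tok, "'")
        init[[length(init) + 1L]] <-
          list(field = m[2], idx = as.integer(strip_line(strsplit(m[3], ",")[[1]])))
      }
    }
  }
  if (is.na(N)) stop("missing [params] section with N")
  model_spec(N, fields, rules, ham, init)
}

#' Serialize a model to the plain-text format
#'
#' Inverse of [parse_model()]: `parse_model(render_model(spec))` reproduces
#' `spec` exactly (sections are written in canonical order; declaration order
#' within sections is preserved).
#'
#' @param spec A `model_spec`.
#' @return A single string in the model format.
#' @export
render_model <- function(spec) {
  out <- c("[params]", paste0("N = ", spec$N), "", "[fields]")
  for (f in spec$fields) {
    out <- c(out, switch(f$kind,
      particle = paste0(f$name, " : particle"),
      site = paste0(f$name, " : site on ", f$host),
      bond = paste0(f$name, " : bond(", f$endpoints[1],
                    if (f$symmetric) "--" else "->", f$endpoints[2], ")",
                    if (f$allow_self) " self" else "")))
  }
  out <- c(out, "", "[rules]")
  for (r in spec$rules) {
    toks <- vapply(r$factors, function(fa)
      paste0(OP_GLYPH[[fa$op]], fa$field, "(", paste(fa$vars, collapse = ","), ")"),
      "")
    suffix <- switch(r$constraint, none = "", `all-distinct` = " | i!=j",
                     `i<j` = " | i<j")
    out <- c(out, paste0(r$name, " : ", sprintf("%.17g", r$rate), " : ",
                         paste(toks, collapse = " "), suffix))
  }
  if (length(spec$hamiltonian)) {
    out <- c(out, "", "[hamiltonian]")
    for (h in spec$hamiltonian) {
      f <- field_by_name(spec, h$field)
      vars <- if (field_arity(f) == 2L) "i,j" else "i"
      out <- c(out, paste0(if (h$sign < 0) "-" else "+", h$coef, " : ?",
                           h$field, "(", vars, ")"))
    }
  }
  if (length(spec$init)) {
    out <- c(out, "", "[init]")
    out <- c(out, paste(vapply(spec$init, function(e)
      paste0(e$field, "(", paste(e$idx, collapse = ","), ")"), ""),
      collapse = " "))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> N =", x$N, "|", length(x$fields), "fields,",
      length(x$rules), "rules,", length(x$init), "init excitations\n")
  invisible(x)
}

#' @export
format.rule_template <- function(x, ...) {
  toks <- vapply(x$factors, function(fa)
    paste0(OP_GLYPH[[fa$op]], fa$field, "(", paste(fa$vars, collapse = ","), ")"), "")
  paste0(x$name, ": ", paste(toks, collapse = " "),
         if (x$constraint != "none") paste0(" | ", x$constraint) else "")
}
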