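## Built-in fixture models: the canonical polymer systems.

fixture_names <- c("monomer", "homodimer", "homopolymer", "heterodimer",
                   "occlusive", "cooperative", "heteropolymer",
                   "branched_homopolymer", "isotropic_homopolymer")

fac <- function(op, field, vars) rule_factor(op, field, vars)

#' Built-in fixture models
#'
#' Returns the model for one of the canonical systems. Rule naming follows
#' the forward/reverse convention: for each reversible pair, the reverse rule
#' is the factor-wise conjugate of the forward rule (create <-> annihilate).
#'
#' Systems:
#' \describe{
#'   \item{monomer}{particle field `A`, creation/annihilation only (rules
#'     `r1`, `r2`).}
#'   \item{homodimer}{`A` with one site `a` and symmetric bond `I`;
#'     `r1`/`r2` create/annihilate free monomers, `r3`/`r4` form/break a
#'     dimer bond (index constraint `i<j`, so no symmetry factor).}
#'   \item{homopolymer}{`A` with sites `a` (outgoing) and `b` (incoming) and
#'     directed bond `J(a->b)`; generates x-chains and x-rings.}
#'   \item{heterodimer}{two particle fields `A`, `B` with a directed bond
#'     between their sites.}
#'   \item{occlusive}{ligands `B` and `C` compete for the single site `a`
#'     on `A`.}
#'   \item{cooperative}{`C` can bind `A` only when `B` is already bound
#'     (the `C`-binding rule carries a presence factor on site `a`).}
#'   \item{heteropolymer}{alternating `A`/`B` chains via two directed bonds.}
#'   \item{branched_homopolymer}{`A` with sites `a`, `b`, `c` and directed
#'     bonds `I(a->c)`, `J(b->c)`; generates trees and groves.}
#'   \item{isotropic_homopolymer}{`A` with sites `a`, `b` and two symmetric
#'     bonds `I(a--a)`, `J(b--b)`; `I` and `J` alternate in all multimers and
#'     rings have even length.}
#' }
#'
#' @param name Fixture name: `monomer`, `homodimer`, `homopolymer`,
#'   `heterodimer`, `occlusive`, `cooperative`, `heteropolymer`,
#'   `branched_homopolymer` or `isotropic_homopolymer`.
#' @param N Number of modes per particle field.
#' @param rates Named list overriding per-instance rates by rule name
#'   (default 1 for every rule).
#' @param allow_self For the homopolymer: admit self-bonds `J(i,i)`
#'   (1-rings). Default `FALSE`.
#' @param init Optional init excitation list passed to [model_spec()].
#' @return A validated [model_spec()].
#' @export
builtin_fixture <- function(name, N, rates = list(), allow_self = FALSE,
                            init = list()) {
  name <- match.arg(name, fixture_names)
  r <- function(nm) if (!is.null(rates[[nm]])) rates[[nm]] else 1
  b <- switch(name,
    monomer = list(
      fields = list(field_spec("A", "particle")),
      rules = list(
        rule_template("r1", list(fac("create", "A", "i")), r("r1")),
        rule_template("r2", list(fac("annihilate", "A", "i")), r("r2"))),
      ham = list(list(coef = "mu", sign = -1, field = "A"))),
    homodimer = list(
      fields = list(field_spec("A", "particle"),
                    field_spec("a", "site", host = "A"),
                    field_spec("I", "bond", endpoints = c("a", "a"),
                               symmetric = TRUE)),
      rules = list(
        rule_template("r1", list(fac("create", "A", "i"),
                                 fac("absence", "a", "i")), r("r1")),
        rule_template("r2", list(fac("annihilate", "A", "i"),
                                 fac("absence", "a", "i")), r("r2")),
        rule_template("r3", list(fac("presence", "A", "i"),
                                 fac("presence", "A", "j"),
                                 fac("create", "a", "i"),
                                 fac("create", "a", "j"),
                                 fac("create", "I", c("i", "j"))),
                      r("r3"), "i<j"),
        rule_template("r4", list(fac("presence", "A", "i"),
                                 fac("presence", "A", "j"),
                                 fac("annihilate", "a", "i"),
                                 fac("annihilate", "a", "j"),
                                 fac("annihilate", "I", c("i", "j"))),
                      r("r4"), "i<j")),
      ham = list(list(coef = "mu", sign = -1, field = "A"),
                 list(coef = "eps", sign = 1, field = "I"))),
    homopolymer = list(
      fields = list(field_spec("A", "particle"),
                    field_spec("a", "site", host = "A"),
                    field_spec("b", "site", host = "A"),
                    field_spec("J", "bond", endpoints = c("a", "b"),
                               allow_self = allow_self)),
      rules = list(
        rule_template("r1", list(fac("create", "A", "i"),
                                 fac("absence", "a", "i"),
                                 fac("absence", "b", "i")), r("r1")),
        rule_template("r2", list(fac("annihilate", "A", "i"),
                                 fac("absence", "a", "i"),
                                 fac("absence", "b", "i")), r("r2")),
        rule_template("r3", list(fac("presence", "A", "i"),
                                 fac("presence", "A", "j"),
                                 fac("create", "a", "i"),
                                 fac("create", "b", "j"),
                                 fac("create", "J", c("i", "j"))),
                      r("r3"), if (allow_self) "none" else "all-distinct"),
        rule_template("r4", list(fac("presence", "A", "i"),
                                 fac("presence", "A", "j"),
                                 fac("annihilate", "a", "i"),
                                 fac("annihilate", "b", "j"),
                                 fac("annihilate", "J", c("i", "j"))),
                      r("r4"), if (allow_self) "none" else "all-distinct")),
      ham = list(list(coef = "mu", sign = -1, field = "A"),
                 list(coef = "eps", sign = 1, field = "J"))),
    heterodimer = list(
      fields = list(field_spec("A", "particle"), field_spec("B", "particle"),
                    field_spec("a", "site", host = "A"),
                    field_spec("b", "site", host = "B"),
                    field_spec("I", "bond", endpoints = c("a", "b"),
                               allow_self = TRUE)),
      rules = list(
        rule_template("r1f", list(fac("create", "A", "i"),
                                  fac("absence", "a", "i")), r("r1f")),
        rule_template("r1r", list(fac("annihilate", "A", "i"),
                                  fac("absence", "a", "i")), r("r1r")),
        rule_template("r2f", list(fac("create", "B", "i"),
                                  fac("absence", "b", "i")), r("r2f")),
        rule_template("r2r", list(fac("annihilate", "B", "i"),
                                  fac("absence", "b", "i")), r("r2r")),
        rule_template("r3f", list(fac("presence", "A", "i"),
                                  fac("presence", "B", "j"),
                                  fac("create", "a", "i"),
                                  fac("create", "b", "j"),
                                  fac("create", "I", c("i", "j"))), r("r3f")),
        rule_template("r3r", list(fac("presence", "A", "i"),
                                  fac("presence", "B", "j"),
                                  fac("annihilate", "a", "i"),
                                  fac("annihilate", "b", "j"),
                                  fac("annihilate", "I", c("i", "j"))), r("r3r"))),
      ham = list()),
    occlusive = list(
      fields = list(field_spec("A", "particle"), field_spec("B", "particle"),
                    field_spec("C", "particle"),
                    field_spec("a", "site", host = "A"),
                    field_spec("b", "site", host = "B"),
                    field_spec("c", "site", host = "C"),
                    field_spec("I", "bond", endpoints = c("b", "a"),
                               allow_self = TRUE),
                    field_spec("J", "bond", endpoints = c("c", "a"),
                               allow_self = TRUE)),
      rules = list(
        rule_template("r1f", list(fac("create", "A", "i"),
                                  fac("absence", "a", "i")), r("r1f")),
        rule_template("r1r", list(fac("annihilate", "A", "i"),
                                  fac("absence", "a", "i")), r("r1r")),
        rule_template("r2f", list(fac("create", "B", "i"),
                                  fac("absence", "b", "i")), r("r2f")),
        rule_template("r2r", list(fac("annihilate", "B", "i"),
                                  fac("absence", "b", "i")), r("r2r")),
        rule_template("r3f", list(fac("create", "C", "i"),
                                  fac("absence", "c", "i")), r("r3f")),
        rule_template("r3r", list(fac("annihilate", "C", "i"),
                                  fac("absence", "c", "i")), r("r3r")),
        rule_template("r4f", list(fac("presence", "B", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "b", "i"),
                                  fac("create", "a", "j"),
                                  fac("create", "I", c("i", "j"))), r("r4f")),
        rule_template("r4r", list(fac("presence", "B", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "b", "i"),
                                  fac("annihilate", "a", "j"),
                                  fac("annihilate", "I", c("i", "j"))), r("r4r")),
        rule_template("r5f", list(fac("presence", "C", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "c", "i"),
                                  fac("create", "a", "j"),
                                  fac("create", "J", c("i", "j"))), r("r5f")),
        rule_template("r5r", list(fac("presence", "C", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "c", "i"),
                                  fac("annihilate", "a", "j"),
                                  fac("annihilate", "J", c("i", "j"))), r("r5r"))),
      ham = list()),
    cooperative = list(
      fields = list(field_spec("A", "particle"), field_spec("B", "particle"),
                    field_spec("C", "particle"),
                    field_spec("a", "site", host = "A"),
                    field_spec("a2", "site", host = "A"),
                    field_spec("b", "site", host = "B"),
                    field_spec("c", "site", host = "C"),
                    field_spec("I", "bond", endpoints = c("b", "a"),
                               allow_self = TRUE),
                    field_spec("J", "bond", endpoints = c("c", "a2"),
                               allow_self = TRUE)),
      rules = list(
        rule_template("r1f", list(fac("create", "A", "i"),
                                  fac("absence", "a", "i"),
                                  fac("absence", "a2", "i")), r("r1f")),
        rule_template("r1r", list(fac("annihilate", "A", "i"),
                                  fac("absence", "a", "i"),
                                  fac("absence", "a2", "i")), r("r1r")),
        rule_template("r2f", list(fac("create", "B", "i"),
                                  fac("absence", "b", "i")), r("r2f")),
        rule_template("r2r", list(fac("annihilate", "B", "i"),
                                  fac("absence", "b", "i")), r("r2r")),
        rule_template("r3f", list(fac("create", "C", "i"),
                                  fac("absence", "c", "i")), r("r3f")),
        rule_template("r3r", list(fac("annihilate", "C", "i"),
                                  fac("absence", "c", "i")), r("r3r")),
        rule_template("r4f", list(fac("presence", "B", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "b", "i"),
                                  fac("create", "a", "j"),
                                  fac("create", "I", c("i", "j"))), r("r4f")),
        rule_template("r4r", list(fac("presence", "B", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "b", "i"),
                                  fac("annihilate", "a", "j"),
                                  fac("annihilate", "I", c("i", "j"))), r("r4r")),
        ## C binds A only if site a is occupied (B already bound): cooperativity
        rule_template("r5f", list(fac("presence", "C", "i"),
                                  fac("presence", "A", "j"),
                                  fac("presence", "a", "j"),
                                  fac("create", "c", "i"),
                                  fac("create", "a2", "j"),
                                  fac("create", "J", c("i", "j"))), r("r5f")),
        rule_template("r5r", list(fac("presence", "C", "i"),
                                  fac("presence", "A", "j"),
                                  fac("presence", "a", "j"),
                                  fac("annihilate", "c", "i"),
                                  fac("annihilate", "a2", "j"),
                                  fac("annihilate", "J", c("i", "j"))), r("r5r"))),
      ham = list()),
    heteropolymer = list(
      fields = list(field_spec("A", "particle"), field_spec("B", "particle"),
                    field_spec("ao", "site", host = "A"),
                    field_spec("ai", "site", host = "A"),
                    field_spec("bo", "site", host = "B"),
                    field_spec("bi", "site", host = "B"),
                    field_spec("I", "bond", endpoints = c("ao", "bi"),
                               allow_self = TRUE),
                    field_spec("J", "bond", endpoints = c("bo", "ai"),
                               allow_self = TRUE)),
      rules = list(
        rule_template("r1f", list(fac("create", "A", "i"),
                                  fac("absence", "ao", "i"),
                                  fac("absence", "ai", "i")), r("r1f")),
        rule_template("r1r", list(fac("annihilate", "A", "i"),
                                  fac("absence", "ao", "i"),
                                  fac("absence", "ai", "i")), r("r1r")),
        rule_template("r2f", list(fac("create", "B", "i"),
                                  fac("absence", "bo", "i"),
                                  fac("absence", "bi", "i")), r("r2f")),
        rule_template("r2r", list(fac("annihilate", "B", "i"),
                                  fac("absence", "bo", "i"),
                                  fac("absence", "bi", "i")), r("r2r")),
        rule_template("r3f", list(fac("presence", "A", "i"),
                                  fac("presence", "B", "j"),
                                  fac("create", "ao", "i"),
                                  fac("create", "bi", "j"),
                                  fac("create", "I", c("i", "j"))), r("r3f")),
        rule_template("r3r", list(fac("presence", "A", "i"),
                                  fac("presence", "B", "j"),
                                  fac("annihilate", "ao", "i"),
                                  fac("annihilate", "bi", "j"),
                                  fac("annihilate", "I", c("i", "j"))), r("r3r")),
        rule_template("r4f", list(fac("presence", "B", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "bo", "i"),
                                  fac("create", "ai", "j"),
                                  fac("create", "J", c("i", "j"))), r("r4f")),
        rule_template("r4r", list(fac("presence", "B", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "bo", "i"),
                                  fac("annihilate", "ai", "j"),
                                  fac("annihilate", "J", c("i", "j"))), r("r4r"))),
      ham = list()),
    branched_homopolymer = list(
      fields = list(field_spec("A", "particle"),
                    field_spec("a", "site", host = "A"),
                    field_spec("b", "site", host = "A"),
                    field_spec("c", "site", host = "A"),
                    field_spec("I", "bond", endpoints = c("a", "c")),
                    field_spec("J", "bond", endpoints = c("b", "c"))),
      rules = list(
        rule_template("r1f", list(fac("create", "A", "i"),
                                  fac("absence", "a", "i"),
                                  fac("absence", "b", "i"),
                                  fac("absence", "c", "i")), r("r1f")),
        rule_template("r1r", list(fac("annihilate", "A", "i"),
                                  fac("absence", "a", "i"),
                                  fac("absence", "b", "i"),
                                  fac("absence", "c", "i")), r("r1r")),
        rule_template("r2f", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "a", "i"),
                                  fac("create", "c", "j"),
                                  fac("create", "I", c("i", "j"))),
                      r("r2f"), "all-distinct"),
        rule_template("r2r", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "a", "i"),
                                  fac("annihilate", "c", "j"),
                                  fac("annihilate", "I", c("i", "j"))),
                      r("r2r"), "all-distinct"),
        rule_template("r3f", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "b", "i"),
                                  fac("create", "c", "j"),
                                  fac("create", "J", c("i", "j"))),
                      r("r3f"), "all-distinct"),
        rule_template("r3r", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "b", "i"),
                                  fac("annihilate", "c", "j"),
                                  fac("annihilate", "J", c("i", "j"))),
                      r("r3r"), "all-distinct")),
      ham = list(list(coef = "mu", sign = -1, field = "A"),
                 list(coef = "eps", sign = 1, field = "I"),
                 list(coef = "eps", sign = 1, field = "J"))),
    isotropic_homopolymer = list(
      fields = list(field_spec("A", "particle"),
                    field_spec("a", "site", host = "A"),
                    field_spec("b", "site", host = "A"),
                    field_spec("I", "bond", endpoints = c("a", "a"),
                               symmetric = TRUE),
                    field_spec("J", "bond", endpoints = c("b", "b"),
                               symmetric = TRUE)),
      rules = list(
        rule_template("r1f", list(fac("create", "A", "i"),
                                  fac("absence", "a", "i"),
                                  fac("absence", "b", "i")), r("r1f")),
        rule_template("r1r", list(fac("annihilate", "A", "i"),
                                  fac("absence", "a", "i"),
                                  fac("absence", "b", "i")), r("r1r")),
        rule_template("r2f", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "a", "i"),
                                  fac("create", "a", "j"),
                                  fac("create", "I", c("i", "j"))),
                      r("r2f"), "i<j"),
        rule_template("r2r", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "a", "i"),
                                  fac("annihilate", "a", "j"),
                                  fac("annihilate", "I", c("i", "j"))),
                      r("r2r"), "i<j"),
        rule_template("r3f", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("create", "b", "i"),
                                  fac("create", "b", "j"),
                                  fac("create", "J", c("i", "j"))),
                      r("r3f"), "i<j"),
        rule_template("r3r", list(fac("presence", "A", "i"),
                                  fac("presence", "A", "j"),
                                  fac("annihilate", "b", "i"),
                                  fac("annihilate", "b", "j"),
                                  fac("annihilate", "J", c("i", "j"))),
                      r("r3r"), "i<j")),
      ham = list(list(coef = "mu", sign = -1, field = "A"),
                 list(coef = "eps", sign = 1, field = "I"),
                 list(coef = "eps", sign = 1, field = "J"))))
  model_spec(N, b$fields, b$rules, b$ham, init)
}
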