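## species_census: microstate -> multiset of complexes via connected
## components over bond modes; canonical topology classification
## (x-chain, x-ring, tree, grove, generic canonical graph).

#' Decompose a microstate into complexes
#'
#' Builds the particle-bond graph (vertices: excited particle modes; edges:
#' excited bond modes with their site ports and directedness), checks
#' structural integrity, and returns the multiset of canonical species
#' labels of its connected components. Free particles are size-1 chains.
#'
#' @param fm Compiled model.
#' @param s Microstate.
#' @param check Verify structural integrity (no dangling bonds, site
#'   occupation consistent with bonds). Rules preserve integrity, so this
#'   can only fail on hand-written states.
#' @return Named integer vector: species label -> count.
#' @export
microstate_to_complexes <- function(fm, s, check = TRUE) {
  g <- state_graph(fm, s, check = check)
  if (nrow(g$vertices) == 0L) return(setNames(integer(0), character(0)))
  comp <- components_of(nrow(g$vertices), g$edges)
  labs <- vapply(seq_len(max(comp)), function(k) {
    vs <- which(comp == k)
    es <- g$edges[g$edges$from %in% vs, , drop = FALSE]
    classify_topology(component_graph(g, vs, es), fm)$label
  }, "")
  tab <- table(labs)
  setNames(as.integer(tab), names(tab))
}

## assemble the full particle-bond graph of a microstate
state_graph <- function(fm, s, check = TRUE) {
  md <- fm$modes
  part <- s[md$kind[s] == "particle"]
  vertices <- data.frame(field = md$field[part], index = md$i[part],
                         stringsAsFactors = FALSE)
  vid <- if (length(part))
    setNames(seq_along(part), paste0(md$field[part], ":", md$i[part]))
  else setNames(integer(0), character(0))
  bonds <- s[md$kind[s] == "bond"]
  from <- integer(0); to <- integer(0)
  bf <- character(0); pf <- character(0); pt <- character(0); dir <- logical(0)
  used_sites <- integer(0)
  for (m in bonds) {
    f <- fm$fields[[md$field[m]]]
    ep <- lapply(seq_len(2), function(k) {
      efield <- fm$fields[[f$endpoints[k]]]
      idx <- if (k == 1) md$i[m] else md$j[m]
      host <- if (efield$kind == "site") efield$host else efield$name
      list(host = host, idx = idx, site = if (efield$kind == "site")
        mode_id(fm, efield$name, idx) else NA_integer_)
    })
    v1 <- vid[paste0(ep[[1]]$host, ":", ep[[1]]$idx)]
    v2 <- vid[paste0(ep[[2]]$host, ":", ep[[2]]$idx)]
    if (check && (is.na(v1) || is.na(v2)))
      stop("dangling bond: mode ", names(fm$mode_ids)[m],
           " lacks an excited endpoint particle")
    for (e in ep) if (!is.na(e$site)) {
      if (check && !(e$site %in% s))
        stop("bond ", names(fm$mode_ids)[m], " with unoccupied site ",
             names(fm$mode_ids)[e$site])
      used_sites <- c(used_sites, e$site)
    }
    from <- c(from, v1); to <- c(to, v2)
    bf <- c(bf, f$name); pf <- c(pf, f$endpoints[1]); pt <- c(pt, f$endpoints[2])
    dir <- c(dir, !f$symmetric)
  }
  if (check) {
    excited_sites <- s[md$kind[s] == "site"]
    if (!identical(sort(unique(used_sites)), sort(excited_sites)) ||
        anyDuplicated(used_sites))
      stop("orphan or doubly-used site excitation (sites ",
           paste(setdiff(excited_sites, used_sites), collapse = ","), ")")
    if (check && length(bonds)) {
      ## both endpoint particles of every bond must be excited (covered above)
    }
  }
  list(vertices = vertices,
       edges = data.frame(from = from, to = to, bond = bf,
                          port_from = pf, port_to = pt, directed = dir,
                          stringsAsFactors = FALSE))
}

## union-find connected components
components_of <- function(nv, edges) {
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges$from[e]); b <- find(edges$to[e])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(nv), find, 1L)
  match(roots, unique(roots))
}

component_graph <- function(g, vs, es) {
  remap <- setNames(seq_along(vs), vs)
  es$from <- remap[as.character(es$from)]
  es$to <- remap[as.character(es$to)]
  list(vertices = g$vertices[vs, , drop = FALSE], edges = es)
}

#' Classify the topology of a connected complex
#'
#' `x` vertices with `x - 1` path-forming bonds give `chain-x`; `x` cycle
#' bonds with all degrees 2 give `ring-x`; other acyclic graphs are trees;
#' exactly one cycle with pendant trees is a grove; anything else falls back
#' to the canonical string. For models with one particle field and at most
#' one bond field the chain/ring names are the label; otherwise the label
#' carries the canonical string so that, e.g., the two even-length
#' alternating-bond chain species of the isotropic homopolymer stay
#' distinct.
#'
#' @param g A component graph (`vertices`, `edges` data frames) as produced
#'   internally by [microstate_to_complexes()].
#' @param fm Compiled model (for the simple-system label shortcut).
#' @return `list(label =, kind =, size =)`; kind in
#'   `c("chain", "ring", "tree", "grove", "other")`.
#' @export
classify_topology <- function(g, fm = NULL) {
  nv <- nrow(g$vertices); ne <- nrow(g$edges)
  deg <- tabulate(c(g$edges$from, g$edges$to), nbins = nv)
  kind <-
    if (ne == nv - 1L && all(deg <= 2L)) "chain"
    else if (ne == nv && all(deg == 2L)) "ring"
    else if (ne == nv - 1L) "tree"
    else if (ne == nv) "grove"
    else "other"
  simple <- !is.null(fm) &&
    sum(vapply(fm$fields, function(f) f$kind == "particle", TRUE)) == 1L &&
    sum(vapply(fm$fields, function(f) f$kind == "bond", TRUE)) <= 1L
  label <- if (simple && kind %in% c("chain", "ring")) {
    paste0(kind, "-", nv)
  } else {
    paste0(kind, "-", nv, "[", canonical_string(g), "]")
  }
  list(label = label, kind = kind, size = nv)
}

## ---------------------------------------------------------------------------
## Canonical labeling: iterative color refinement with individualization and
## lexicographic tie-breaking. Vertex colors start from the particle field;
## edge colors carry the bond field, the two site ports, and directedness,
## so ring rotations and mirror symmetries collapse to one label while
## genuinely different port usage does not.
## ---------------------------------------------------------------------------

canonical_string <- function(g) {
  nv <- nrow(g$vertices)
  if (nv == 0L) return("empty")
  if (nv > 40L) {
    ## guard: fall back to a strong but non-canonical invariant
    return(paste0("big:", nv, ":", nrow(g$edges), ":",
                  paste(sort(table(g$vertices$field)), collapse = ","),
                  ":", paste(sort(paste(g$edges$bond, g$edges$port_from,
                                        g$edges$port_to)), collapse = ",")))
  }
  ecol <- paste(g$edges$bond, g$edges$port_from, g$edges$port_to,
                ifelse(g$edges$directed, "d", "u"))
  ## adjacency with per-vertex incident-edge descriptors
  inc <- vector("list", nv)
  for (e in seq_len(nrow(g$edges))) {
    u <- g$edges$from[e]; v <- g$edges$to[e]
    tag_out <- if (g$edges$directed[e]) ">" else "-"
    tag_in <- if (g$edges$directed[e]) "<" else "-"
    inc[[u]] <- c(inc[[u]], list(list(other = v, tag = paste0(ecol[e], tag_out))))
    inc[[v]] <- c(inc[[v]], list(list(other = u, tag = paste0(ecol[e], tag_in))))
  }
  vcol0 <- match(g$vertices$field, sort(unique(g$vertices$field)))

  refine <- function(colors) {
    repeat {
      sig <- vapply(seq_len(nv), function(v) {
        nb <- vapply(inc[[v]], function(x)
          paste0(x$tag, "#", colors[x$other]), "")
        paste0(colors[v], "|", paste(sort(nb), collapse = ";"))
      }, "")
      newc <- match(sig, sort(unique(sig)))
      if (identical(newc, colors)) return(colors)
      colors <- newc
    }
  }
  serialize <- function(order_) {
    pos <- match(seq_len(nv), order_)
    vtxt <- paste(g$vertices$field[order_], collapse = ",")
    etxt <- vapply(seq_len(nrow(g$edges)), function(e) {
      a <- pos[g$edges$from[e]]; b <- pos[g$edges$to[e]]
      if (!g$edges$directed[e] && a > b) { tmp <- a; a <- b; b <- tmp }
      paste0(a, if (g$edges$directed[e]) ">" else "-", b, ":", ecol[e])
    }, "")
    paste0("V[", vtxt, "]E[", paste(sort(etxt), collapse = "|"), "]")
  }
  best <- NULL
  search <- function(colors) {
    colors <- refine(colors)
    if (!anyDuplicated(colors)) {
      s <- serialize(order(colors))
      if (is.null(best) || s < best) best <<- s
      return()
    }
    tabs <- table(colors)
    cell <- as.integer(names(tabs)[tabs > 1L][1])
    for (v in which(colors == cell)) {
      c2 <- colors
      c2[v] <- max(colors) + 1L
      search(c2)
    }
  }
  search(vcol0)
  best
}

#' A census labeler for master-equation projections
#'
#' Returns a function mapping a microstate to a canonical census string
#' (`"label:count|label:count"`, labels sorted), suitable for
#' [macrostate_distribution()] and [build_macro_generator()].
#'
#' @param fm Compiled model.
#' @return A function `microstate -> character`.
#' @export
census_labeler <- function(fm) {
  force(fm)
  function(s) {
    cc <- microstate_to_complexes(fm, s, check = FALSE)
    if (length(cc) == 0L) return("empty")
    cc <- cc[order(names(cc))]
    paste(paste0(names(cc), ":", cc), collapse = "|")
  }
}

#' Census time series of a trajectory
#'
#' Piecewise-constant sampling: at each query time the state immediately
#' after the last event at or before that time is classified.
#'
#' @param traj A `fock_trajectory`.
#' @param times Query times within `[0, tmax]`.
#' @param fm The compiled model.
#' @return Integer matrix, `length(times)` rows x one column per species
#'   observed, with attribute `"times"`; class `census_table`.
#' @export
trajectory_census <- function(traj, times, fm) {
  stopifnot(all(times >= 0))
  s <- traj$init
  ev <- 1L
  nev <- length(traj$times)
  rows <- vector("list", length(times))
  for (k in seq_along(times)) {
    while (ev <= nev && traj$times[ev] <= times[k]) {
      s <- c(s[!(s %in% traj$rms[[ev]])], traj$adds[[ev]])
      ev <- ev + 1L
    }
    rows[[k]] <- microstate_to_complexes(fm, sort(s), check = FALSE)
  }
  species <- sort(unique(unlist(lapply(rows, names))))
  out <- matrix(0L, length(times), length(species),
                dimnames = list(NULL, species))
  for (k in seq_along(times)) {
    r <- rows[[k]]
    if (length(r)) out[k, names(r)] <- r
  }
  attr(out, "times") <- times
  class(out) <- c("census_table", class(out))
  out
}

#' Ensemble mean and standard deviation of census tables
#'
#' @param runs List of [trajectory_census()] tables on a common time grid.
#' @return `list(mean =, sd =, n =, times =)`; species absent from every run
#'   are omitted.
#' @export
ensemble_stats <- function(runs) {
  stopifnot(length(runs) >= 2L)
  times <- attr(runs[[1]], "times")
  for (r in runs) if (!isTRUE(all.equal(attr(r, "times"), times)))
    stop("census tables are on mismatched time grids")
  species <- sort(unique(unlist(lapply(runs, colnames))))
  nt <- length(times)
  arr <- array(0, c(nt, length(species), length(runs)),
               dimnames = list(NULL, species, NULL))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (ncol(r)) arr[, colnames(r), i] <- r
  }
  list(mean = apply(arr, c(1, 2), mean),
       sd = apply(arr, c(1, 2), sd),
       n = length(runs), times = times)
}
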