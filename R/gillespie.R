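## gillespie_ssa: eligibility-driven stochastic simulation (Algorithm-style
## operator bookkeeping: modes carry excitation flags, rules are eligible iff
## every factor is eligible, the state constructor is the set of creation
## operators rebuilding the current microstate from the vacuum).

#' Initialize a simulation state
#'
#' Builds the mode excitation flags and the state constructor from the
#' model's initial excitations. The static indices (mode universe, rule
#' instances, operator-to-rule incidence) live in the compiled model itself.
#'
#' @param fm Compiled model.
#' @param init Optional initial microstate (default: the model's `[init]`).
#' @return A `sim_state`: list with `excited` (logical over modes),
#'   `constructor` (sorted ids of excited modes, i.e. the creation operators
#'   applied to the vacuum), `t`, and the incremental eligibility counter
#'   `unsat`.
#' @export
ssa_initialize <- function(fm, init = NULL) {
  s <- if (is.null(init)) build_state(fm) else sort(unique(as.integer(init)))
  excited <- logical(fm$n_modes)
  excited[s] <- TRUE
  bad <- excited[fm$cond_mode] != fm$cond_req
  unsat <- tabulate(fm$cond_inst[bad], nbins = fm$n_inst)
  structure(list(excited = excited, constructor = s, t = 0, unsat = unsat),
            class = "sim_state")
}

#' Eligible rule instances of a simulation state
#'
#' @param fm Compiled model.
#' @param state A [ssa_initialize()] state.
#' @param mode `"indexed"` trusts the incrementally maintained counter;
#'   `"naive"` rescans every instance from the excitation flags. Both return
#'   identical sets.
#' @return Integer vector of eligible instance ids.
#' @export
eligible_rules <- function(fm, state, mode = c("indexed", "naive")) {
  mode <- match.arg(mode)
  if (mode == "naive")
    return(eligible_instance_ids(fm, which(state$excited)))
  which(state$unsat == 0L)
}

#' One Gillespie draw
#'
#' Samples the waiting time (exponential with the summed rate, via inverse
#' CDF) and the firing instance (cumulative-rate search in instance-id
#' order) from R's current RNG stream.
#'
#' @param rates Rates of the eligible instances, in instance-id order.
#' @return `list(dt =, pick =)` where `pick` indexes into `rates`.
#' @export
gillespie_step <- function(rates) {
  R <- sum(rates)
  if (R <= 0) stop("gillespie_step on an empty eligible set")
  dt <- -log(runif(1)) / R
  cs <- cumsum(rates)
  pick <- findInterval(runif(1) * R, cs, left.open = TRUE) + 1L
  if (pick > length(rates)) pick <- length(rates)
  list(dt = dt, pick = pick)
}

## flip one set of modes and maintain the unsat counter
flip_modes <- function(fm, state, add, rm_) {
  for (m in c(add, rm_)) {
    state$excited[m] <- !state$excited[m]
    ci <- fm$conds_by_mode[[m]]
    if (length(ci)) {
      ok <- fm$cond_req[ci] == state$excited[m]
      state$unsat[fm$cond_inst[ci]] <- state$unsat[fm$cond_inst[ci]] +
        ifelse(ok, -1L, 1L)
    }
  }
  state$constructor <- which(state$excited)
  state
}

#' Apply a chosen instance and append it to a trajectory record
#'
#' Creation factors add their mode's creation operator to the constructor,
#' annihilation factors remove the corresponding creation operator;
#' presence/absence factors flip nothing. Excitation flags and the
#' incremental eligibility counter are updated for every flipped mode.
#'
#' @param fm Compiled model.
#' @param state Simulation state.
#' @param inst Instance id (must be eligible).
#' @param rec Internal record accumulator (or `NULL`).
#' @return Updated state (with `rec` attached as attribute when given).
#' @export
apply_and_record <- function(fm, state, inst, rec = NULL) {
  if (state$unsat[inst] != 0L)
    stop("internal consistency error: applying ineligible instance ", inst)
  fi <- fm$flips_by_inst[[inst]]
  add <- fm$flip_mode[fi][fm$flip_add[fi]]
  rm_ <- fm$flip_mode[fi][!fm$flip_add[fi]]
  state <- flip_modes(fm, state, add, rm_)
  if (!is.null(rec)) {
    rec$n <- rec$n + 1L
    rec$times[[rec$n]] <- state$t
    rec$inst[[rec$n]] <- inst
    rec$adds[[rec$n]] <- add
    rec$rms[[rec$n]] <- rm_
    attr(state, "rec") <- rec
  }
  state
}

#' Run the stochastic simulation algorithm
#'
#' Repeatedly identifies eligible instances, samples a waiting time and an
#' instance, applies it, and records the event, until `tmax` is crossed or
#' no rule is eligible (absorbing state, flagged). Bitwise reproducible
#' given `(model, tmax, seed, mode)`; `"naive"` and `"indexed"` eligibility
#' give identical trajectories for identical seeds.
#'
#' @param fm Compiled model.
#' @param tmax Simulation end time.
#' @param seed Integer seed (recorded in the trajectory metadata).
#' @param mode `"indexed"` (incremental eligibility, default) or `"naive"`
#'   (full rescan per step, the reference implementation).
#' @param init Optional initial microstate.
#' @param snapshot_every Store a full constructor snapshot every this many
#'   events (bounds replay cost).
#' @param max_events Safety cap on the number of events.
#' @return A `fock_trajectory`: event times, instance ids, mode deltas,
#'   periodic snapshots and metadata.
#' @export
run_ssa <- function(fm, tmax, seed, mode = c("indexed", "naive"),
                    init = NULL, snapshot_every = 1000L, max_events = 1e7) {
  mode <- match.arg(mode)
  stopifnot(tmax > 0)
  set.seed(as.integer(seed))
  state <- ssa_initialize(fm, init)
  init_ids <- state$constructor
  n_alloc <- 1024L
  times <- numeric(n_alloc); inst <- integer(n_alloc)
  adds <- vector("list", n_alloc); rms <- vector("list", n_alloc)
  snapshots <- list()
  n <- 0L
  absorbed <- FALSE
  rate <- fm$inst_rate
  repeat {
    elig <- if (mode == "naive")
      eligible_instance_ids(fm, which(state$excited)) else which(state$unsat == 0L)
    if (length(elig) == 0L) { absorbed <- TRUE; break }
    st <- gillespie_step(rate[elig])
    tnew <- state$t + st$dt
    if (tnew > tmax) break
    chosen <- elig[st$pick]
    state$t <- tnew
    fi <- fm$flips_by_inst[[chosen]]
    add <- fm$flip_mode[fi][fm$flip_add[fi]]
    rm_ <- fm$flip_mode[fi][!fm$flip_add[fi]]
    state <- flip_modes(fm, state, add, rm_)
    n <- n + 1L
    if (n > max_events) stop("max_events exceeded")
    if (n > n_alloc) {
      n_alloc <- 2L * n_alloc
      length(times) <- n_alloc; length(inst) <- n_alloc
      length(adds) <- n_alloc; length(rms) <- n_alloc
    }
    times[n] <- tnew; inst[n] <- chosen
    adds[[n]] <- add; rms[[n]] <- rm_
    if (n %% snapshot_every == 0L)
      snapshots[[as.character(n)]] <- state$constructor
  }
  structure(list(
    times = times[seq_len(n)], inst = inst[seq_len(n)],
    adds = adds[seq_len(n)], rms = rms[seq_len(n)],
    init = init_ids, snapshots = snapshots,
    meta = list(seed = as.integer(seed), tmax = tmax, mode = mode,
                N = fm$N, n_events = n, absorbed = absorbed,
                rng = RNGkind()[1],
                model_hash = model_hash(fm$spec))),
    class = "fock_trajectory")
}

model_hash <- function(spec) {
  txt <- render_model(spec)
  ## small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", h)
}

#' Replay a trajectory to the state just after event `k`
#'
#' Starts from the nearest stored snapshot and applies deltas.
#'
#' @param traj A `fock_trajectory`.
#' @param k Event index (0 = initial state).
#' @return Sorted integer vector of excited mode ids.
#' @export
replay_state <- function(traj, k) {
  stopifnot(k >= 0, k <= length(traj$times))
  snaps <- as.integer(names(traj$snapshots))
  base <- snaps[snaps <= k]
  if (length(base)) {
    b <- max(base)
    s <- traj$snapshots[[as.character(b)]]
  } else { b <- 0L; s <- traj$init }
  if (k > b) for (e in (b + 1L):k) {
    s <- c(s[!(s %in% traj$rms[[e]])], traj$adds[[e]])
  }
  sort(s)
}

#' @export
print.fock_trajectory <- function(x, ...) {
  cat("<fock_trajectory>", length(x$times), "events, tmax =", x$meta$tmax,
      if (x$meta$absorbed) "(absorbed)" else "", "\n")
  invisible(x)
}

#' Write a trajectory as JSON lines
#'
#' One metadata header line, then one line per event:
#' `{"t":..., "rule":..., "delta":{"add":[...],"remove":[...]}}`.
#'
#' @param traj A `fock_trajectory`.
#' @param fm The compiled model it came from (for instance labels).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(traj, fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(c(traj$meta, list(init = traj$init)),
                              auto_unbox = TRUE, digits = NA), con)
  for (e in seq_along(traj$times)) {
    writeLines(jsonlite::toJSON(list(
      t = traj$times[e], rule = fm$inst_label[traj$inst[e]],
      delta = list(add = traj$adds[[e]], remove = traj$rms[[e]])),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
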