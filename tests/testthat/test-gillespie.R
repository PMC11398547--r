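hd_init <- lapply(c(2, 3, 5, 7), function(i) list(field = "A", idx = i))

test_that("initialization builds the constructor and eligibility flags", {
  fm <- compile_model(builtin_fixture("homodimer", 10, init = hd_init))
  st <- ssa_initialize(fm)
  expect_equal(st$constructor, vapply(c(2, 3, 5, 7), function(i)
    mode_id(fm, "A", i), 1L))
  expect_true(all(st$excited[st$constructor]))
  expect_equal(sum(st$excited), 4L)
  ## vacuum init gives an empty constructor
  st0 <- ssa_initialize(fm, init = integer(0))
  expect_length(st0$constructor, 0L)
  ## cross-reference structure: every instance's conditions reference modes
  ## whose per-mode incidence lists the instance back
  for (inst in sample(fm$n_inst, 10)) {
    ci <- fm$conds_by_inst[[inst]]
    for (m in fm$cond_mode[ci])
      expect_true(inst %in% fm$cond_inst[fm$conds_by_mode[[m]]])
  }
})

test_that("eligible rule counts match the homodimer walkthrough", {
  fm <- compile_model(builtin_fixture("homodimer", 10, init = hd_init))
  st <- ssa_initialize(fm)
  elig <- eligible_rules(fm, st)
  tmpl <- fm$inst_template[elig]
  expect_equal(as.integer(table(factor(tmpl, levels = 1:4))),
               c(6L, 4L, 6L, 0L))   # 6 creations, 4 annihilations, 6 bindings
  expect_length(elig, 16L)
  ## apply the (3,7) binding
  b <- instantiate_rules(fm, "r3")
  id37 <- b$inst[b$i == 3 & b$j == 7]
  st2 <- apply_and_record(fm, st, id37, NULL)
  elig2 <- eligible_rules(fm, st2)
  expect_length(elig2, 10L)   # 6 + 2 + 1 + 1
  expect_equal(as.integer(table(factor(fm$inst_template[elig2], levels = 1:4))),
               c(6L, 2L, 1L, 1L))
  ## naive rescan and incremental index agree
  expect_equal(eligible_rules(fm, st2, "naive"), elig2)
  ## vacuum: only creations
  st0 <- ssa_initialize(fm, init = integer(0))
  expect_true(all(fm$inst_template[eligible_rules(fm, st0)] == 1L))
})

test_that("gillespie draws follow the sampling laws", {
  set.seed(99)
  n <- 1e4
  picks <- integer(n); dts <- numeric(n)
  for (k in seq_len(n)) {
    g <- gillespie_step(c(1, 3))
    picks[k] <- g$pick; dts[k] <- g$dt
  }
  freq2 <- mean(picks == 2L)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(freq2 - 0.75), 3 * se)
  expect_lt(abs(mean(dts) - 1 / 4), 3 * (1 / 4) / sqrt(n))
  ## single instance: always picked
  set.seed(1)
  expect_equal(gillespie_step(2.5)$pick, 1L)
  expect_error(gillespie_step(numeric(0)), "empty eligible")
})

test_that("applying rules updates the constructor like the walkthrough", {
  fm <- compile_model(builtin_fixture("homodimer", 10, init = hd_init))
  st <- ssa_initialize(fm)
  b <- instantiate_rules(fm, "r3")
  id37 <- b$inst[b$i == 3 & b$j == 7]
  st2 <- apply_and_record(fm, st, id37, NULL)
  expect_setequal(st2$constructor,
                  c(st$constructor, mode_id(fm, "a", 3), mode_id(fm, "a", 7),
                    mode_id(fm, "I", 3, 7)))
  ## dissociating returns the original constructor
  u <- instantiate_rules(fm, "r4")
  id37u <- u$inst[u$i == 3 & u$j == 7]
  st3 <- apply_and_record(fm, st2, id37u, NULL)
  expect_equal(st3$constructor, st$constructor)
  ## ineligible application is an internal error
  expect_error(apply_and_record(fm, st, id37u, NULL), "ineligible")
})

test_that("trajectories are reproducible and mode-independent", {
  fm <- compile_model(builtin_fixture("homopolymer", 4))
  t1 <- run_ssa(fm, 2, seed = 5, mode = "indexed")
  t2 <- run_ssa(fm, 2, seed = 5, mode = "indexed")
  t3 <- run_ssa(fm, 2, seed = 5, mode = "naive")
  expect_identical(t1$times, t2$times)
  expect_identical(t1$inst, t2$inst)
  expect_identical(t1$times, t3$times)
  expect_identical(t1$inst, t3$inst)
  expect_equal(t1$meta$seed, 5L)
  ## naive vs indexed on randomized rates too
  for (seed in 1:4) {
    rates <- as.list(setNames(round(runif(4, 0.2, 2), 3),
                              c("r1", "r2", "r3", "r4")))
    fmr <- compile_model(builtin_fixture("homodimer", 5, rates = rates))
    a <- run_ssa(fmr, 1.5, seed = seed, mode = "indexed")
    b <- run_ssa(fmr, 1.5, seed = seed, mode = "naive")
    expect_identical(a$inst, b$inst)
    expect_identical(a$times, b$times)
  }
})

test_that("replay from snapshots and deltas reconstructs every state", {
  fm <- compile_model(builtin_fixture("homopolymer", 5))
  traj <- run_ssa(fm, 4, seed = 3, snapshot_every = 7L)
  expect_gt(length(traj$snapshots), 0L)
  ## replay agrees with a straight fold over deltas
  s <- traj$init
  for (k in seq_along(traj$times)) {
    s <- sort(c(s[!(s %in% traj$rms[[k]])], traj$adds[[k]]))
    expect_identical(replay_state(traj, k), s)
  }
  ## constructor/flag coherence and structural integrity at every event
  for (k in seq_along(traj$times)) {
    st <- replay_state(traj, k)
    expect_silent(microstate_to_complexes(fm, st, check = TRUE))
  }
})

test_that("the absorbed flag marks dead ends and empty models", {
  empty <- parse_model("[params]\nN = 2\n[fields]\nA : particle\n[rules]\n")
  traj <- run_ssa(compile_model(empty), 1, seed = 1)
  expect_true(traj$meta$absorbed)
  expect_length(traj$times, 0L)
})

test_that("monomer terminal counts are binomial across runs", {
  fm <- compile_model(builtin_fixture("monomer", 20))
  counts <- vapply(1:200, function(s) {
    traj <- run_ssa(fm, 6, seed = s)
    length(replay_state(traj, length(traj$times)))
  }, 1L)
  expected <- 200 * dbinom(0:20, 20, 0.5)
  bins <- c(-Inf, 6.5, 8.5, 10.5, 12.5, Inf)
  obs <- table(cut(counts, bins))
  exp_p <- diff(pbinom(c(-Inf, 6.5, 8.5, 10.5, 12.5, Inf), 20, 0.5))
  chi <- sum((as.integer(obs) - 200 * exp_p)^2 / (200 * exp_p))
  p_val <- pchisq(chi, df = 4, lower.tail = FALSE)
  expect_gt(p_val, 0.001)
})

test_that("trajectory JSONL round-trips", {
  fm <- compile_model(builtin_fixture("homodimer", 3))
  traj <- run_ssa(fm, 2, seed = 8)
  path <- tempfile(fileext = ".jsonl")
  write_trajectory_jsonl(traj, fm, path)
  back <- read_trajectory_jsonl(path)
  expect_equal(back$times, traj$times)
  expect_equal(back$adds, traj$adds)
  expect_equal(back$rms, traj$rms)
  expect_equal(back$init, traj$init)
  unlink(path)
})
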