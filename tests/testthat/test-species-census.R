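fm_hp <- compile_model(builtin_fixture("homopolymer", 8))

test_that("microstates decompose into the expected complexes", {
  fm <- compile_model(builtin_fixture("homodimer", 10))
  s <- build_state(fm, c(lapply(c(2, 3, 5, 7), function(i)
    list(field = "A", idx = i)),
    list(list(field = "a", idx = 3L), list(field = "a", idx = 7L),
         list(field = "I", idx = c(3L, 7L)))))
  cc <- microstate_to_complexes(fm, s)
  expect_equal(cc[["chain-1"]], 2L)   # two free monomers
  expect_equal(cc[["chain-2"]], 1L)   # one dimer
  s3 <- hp_state(fm_hp, chains = list(1:3))
  expect_equal(microstate_to_complexes(fm_hp, s3), c("chain-3" = 1L))
  expect_length(microstate_to_complexes(fm_hp, integer(0)), 0L)
})

test_that("structural integrity failures are caught and named", {
  ## bond without its site excitations
  s_bad <- build_state(fm_hp, list(list(field = "A", idx = 1L),
                                   list(field = "A", idx = 2L),
                                   list(field = "J", idx = c(1L, 2L))))
  expect_error(microstate_to_complexes(fm_hp, s_bad), "unoccupied site")
  ## orphan site excitation
  s_orph <- build_state(fm_hp, list(list(field = "A", idx = 1L),
                                    list(field = "a", idx = 1L)))
  expect_error(microstate_to_complexes(fm_hp, s_orph), "orphan")
  ## dangling bond (endpoint particle missing)
  s_dang <- build_state(fm_hp, list(list(field = "A", idx = 1L),
                                    list(field = "a", idx = 1L),
                                    list(field = "b", idx = 2L),
                                    list(field = "J", idx = c(1L, 2L))))
  expect_error(microstate_to_complexes(fm_hp, s_dang), "dangling")
})

test_that("topology classification separates chains, rings, trees, groves", {
  s_c4 <- hp_state(fm_hp, chains = list(1:4))
  expect_equal(names(microstate_to_complexes(fm_hp, s_c4)), "chain-4")
  s_r3 <- hp_state(fm_hp, rings = list(1:3))
  expect_equal(names(microstate_to_complexes(fm_hp, s_r3)), "ring-3")
  s_m <- hp_state(fm_hp, chains = list(1))
  expect_equal(names(microstate_to_complexes(fm_hp, s_m)), "chain-1")
  ## branched fixture: node 1 carries two children (via a and b) and is
  ## itself the child of node 4 -- a degree-3 vertex, hence a tree
  fmb <- compile_model(builtin_fixture("branched_homopolymer", 6))
  tree <- build_state(fmb, list(
    list(field = "A", idx = 1L), list(field = "A", idx = 2L),
    list(field = "A", idx = 3L), list(field = "A", idx = 4L),
    list(field = "a", idx = 1L), list(field = "c", idx = 2L),
    list(field = "I", idx = c(1L, 2L)),
    list(field = "b", idx = 1L), list(field = "c", idx = 3L),
    list(field = "J", idx = c(1L, 3L)),
    list(field = "a", idx = 4L), list(field = "c", idx = 1L),
    list(field = "I", idx = c(4L, 1L))))
  cc <- microstate_to_complexes(fmb, tree)
  expect_length(cc, 1L)
  expect_match(names(cc), "^tree-4")
  ## a path-shaped branched complex classifies structurally as a chain but
  ## keeps its port-colored canonical label
  path2 <- build_state(fmb, list(
    list(field = "A", idx = 1L), list(field = "A", idx = 2L),
    list(field = "a", idx = 1L), list(field = "c", idx = 2L),
    list(field = "I", idx = c(1L, 2L))))
  expect_match(names(microstate_to_complexes(fmb, path2)), "^chain-2\\[")
  ## grove: a 2-ring with one pendant tree
  grove <- build_state(fmb, list(
    list(field = "A", idx = 1L), list(field = "A", idx = 2L),
    list(field = "A", idx = 3L),
    list(field = "a", idx = 1L), list(field = "c", idx = 2L),
    list(field = "I", idx = c(1L, 2L)),
    list(field = "a", idx = 2L), list(field = "c", idx = 1L),
    list(field = "I", idx = c(2L, 1L)),
    list(field = "b", idx = 1L), list(field = "c", idx = 3L),
    list(field = "J", idx = c(1L, 3L))))
  ccg <- microstate_to_complexes(fmb, grove)
  expect_match(names(ccg), "^grove-3")
})

test_that("census labels are invariant under particle relabeling", {
  set.seed(21)
  for (rep in 1:10) {
    sizes <- sample(1:2, 3, replace = TRUE)
    idx <- split(sample(8, sum(sizes)), rep(seq_along(sizes), sizes))
    chains <- idx[lengths(idx) >= 1]
    s <- hp_state(fm_hp, chains = chains)
    perm <- sample(8)
    chains_p <- lapply(chains, function(ch) perm[ch])
    sp <- hp_state(fm_hp, chains = chains_p)
    expect_equal(microstate_to_complexes(fm_hp, s),
                 microstate_to_complexes(fm_hp, sp))
  }
})

test_that("isotropic even chains form two species and rings collapse mirrors", {
  fmi <- compile_model(builtin_fixture("isotropic_homopolymer", 8))
  iso_chain <- function(idx, start_bond) {
    ex <- lapply(idx, function(i) list(field = "A", idx = i))
    bonds <- rep(c(start_bond, setdiff(c("I", "J"), start_bond)),
                 length.out = length(idx) - 1)
    for (k in seq_len(length(idx) - 1)) {
      f <- bonds[k]
      site <- if (f == "I") "a" else "b"
      ex <- c(ex, list(list(field = site, idx = idx[k]),
                       list(field = site, idx = idx[k + 1]),
                       list(field = f, idx = c(idx[k], idx[k + 1]))))
    }
    build_state(fmi, ex)
  }
  ## 4-chain starting with I vs starting with J: distinct species
  lab_I <- names(microstate_to_complexes(fmi, iso_chain(1:4, "I")))
  lab_J <- names(microstate_to_complexes(fmi, iso_chain(1:4, "J")))
  expect_false(lab_I == lab_J)
  ## 3-chain: exchanging I and J is a flip, same species
  lab3_I <- names(microstate_to_complexes(fmi, iso_chain(1:3, "I")))
  lab3_J <- names(microstate_to_complexes(fmi, iso_chain(5:7, "J")))
  expect_equal(lab3_I, lab3_J)
  ## 4-ring: rotations and mirror give one label
  iso_ring4 <- function(idx) {
    ex <- lapply(idx, function(i) list(field = "A", idx = i))
    bonds <- c("I", "J", "I", "J")
    nxt <- c(idx[-1], idx[1])
    for (k in 1:4) {
      f <- bonds[k]; site <- if (f == "I") "a" else "b"
      ex <- c(ex, list(list(field = site, idx = idx[k]),
                       list(field = site, idx = nxt[k]),
                       list(field = f, idx = c(idx[k], nxt[k]))))
    }
    build_state(fmi, ex)
  }
  l1 <- names(microstate_to_complexes(fmi, iso_ring4(1:4)))
  l2 <- names(microstate_to_complexes(fmi, iso_ring4(c(3, 4, 1, 2))))
  l3 <- names(microstate_to_complexes(fmi, iso_ring4(c(4, 3, 2, 1))))
  expect_equal(l1, l2)
  expect_equal(l1, l3)
})

test_that("trajectory census samples piecewise-constant states", {
  fm <- compile_model(builtin_fixture("homodimer", 4))
  traj <- run_ssa(fm, 3, seed = 17)
  times <- seq(0, 3, length.out = 13)
  tab <- trajectory_census(traj, times, fm)
  expect_equal(sum(tab[1, ]), 0L)   # vacuum at t = 0
  ## particle conservation: sum over species of size x count equals the
  ## number of excited particle modes at each sampled time
  sizes <- as.integer(sub("^[a-z]+-", "", colnames(tab)))
  md <- fm$modes
  for (k in seq_along(times)) {
    ev <- sum(traj$times <= times[k])
    s <- replay_state(traj, ev)
    expect_equal(sum(sizes * tab[k, ]), sum(md$kind[s] == "particle"))
  }
})

test_that("homopolymer censuses tie particle and link counts together", {
  fmx <- compile_model(builtin_fixture("homopolymer", 10))
  set.seed(5)
  for (rep in 1:8) {
    traj <- run_ssa(fmx, 2, seed = rep)
    s <- replay_state(traj, length(traj$times))
    cc <- microstate_to_complexes(fmx, s)
    if (length(cc) == 0L) next
    kind <- sub("-.*$", "", names(cc))
    x <- as.integer(sub("^[a-z]+-", "", names(cc)))
    md <- fmx$modes
    expect_equal(sum(x * cc), sum(md$kind[s] == "particle"))
    nlink <- sum(ifelse(kind == "chain", x - 1L, x) * cc)
    expect_equal(nlink, sum(md$kind[s] == "bond"))
  }
})

test_that("ensemble statistics behave at the degenerate ends", {
  fm <- compile_model(builtin_fixture("monomer", 5))
  times <- seq(0, 1, length.out = 5)
  one <- trajectory_census(run_ssa(fm, 1, seed = 2), times, fm)
  st <- ensemble_stats(list(one, one, one))
  expect_true(all(st$sd == 0))
  expect_equal(st$mean, one + 0, ignore_attr = TRUE)
  other <- trajectory_census(run_ssa(fm, 1, seed = 3), times + 0.5, fm)
  expect_error(ensemble_stats(list(one, other)), "mismatched")
  expect_error(ensemble_stats(list(one)), "length")
})
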