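test_that("the p=1, q=2 expansion has the seven-term structure", {
  prod <- labeled_product("homodimer", 1, 2)
  terms <- enumerate_contractions(prod)
  k <- vapply(terms, function(t) t$residual$n_contractions, 1L)
  expect_length(terms, 7L)
  expect_equal(sum(k == 0L), 1L)    # uncontracted
  expect_equal(sum(k == 1L), 4L)    # single contractions
  expect_equal(sum(k == 2L), 2L)    # the two surviving double contractions
  ## only the fully contracted terms survive on the vacuum
  survivors <- Filter(function(t) t$residual$open_presence_slots == 0L, terms)
  expect_length(survivors, 2L)
  ## empty product: a single empty scheme
  expect_length(enumerate_contractions(labeled_product("homodimer", 0, 0)), 1L)
})

test_that("scheme counts by topology match the worked coefficients", {
  expect_equal(count_schemes_by_topology(2, 5, "homodimer", "same_F2_double"),
               40L)   # (5*4) x (4*1) / 2!
  expect_equal(count_schemes_by_topology(2, 5, "homodimer", "fully_contracted"),
               120L)  # q!/(q-2p)! at q = 5, p = 2
  expect_equal(count_schemes_by_topology(1, 2, "homodimer", "fully_contracted"),
               2L)
  ## q < 2p: no complete contraction exists
  expect_equal(count_schemes_by_topology(1, 1, "homodimer", "fully_contracted"),
               0L)
  expect_error(count_schemes_by_topology(5, 4, "homodimer", "fully_contracted"),
               "guard")
})

test_that("the factory term closed form holds for p <= 3, q <= 8", {
  for (p in 0:3) for (q in 0:8) {
    res <- factory_apply_vacuum(p, q, "homodimer")
    if (q >= 2 * p) {
      expect_equal(res$coefficient, 1, label = sprintf("p=%d q=%d", p, q))
      expect_equal(res$monomers, q - 2 * p)
      expect_equal(res$dimers, p)
    } else {
      expect_equal(res$coefficient, 0, label = sprintf("p=%d q=%d", p, q))
    }
  }
})

test_that("combinatorial and matrix routes agree for small factory terms", {
  fm <- compile_model(builtin_fixture("homodimer", 4))
  F1 <- template_matrix(fm, "r1")
  F2 <- template_matrix(fm, "r3")
  v0 <- vacuum_vector(fm)
  Mh <- template_matrix(fm, "r1")
  Dh <- NULL
  for (i in 1:3) for (j in (i + 1):4) {
    Dij <- composite_creation_matrix(fm, c(
      mode_id(fm, "A", i), mode_id(fm, "A", j),
      mode_id(fm, "a", i), mode_id(fm, "a", j), mode_id(fm, "I", i, j)))
    Dh <- if (is.null(Dh)) Dij else Dh + Dij
  }
  macro_md <- function(m, d) {
    v <- v0
    if (m > 0) for (k in 1:m) v <- as.numeric(Mh %*% v)
    if (d > 0) for (k in 1:d) v <- as.numeric(Dh %*% v)
    v / (factorial(m) * factorial(d))
  }
  powv <- function(M, k, v) { for (i in seq_len(k)) v <- as.numeric(M %*% v); v }
  for (p in 0:2) for (q in 0:4) {
    lhs <- powv(F2, p, powv(F1, q, v0)) / (factorial(p) * factorial(q))
    res <- factory_apply_vacuum(p, q, "homodimer")
    rhs <- if (res$coefficient == 0) 0 * v0 else
      res$coefficient * macro_md(res$monomers, res$dimers)
    expect_equal(max(abs(lhs - rhs)), 0, label = sprintf("p=%d q=%d", p, q))
  }
})

test_that("homopolymer contractions build labeled chains and rings with unit weight", {
  for (p in 0:3) for (q in 0:4) {
    res <- factory_apply_vacuum(p, q, "homopolymer")
    if (nrow(res) > 0)
      expect_true(all(abs(res$coefficient - 1) < 1e-12),
                  label = sprintf("p=%d q=%d", p, q))
  }
  ## a-side and b-side contractions on one creation operator may coexist
  ## (non-central products): a 2-ring needs both ports of both creations
  r22 <- factory_apply_vacuum(2, 2, "homopolymer")
  expect_true("c[]r[2]" %in% r22$species)
  ## but self-contraction (1-ring) is excluded unless allowed
  r11 <- factory_apply_vacuum(1, 1, "homopolymer")
  expect_false("c[]r[1]" %in% r11$species)
  r11s <- factory_apply_vacuum(1, 1, "homopolymer", allow_self = TRUE)
  expect_true("c[]r[1]" %in% r11s$species)
})

test_that("factory and gallery states coincide exactly on explicit spaces", {
  hd <- factory_gallery_check("homodimer", 4)
  expect_true(hd$equal)
  expect_equal(hd$max_dev, 0)
  ## the homodimer gallery is the sum over all (m, d) with m + 2d <= 4
  expect_equal(sum(hd$gallery), sum(vapply(0:2, function(d)
    sum(vapply(0:(4 - 2 * d), function(m) choose(4, m) *
      choose(4 - m, 2 * d) * (factorial(2 * d) / (2^d * factorial(d))), 1)),
    1)))
  hp <- factory_gallery_check("homopolymer", 3)
  expect_true(hp$equal)
  expect_equal(hp$max_dev, 0)
  ## empty factory: the vacuum
  fm <- compile_model(builtin_fixture("homodimer", 3))
  Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = rep(fock_dim(fm), 2))
  v0 <- vacuum_vector(fm)
  ## exponential of an empty factory operator leaves |0> untouched
  expect_equal(polyfock:::expm_apply(Z, v0), v0)
})
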