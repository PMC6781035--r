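test_that("Haldane map function and composition behave correctly", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(1e6), 0.5, tolerance = 1e-12)
  expect_equal(haldane_r(50), (1 - exp(-1)) / 2)
  expect_error(haldane_r(-1), "non-negative")

  expect_equal(combine_r(0, 0.3), 0.3)
  expect_equal(combine_r(0.5, 0.2), 0.5)
  expect_equal(combine_r(0.1, 0.2), 0.26)
  expect_error(combine_r(0.6, 0.1), "0.5")
  # composing Haldane fractions of adjacent intervals gives the Haldane
  # fraction of the union
  expect_equal(combine_r(haldane_r(12), haldane_r(30)), haldane_r(42))
})

test_that("recomb_model validates inputs and fills pairwise rates", {
  m <- recomb_model(map = c(0, 10, 35))
  expect_equal(m$L, 3)
  expect_true(m$sex_equal)
  expect_equal(m$rf[1, 3], haldane_r(35))
  expect_equal(m$rf[1, 3], combine_r(m$rf[1, 2], m$rf[2, 3]))

  # adjacent-fraction input fills non-adjacent entries by composition
  m2 <- recomb_model(r = c(0.1, 0.2))
  expect_equal(m2$rf[1, 3], 0.26)

  expect_error(recomb_model(map = c(5, 5, 10)), "strictly increasing")
  expect_error(recomb_model(r = 0.7), "0.5")
  expect_error(recomb_model(), "exactly one")
  expect_error(recomb_model(map = c(0, 10), r = 0.1), "exactly one")
  bad <- matrix(c(0, 0.1, 0.2, 0), 2, 2)
  expect_error(recomb_model(r = bad), "symmetric")
  # inconsistent full matrix is accepted with a warning
  full <- matrix(0, 3, 3)
  full[1, 2] <- full[2, 1] <- 0.1
  full[2, 3] <- full[3, 2] <- 0.1
  full[1, 3] <- full[3, 1] <- 0.45
  expect_warning(recomb_model(r = full), "no-interference")

  ms <- recomb_model(rf = 0.1, rm = 0.3)
  expect_false(ms$sex_equal)
  expect_true(recomb_model(rf = 0.2, rm = 0.2)$sex_equal)
})

test_that("allowed transitions follow the parentage rule", {
  expect_true(allowed_transition(c(0, 0), c(0, 2)))
  expect_false(allowed_transition(c(0, 0), c(1, 0)))
  expect_true(allowed_transition(c(2, 1), c(1, 2)))
  expect_false(allowed_transition(c(2, 1), c(0, 2)))
  expect_error(allowed_transition(c(0, 0), c(0, 0, 0)), "length")
})

test_that("per-meiosis factors match direct two-locus calculations", {
  m <- recomb_model(r = 0.25)
  expect_equal(chromosome_factor(0, c(0, 0), c(0, 0), m), (1 - 0.25) / 2)
  expect_equal(chromosome_factor(2, c(0, 0), c(0, 2), m), 0.5)
  # empty locus list: factor 1
  expect_equal(chromosome_factor(3, c(0, 0), c(0, 2), m), 1)
  expect_error(chromosome_factor(0, c(0, 0), c(1, 0), m), "not allowed")
})

test_that("transition probabilities match hand-computed two-locus entries", {
  r <- 0.25
  m <- recomb_model(r = r)
  expect_equal(transition_probability(c(0, 0), c(0, 0), m), (1 - r) / 2)
  expect_equal(transition_probability(c(0, 0), c(2, 0), m), 1 / 4)
  expect_equal(transition_probability(c(0, 0), c(0, 2), m), 1 / 4)
  expect_equal(transition_probability(c(0, 0), c(2, 2), m), (1 - r) / 2)
  expect_equal(transition_probability(c(0, 0), c(1, 0), m), 0)
})

test_that("transitions into any fixed target sum to one over all origins", {
  # this is the stochasticity direction that makes the homogeneous system
  # rank-deficient by exactly one
  set.seed(21)
  for (L in 2:4) {
    pos <- sort(runif(L, 0, 60))
    m <- recomb_model(map = pos)
    M <- transition_matrix(m)
    expect_equal(unname(colSums(M)), rep(1, 4^L), tolerance = 1e-12)
  }
  # sex-dependent rates as well
  ms <- recomb_model(rf = 0.12, rm = 0.31)
  expect_equal(unname(colSums(transition_matrix(ms))), rep(1, 16),
               tolerance = 1e-12)
})

test_that("with all rates 1/2 the matrix is uniform on allowed transitions", {
  for (L in 2:3) {
    m <- recomb_model(r = matrix(0.5, L, L) - diag(0.5, L))
    M <- transition_matrix(m)
    expect_true(all(M %in% c(0, 2^-L)))
    # at r = 1/2 the matrix is doubly stochastic
    expect_equal(unname(rowSums(M)), rep(1, 4^L), tolerance = 1e-12)
    expect_equal(unname(colSums(M)), rep(1, 4^L), tolerance = 1e-12)
  }
})

test_that("transition probabilities are equivariant under the symmetry group", {
  # relabeling the F1 chromosomes by g relabels the next generation's
  # chromosomes by the induced permutation: within-sex swaps leave the
  # offspring labels untouched, while the sex swap exchanges the roles of
  # the two meioses, i.e. swaps 0 with 1 and 2 with 3
  induced <- function(g) if (g[1] >= 2) c(1L, 0L, 3L, 2L) else 0:3
  set.seed(22)
  m <- recomb_model(map = c(0, 15, 40))
  for (i in 1:20) {
    u <- sample(0:3, 3, replace = TRUE)
    v <- 2L * sample(0:1, 3, replace = TRUE) + (u >= 2L)
    p <- transition_probability(u, v, m)
    for (g in symmetry_group("equal")) {
      gp <- induced(g)
      expect_equal(transition_probability(g[u + 1], gp[v + 1], m), p,
                   tolerance = 1e-13)
    }
  }
  # sex-dependent models keep only the within-sex swaps (induced identity)
  ms <- recomb_model(rf = 0.1, rm = 0.3)
  for (g in symmetry_group("sexdep"))
    expect_equal(
      transition_probability(g[c(0, 2) + 1], c(2, 1), ms),
      transition_probability(c(0, 2), c(2, 1), ms), tolerance = 1e-13)
})
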