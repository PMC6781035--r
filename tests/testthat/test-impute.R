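test_that("masking hits the exact count and nothing else", {
  set.seed(61)
  truth <- matrix(sample(c("A", "a"), 100 * 100, replace = TRUE), 100, 100)
  mk <- mask_genotypes(truth, 0.3)
  expect_equal(sum(mk$mask), 3000)
  expect_true(all(is.na(mk$genotypes[mk$mask])))
  expect_identical(mk$genotypes[!mk$mask], truth[!mk$mask])
  mk0 <- mask_genotypes(truth, 0)
  expect_identical(mk0$genotypes, truth)
  expect_error(mask_genotypes(truth, 1), "fraction")
})

test_that("missing blocks are found with correct flanks", {
  b <- find_missing_blocks(c("A", NA, NA, "a"))
  expect_equal(b$start, 2)
  expect_equal(b$end, 3)
  expect_equal(b$left, "A")
  expect_equal(b$right, "a")
  # leading block has only a right flank
  b2 <- find_missing_blocks(c(NA, "A", "a", NA, NA))
  expect_equal(nrow(b2), 2)
  expect_true(is.na(b2$left[1]) && b2$right[1] == "A")
  expect_true(b2$left[2] == "a" && is.na(b2$right[2]))
  expect_equal(nrow(find_missing_blocks(c("A", "a", "A"))), 0)
})

test_that("trivial block cases copy flanks", {
  m <- recomb_model(map = c(0, 5, 10, 15, 20))
  blk <- function(s, e, l, r) list(start = s, end = e, left = l, right = r)
  expect_equal(impute_block(blk(2, 4, "A", "A"), m), c("A", "A", "A"))
  expect_equal(impute_block(blk(1, 2, NA, "a"), m), c("a", "a"))
  expect_equal(impute_block(blk(4, 5, "A", NA), m), c("A", "A"))
})

test_that("a recombinant block places the crossover in the larger interval", {
  # single missing marker between discordant flanks: the exact 3-locus
  # argmax puts the switch in the wider gap.  Independent oracle: the two
  # candidate probabilities from the pairwise-constraint construction.
  check <- function(pos) {
    m <- recomb_model(map = pos)
    R12 <- hw_R(m$rf[1, 2]); R23 <- hw_R(m$rf[2, 3]); R13 <- hw_R(m$rf[1, 3])
    A <- rbind(c(1, 1, 1, 1), c(0, 0, 1, 1), c(0, 1, 1, 0), c(0, 1, 0, 1))
    p <- solve(A, c(1, R12, R23, R13))
    oracle <- if (p[2] > p[4]) "A" else "a"   # P(AAa) vs P(Aaa), halved alike
    got <- impute_block(list(start = 2, end = 2, left = "A", right = "a"), m)
    expect_equal(got, oracle)
    got
  }
  expect_equal(check(c(0, 5, 30)), "A")   # marker close to the left flank
  expect_equal(check(c(0, 25, 30)), "a")  # marker close to the right flank
})

test_that("exact ties between candidates resolve toward the left flank", {
  m <- recomb_model(map = c(0, 10, 20))
  got <- impute_block(list(start = 2, end = 2, left = "A", right = "a"), m)
  expect_equal(got, "A")
  # and symmetrically when the left flank carries the other allele
  got2 <- impute_block(list(start = 2, end = 2, left = "a", right = "A"), m)
  expect_equal(got2, "a")
})

test_that("overlong recombinant blocks split at the genetic midpoint", {
  m <- recomb_model(map = c(0, 1:9, 20))
  expect_warning(
    got <- impute_block(list(start = 2, end = 10, left = "A", right = "a"), m,
                        max_block_loci = 6),
    "midpoint")
  # midpoint of [0, 20] is 10: markers at 1..9 all take the left call
  expect_equal(got, rep("A", 9))
})

test_that("matrix imputation is deterministic, complete and non-invasive", {
  set.seed(62)
  map <- random_map(40, 60)
  m <- recomb_model(map = map)
  truth <- simulate_population(30, m)
  mk <- mask_genotypes(truth, 0.2)
  imp1 <- impute_matrix(mk$genotypes, m)
  imp2 <- impute_matrix(mk$genotypes, m)
  expect_identical(imp1, imp2)
  expect_false(anyNA(imp1))
  expect_identical(imp1[!mk$mask], truth[!mk$mask])
  # no missing data: identity
  expect_identical(impute_matrix(truth, m), truth)
})

test_that("error rates score masked cells only", {
  truth <- matrix(c("A", "a", "A", "a"), 2, 2)
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(imputation_error(truth, truth, mask), 0)
  flipped <- matrix(c("a", "a", "A", "A"), 2, 2)
  expect_equal(imputation_error(flipped, truth, mask), 1)
  half <- matrix(c("a", "a", "A", "a"), 2, 2)
  expect_equal(imputation_error(half, truth, mask), 0.5)
  expect_equal(imputation_error(truth, truth, mask & FALSE), 0)
})

test_that("exact-probability imputation beats naive baselines", {
  set.seed(63)
  map <- random_map(60, 90)
  m <- recomb_model(map = map)
  truth <- simulate_population(40, m)
  mk <- mask_genotypes(truth, 0.3)
  imp <- suppressWarnings(impute_matrix(mk$genotypes, m, max_block_loci = 6))
  err <- imputation_error(imp, truth, mk$mask)
  expect_lt(err, 0.5)  # far better than a coin flip
  # nearest-flank-only fill (in genetic distance) on the same masked data
  pos <- map$position_cM
  naive <- mk$genotypes
  for (i in seq_len(nrow(naive))) {
    blocks <- find_missing_blocks(naive[i, ])
    for (b in seq_len(nrow(blocks))) {
      s <- blocks$start[b]; e <- blocks$end[b]
      l <- blocks$left[b]; r <- blocks$right[b]
      fill <- if (is.na(l)) rep(r, e - s + 1)
              else if (is.na(r)) rep(l, e - s + 1)
              else ifelse(abs(pos[s:e] - pos[s - 1]) <=
                          abs(pos[e + 1] - pos[s:e]), l, r)
      naive[i, s:e] <- fill
    }
  }
  err_naive <- imputation_error(naive, truth, mk$mask)
  expect_lte(err, err_naive)
})
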