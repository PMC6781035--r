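test_that("compatible index lists follow the allele-class rule", {
  expect_equal(sort(compatible_indices("A")[, 1]), c(0L, 2L))
  m <- compatible_indices("Aa")
  expect_equal(nrow(m), 4)
  key <- apply(m, 1, paste, collapse = ",")
  expect_setequal(key, c("0,1", "0,3", "2,1", "2,3"))
  expect_equal(nrow(compatible_indices("AaAa")), 16)
  expect_error(compatible_indices("AB"), "alleles")
})

test_that("two-locus genotype probabilities match the closed forms", {
  d <- genotype_distribution(recomb_model(r = 1 / 4))
  expect_equal(d$probability[match(c("AA", "aa", "Aa", "aA"), d$genotype)],
               c(0.3, 0.3, 0.2, 0.2), tolerance = 1e-14)
  sol <- solve_Q(recomb_model(r = 1 / 4))
  expect_equal(genotype_probability(sol, "Aa"), 0.2, tolerance = 1e-14)
  expect_equal(as.numeric(pairwise_R(sol, 1, 2)), hw_R(1 / 4),
               tolerance = 1e-14)
})

test_that("the distribution is normalized with equal complementary pairs", {
  set.seed(41)
  for (i in 1:4) {
    L <- sample(2:5, 1)
    d <- genotype_distribution(recomb_model(map = sort(runif(L, 0, 120))))
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
    comp <- chartr("Aa", "aA", d$genotype)
    expect_equal(d$probability, d$probability[match(comp, d$genotype)],
                 tolerance = 1e-12)
  }
})

test_that("degenerate rates give the expected distributions", {
  # unlinked loci: every genotype equally likely
  L <- 3
  d <- genotype_distribution(recomb_model(r = matrix(0.5, L, L) - diag(0.5, L)))
  expect_equal(d$probability, rep(2^-L, 2^L), tolerance = 1e-12)
  # no recombination: the two parental genotypes fix with probability 1/2
  d0 <- genotype_distribution(recomb_model(r = c(0, 0)))
  expect_equal(d0$probability[d0$genotype == "AAA"], 0.5, tolerance = 1e-12)
  expect_equal(d0$probability[d0$genotype == "aaa"], 0.5, tolerance = 1e-12)
  expect_equal(sum(d0$probability), 1, tolerance = 1e-12)
  # single locus
  d1 <- genotype_distribution(recomb_model(r = matrix(0, 1, 1)))
  expect_equal(d1$probability, c(0.5, 0.5))
})

test_that("the distribution is invariant under reversing locus order", {
  m <- recomb_model(map = c(0, 7, 30, 41))
  mr <- recomb_model(map = rev(41 - c(0, 7, 30, 41)))
  d <- genotype_distribution(m)
  dr <- genotype_distribution(mr)
  rev_gt <- vapply(strsplit(d$genotype, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  expect_equal(d$probability, dr$probability[match(rev_gt, dr$genotype)],
               tolerance = 1e-12)
})

test_that("pairwise marginals of multilocus solutions equal the two-locus form", {
  set.seed(42)
  for (L in c(3, 4)) {
    m <- recomb_model(map = sort(runif(L, 0, 100)))
    sol <- solve_Q(m)
    for (l in 1:(L - 1)) for (l2 in (l + 1):L)
      expect_equal(pairwise_R(sol, l, l2), hw_R(m$rf[l, l2]),
                   tolerance = 1e-10)
  }
  # marginalization and a direct two-locus solve agree
  m4 <- recomb_model(map = c(0, 18, 33, 70))
  sol4 <- solve_Q(m4)
  sol2 <- solve_Q(recomb_model(r = m4$rf[2, 4]))
  expect_equal(as.numeric(pairwise_R(sol4, 2, 4)),
               as.numeric(pairwise_R(sol2, 1, 2)), tolerance = 1e-10)
})

test_that("three-locus probabilities are recovered from pairwise constraints", {
  # the four complementary-pair probabilities solve a linear system driven
  # only by the three pairwise RIL recombination fractions
  m <- recomb_model(map = c(0, 25, 60))
  R12 <- hw_R(m$rf[1, 2]); R23 <- hw_R(m$rf[2, 3]); R13 <- hw_R(m$rf[1, 3])
  A <- rbind(c(1, 1, 1, 1),   # pairs: {ABC,abc},{ABc,abC},{AbC,aBc},{Abc,aBC}
             c(0, 0, 1, 1),   # discordant at loci 1,2
             c(0, 1, 1, 0),   # discordant at loci 2,3
             c(0, 1, 0, 1))   # discordant at loci 1,3
  p <- solve(A, c(1, R12, R23, R13))
  d <- genotype_distribution(m)
  pr <- function(g) d$probability[d$genotype == g]
  expect_equal(pr("AAA") + pr("aaa"), p[1], tolerance = 1e-12)
  expect_equal(pr("AAa") + pr("aaA"), p[2], tolerance = 1e-12)
  expect_equal(pr("AaA") + pr("aAa"), p[3], tolerance = 1e-12)
  expect_equal(pr("Aaa") + pr("aAA"), p[4], tolerance = 1e-12)
})

test_that("closed-form RIL recombination fractions are correct", {
  expect_equal(hw_R(0), 0)
  expect_equal(hw_R(0.5), 0.5)
  expect_equal(hw_R(0.25), 0.4)
  expect_error(hw_R(0.6), "0.5")
  # sex-dependent form depends only on the mean rate and reduces to the
  # equal-rate formula
  expect_equal(hw_R_sexdep(0.1, 0.3), 4 / 11)
  expect_equal(hw_R_sexdep(0.1, 0.3), hw_R(0.2))
  expect_equal(hw_R_sexdep(0.2, 0.2), hw_R(0.2))
  # and matches the sex-dependent solver marginal
  sol <- solve_Q(recomb_model(rf = 0.1, rm = 0.3))
  expect_equal(as.numeric(pairwise_R(sol, 1, 2)), hw_R_sexdep(0.1, 0.3),
               tolerance = 1e-13)
})
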