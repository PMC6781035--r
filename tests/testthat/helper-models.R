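# Shared fixtures: hand-derived reference systems and closed forms for two loci,
# and small utilities used across tests.

# 3x3 equal-sex two-locus system: normalization with orbit weights, then the
# sign-flipped self-consistency rows for Q(0,0) and Q(0,1)
two_locus_system <- function(r) {
  rbind(c(4, 4, 8),
        c(r, 0, -1 / 2),
        c(r, -1, 1 / 2))
}

# 6x6 sex-dependent two-locus system in the unknown order
# Q(0,0), Q(0,1), Q(0,2), Q(2,0), Q(2,2), Q(2,3); self-consistency rows for
# (0,0), (0,1), (0,2), (2,2), (2,3) — the row for (2,0) is the omitted one
sexdep_two_locus_system <- function(rf, rm) {
  rbf <- 1 - rf
  rbm <- 1 - rm
  rbind(
    c(2, 2, 4, 4, 2, 2),
    c(rbf / 2 - 1, 0, 1 / 4, 1 / 4, rbf / 2, 0),
    c(rf / 2, -1, 1 / 4, 1 / 4, rf / 2, 0),
    c(0, 1 / 4, -3 / 4, 1 / 4, 0, 1 / 4),
    c(rbm / 2, 0, 1 / 4, 1 / 4, rbm / 2 - 1, 0),
    c(rm / 2, 0, 1 / 4, 1 / 4, rm / 2, -1))
}

# closed forms for the equal-sex two-locus solution, derived by resolving the
# 3x3 system by hand: r Q00 = Q02 / 2 and r Q00 - Q01 + Q02 / 2 = 0 give
# Q01 = Q02 = 2 r Q00, and the normalization then fixes Q00
two_locus_Q <- function(r) {
  q00 <- 1 / (4 + 24 * r)
  c(q00, 2 * r * q00, 2 * r * q00)
}

# brute-force orbit partition of all 4^L lists, independent of the package's
# canonicalization: repeatedly apply group elements until closure
brute_orbits <- function(L, mode) {
  perms <- symmetry_group(mode)
  codes <- 0:(4^L - 1)
  digits <- function(code) as.integer((code %/% 4^(L - seq_len(L))) %% 4)
  code_of <- function(u) sum(u * 4^(L - seq_along(u)))
  seen <- rep(FALSE, 4^L)
  orbits <- list()
  for (cd in codes) {
    if (seen[cd + 1]) next
    u <- digits(cd)
    orb <- sort(unique(vapply(perms, function(p) code_of(p[u + 1]), numeric(1))))
    seen[orb + 1] <- TRUE
    orbits[[length(orbits) + 1]] <- orb
  }
  orbits
}

# genotype frequency table of a simulated population, in the order of a
# genotype_distribution data frame
empirical_freqs <- function(geno, dist) {
  lab <- apply(geno, 1, paste, collapse = "")
  as.numeric(table(factor(lab, levels = dist$genotype))) / nrow(geno)
}
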