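# From IBD probabilities to the 2^L multilocus genotype probabilities and
# pairwise RIL recombination fractions.

# parse a genotype given as "Aa...", c("A","a",...) or 0/1 bits into bits
# (0 = parent-1 allele A, 1 = parent-2 allele a)
.parse_genotype <- function(G) {
  if (is.character(G) && length(G) == 1L && nchar(G) > 1L)
    G <- strsplit(G, "")[[1]]
  if (is.character(G)) {
    if (!all(G %in% c("A", "a"))) stop("genotype alleles must be \"A\" or \"a\"")
    return(as.integer(G == "a"))
  }
  g <- as.integer(G)
  if (anyNA(g) || any(g < 0L | g > 1L)) stop("genotype bits must be 0 or 1")
  g
}

.genotype_string <- function(bits) paste(c("A", "a")[bits + 1L], collapse = "")

#' IBD index lists compatible with a genotype
#'
#' A fixed line carries the parent-1 allele A at a locus exactly when its IBD
#' label there is 0 or 2, and the parent-2 allele a when the label is 1 or 3.
#' A genotype of L alleles is therefore compatible with exactly 2^L index
#' lists.
#'
#' @param G genotype: a string like `"Aa"`, a character vector of
#'   `"A"`/`"a"`, or 0/1 bits.
#' @return A 2^L x L integer matrix, one compatible index list per row.
#' @export
#' @examples
#' compatible_indices("Aa")
compatible_indices <- function(G) {
  g <- .parse_genotype(G)
  L <- length(g)
  out <- matrix(0L, 2^L, L)
  for (ci in 0:(2^L - 1)) {
    cbits <- (ci %/% 2^(seq_len(L) - 1L)) %% 2L
    out[ci + 1L, ] <- as.integer(2L * cbits + g)
  }
  out
}

# lexicographic codes of all lists compatible with genotype bits g
.compatible_codes <- function(g) {
  L <- length(g)
  pow <- 4^(L - seq_len(L))
  codes <- numeric(2^L)
  for (ci in 0:(2^L - 1)) {
    cbits <- (ci %/% 2^(seq_len(L) - 1L)) %% 2L
    codes[ci + 1L] <- sum((2L * cbits + g) * pow)
  }
  codes
}

#' Probability of one multilocus RIL genotype
#'
#' Sums Q over the 2^L IBD index lists compatible with the genotype
#' (canonical lookup per list).
#'
#' @param sol an `"ibd_solution"` from [solve_Q()].
#' @param G genotype (see [compatible_indices()]) of length `sol$L`.
#' @return A probability.
#' @export
genotype_probability <- function(sol, G) {
  g <- .parse_genotype(G)
  if (length(g) != sol$L) stop("genotype must have ", sol$L, " alleles")
  sum(sol$Q[sol$index[.compatible_codes(g) + 1]])
}

#' Probabilities of all 2^L RIL genotypes
#'
#' The full multilocus genotype distribution of the fixed line.  Complementary
#' genotypes (A and a exchanged at every locus) always have equal
#' probability, and the table sums to one.
#'
#' @param x a [recomb_model()] (solved internally) or an `"ibd_solution"`.
#' @param ... passed to [solve_Q()] when `x` is a model.
#' @return A data frame with columns `genotype` and `probability` (and exact
#'   `num`/`den` columns when the solution is exact rational), one row per
#'   genotype in binary order (A before a, leftmost locus most significant).
#' @export
#' @examples
#' genotype_distribution(recomb_model(r = 1/4))  # 0.3, 0.2, 0.2, 0.3
genotype_distribution <- function(x, ...) {
  sol <- if (inherits(x, "recomb_model")) solve_Q(x, ...) else x
  if (!inherits(sol, "ibd_solution")) stop("x must be a recomb_model or ibd_solution")
  L <- sol$L
  gt <- character(2^L)
  pr <- numeric(2^L)
  exact <- !is.null(sol$Q_num)
  if (exact) {
    pn <- numeric(2^L)
    pd <- rep(1, 2^L)
  }
  for (gi in 0:(2^L - 1)) {
    # leftmost locus = most significant bit
    g <- (gi %/% 2^(L - seq_len(L))) %% 2L
    gt[gi + 1L] <- .genotype_string(g)
    idx <- sol$index[.compatible_codes(g) + 1]
    pr[gi + 1L] <- sum(sol$Q[idx])
    if (exact) {
      acc <- list(n = 0, d = 1)
      for (k in idx)
        acc <- .rat_add(acc, list(n = sol$Q_num[k], d = sol$Q_den[k]))
      pn[gi + 1L] <- acc$n
      pd[gi + 1L] <- acc$d
    }
  }
  out <- data.frame(genotype = gt, probability = pr, stringsAsFactors = FALSE)
  if (exact) {
    out$num <- pn
    out$den <- pd
  }
  attr(out, "L") <- L
  attr(out, "mode") <- sol$mode
  out
}

#' Pairwise RIL recombination fraction from a multilocus solution
#'
#' The probability that the fixed line carries alleles of different founders
#' at loci `l1` and `l2`, obtained by marginalizing the L-locus IBD solution:
#' the sum of Q(u) over all 4^L lists whose labels at the two loci fall in
#' different allele classes (\{0,2\} vs \{1,3\}).  With map-derived
#' (no-interference) rates this equals the two-locus closed form
#' [hw_R()] evaluated at the pairwise meiotic fraction.  When the solution is
#' exact rational the attributes `num` and `den` carry the exact value.
#'
#' @param sol an `"ibd_solution"`.
#' @param l1,l2 distinct locus indices in 1..L.
#' @return A probability.
#' @export
pairwise_R <- function(sol, l1, l2) {
  L <- sol$L
  l1 <- as.integer(l1)
  l2 <- as.integer(l2)
  if (anyNA(c(l1, l2)) || l1 < 1L || l2 < 1L || l1 > L || l2 > L)
    stop("locus indices must be in 1..", L)
  if (l1 == l2) stop("l1 and l2 must differ")
  codes <- 0:(4^L - 1)
  d1 <- (codes %/% 4^(L - l1)) %% 4
  d2 <- (codes %/% 4^(L - l2)) %% 4
  disc <- (d1 %% 2) != (d2 %% 2)  # allele class is the label's parity
  idx <- sol$index[codes[disc] + 1]
  R <- sum(sol$Q[idx])
  if (!is.null(sol$Q_num) && L <= 4L) {
    acc <- list(n = 0, d = 1)
    for (k in idx) acc <- .rat_add(acc, list(n = sol$Q_num[k], d = sol$Q_den[k]))
    attr(R, "num") <- acc$n
    attr(R, "den") <- acc$d
  }
  R
}

#' Two-locus RIL recombination fraction, closed forms
#'
#' `hw_R()` is the Haldane–Waddington relation R = 4r / (1 + 6r) for
#' sibling-mated lines with equal female and male meiotic fraction r.
#' `hw_R_sexdep()` is its sex-dependent generalization
#' R = 2 (rf + rm) / (3 (rf + rm) + 1), which depends on the two rates only
#' through their mean: `hw_R_sexdep(rf, rm) == hw_R((rf + rm) / 2)`.
#'
#' @param r,rf,rm meiotic recombination fractions in \[0, 0.5\].
#' @return The RIL recombination fraction.
#' @export
hw_R <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  4 * r / (1 + 6 * r)
}

#' @rdname hw_R
#' @export
hw_R_sexdep <- function(rf, rm) {
  if (any(rf < 0 | rf > 0.5) || any(rm < 0 | rm > 0.5))
    stop("rates must lie in [0, 0.5]")
  2 * (rf + rm) / (3 * (rf + rm) + 1)
}
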