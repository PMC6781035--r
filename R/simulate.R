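# Forward simulation of SIB-mating pedigrees to IBD fixation.
#
# Chromosome labels follow the pedigree convention: 0, 1 are the female's
# homologues and 2, 3 the male's; at every generation the new chromosomes 0
# and 2 are products of the mother's (female) meiosis and 1 and 3 of the
# father's (male) meiosis.  The simulator tracks, per locus, which F1
# chromosome the material is identical by descent with, and stops when all
# four chromosomes of the sibling pair agree at every locus (IBD fixation,
# which implies allelic fixation).

#' Simulate one meiotic product (gamete)
#'
#' Marker-resolution meiosis under the Haldane model: the first locus copies
#' from either homologue with probability 1/2, and each subsequent interval
#' switches the source homologue independently with its recombination
#' fraction (no interference).  At marker resolution this is exactly
#' equivalent to drawing continuous crossover positions.
#'
#' @param h1,h2 the two homologues: equal-length vectors (IBD labels,
#'   alleles, ...).
#' @param r_adjacent adjacent-interval recombination fractions, length
#'   `length(h1) - 1`.
#' @return A vector of the same length: the transmitted sequence.
#' @export
simulate_gamete <- function(h1, h2, r_adjacent) {
  L <- length(h1)
  if (length(h2) != L) stop("homologues must have equal length")
  if (length(r_adjacent) != max(L - 1L, 0L))
    stop("r_adjacent must have length L - 1")
  src <- integer(L)
  src[1L] <- stats::rbinom(1L, 1L, 0.5)
  if (L > 1L) {
    sw <- stats::runif(L - 1L) < r_adjacent
    src <- cumsum(c(src[1L], sw)) %% 2L
  }
  ifelse(src == 0L, h1, h2)
}

# Vectorized engine: simulate n pedigrees to IBD fixation.
# Returns list(labels = n x L matrix of fixed F1 labels, generations).
.sim_fix <- function(n, model, max_generations = 500L) {
  L <- model$L
  rf <- .adjacent_r(model, "f")
  rm_ <- .adjacent_r(model, "m")
  gamete <- function(H1, H2, r) {
    m <- nrow(H1)
    src <- matrix(0L, m, L)
    src[, 1L] <- stats::rbinom(m, 1L, 0.5)
    if (L > 1L) {
      acc <- src[, 1L]
      for (l in 2:L) {
        acc <- (acc + (stats::runif(m) < r[l - 1L])) %% 2L
        src[, l] <- acc
      }
    }
    out <- H1
    out[src == 1L] <- H2[src == 1L]
    out
  }
  C0 <- matrix(0L, n, L); C1 <- matrix(1L, n, L)
  C2 <- matrix(2L, n, L); C3 <- matrix(3L, n, L)
  labels <- matrix(0L, n, L)
  gens <- integer(n)
  active <- seq_len(n)
  g <- 0L
  warned <- FALSE
  while (length(active)) {
    g <- g + 1L
    if (g > max_generations && !warned) {
      warning(length(active), " pedigree(s) not IBD-fixed after ",
              max_generations, " generations; continuing until fixation")
      warned <- TRUE
    }
    n0 <- gamete(C0, C1, rf)   # daughter, maternal product
    n1 <- gamete(C2, C3, rm_)  # daughter, paternal product
    n2 <- gamete(C0, C1, rf)   # son, maternal product
    n3 <- gamete(C2, C3, rm_)  # son, paternal product
    C0 <- n0; C1 <- n1; C2 <- n2; C3 <- n3
    fixed <- rowSums(C0 == C1 & C0 == C2 & C0 == C3) == L
    if (any(fixed)) {
      labels[active[fixed], ] <- C0[fixed, , drop = FALSE]
      gens[active[fixed]] <- g
      keep <- !fixed
      active <- active[keep]
      C0 <- C0[keep, , drop = FALSE]; C1 <- C1[keep, , drop = FALSE]
      C2 <- C2[keep, , drop = FALSE]; C3 <- C3[keep, , drop = FALSE]
    }
  }
  list(labels = labels, generations = gens)
}

#' Simulate a single RIL to IBD fixation
#'
#' Iterates sibling mating from the F1 state until the four chromosomes are
#' identical by descent at every locus.  The fixed genotype follows from the
#' fixed labels: 0 and 2 carry the parent-1 allele A, 1 and 3 the parent-2
#' allele a.
#'
#' @param model a [recomb_model()].
#' @param max_generations soft cap; fixation is almost sure, so the
#'   simulation continues past the cap with a warning rather than failing.
#' @return A list with `ibd` (fixed label list), `genotype` (character
#'   vector of `"A"`/`"a"`), and `generations` to fixation.
#' @export
simulate_ril <- function(model, max_generations = 500L) {
  s <- .sim_fix(1L, model, max_generations)
  lab <- s$labels[1L, ]
  list(ibd = lab, genotype = c("A", "a")[(lab %% 2L) + 1L],
       generations = s$generations[1L])
}

#' Simulate a SIB RIL population
#'
#' Independent replicates of [simulate_ril()], returned as an
#' individuals-by-markers genotype matrix of `"A"`/`"a"` calls.
#'
#' @param n number of lines.
#' @param model a [recomb_model()].
#' @param seed optional integer seed for reproducibility.
#' @param keep_ibd also return the fixed IBD label matrix.
#' @inheritParams simulate_ril
#' @return A character matrix with rownames `RIL<i>` and the model's marker
#'   ids as colnames; attribute `generations` holds the per-line fixation
#'   times, and `ibd` the label matrix when requested.
#' @export
#' @examples
#' m <- recomb_model(map = c(0, 20, 50))
#' g <- simulate_population(20, m, seed = 1)
simulate_population <- function(n, model, seed = NULL, max_generations = 500L,
                                keep_ibd = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  s <- .sim_fix(n, model, max_generations)
  geno <- matrix(c("A", "a")[(s$labels %% 2L) + 1L], n, model$L,
                 dimnames = list(sprintf("RIL%d", seq_len(n)), model$marker_id))
  attr(geno, "generations") <- s$generations
  if (keep_ibd) attr(geno, "ibd") <- s$labels
  geno
}

#' Random marker map
#'
#' Positions `L` markers uniformly on a chromosome of the given genetic
#' length, sorted and separated by at least a small epsilon so no two
#' markers coincide.
#'
#' @param L number of markers (>= 2).
#' @param length_cM chromosome length in centimorgans.
#' @param seed optional integer seed.
#' @param min_spacing minimum spacing in cM enforced after sorting.
#' @return A data frame with columns `marker_id` and `position_cM`.
#' @export
random_map <- function(L, length_cM, seed = NULL, min_spacing = 1e-6) {
  if (L < 2L) stop("L must be >= 2")
  if (length_cM <= 0) stop("length_cM must be positive")
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(stats::runif(L, 0, length_cM))
  for (l in 2:L) if (pos[l] - pos[l - 1L] < min_spacing)
    pos[l] <- pos[l - 1L] + min_spacing
  data.frame(marker_id = sprintf("M%03d", seq_len(L)), position_cM = pos,
             stringsAsFactors = FALSE)
}
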