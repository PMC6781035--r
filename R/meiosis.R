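# Recombination model and single-generation IBD transition probabilities
# under the Haldane (no crossover interference) model.

#' Haldane map function
#'
#' Converts a genetic map distance in centimorgans to a recombination
#' fraction assuming crossovers arise without interference:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM map distance in centimorgans (>= 0), vectorized.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
#' @examples
#' haldane_r(c(0, 10, 50))
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distances must be non-negative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Compose recombination fractions over adjacent intervals
#'
#' Under no interference the fraction over a union of adjacent intervals is
#' r_ac = r_ab + r_bc - 2 r_ab r_bc (an odd number of crossovers in exactly
#' one of the two intervals).
#'
#' @param r_ab,r_bc recombination fractions in \[0, 0.5\].
#' @return The composed fraction, again in \[0, 0.5\].
#' @export
combine_r <- function(r_ab, r_bc) {
  if (any(r_ab < 0 | r_ab > 0.5) || any(r_bc < 0 | r_bc > 0.5))
    stop("recombination fractions must lie in [0, 0.5]")
  r_ab + r_bc - 2 * r_ab * r_bc
}

.check_r_matrix <- function(r, what) {
  if (!is.matrix(r) || nrow(r) != ncol(r))
    stop(what, " must be a square matrix")
  if (any(abs(diag(r)) > 0)) stop(what, " must have a zero diagonal")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12)))
    stop(what, " must be symmetric")
  if (any(r < 0 | r > 0.5)) stop(what, " entries must lie in [0, 0.5]")
  (r + t(r)) / 2
}

# attempt an exact rational copy of a rate matrix; NULL when any entry has no
# small exact fraction
.rat_matrix <- function(r, max_den = 10000L) {
  out_n <- matrix(0, nrow(r), ncol(r))
  out_d <- matrix(1, nrow(r), ncol(r))
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    if (i == j) next
    pq <- .as_rational(r[i, j], max_den)
    if (is.null(pq)) return(NULL)
    out_n[i, j] <- pq[1]
    out_d[i, j] <- pq[2]
  }
  list(n = out_n, d = out_d)
}

# fill non-adjacent entries of a rate matrix from adjacent fractions
.fill_from_adjacent <- function(adj) {
  L <- length(adj) + 1L
  r <- matrix(0, L, L)
  for (l in seq_len(L - 1L)) {
    acc <- 0
    for (l2 in (l + 1L):L) {
      acc <- combine_r(acc, adj[l2 - 1L])
      r[l, l2] <- r[l2, l] <- acc
    }
  }
  r
}

#' Recombination model for a single linkage group
#'
#' Holds the number of loci, optional genetic-map positions, and the full
#' pairwise recombination-fraction matrices for female and male meiosis.
#' Exactly one rate source must be supplied:
#' \itemize{
#'   \item `map`: marker positions in cM (a numeric vector, or a data frame
#'     with columns `marker_id` and `position_cM`).  All pairwise fractions,
#'     including non-adjacent ones, are derived through the Haldane map
#'     function, which guarantees no-interference consistency.
#'   \item `r` (equal sexes) or both `rf` and `rm`: a single fraction (two
#'     loci), a length L-1 vector of adjacent fractions (non-adjacent entries
#'     filled by [combine_r()]), or a full symmetric L x L matrix.  A full
#'     matrix is validated for symmetry and range but not forced to be
#'     Haldane-consistent; a warning is issued if it measurably violates
#'     no-interference additivity.
#' }
#' When the rates are exactly representable as small fractions an exact
#' rational copy is kept so that downstream solves can be performed in exact
#' arithmetic.
#'
#' @param map marker map (positions in cM, strictly increasing), or `NULL`.
#' @param r sex-averaged rates (implies `sex_equal = TRUE`), or `NULL`.
#' @param rf,rm female and male rates, same shape, or `NULL`.
#' @param max_denominator largest denominator tried when converting rates to
#'   exact fractions.
#' @return An object of class `"recomb_model"`.
#' @export
#' @examples
#' recomb_model(r = 0.25)                     # two loci, r = 1/4
#' recomb_model(map = c(0, 20, 50))           # three loci on a 50 cM map
#' recomb_model(rf = 0.1, rm = 0.3)           # sex-dependent two-locus model
recomb_model <- function(map = NULL, r = NULL, rf = NULL, rm = NULL,
                         max_denominator = 10000L) {
  has_map <- !is.null(map)
  has_r <- !is.null(r)
  has_sex <- !is.null(rf) || !is.null(rm)
  if (has_map + has_r + has_sex != 1L)
    stop("supply exactly one rate source: map, r, or both rf and rm")

  marker_id <- NULL
  positions <- NULL
  rat <- NULL

  expand_rates <- function(x, what) {
    if (is.matrix(x)) {
      x <- .check_r_matrix(x, what)
      # warn when a user-supplied full matrix is not no-interference
      # consistent; the linear algebra is well defined regardless
      L <- nrow(x)
      if (L >= 3L) {
        bad <- FALSE
        for (l in seq_len(L - 2L))
          if (abs(x[l, l + 2L] - combine_r(x[l, l + 1L], x[l + 1L, l + 2L])) > 1e-8)
            bad <- TRUE
        if (bad)
          warning(what, " is not consistent with a no-interference map; ",
                  "using it as given", call. = FALSE)
      }
      x
    } else if (length(x) == 1L) {
      if (x < 0 || x > 0.5) stop(what, " must lie in [0, 0.5]")
      matrix(c(0, x, x, 0), 2L, 2L)
    } else {
      if (any(x < 0 | x > 0.5)) stop(what, " entries must lie in [0, 0.5]")
      .fill_from_adjacent(as.numeric(x))
    }
  }

  if (has_map) {
    if (is.data.frame(map)) {
      if (!all(c("marker_id", "position_cM") %in% names(map)))
        stop("a map data frame needs columns marker_id and position_cM")
      marker_id <- as.character(map$marker_id)
      positions <- as.numeric(map$position_cM)
    } else {
      positions <- as.numeric(map)
    }
    if (length(positions) < 1L || anyNA(positions))
      stop("map positions must be numeric and non-missing")
    if (is.unsorted(positions, strictly = TRUE))
      stop("map positions must be strictly increasing")
    L <- length(positions)
    rfm <- haldane_r(abs(outer(positions, positions, "-")))
    diag(rfm) <- 0
    rmm <- rfm
    sex_equal <- TRUE
  } else if (has_r) {
    rfm <- rmm <- expand_rates(r, "r")
    sex_equal <- TRUE
  } else {
    if (is.null(rf) || is.null(rm)) stop("supply both rf and rm")
    rfm <- expand_rates(rf, "rf")
    rmm <- expand_rates(rm, "rm")
    if (!identical(dim(rfm), dim(rmm))) stop("rf and rm must have the same shape")
    sex_equal <- identical(rfm, rmm)
  }

  L <- nrow(rfm)
  if (is.null(marker_id)) marker_id <- sprintf("M%d", seq_len(L))
  if (!has_map && L <= 8L) {
    ratf <- .rat_matrix(rfm, max_denominator)
    ratm <- if (sex_equal) ratf else .rat_matrix(rmm, max_denominator)
    if (!is.null(ratf) && !is.null(ratm)) rat <- list(rf = ratf, rm = ratm)
  }

  structure(list(L = L, marker_id = marker_id, positions = positions,
                 rf = rfm, rm = rmm, sex_equal = sex_equal, rat = rat),
            class = "recomb_model")
}

#' @export
print.recomb_model <- function(x, ...) {
  cat(sprintf("recombination model: %d loci, %s rates%s\n", x$L,
              if (x$sex_equal) "sex-equal" else "sex-dependent",
              if (is.null(x$positions)) "" else
                sprintf(", map %.4g-%.4g cM", min(x$positions), max(x$positions))))
  if (!is.null(x$rat)) cat("rates exactly rational: exact solver available\n")
  invisible(x)
}

# restriction of a model to a subset of loci (used by block imputation);
# pairwise matrices restrict exactly, no refitting needed
.model_subset <- function(model, loci) {
  out <- model
  out$L <- length(loci)
  out$marker_id <- model$marker_id[loci]
  out$positions <- model$positions[loci]
  out$rf <- model$rf[loci, loci, drop = FALSE]
  out$rm <- model$rm[loci, loci, drop = FALSE]
  if (!is.null(model$rat))
    out$rat <- list(
      rf = list(n = model$rat$rf$n[loci, loci, drop = FALSE],
                d = model$rat$rf$d[loci, loci, drop = FALSE]),
      rm = list(n = model$rat$rm$n[loci, loci, drop = FALSE],
                d = model$rat$rm$d[loci, loci, drop = FALSE]))
  out
}

# adjacent-interval fractions for one sex, used by the forward simulator
.adjacent_r <- function(model, sex = c("f", "m")) {
  sex <- match.arg(sex)
  r <- if (sex == "f") model$rf else model$rm
  if (model$L < 2L) return(numeric(0))
  r[cbind(seq_len(model$L - 1L), 2:model$L)]
}

#' Is a single-generation IBD transition allowed?
#'
#' Locus by locus, material on the new female-meiosis products (labels 0, 2)
#' descends from the mother's chromosomes (labels 0, 1), and material on the
#' male-meiosis products (1, 3) from the father's (2, 3).  Hence a locus with
#' index 0 or 1 can only propagate to 0 or 2, and one with 2 or 3 only to
#' 1 or 3.
#'
#' @param u,v IBD index lists of equal length (F1 level and F2 level).
#' @return `TRUE` or `FALSE`.
#' @export
allowed_transition <- function(u, v) {
  u <- .check_index_list(u)
  v <- .check_index_list(v)
  if (length(u) != length(v)) stop("u and v must have the same length")
  all(v %% 2L == (u >= 2L))
}

#' Per-meiosis factor of a transition probability
#'
#' The factor contributed by the meiosis that produces chromosome `j` of the
#' next generation.  Let S be the ordered list of loci l with `v[l] == j`.
#' If S is empty the factor is 1; otherwise it is 0.5 (the first locus picks
#' one of two homologues) times, for each successive pair (l, l') of S, the
#' probability that the interval is recombinant (`u[l] != u[l']`) or not:
#' r_{l,l'} or 1 - r_{l,l'}.  Chromosomes 0 and 2 are female-meiosis
#' products, so j = 0, 2 uses the female rates and j = 1, 3 the male rates.
#'
#' @param j chromosome label in 0..3.
#' @param u,v IBD index lists; the transition must be allowed.
#' @param model a [recomb_model()].
#' @return A probability.
#' @export
chromosome_factor <- function(j, u, v, model) {
  j <- as.integer(j)
  if (is.na(j) || j < 0L || j > 3L) stop("j must be in 0..3")
  u <- .check_index_list(u)
  v <- .check_index_list(v)
  if (!allowed_transition(u, v)) stop("transition u -> v is not allowed")
  S <- which(v == j)
  if (length(S) == 0L) return(1)
  rmat <- if (j %% 2L == 0L) model$rf else model$rm
  p <- 0.5
  if (length(S) > 1L)
    for (k in seq_len(length(S) - 1L)) {
      l <- S[k]; l2 <- S[k + 1L]
      r <- rmat[l, l2]
      p <- p * if (u[l] != u[l2]) r else 1 - r
    }
  p
}

#' Single-generation IBD transition probability
#'
#' T\[u -> v\] is the product of the four per-meiosis factors
#' ([chromosome_factor()]) or 0 when the transition is not allowed.  Summed
#' over all origins u, the transition probabilities into any fixed v equal 1
#' (the stochasticity direction used to show that the homogeneous
#' self-consistent system has a one-dimensional solution space).
#'
#' @inheritParams chromosome_factor
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' m <- recomb_model(r = 0.25)
#' transition_probability(c(0, 0), c(0, 0), m)  # (1 - r) / 2
#' transition_probability(c(0, 0), c(2, 0), m)  # 1/4
transition_probability <- function(u, v, model) {
  u <- .check_index_list(u)
  v <- .check_index_list(v)
  if (length(u) != length(v)) stop("u and v must have the same length")
  if (length(u) != model$L) stop("index lists must match the model's loci")
  if (!allowed_transition(u, v)) return(0)
  p <- 1
  for (j in 0:3) p <- p * chromosome_factor(j, u, v, model)
  p
}

#' Full 4^L transition matrix
#'
#' Dense matrix with entry \[u, v\] = T\[u -> v\], rows and columns indexed by
#' the lexicographic code of the index lists (leftmost locus most
#' significant).  Intended for inspection and testing; the solver never
#' materializes this matrix.
#'
#' @param model a [recomb_model()]; `model$L` must be at most 5.
#' @return A 4^L x 4^L numeric matrix.
#' @export
transition_matrix <- function(model) {
  if (model$L > 5L) stop("full transition matrix is limited to L <= 5")
  U <- .all_index_lists(model$L)
  storage.mode(U) <- "integer"
  tri <- .transition_triplets(U, seq_len(nrow(U)), model)
  M <- matrix(0, nrow(U), nrow(U))
  M[cbind(tri$i, tri$j)] <- tri$x
  M
}

# Vectorized transition computation used by the system builder and
# transition_matrix.  For every row u of U (N x L matrix of labels) and every
# origin-choice pattern c in {0,1}^L, the reachable list is
# v_l = 2 c_l + [u_l >= 2]; T[u -> v] accumulates one 0.5 per nonempty
# meiosis and one r / (1 - r) factor per successive same-label locus pair.
# `index` maps the lexicographic code of v (plus one) to a column; duplicate
# (i, j) pairs are NOT merged here.
.transition_triplets <- function(U, index, model) {
  N <- nrow(U)
  L <- ncol(U)
  B <- (U >= 2L) * 1L
  pow <- 4^(L - seq_len(L))
  rows <- seq_len(N)
  ii <- jj <- xx <- vector("list", 2^L)
  for (ci in 0:(2^L - 1)) {
    cbits <- (ci %/% 2^(seq_len(L) - 1L)) %% 2L
    Tvec <- rep(1, N)
    last <- matrix(0L, N, 4L)
    vcode <- numeric(N)
    for (l in seq_len(L)) {
      vl <- 2L * cbits[l] + B[, l]
      vcode <- vcode + vl * pow[l]
      prev <- last[cbind(rows, vl + 1L)]
      first <- prev == 0L
      if (any(first)) Tvec[first] <- Tvec[first] * 0.5
      has <- !first
      if (any(has)) {
        w <- which(has)
        pl <- prev[w]
        rv <- ifelse(vl[w] %% 2L == 0L,
                     model$rf[cbind(pl, l)], model$rm[cbind(pl, l)])
        e <- U[cbind(w, rep(l, length(w)))] != U[cbind(w, pl)]
        Tvec[w] <- Tvec[w] * ifelse(e, rv, 1 - rv)
      }
      last[cbind(rows, vl + 1L)] <- l
    }
    ii[[ci + 1L]] <- rows
    jj[[ci + 1L]] <- index[vcode + 1]
    xx[[ci + 1L]] <- Tvec
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx))
}

# exact-rational transition probability; rat = model$rat, scalar loop
.transition_rat <- function(u, v, rat) {
  p <- list(n = 1, d = 1)
  for (j in 0:3) {
    S <- which(v == j)
    if (length(S) == 0L) next
    rm_ <- if (j %% 2L == 0L) rat$rf else rat$rm
    p <- .rat_mul(p, list(n = 1, d = 2))
    if (length(S) > 1L)
      for (k in seq_len(length(S) - 1L)) {
        l <- S[k]; l2 <- S[k + 1L]
        f <- if (u[l] != u[l2]) list(n = rm_$n[l, l2], d = rm_$d[l, l2])
             else .rat_sub(list(n = 1, d = 1),
                           list(n = rm_$n[l, l2], d = rm_$d[l, l2]))
        p <- .rat_mul(p, f)
      }
  }
  p
}
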