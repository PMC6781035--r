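# Building and solving the reduced self-consistent linear system for the
# non-equivalent IBD probabilities Q.

#' Build the reduced self-consistent linear system
#'
#' The 4^L IBD probabilities satisfy the homogeneous self-consistency
#' Q(u) = sum_v T\[u -> v\] Q(v): the inheritance from the F1 generation can
#' be decomposed over the F2-level inheritance, and the F2-to-fixation
#' process is statistically identical to the F1-to-fixation one.  Restricted
#' to canonical representatives (every Q(v) replaced by its class
#' representative), these give N homogeneous equations for the N
#' non-equivalent unknowns; they are linearly dependent (transition
#' probabilities into any fixed v sum to 1 over the origins u), so one of
#' them — by default the last in lexicographic order — is dropped and
#' replaced by the normalization sum_u Q(u) = 1, whose coefficients are the
#' orbit weights.
#'
#' @param model a [recomb_model()].
#' @param mode `"equal"` or `"sexdep"`; defaults to the model's symmetry.
#'   `"equal"` requires equal female and male rates.
#' @param drop index (1..N) of the representative whose homogeneous equation
#'   is omitted; the solution does not depend on the choice.
#' @param arithmetic `"auto"` (exact rationals when the rates allow it and
#'   the system is small, floating point otherwise), `"rational"`, or
#'   `"double"`.
#' @return An object of class `"reduced_system"` with the coefficient matrix
#'   `A` (dense or sparse), right-hand side `b = (1, 0, ..., 0)`, the class
#'   enumeration, and the full reduced transition matrix `Tmat` used for
#'   residual checks.
#' @export
build_reduced_system <- function(model, mode = NULL, drop = NULL,
                                 arithmetic = c("auto", "rational", "double")) {
  arithmetic <- match.arg(arithmetic)
  if (is.null(mode)) mode <- if (model$sex_equal) "equal" else "sexdep"
  mode <- .mode_match(mode)
  if (mode == "equal" && !model$sex_equal)
    stop("equal-sex mode requires equal female and male rates; use mode = \"sexdep\"")
  cls <- ibd_classes(model$L, mode)
  N <- length(cls$weights)
  if (is.null(drop)) drop <- N
  drop <- as.integer(drop)
  if (is.na(drop) || drop < 1L || drop > N)
    stop("drop must select one of the ", N, " representatives")

  tri <- .transition_triplets(cls$reps, cls$index, model)
  Tmat <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x, dims = c(N, N))
  keep <- setdiff(seq_len(N), drop)
  A <- rbind(Matrix::Matrix(cls$weights, nrow = 1, sparse = TRUE),
             (Matrix::Diagonal(N) - Tmat)[keep, , drop = FALSE])
  b <- c(1, rep(0, N - 1L))
  # dense LU beats sparse LU here up to a few thousand unknowns: the reduced
  # matrix has ~2^L structural nonzeros per row and fills in heavily
  dense <- N <= 2500L
  if (dense) A <- as.matrix(A)

  rational <- NULL
  want_rat <- arithmetic == "rational" ||
    (arithmetic == "auto" && !is.null(model$rat) && N <= 64L)
  if (want_rat) {
    if (is.null(model$rat))
      stop("rates are not exactly rational; exact arithmetic unavailable")
    if (N > 64L)
      stop("exact rational solve is limited to systems of at most 64 unknowns")
    An <- matrix(0, N, N)
    Ad <- matrix(1, N, N)
    # self-consistency rows in exact arithmetic
    for (i in seq_len(N)) {
      u <- cls$reps[i, ]
      B <- (u >= 2L) * 1L
      acc_n <- numeric(N)
      acc_d <- rep(1, N)
      for (ci in 0:(2^model$L - 1)) {
        cbits <- (ci %/% 2^(seq_len(model$L) - 1L)) %% 2L
        v <- 2L * cbits + B
        jcol <- cls$index[.ibd_code(v) + 1]
        tp <- .transition_rat(u, v, model$rat)
        s <- .rat_add(list(n = acc_n[jcol], d = acc_d[jcol]), tp)
        acc_n[jcol] <- s$n
        acc_d[jcol] <- s$d
      }
      row <- .rat(-acc_n, acc_d)
      An[i, ] <- row$n
      Ad[i, ] <- row$d
      d <- .rat_add(list(n = An[i, i], d = Ad[i, i]), list(n = 1, d = 1))
      An[i, i] <- d$n
      Ad[i, i] <- d$d
    }
    An <- rbind(cls$weights, An[keep, , drop = FALSE])
    Ad <- rbind(rep(1, N), Ad[keep, , drop = FALSE])
    rational <- list(An = An, Ad = Ad)
  }

  structure(list(A = A, b = b, Tmat = Tmat, cls = cls, mode = mode,
                 drop = drop, model = model, rational = rational),
            class = "reduced_system")
}

#' Solve for the non-equivalent IBD probabilities
#'
#' Solves the reduced system for the probabilities Q on canonical
#' representatives.  With exact rational coefficients the solution is exact
#' (numerators and denominators are returned alongside); otherwise a dense LU
#' solve is used for small systems and a sparse direct solve above 500
#' unknowns.  If exact arithmetic overflows the solver silently falls back to
#' floating point (recorded in the `arithmetic` field).
#'
#' @param x a `"reduced_system"` from [build_reduced_system()], or a
#'   [recomb_model()] (the system is then built with the given `...`
#'   arguments).
#' @param ... passed on to [build_reduced_system()] when `x` is a model.
#' @return An object of class `"ibd_solution"`: probabilities `Q` (one per
#'   canonical representative), orbit `weights`, exact `Q_num`/`Q_den` when
#'   available, the class lookup table, and the maximum self-consistency
#'   residual of the solve.
#' @export
#' @examples
#' sol <- solve_Q(recomb_model(r = 1/4))
#' sol$Q  # 1/10, 1/20, 1/20 for Q(0,0), Q(0,1), Q(0,2)
solve_Q <- function(x, ...) {
  sys <- if (inherits(x, "recomb_model")) build_reduced_system(x, ...) else x
  if (!inherits(sys, "reduced_system")) stop("x must be a reduced_system or recomb_model")
  N <- length(sys$b)
  Q_num <- Q_den <- NULL
  arithmetic <- "double"
  Q <- NULL
  if (!is.null(sys$rational)) {
    sol <- tryCatch(
      .rat_solve(sys$rational$An, sys$rational$Ad, sys$b, rep(1, N)),
      sibril_rat_overflow = function(e) NULL)
    if (!is.null(sol)) {
      Q_num <- unname(sol$n)
      Q_den <- unname(sol$d)
      Q <- Q_num / Q_den
      arithmetic <- "rational"
    }
  }
  if (is.null(Q)) {
    Q <- tryCatch(
      as.numeric(Matrix::solve(sys$A, sys$b)),
      error = function(e)
        stop("the reduced system is singular or could not be solved (",
             conditionMessage(e), "); coincident loci (r = 0 between distinct ",
             "markers) should be merged before solving", call. = FALSE))
  }
  if (any(Q < -1e-8))
    warning("negative probabilities beyond numerical tolerance in Q")
  residual <- max(abs(Q - as.numeric(sys$Tmat %*% Q)),
                  abs(sum(sys$cls$weights * Q) - 1))
  structure(list(L = sys$model$L, mode = sys$mode, Q = Q,
                 Q_num = Q_num, Q_den = Q_den,
                 reps = sys$cls$reps, weights = sys$cls$weights,
                 index = sys$cls$index, model = sys$model,
                 arithmetic = arithmetic, drop = sys$drop,
                 residual = residual),
            class = "ibd_solution")
}

#' @export
print.ibd_solution <- function(x, ...) {
  cat(sprintf("IBD probabilities: %d classes, L = %d, %s-sex mode, %s arithmetic\n",
              length(x$Q), x$L,
              if (x$mode == "equal") "equal" else "dependent", x$arithmetic))
  df <- data.frame(index_list = apply(x$reps, 1L, paste, collapse = ","),
                   weight = x$weights, Q = x$Q)
  if (!is.null(x$Q_num)) {
    df$Q_num <- x$Q_num
    df$Q_den <- x$Q_den
  }
  print(utils::head(df, 15L), row.names = FALSE)
  if (nrow(df) > 15L) cat("...", nrow(df) - 15L, "more classes\n")
  cat(sprintf("max self-consistency residual: %.3g\n", x$residual))
  invisible(x)
}

#' Probability of an arbitrary IBD index list
#'
#' Looks up Q at the canonical representative of `u`, so any of the 4^L
#' lists can be queried.
#'
#' @param sol an `"ibd_solution"` from [solve_Q()].
#' @param u IBD index list of length `sol$L`.
#' @return A probability.
#' @export
lookup_Q <- function(sol, u) {
  u <- .check_index_list(u)
  if (length(u) != sol$L) stop("u must have length ", sol$L)
  sol$Q[sol$index[.ibd_code(u) + 1]]
}

#' Self-consistency residual of a solution
#'
#' Recomputes, through the scalar transition-probability path (independent of
#' the vectorized system builder), the residual of every representative's
#' self-consistency equation — including the one dropped when building the
#' system — together with the normalization constraint, and returns the
#' largest absolute value.
#'
#' @param sol an `"ibd_solution"`.
#' @return Maximum absolute residual (0 for an exact solve, tiny for a
#'   floating-point one).
#' @export
residual_check <- function(sol) {
  L <- sol$L
  N <- nrow(sol$reps)
  res <- abs(sum(sol$weights * sol$Q) - 1)
  for (i in seq_len(N)) {
    u <- sol$reps[i, ]
    B <- (u >= 2L) * 1L
    acc <- 0
    for (ci in 0:(2^L - 1)) {
      cbits <- (ci %/% 2^(seq_len(L) - 1L)) %% 2L
      v <- 2L * cbits + B
      acc <- acc + transition_probability(u, v, sol$model) *
        sol$Q[sol$index[.ibd_code(v) + 1]]
    }
    res <- max(res, abs(sol$Q[i] - acc))
  }
  res
}
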