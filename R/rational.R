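# Internal exact rational arithmetic.
#
# Rationals are stored as list(n = numerator, d = denominator) with both held
# in doubles; every value is kept reduced, d > 0, and |n|, d below 2^52 so all
# integer arithmetic on them is exact.  When an operation would leave the
# exactly-representable range a condition of class "sibril_rat_overflow" is
# raised; callers fall back to floating point.

.RAT_MAX <- 2^52

.rat_overflow <- function() {
  stop(structure(
    class = c("sibril_rat_overflow", "error", "condition"),
    list(message = "exact rational arithmetic overflowed; use floating point",
         call = NULL)))
}

# vectorized Euclid; inputs are non-negative integers stored in doubles
.gcd <- function(a, b) {
  while (any(b > 0)) {
    keep <- b > 0
    t <- b
    b[keep] <- a[keep] %% b[keep]
    a <- ifelse(keep, t, a)
  }
  a
}

.rat <- function(n, d = rep(1, length(n))) {
  if (any(d == 0)) stop("zero denominator")
  neg <- d < 0
  n[neg] <- -n[neg]
  d[neg] <- -d[neg]
  if (any(abs(n) > .RAT_MAX) || any(d > .RAT_MAX)) .rat_overflow()
  z <- n == 0
  d[z] <- 1
  g <- .gcd(abs(n), d)
  g[g == 0] <- 1
  list(n = n / g, d = d / g)
}

.rat_add <- function(x, y) .rat(x$n * y$d + y$n * x$d, x$d * y$d)
.rat_sub <- function(x, y) .rat(x$n * y$d - y$n * x$d, x$d * y$d)
.rat_mul <- function(x, y) .rat(x$n * y$n, x$d * y$d)
.rat_div <- function(x, y) {
  if (any(y$n == 0)) stop("rational division by zero")
  .rat(x$n * y$d, x$d * y$n)
}
.rat_idx <- function(x, i) list(n = x$n[i], d = x$d[i])

# Recover p/q from a double, or NULL when no small exact fraction reproduces
# it bit-for-bit.  Used to decide whether the exact solver path is available.
.as_rational <- function(x, max_den = 10000L) {
  if (!is.finite(x)) return(NULL)
  q <- seq_len(max_den)
  p <- round(x * q)
  hit <- which(p / q == x)
  if (!length(hit)) return(NULL)
  q <- q[hit[1L]]
  p <- p[hit[1L]]
  g <- .gcd(abs(p), q)
  if (g == 0) g <- 1
  c(p / g, q / g)
}

# Gauss-Jordan solve of an exact rational linear system.
# An, Ad: N x N numerator/denominator matrices; bn, bd: length-N vectors.
# Returns list(n, d) for the solution, or raises sibril_rat_overflow /
# an error on singularity.
.rat_solve <- function(An, Ad, bn, bd) {
  N <- nrow(An)
  An <- cbind(An, bn)
  Ad <- cbind(Ad, bd)
  for (k in seq_len(N)) {
    piv <- which(An[k:N, k] != 0)
    if (!length(piv)) stop("singular system in exact rational solve")
    piv <- piv[1L] + k - 1L
    if (piv != k) {
      An[c(k, piv), ] <- An[c(piv, k), ]
      Ad[c(k, piv), ] <- Ad[c(piv, k), ]
    }
    # normalize pivot row
    pk <- list(n = An[k, k], d = Ad[k, k])
    row <- .rat_div(list(n = An[k, ], d = Ad[k, ]), list(n = rep(pk$n, N + 1), d = rep(pk$d, N + 1)))
    An[k, ] <- row$n
    Ad[k, ] <- row$d
    for (i in seq_len(N)) {
      if (i == k || An[i, k] == 0) next
      f <- list(n = rep(An[i, k], N + 1), d = rep(Ad[i, k], N + 1))
      upd <- .rat_sub(list(n = An[i, ], d = Ad[i, ]), .rat_mul(f, row))
      An[i, ] <- upd$n
      Ad[i, ] <- upd$d
    }
  }
  list(n = An[, N + 1], d = Ad[, N + 1])
}
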