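# Symmetry classes of multilocus IBD index lists.
#
# An IBD index list u = (i_1, ..., i_L) records, locus by locus, which of the
# four F1 chromosomes (0, 1 = female homologues; 2, 3 = male homologues) a
# fixed RIL inherits from.  Chromosome relabelings that leave the inheritance
# process statistically invariant partition the 4^L lists into equivalence
# classes; only one probability Q per class needs to be solved for.

.sibril_cache <- new.env(parent = emptyenv())

.mode_match <- function(mode) {
  key <- tolower(gsub("[^a-z]", "", tolower(as.character(mode)[1])))
  map <- c(equal = "equal", equalsex = "equal",
           sexdep = "sexdep", sexdependent = "sexdep")
  if (is.na(map[key])) stop("unknown symmetry mode: ", mode,
                            " (use \"equal\" or \"sexdep\")")
  unname(map[key])
}

.check_index_list <- function(u) {
  u <- as.integer(u)
  if (length(u) < 1L || anyNA(u) || any(u < 0L | u > 3L))
    stop("an IBD index list must have entries in {0,1,2,3}")
  u
}

# lexicographic code of an index list, leftmost locus most significant
.ibd_code <- function(u) sum(u * 4^(rev(seq_along(u)) - 1L))

.perm_compose <- function(p, q) p[q + 1L]

#' Chromosome-relabeling symmetry group
#'
#' The permutations of the F1 chromosome labels \{0,1,2,3\} under which the
#' SIB-mating inheritance process is statistically invariant.  Swapping the
#' two homologues within a sex (0 with 1, or 2 with 3) is always allowed; when
#' female and male meioses behave identically the female/male pair swap
#' (0,1) with (2,3) is allowed as well, giving a group of 8 elements instead
#' of 4.
#'
#' @param mode `"equal"` (sex-symmetric, 8 elements) or `"sexdep"`
#'   (sex-dependent recombination rates, 4 elements).
#' @return A list of integer vectors of length 4; element `p` maps label
#'   `i` to `p[i + 1]`.
#' @export
#' @examples
#' length(symmetry_group("equal"))   # 8
#' length(symmetry_group("sexdep"))  # 4
symmetry_group <- function(mode = c("equal", "sexdep")) {
  mode <- .mode_match(mode)
  gens <- list(c(1L, 0L, 2L, 3L),   # swap female homologues 0 <-> 1
               c(0L, 1L, 3L, 2L))   # swap male homologues 2 <-> 3
  if (mode == "equal")
    gens <- c(gens, list(c(2L, 3L, 0L, 1L)))  # swap sexes (0,1) <-> (2,3)
  elems <- list(c(0L, 1L, 2L, 3L))
  keys <- "0123"
  repeat {
    added <- FALSE
    for (e in elems) for (g in gens) {
      h <- .perm_compose(g, e)
      k <- paste(h, collapse = "")
      if (!k %in% keys) {
        elems[[length(elems) + 1L]] <- h
        keys <- c(keys, k)
        added <- TRUE
      }
    }
    if (!added) break
  }
  elems
}

#' Canonical representative of an IBD index list
#'
#' Maps `u` to the lexicographically smallest member of its orbit under the
#' symmetry group, e.g. (2,0) -> (0,2) and (2,2) -> (0,0) in the equal-sex
#' mode.
#'
#' @param u integer vector with entries in \{0,1,2,3\}.
#' @inheritParams symmetry_group
#' @return An integer vector of the same length as `u`.
#' @export
canonicalize <- function(u, mode = c("equal", "sexdep")) {
  u <- .check_index_list(u)
  perms <- symmetry_group(mode)
  imgs <- lapply(perms, function(p) p[u + 1L])
  imgs[[which.min(vapply(imgs, .ibd_code, numeric(1)))]]
}

#' Orbit size of an IBD index list
#'
#' The number of distinct images of `u` under the symmetry group.  This is
#' the weight with which the class of `u` enters the sum-to-one constraint:
#' 4 or 8 in the equal-sex mode (8 whenever `u` mixes female- and
#' male-origin labels), 2 or 4 in the sex-dependent mode.
#'
#' @inheritParams canonicalize
#' @return An integer.
#' @export
orbit_weight <- function(u, mode = c("equal", "sexdep")) {
  u <- .check_index_list(u)
  perms <- symmetry_group(mode)
  length(unique(vapply(perms, function(p) .ibd_code(p[u + 1L]), numeric(1))))
}

# all 4^L index lists as a matrix of digits; row i encodes code i - 1
.all_index_lists <- function(L) {
  codes <- 0:(4^L - 1)
  vapply(seq_len(L), function(l) (codes %/% 4^(L - l)) %% 4, numeric(4^L))
}

# Orbit partition of all 4^L lists, cached: canonical code, representative
# matrix, orbit weights and a lookup from any code to its class index.
.ibd_class_table <- function(L, mode) {
  key <- sprintf("cls:%d:%s", L, mode)
  if (!is.null(.sibril_cache[[key]])) return(.sibril_cache[[key]])
  D <- .all_index_lists(L)
  pow <- 4^(L - seq_len(L))
  perms <- symmetry_group(mode)
  canon <- rep(Inf, nrow(D))
  for (p in perms) {
    cp <- numeric(nrow(D))
    for (l in seq_len(L)) cp <- cp + p[D[, l] + 1L] * pow[l]
    canon <- pmin(canon, cp)
  }
  rep_codes <- sort(unique(canon))
  index <- match(canon, rep_codes)
  reps <- D[match(rep_codes, 0:(4^L - 1)), , drop = FALSE]
  storage.mode(reps) <- "integer"
  out <- list(L = L, mode = mode, reps = reps,
              weights = tabulate(index, nbins = length(rep_codes)),
              codes = rep_codes, index = index)
  .sibril_cache[[key]] <- out
  out
}

#' Enumerate the non-equivalent IBD classes
#'
#' Lists all equivalence classes of the 4^L IBD index lists under the
#' symmetry group, in lexicographic order of their canonical representatives,
#' together with the orbit weights.  In the equal-sex mode the number of
#' classes equals `n_ibd_classes(L)`.
#'
#' @param L number of loci (1..10).
#' @inheritParams symmetry_group
#' @return An object of class `"ibd_classes"`: list with elements `L`,
#'   `mode`, `reps` (N x L integer matrix of canonical representatives),
#'   `weights` (orbit sizes), `codes` and `index` (lookup from the
#'   lexicographic code of any list to its class).
#' @export
#' @examples
#' ibd_classes(2, "equal")$reps    # (0,0), (0,1), (0,2)
#' ibd_classes(2, "equal")$weights # 4 4 8
ibd_classes <- function(L, mode = c("equal", "sexdep")) {
  mode <- .mode_match(mode)
  L <- as.integer(L)
  if (is.na(L) || L < 1L || L > 10L)
    stop("L must be an integer in 1..10 (4^L lists are enumerated)")
  out <- .ibd_class_table(L, mode)
  class(out) <- "ibd_classes"
  out
}

#' @export
print.ibd_classes <- function(x, ...) {
  cat(sprintf("%d non-equivalent IBD classes for L = %d loci (%s-sex mode)\n",
              length(x$weights), x$L,
              if (x$mode == "equal") "equal" else "dependent"))
  df <- as.data.frame(x)
  print(utils::head(df, 20L), row.names = FALSE)
  if (nrow(df) > 20L) cat("...", nrow(df) - 20L, "more classes\n")
  invisible(x)
}

#' @export
as.data.frame.ibd_classes <- function(x, ...) {
  data.frame(index_list = apply(x$reps, 1L, paste, collapse = ","),
             weight = x$weights, stringsAsFactors = FALSE)
}

#' Number of non-equivalent IBD classes (equal-sex mode)
#'
#' Closed form 2^(L-2) (2^(L-1) + 1): 1, 3, 10, 36, 136, ... for
#' L = 1, 2, 3, 4, 5.  Equals `length(ibd_classes(L, "equal")$weights)`.
#'
#' @param L number of loci.
#' @return A number (integer-valued).
#' @export
n_ibd_classes <- function(L) {
  if (any(L < 1)) stop("L must be >= 1")
  2^(L - 2) * (2^(L - 1) + 1)
}
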