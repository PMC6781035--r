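# Imputation of missing RIL genotype calls by maximizing exact multilocus
# genotype probabilities over blocks of adjacent missing markers.

#' Mask genotype calls at random
#'
#' Sets an exact count `round(fraction * length(mat))` of cells, drawn
#' uniformly without replacement over the whole matrix, to `NA`.  Returns the
#' mask so imputations can be scored against the truth.
#'
#' @param mat character genotype matrix (`"A"`/`"a"`, possibly `NA`).
#' @param fraction fraction of cells to mask, in \[0, 1).
#' @param seed optional integer seed.
#' @return `list(genotypes, mask)` where `mask` is a logical matrix marking
#'   the newly masked cells.
#' @export
mask_genotypes <- function(mat, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  k <- round(fraction * length(mat))
  if (k > 0) {
    idx <- sample.int(length(mat), k)
    mat[idx] <- NA
    mask[idx] <- TRUE
  }
  list(genotypes = mat, mask = mask)
}

#' Blocks of adjacent missing markers in one individual
#'
#' Maximal runs of `NA` calls, each with its flanking non-missing calls; a
#' run touching a chromosome end has a single flank.
#'
#' @param row character vector of calls (`"A"`/`"a"`/`NA`) in map order.
#' @return A data frame with one row per block: `start` and `end` (1-based
#'   inclusive marker indices), `left` and `right` (flanking calls, `NA` at
#'   chromosome ends).
#' @export
#' @examples
#' find_missing_blocks(c("A", NA, NA, "a"))
find_missing_blocks <- function(row) {
  miss <- is.na(row)
  if (!any(miss))
    return(data.frame(start = integer(0), end = integer(0),
                      left = character(0), right = character(0),
                      stringsAsFactors = FALSE))
  rl <- rle(miss)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  starts <- starts[keep]
  ends <- ends[keep]
  data.frame(
    start = starts, end = ends,
    left = ifelse(starts > 1L, row[pmax(starts - 1L, 1L)], NA_character_),
    right = ifelse(ends < length(row), row[pmin(ends + 1L, length(row))],
                   NA_character_),
    stringsAsFactors = FALSE)
}

# complement of an allele vector
.flip_allele <- function(x) ifelse(x == "A", "a", "A")

# Maximum-probability interior fill for a recombinant block, computed on the
# sub-model made of the two flanks plus the interior markers, assuming the
# left flank carries A and the right flank a.  Candidate interior patterns
# are enumerated with the left allele sorting first at every position, and
# the first maximizer is kept, so exact ties resolve toward extending the
# left flank.  Returns interior bits (0 = left-flank allele).
.block_argmax <- function(model, lidx, ridx) {
  loci <- lidx:ridx
  sub <- .model_subset(model, loci)
  sol <- solve_Q(build_reduced_system(
    sub, mode = if (sub$sex_equal) "equal" else "sexdep",
    arithmetic = "double"))
  k <- length(loci) - 2L
  best_p <- -1
  best <- integer(k)
  for (ci in 0:(2^k - 1)) {
    # leftmost interior marker is the most significant bit so candidates
    # with the left-flank allele extend first
    bits <- (ci %/% 2^(k - seq_len(k))) %% 2L
    p <- genotype_probability(sol, c(0L, bits, 1L))
    if (p > best_p + 1e-15) {
      best_p <- p
      best <- bits
    }
  }
  best
}

#' Impute one missing block
#'
#' Applies the exact-probability rule for a single block of adjacent missing
#' markers: with one flank (chromosome end) the flank's call is copied
#' across; with two concordant flanks their shared call fills the block;
#' with two discordant flanks the multilocus genotype probabilities of the
#' flanks-plus-block loci are computed exactly and the maximum-probability
#' genotype compatible with both flank calls determines the fill.  Blocks
#' whose flanks-plus-interior exceed `max_block_loci` loci are split at the
#' genetic midpoint of the flanked interval, each side copying its nearer
#' flank (with a warning).
#'
#' @param block one row of [find_missing_blocks()] (a list or 1-row data
#'   frame with `start`, `end`, `left`, `right`).
#' @param model a [recomb_model()] covering all markers.
#' @param max_block_loci largest number of loci (block plus flanks) solved
#'   exactly; at most 10.
#' @param cache optional environment reusing per-span solutions across rows.
#' @return Character vector of imputed calls for positions
#'   `block$start:block$end`.
#' @export
impute_block <- function(block, model, max_block_loci = 8L, cache = NULL) {
  if (max_block_loci > 10L) stop("max_block_loci must be at most 10")
  n <- block$end - block$start + 1L
  left <- block$left
  right <- block$right
  if (is.na(left) && is.na(right)) {
    warning("block with no flanking calls; filling with \"A\"")
    return(rep("A", n))
  }
  if (is.na(left)) return(rep(right, n))
  if (is.na(right) || left == right) return(rep(left, n))
  # discordant flanks
  lidx <- block$start - 1L
  ridx <- block$end + 1L
  if (n + 2L <= max_block_loci) {
    key <- sprintf("b:%d:%d", lidx, ridx)
    bits <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(bits)) {
      bits <- .block_argmax(model, lidx, ridx)
      if (!is.null(cache)) cache[[key]] <- bits
    }
    calls <- ifelse(bits == 0L, left, .flip_allele(left))
    return(calls)
  }
  # overlong block: split at the genetic midpoint of the flanked interval
  warning("missing block of ", n, " markers exceeds the exact-computation ",
          "cap; splitting at the genetic midpoint", call. = FALSE)
  pos <- model$positions
  if (is.null(pos)) pos <- seq_len(model$L)
  mid <- (pos[lidx] + pos[ridx]) / 2
  ifelse(pos[block$start:block$end] <= mid, left, right)
}

#' Impute all missing calls in a genotype matrix
#'
#' Runs [impute_block()] over every block of every individual.  The result
#' is deterministic: no randomness is involved.  Non-missing cells are never
#' altered.  Exact per-span block solutions are cached and shared across
#' individuals.
#'
#' @param mat character genotype matrix (`"A"`/`"a"`/`NA`), markers in map
#'   order.
#' @param model a [recomb_model()] whose loci match the columns of `mat`.
#' @inheritParams impute_block
#' @return The matrix with every `NA` replaced.
#' @export
impute_matrix <- function(mat, model, max_block_loci = 8L, cache = NULL) {
  if (ncol(mat) != model$L)
    stop("matrix has ", ncol(mat), " markers but the model has ", model$L)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(mat))) {
    blocks <- find_missing_blocks(mat[i, ])
    for (b in seq_len(nrow(blocks)))
      mat[i, blocks$start[b]:blocks$end[b]] <-
        impute_block(blocks[b, ], model, max_block_loci, cache)
  }
  mat
}

#' Imputation error rate
#'
#' Fraction of masked cells whose imputed call differs from the true call.
#'
#' @param imputed,truth character genotype matrices of equal shape.
#' @param mask logical matrix marking the cells that were masked.
#' @return Error rate in \[0, 1\].
#' @export
imputation_error <- function(imputed, truth, mask) {
  if (!identical(dim(imputed), dim(truth)) || !identical(dim(imputed), dim(mask)))
    stop("imputed, truth and mask must have identical dimensions")
  if (!any(mask)) return(0)
  mean(imputed[mask] != truth[mask])
}

#' Imputation benchmark on simulated populations
#'
#' Replicates the simulation design used to assess the exact-probability
#' imputation: for each replicate a random marker map is drawn, a SIB RIL
#' population simulated, and for each missing-data fraction the calls are
#' masked at random, imputed, and scored.  One population per replicate is
#' shared across fractions, and exact block solutions are cached per
#' replicate.
#'
#' @param replicates number of simulated populations.
#' @param n individuals per population.
#' @param n_markers markers per map.
#' @param length_cM chromosome genetic length.
#' @param fractions missing-data fractions to scan.
#' @param seed optional integer seed (one stream drives the whole benchmark).
#' @param max_block_loci exact-computation cap for the benchmark; defaults to
#'   6 loci (block plus flanks) so a full benchmark stays in the minutes
#'   range — longer blocks are split at the genetic midpoint, which changes
#'   measured error rates by well under the replicate-to-replicate spread.
#' @return A data frame with columns `replicate`, `fraction`, `n_masked`,
#'   `error`.
#' @export
benchmark_impute <- function(replicates = 10L, n = 100L, n_markers = 100L,
                             length_cM = 150, fractions = c(.1, .2, .3, .4, .5, .7),
                             seed = NULL, max_block_loci = 6L) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", replicates * length(fractions))
  k <- 0L
  for (rep_i in seq_len(replicates)) {
    map <- random_map(n_markers, length_cM)
    model <- recomb_model(map = map)
    truth <- simulate_population(n, model)
    cache <- new.env(parent = emptyenv())
    for (f in fractions) {
      masked <- mask_genotypes(truth, f)
      imputed <- suppressWarnings(
        impute_matrix(masked$genotypes, model, max_block_loci, cache))
      k <- k + 1L
      out[[k]] <- data.frame(replicate = rep_i, fraction = f,
                             n_masked = sum(masked$mask),
                             error = imputation_error(imputed, truth, masked$mask))
    }
  }
  do.call(rbind, out)
}
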