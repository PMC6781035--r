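# File formats: marker maps (TSV), genotype matrices (CSV), solution
# manifests (JSON).

#' Read a marker map
#'
#' TSV with header columns `marker_id` and `position_cM`; positions must be
#' strictly increasing.
#'
#' @param path file path.
#' @return A data frame with columns `marker_id` and `position_cM`.
#' @export
read_marker_map <- function(path) {
  map <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot read marker map ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!all(c("marker_id", "position_cM") %in% names(map)))
    stop("marker map ", path, " needs header columns marker_id and position_cM")
  if (nrow(map) == 0L) stop("marker map ", path, " is empty")
  pos <- as.numeric(map$position_cM)
  if (anyNA(pos)) stop("non-numeric position_cM in ", path)
  bad <- which(diff(pos) <= 0)
  if (length(bad))
    stop("positions in ", path, " must be strictly increasing; violation at line ",
         bad[1L] + 2L, " (data line ", bad[1L] + 1L, ")")
  data.frame(marker_id = as.character(map$marker_id), position_cM = pos,
             stringsAsFactors = FALSE)
}

#' Write a marker map
#'
#' @param map data frame with columns `marker_id` and `position_cM`.
#' @param path file path.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map[, c("marker_id", "position_cM")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' CSV whose first column holds individual ids and whose remaining columns
#' are markers in map order.  Calls are `"A"`, `"a"`, or the missing token.
#' Heterozygous or otherwise non-parental calls are coerced to missing when
#' `coerce = TRUE` (lines near fixation are treated as fixed, with residual
#' heterozygosity recorded as missing data), and rejected otherwise.
#'
#' @param path file path.
#' @param missing_token token(s) representing missing data (besides empty
#'   cells).
#' @param coerce coerce unknown tokens to missing instead of failing.
#' @return A character matrix with individual ids as rownames.
#' @export
read_genotype_matrix <- function(path, missing_token = "NA", coerce = TRUE) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = "character", na.strings = NULL),
                 error = function(e) stop("cannot read genotypes ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L) stop("genotype file ", path, " needs an id column plus markers")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat[mat %in% c(missing_token, "")] <- NA_character_
  bad <- !is.na(mat) & !mat %in% c("A", "a")
  if (any(bad)) {
    if (!coerce)
      stop("unknown genotype tokens in ", path, ": ",
           paste(unique(mat[bad]), collapse = ", "))
    mat[bad] <- NA_character_
  }
  mat
}

#' Write a genotype matrix
#'
#' @param mat character genotype matrix with individual ids as rownames.
#' @param path file path.
#' @param missing_token written for `NA` calls.
#' @export
write_genotype_matrix <- function(mat, path, missing_token = "NA") {
  out <- mat
  out[is.na(out)] <- missing_token
  df <- data.frame(id = rownames(out) %||% sprintf("RIL%d", seq_len(nrow(out))),
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an IBD solution manifest
#'
#' JSON with the representatives, orbit weights, probabilities (numerators
#' and denominators included for exact solves, so rationals round-trip
#' losslessly), the residual, and the model's rates.
#'
#' @param sol an `"ibd_solution"`.
#' @param path file path.
#' @export
write_ibd_solution <- function(sol, path) {
  obj <- list(
    L = sol$L, mode = sol$mode, arithmetic = sol$arithmetic,
    representatives = apply(sol$reps, 1L, paste, collapse = ","),
    weights = sol$weights, Q = sol$Q,
    residual = sol$residual,
    rf = sol$model$rf, rm = sol$model$rm,
    positions_cM = sol$model$positions)
  if (!is.null(sol$Q_num)) {
    obj$Q_num <- sol$Q_num
    obj$Q_den <- sol$Q_den
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back an IBD solution manifest
#'
#' @param path file path written by [write_ibd_solution()].
#' @return A list mirroring the written fields; `Q` is restored from the
#'   exact numerators/denominators when present.
#' @export
read_ibd_solution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$Q_num)) obj$Q <- obj$Q_num / obj$Q_den
  obj
}
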