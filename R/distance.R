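#' Optimal-matching cost scheme
#'
#' The default is the field's constant cost matrix: every substitution
#' costs `sub` and an insertion or deletion costs `indel`.  A full 5x5
#' symmetric substitution matrix with zero diagonal may be supplied instead.
#'
#' @param sub scalar constant substitution cost, or a 5x5 symmetric
#'   nonnegative matrix with zero diagonal.
#' @param indel positive insertion/deletion cost.
#' @return list of class `cost_scheme` with elements `sub` (5x5 matrix),
#'   `indel`, and `constant` (logical).
#' @export
cost_scheme <- function(sub = 2, indel = 1) {
  n <- length(CAL_STATES)
  if (length(sub) == 1L) {
    m <- matrix(as.numeric(sub), n, n)
    diag(m) <- 0
  } else {
    m <- as.matrix(sub)
    if (!all(dim(m) == n)) stop("substitution matrix must be ", n, "x", n)
    if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
    if (any(diag(m) != 0)) stop("substitution matrix must have zero diagonal")
  }
  if (any(m < 0) || indel <= 0) stop("costs must be nonnegative, indel positive")
  off <- m[upper.tri(m)]
  dimnames(m) <- list(CAL_STATES, CAL_STATES)
  structure(list(sub = m, indel = as.numeric(indel),
                 constant = length(unique(off)) == 1L),
            class = "cost_scheme")
}

as_code_vec <- function(x) {
  if (is.character(x)) x <- state_codes(x)
  as.integer(x)
}

#' Optimal-matching distance between two state sequences
#'
#' Minimum total cost of substitutions, insertions and deletions transforming
#' one sequence into the other, by the standard `(|a|+1) x (|b|+1)` dynamic
#' program.  Symmetric in its arguments.
#'
#' @param a,b integer state-code vectors (1..5) or character state vectors.
#' @param costs a [cost_scheme()].
#' @return Nonnegative scalar distance.
#' @export
#' @examples
#' om_distance(c("NONE","NONE","PREG"), c("NONE","PREG","PREG"))  # 2
om_distance <- function(a, b, costs = cost_scheme()) {
  .om_distance_cpp(as_code_vec(a), as_code_vec(b), costs$sub, costs$indel)
}

#' Reference optimal-matching distance by exhaustive recursion
#'
#' Unmemoized recursion over the full alignment lattice; exponential, guarded
#' to short sequences.  Exists as an independent oracle for [om_distance()].
#'
#' @inheritParams om_distance
#' @param max_len guard on sequence length (default 8).
#' @return Nonnegative scalar distance.
#' @export
om_distance_reference <- function(a, b, costs = cost_scheme(), max_len = 8) {
  a <- as_code_vec(a); b <- as_code_vec(b)
  if (length(a) > max_len || length(b) > max_len)
    stop("reference recursion limited to sequences of length <= ", max_len)
  rec <- function(i, j) {
    if (i == 0L) return(j * costs$indel)
    if (j == 0L) return(i * costs$indel)
    min(rec(i - 1L, j - 1L) + costs$sub[a[i], b[j]],
        rec(i - 1L, j) + costs$indel,
        rec(i, j - 1L) + costs$indel)
  }
  rec(length(a), length(b))
}

#' Pairwise dissimilarity matrix with identical-sequence aggregation
#'
#' Identical sequences are collapsed to one representative whose aggregation
#' weight is the sum of the members' survey weights; the full OM matrix is
#' then computed over the unique sequences only.  This is exact for weighted
#' PAM and all weighted descriptives, and reduces the `O(u^2 L^2)` dynamic
#' program to the unique count `u`.
#'
#' Under a constant scheme with `sub >= 2*indel`, substitutions are never
#' strictly cheaper than a deletion plus an insertion, so the OM distance
#' between equal-length sequences equals `indel*(2L - 2*LLCS)`; a
#' bit-parallel longest-common-subsequence kernel is used in that regime
#' (the 59-month window fits one machine word) and agrees exactly with the
#' dynamic program.
#'
#' @param seqs a `state_seqs` object (or integer matrix of codes).
#' @param weights per-sequence survey weights (default 1).
#' @param costs a [cost_scheme()].
#' @return Object of class `calseg_diss`: list with `d` (u x u symmetric
#'   matrix), `weights` (aggregated, length u), `index` (length n map from
#'   input row to unique row), `ids` (representative case ids), `costs`.
#' @export
pairwise_matrix <- function(seqs, weights = NULL, costs = cost_scheme()) {
  m <- unclass(seqs)
  storage.mode(m) <- "integer"
  n <- nrow(m)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  key <- apply(matrix(CAL_STATE_LETTERS[CAL_STATES[m]], nrow = n), 1,
               paste, collapse = "")
  uniq <- !duplicated(key)
  ukey <- key[uniq]
  index <- match(key, ukey)
  agg_w <- as.numeric(rowsum(weights, index)[, 1])
  um <- m[uniq, , drop = FALSE]
  fast <- costs$constant && costs$sub[1, 2] >= 2 * costs$indel &&
    ncol(um) <= 64
  d <- .om_matrix_cpp(um, costs$sub, costs$indel, fast,
                      length(CAL_STATES))
  ids <- rownames(m)[uniq]
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  structure(list(d = d, weights = agg_w, index = index, ids = ids,
                 costs = costs, n = n),
            class = "calseg_diss")
}

#' @export
print.calseg_diss <- function(x, ...) {
  cat(sprintf(paste0("<calseg_diss: %d unique sequences (from %d), ",
                     "sub %s / indel %g>\n"),
              length(x$weights), x$n,
              if (x$costs$constant) format(x$costs$sub[1, 2]) else "matrix",
              x$costs$indel))
  invisible(x)
}

#' Persist / reload a dissimilarity matrix as delimited text
#'
#' The header records the cost scheme and a content hash of the unique
#' sequences; [read_dissimilarity()] refuses to load a file whose hash does
#' not match the sequences it is given.
#'
#' @param diss a `calseg_diss` object.
#' @param path output path.
#' @export
write_dissimilarity <- function(diss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# calseg_diss u=%d n=%d indel=%g sub=%g hash=%s",
            length(diss$weights), diss$n, diss$costs$indel,
            if (diss$costs$constant) diss$costs$sub[1, 2] else NA,
            diss_hash(diss))), con)
  write.table(cbind(weight = diss$weights, diss$d), con, sep = ",",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

diss_hash <- function(diss) {
  # order-sensitive content checksum of unique ids + weights (plain R, text)
  s <- paste(c(diss$ids, format(sum(diss$weights), digits = 12)),
             collapse = "|")
  v <- utf8ToInt(s)
  format(sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' @rdname write_dissimilarity
#' @param path path written by [write_dissimilarity()].
#' @param diss_check optional `calseg_diss` whose hash must match.
#' @export
read_dissimilarity <- function(path, diss_check = NULL) {
  hdr <- readLines(path, n = 1)
  m <- as.matrix(read.csv(path, skip = 1, header = FALSE))
  w <- m[, 1]
  d <- unname(m[, -1, drop = FALSE])
  out <- list(d = d, weights = w, header = hdr)
  if (!is.null(diss_check)) {
    h <- sub(".*hash=([0-9]+).*", "\\1", hdr)
    if (!identical(h, diss_hash(diss_check)))
      stop("stored dissimilarity header does not match the supplied sequences")
  }
  out
}
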