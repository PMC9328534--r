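#' Weighted k-medoid (PAM) clustering of a dissimilarity matrix
#'
#' Partitioning around medoids with observation weights: a greedy BUILD
#' phase (each new medoid maximizes the weighted reduction of total cost)
#' followed by a SWAP phase that repeatedly applies the best strictly
#' improving medoid/non-medoid exchange until none exists.  All ties are
#' broken by lowest index, so the result is deterministic for a given matrix.
#'
#' Weights enter as aggregation multiplicities: clustering a deduplicated
#' matrix with summed weights is exactly equivalent to clustering the
#' duplicated observations unweighted.
#'
#' On small matrices (u <= 50 by default) the search is restarted with each
#' point forced as the initial BUILD medoid and the best objective kept, a
#' deterministic multi-start that escapes the occasional local optimum of
#' single-start PAM; large matrices use the canonical single BUILD.
#'
#' @param dissim a `calseg_diss` from [pairwise_matrix()], or a plain
#'   symmetric matrix.
#' @param k number of clusters, `1 <= k <= u`.
#' @param weights optional weights when `dissim` is a plain matrix.
#' @param maxit SWAP iteration cap (guards exact-tie cycling).
#' @param restarts number of forced-first-medoid restarts; `NULL` chooses
#'   `u` when `u <= 50` and 1 otherwise.
#' @return Object of class `pam_solution`: `k`, `medoids` (unique-sequence
#'   indices), `assignment` (per unique sequence, values 1..k), `objective`
#'   (weighted sum of distances to assigned medoids), `iterations`.
#' @export
pam <- function(dissim, k, weights = NULL, maxit = 500, restarts = NULL) {
  d <- if (inherits(dissim, "calseg_diss")) dissim$d else as.matrix(dissim)
  w <- if (inherits(dissim, "calseg_diss")) dissim$weights
       else if (is.null(weights)) rep(1, nrow(d)) else weights
  u <- nrow(d)
  if (k < 1 || k > u) stop("k must be between 1 and the number of unique sequences (", u, ")")
  if (is.null(restarts)) restarts <- if (u <= 50) u else 1L
  res <- .pam_cpp(d, as.numeric(w), as.integer(k), as.integer(maxit),
                  as.integer(restarts))
  if (res$iterations >= maxit)
    warning("SWAP phase hit the iteration cap (", maxit, ") without converging")
  structure(list(k = as.integer(k), medoids = res$medoids,
                 assignment = res$assignment, objective = res$objective,
                 iterations = res$iterations, weights = as.numeric(w)),
            class = "pam_solution")
}

#' @export
print.pam_solution <- function(x, ...) {
  cat(sprintf("<pam_solution: k=%d, objective=%.4f, %d swap iterations>\n",
              x$k, x$objective, x$iterations))
  cat("medoid indices:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' Weighted silhouette widths
#'
#' For each unique sequence `i`, `s_i = (b_i - a_i) / max(a_i, b_i)` where
#' `a_i` is the weighted mean distance to its own cluster (self excluded in
#' a weight-corrected way: denominator `W_own - w_i`) and `b_i` the smallest
#' weighted mean distance to another cluster.  Singletons get `s_i = 0`.
#' Invariant to rescaling all weights.
#'
#' @param dissim `calseg_diss` or plain matrix.
#' @param solution a [pam()] solution (or any list with `assignment`, `k`).
#' @param weights optional, as in [pam()].
#' @return Numeric vector of widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(dissim, solution, weights = NULL) {
  d <- if (inherits(dissim, "calseg_diss")) dissim$d else as.matrix(dissim)
  w <- if (inherits(dissim, "calseg_diss")) dissim$weights
       else if (is.null(weights)) rep(1, nrow(d)) else weights
  if (solution$k < 2) stop("silhouette requires k >= 2")
  .silhouette_cpp(d, as.numeric(w), as.integer(solution$assignment),
                  as.integer(solution$k))
}

#' Cluster-quality metrics: ASW, PBC and Hubert's Gamma
#'
#' * ASW: weighted mean silhouette width.
#' * PBC: weighted Pearson correlation between the pairwise distances and
#'   the different-cluster indicator (positive when distant pairs straddle
#'   clusters).
#' * HG: `(s+ - s-)/(s+ + s-)` over weighted pairs of (within, between)
#'   distance pairs; concordant when the between-cluster distance is the
#'   larger, ties counted in neither.
#'
#' All three lie in `[-1, 1]` and are invariant to rescaling all weights.
#' If every distance is identical the metrics are defined as 0 with a
#' warning.
#'
#' @inheritParams silhouette_widths
#' @return Named numeric vector `c(ASW, PBC, HG)`.
#' @export
quality_metrics <- function(dissim, solution, weights = NULL) {
  d <- if (inherits(dissim, "calseg_diss")) dissim$d else as.matrix(dissim)
  w <- if (inherits(dissim, "calseg_diss")) dissim$weights
       else if (is.null(weights)) rep(1, nrow(d)) else weights
  if (solution$k < 2) stop("quality metrics require k >= 2")
  s <- silhouette_widths(d, solution, w)
  asw <- sum(w * s) / sum(w)
  ph <- .pbc_hg_cpp(d, as.numeric(w), as.integer(solution$assignment))
  if (isTRUE(ph$degenerate))
    warning("degenerate distance structure; affected metrics set to 0")
  c(ASW = asw, PBC = ph$pbc, HG = ph$hg)
}

#' Sweep k and select the number of clusters by a quality criterion
#'
#' Fits [pam()] for every `k` in `k_range`, computes ASW, PBC and HG for
#' each, and selects the `k` maximizing the chosen criterion (smallest k on
#' ties).  The full metric table is retained so the choice can be reviewed
#' rather than trusted blindly.
#'
#' @inheritParams pam
#' @param k_range integer vector of candidate k (subset of `2..u-1`).
#' @param criterion one of `"ASW"`, `"PBC"`, `"HG"`.
#' @return Object of class `quality_report`: `table` (data.frame k x
#'   metrics), `selected_k`, `criterion`, `solutions` (list keyed by k).
#' @export
select_k <- function(dissim, k_range = 2:10, criterion = c("ASW", "PBC", "HG"),
                     weights = NULL, maxit = 500) {
  criterion <- match.arg(criterion)
  d <- if (inherits(dissim, "calseg_diss")) dissim$d else as.matrix(dissim)
  u <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= u - 1]
  if (length(k_range) == 0) {
    warning("degenerate input: no candidate k in 2..u-1; selection abstains")
    return(structure(list(table = data.frame(), selected_k = NA_integer_,
                          criterion = criterion, solutions = list()),
                     class = "quality_report"))
  }
  rows <- vector("list", length(k_range))
  sols <- vector("list", length(k_range))
  degenerate <- FALSE
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    sol <- pam(dissim, k, weights = weights, maxit = maxit)
    qm <- withCallingHandlers(
      quality_metrics(dissim, sol, weights = weights),
      warning = function(w) {
        degenerate <<- TRUE
        invokeRestart("muffleWarning")
      })
    rows[[i]] <- data.frame(k = k, ASW = qm[["ASW"]], PBC = qm[["PBC"]],
                            HG = qm[["HG"]], objective = sol$objective)
    sols[[i]] <- sol
  }
  tab <- do.call(rbind, rows)
  names(sols) <- as.character(k_range)
  if (degenerate || all(!is.finite(tab[[criterion]]))) {
    warning("degenerate structure in the k sweep; selection abstains")
    selected <- NA_integer_
  } else {
    selected <- tab$k[which.max(tab[[criterion]])]
  }
  structure(list(table = tab, selected_k = selected, criterion = criterion,
                 solutions = sols),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report: criterion %s, selected k = %s>\n",
              x$criterion, format(x$selected_k)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Exhaustive-search PAM optimum (test oracle)
#'
#' Brute force over all `choose(u, k)` medoid subsets; guarded to small
#' problems.  Used to certify [pam()] optimality on random instances.
#'
#' @inheritParams pam
#' @param max_u guard on matrix size.
#' @return list `medoids`, `objective`.
#' @export
pam_exhaustive <- function(dissim, k, weights = NULL, max_u = 10) {
  d <- if (inherits(dissim, "calseg_diss")) dissim$d else as.matrix(dissim)
  w <- if (inherits(dissim, "calseg_diss")) dissim$weights
       else if (is.null(weights)) rep(1, nrow(d)) else weights
  u <- nrow(d)
  if (u > max_u) stop("exhaustive search limited to u <= ", max_u)
  sets <- utils::combn(u, k)
  best <- NULL; bestv <- Inf
  for (j in seq_len(ncol(sets))) {
    med <- sets[, j]
    v <- sum(w * apply(d[, med, drop = FALSE], 1, min))
    if (v < bestv - 1e-12) { bestv <- v; best <- med }
  }
  list(medoids = best, objective = bestv)
}

#' Map each woman to her cluster
#'
#' Expands a unique-sequence assignment back to the full sample via the
#' deduplication index.
#' @param dissim the `calseg_diss` the solution was fit on.
#' @param solution a [pam()] solution.
#' @return Integer vector of cluster ids, one per original woman.
#' @export
expand_assignment <- function(dissim, solution) {
  stopifnot(inherits(dissim, "calseg_diss"))
  solution$assignment[dissim$index]
}
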