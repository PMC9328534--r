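#' Weighted cross-sectional state distribution
#'
#' Share of each of the five states at each of the 59 months, weighted by
#' survey weight.  Rows (months) sum to one.
#'
#' @param seqs `state_seqs` or integer code matrix.
#' @param weights per-sequence weights (default 1).
#' @return 59 x 5 matrix, columns named by [CAL_STATES].
#' @export
state_distribution <- function(seqs, weights = NULL) {
  m <- unclass(seqs)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  W <- sum(weights)
  out <- vapply(seq_along(CAL_STATES),
                function(s) colSums(weights * (m == s)) / W,
                numeric(ncol(m)))
  colnames(out) <- CAL_STATES
  rownames(out) <- paste0("m", seq_len(nrow(out)))
  out
}

#' Weighted mean months spent in each state
#'
#' Sums to the window length (59).  Algebraically equal to the column sums
#' of [state_distribution()].
#'
#' @inheritParams state_distribution
#' @return Named numeric vector of length 5.
#' @export
mean_time <- function(seqs, weights = NULL) {
  m <- unclass(seqs)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  W <- sum(weights)
  vapply(setNames(seq_along(CAL_STATES), CAL_STATES),
         function(s) sum(weights * rowSums(m == s)) / W, 0)
}

#' Cross-sectional Shannon entropy of a state distribution
#'
#' `-sum(p log p)`, by default normalized by `log(5)` so that a degenerate
#' month scores 0 and a uniform month scores 1.
#'
#' @param p probability vector (a month row of [state_distribution()]).
#' @param normalize divide by `log(length(p))`.
#' @return Scalar in `[0, 1]` (normalized) or `[0, log 5]` (raw).
#' @export
cross_sectional_entropy <- function(p, normalize = TRUE) {
  if (abs(sum(p) - 1) > 1e-8) stop("distribution must sum to 1")
  nz <- p[p > 0]
  h <- -sum(nz * log(nz))
  if (normalize) h / log(length(p)) else h
}

# distinct-successive-states view of one sequence
dss <- function(x) {
  r <- rle(as.integer(x))
  list(states = r$values, durations = r$lengths)
}

# number of distinct subsequences (including the empty one) of a vector,
# standard DP with last-occurrence correction
count_distinct_subsequences <- function(x) {
  n <- length(x)
  dp <- numeric(n + 1)
  dp[1] <- 1
  last <- integer(0)
  for (i in seq_len(n)) {
    dp[i + 1] <- 2 * dp[i]
    key <- as.character(x[i])
    prev <- last[key]
    if (!is.na(prev)) dp[i + 1] <- dp[i + 1] - dp[prev]
    last[key] <- i
  }
  dp[n + 1]
}

# brute-force subsequence count for tiny inputs (test oracle)
count_distinct_subsequences_naive <- function(x) {
  n <- length(x)
  seen <- character(0)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    seen <- union(seen, paste(x[idx], collapse = ","))
  }
  length(seen)
}

#' Sequence turbulence
#'
#' Elzinga's complexity measure
#' `T(x) = log2( phi(x) * (s2_max + 1) / (s2 + 1) )` where `phi(x)` is the
#' number of distinct subsequences (including the empty one) of the
#' distinct-successive-states sequence, `s2` the variance of the spell
#' durations and `s2_max` the maximum attainable variance given the number
#' of spells and total length (all spells minimal except one).  A constant
#' sequence scores `log2(2) = 1`.
#'
#' @param x one sequence: integer codes or character states.
#' @return Nonnegative scalar.
#' @export
turbulence <- function(x) {
  if (is.character(x)) x <- state_codes(x)
  d <- dss(x)
  phi <- count_distinct_subsequences(d$states)
  m <- length(d$durations)
  tbar <- mean(d$durations)
  s2 <- sum((d$durations - tbar)^2) / m
  # max variance: m-1 spells of one month, one spell taking the rest,
  # at the same mean
  s2max <- (m - 1) * (tbar - 1)^2
  log2(phi * (s2max + 1) / (s2 + 1))
}

#' Per-cluster descriptive statistics
#'
#' Assembles, for each cluster of a PAM solution: the weighted monthly state
#' distribution, weighted mean time per state, the monthly entropy profile,
#' the weighted mean turbulence, the medoid sequence, and the cluster's
#' share of total weight.
#'
#' @param seqs the full (non-deduplicated) `state_seqs`.
#' @param weights per-woman survey weights.
#' @param dissim the `calseg_diss` the solution was fit on (provides the
#'   woman -> unique-sequence map).
#' @param solution a [pam()] solution on `dissim`.
#' @return Object of class `cluster_descriptives`: list with `clusters`
#'   (per-cluster list: `n`, `share`, `state_distribution`, `mean_time`,
#'   `entropy`, `mean_turbulence`, `medoid`), plus tidy plot-ready
#'   data.frames `distribution_table` (cluster, month, state, share),
#'   `mean_time_table`, `entropy_table` and `medoid_table`.
#' @export
describe_clusters <- function(seqs, weights, dissim, solution) {
  m <- unclass(seqs)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  asgn <- expand_assignment(dissim, solution)
  stopifnot(length(asgn) == nrow(m))
  W <- sum(weights)
  # per-unique-sequence turbulence, expanded by index
  # rows of first occurrence appear in unique-id order by construction
  turb_u <- apply(m[!duplicated(dissim$index), , drop = FALSE], 1, turbulence)
  turb <- turb_u[dissim$index]
  clusters <- list()
  dist_rows <- list(); mt_rows <- list(); ent_rows <- list(); med_rows <- list()
  for (c in seq_len(solution$k)) {
    sel <- asgn == c
    if (!any(sel)) stop("empty cluster ", c, " (impossible under PAM)")
    sd_c <- state_distribution(m[sel, , drop = FALSE], weights[sel])
    mt_c <- mean_time(m[sel, , drop = FALSE], weights[sel])
    ent_c <- apply(sd_c, 1, cross_sectional_entropy)
    med_idx <- solution$medoids[c]
    medoid <- unclass(seqs)[match(med_idx, dissim$index), ]
    wt <- sum(weights[sel] * turb[sel]) / sum(weights[sel])
    clusters[[c]] <- list(
      n = sum(sel), share = sum(weights[sel]) / W,
      state_distribution = sd_c, mean_time = mt_c, entropy = ent_c,
      mean_turbulence = wt, medoid = medoid)
    dist_rows[[c]] <- data.frame(
      cluster = c, month = rep(seq_len(nrow(sd_c)), ncol(sd_c)),
      state = rep(colnames(sd_c), each = nrow(sd_c)),
      share = as.vector(sd_c))
    mt_rows[[c]] <- data.frame(cluster = c, state = names(mt_c),
                               months = unname(mt_c))
    ent_rows[[c]] <- data.frame(cluster = c, month = seq_along(ent_c),
                                entropy = unname(ent_c))
    med_rows[[c]] <- data.frame(cluster = c, month = seq_along(medoid),
                                state = CAL_STATES[medoid])
  }
  structure(list(clusters = clusters,
                 distribution_table = do.call(rbind, dist_rows),
                 mean_time_table = do.call(rbind, mt_rows),
                 entropy_table = do.call(rbind, ent_rows),
                 medoid_table = do.call(rbind, med_rows)),
            class = "cluster_descriptives")
}

#' @export
print.cluster_descriptives <- function(x, ...) {
  cat("<cluster_descriptives:", length(x$clusters), "clusters>\n")
  for (c in seq_along(x$clusters)) {
    cl <- x$clusters[[c]]
    cat(sprintf("  cluster %d: share %.1f%%, n %d, mean turbulence %.2f\n",
                c, 100 * cl$share, cl$n, cl$mean_turbulence))
  }
  invisible(x)
}

#' Match clusters to archetypes by medoid distance
#'
#' Finds the assignment of cluster medoids to archetype sequences minimizing
#' the total OM distance (exhaustive over permutations; k <= 8).
#'
#' @param seqs,dissim,solution as in [describe_clusters()].
#' @param archetypes list as from [default_archetypes()].
#' @param costs a [cost_scheme()].
#' @return Integer vector: for each cluster, the matched archetype index;
#'   names are archetype names.
#' @export
match_clusters_to_archetypes <- function(seqs, dissim, solution,
                                         archetypes = default_archetypes(),
                                         costs = cost_scheme()) {
  k <- solution$k
  if (k > 8) stop("permutation matching limited to k <= 8")
  med_states <- lapply(solution$medoids, function(mi)
    unclass(seqs)[match(mi, dissim$index), ])
  arch_states <- lapply(archetypes, archetype_states)
  dmat <- matrix(0, k, length(arch_states))
  for (i in seq_len(k))
    for (j in seq_along(arch_states))
      dmat[i, j] <- om_distance(med_states[[i]], arch_states[[j]], costs)
  if (k > length(arch_states)) stop("more clusters than archetypes")
  perms <- permutations_of(seq_along(arch_states), k)
  costs_tot <- vapply(perms, function(p) sum(dmat[cbind(seq_len(k), p)]), 0)
  best <- perms[[which.min(costs_tot)]]
  setNames(best, names(archetypes)[best])
}

permutations_of <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i], k - 1)
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}
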