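test_that("pam recovers trivial and tightly separated structure", {
  # k = u: every point its own medoid, objective 0
  set.seed(1)
  d <- rand_diss(5)
  sol <- pam(d, 5)
  expect_equal(sol$objective, 0)
  expect_setequal(sol$medoids, 1:5)
  # two tight pairs, k = 2: one medoid per pair
  d2 <- matrix(10, 4, 4); diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- 0.1
  d2[3, 4] <- d2[4, 3] <- 0.1
  sol2 <- pam(d2, 2)
  expect_equal(sort(sol2$assignment), c(1, 1, 2, 2))
  expect_equal(sol2$assignment[1], sol2$assignment[2])
  expect_equal(sol2$assignment[3], sol2$assignment[4])
  expect_equal(sol2$objective, 0.2)
  expect_error(pam(d2, 5), "between 1")
})

test_that("pam attains the exhaustive-search optimum on random instances", {
  set.seed(77)
  for (r in 1:25) {
    u <- sample(4:8, 1)
    k <- sample(2:3, 1)
    d <- rand_diss(u)
    w <- runif(u, 0.5, 2)
    sol <- pam(d, k, weights = w)
    opt <- pam_exhaustive(d, k, weights = w)
    expect_equal(sol$objective, opt$objective, tolerance = 1e-10)
  }
})

test_that("pam agrees with the reference implementation on separated data", {
  skip_if_not_installed("cluster")
  gen <- small_gen(120, seed = 33)
  conv <- suppressMessages(records_to_sequences(gen$records))
  diss <- pairwise_matrix(conv$seqs)
  # compare unweighted over the unique sequences (cluster::pam has no weights)
  sol <- pam(diss$d, 6, restarts = 10)
  ref <- cluster::pam(stats::as.dist(diss$d), k = 6, diss = TRUE)
  expect_equal(truth_assignment_accuracy(ref$clustering, sol$assignment), 1)
  ref_obj <- sum(apply(diss$d[, sort(ref$id.med), drop = FALSE], 1, min))
  expect_equal(sol$objective, ref_obj, tolerance = 1e-10)
})

test_that("weighted pam equals unweighted pam on duplicated observations", {
  set.seed(12)
  u <- 7
  d <- rand_diss(u)
  mult <- sample(1:3, u, replace = TRUE)
  idx <- rep(1:u, mult)
  ddup <- d[idx, idx]
  for (k in 2:3) {
    sw <- pam(d, k, weights = mult)
    sd <- pam(ddup, k)
    expect_equal(sw$objective, sd$objective, tolerance = 1e-10)
    expect_equal(sw$assignment[idx], sd$assignment, ignore_attr = TRUE)
  }
})

test_that("silhouette widths match hand computation and the reference", {
  # perfect separation: within 0, between 1
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  sol <- list(assignment = c(1, 1, 2, 2), k = 2)
  expect_equal(silhouette_widths(d, sol), rep(1, 4))

  # worked 4-point fixture
  dm <- matrix(c(0, 1, 4, 5,
                 1, 0, 3, 4,
                 4, 3, 0, 2,
                 5, 4, 2, 0), 4, 4, byrow = TRUE)
  s <- silhouette_widths(dm, list(assignment = c(1, 1, 2, 2), k = 2))
  # a = (1,1,2,2); b = ((4+5)/2, (3+4)/2, (4+3)/2, (5+4)/2)
  expect_equal(s, c((4.5 - 1) / 4.5, (3.5 - 1) / 3.5,
                    (3.5 - 2) / 3.5, (4.5 - 2) / 4.5))
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(c(1, 1, 2, 2), dmatrix = dm)[, "sil_width"]
  expect_equal(s, as.numeric(ref))
})

test_that("a point equidistant to both clusters has zero width", {
  # point 5 sits exactly between two tight pairs
  d <- matrix(4, 5, 5); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  d[5, ] <- d[, 5] <- 2; d[5, 5] <- 0
  s <- silhouette_widths(d, list(assignment = c(1, 1, 2, 2, 1), k = 2))
  expect_equal(s[5], 0)
})

test_that("quality metrics hit their limiting cases", {
  d <- matrix(1, 6, 6); diag(d) <- 0
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) d[p[1], p[2]] <- d[p[2], p[1]] <- 0
  sol <- list(assignment = rep(1:3, each = 2), k = 3)
  qm <- quality_metrics(d, sol)
  expect_equal(unname(qm["ASW"]), 1)
  expect_equal(unname(qm["PBC"]), 1)
  expect_equal(unname(qm["HG"]), 1)
  # degenerate: all distances equal
  dd <- matrix(3, 4, 4); diag(dd) <- 0
  expect_warning(qd <- quality_metrics(dd, list(assignment = c(1, 1, 2, 2),
                                                k = 2)), "degenerate")
  expect_equal(unname(qd["PBC"]), 0)
  expect_equal(unname(qd["HG"]), 0)
})

test_that("quality metrics are near zero under random assignment", {
  set.seed(21)
  d <- rand_diss(100)
  sol <- list(assignment = sample(1:4, 100, replace = TRUE), k = 4)
  qm <- quality_metrics(d, sol)
  expect_lt(abs(qm[["PBC"]]), 0.1)
  expect_lt(abs(qm[["HG"]]), 0.1)
  expect_lt(abs(qm[["ASW"]]), 0.1)
})

test_that("PBC equals the direct weighted correlation on a fixture", {
  set.seed(8)
  d <- rand_diss(5)
  w <- c(1, 2, 1, 3, 1)
  asgn <- c(1, 1, 2, 2, 2)
  qm <- quality_metrics(d, list(assignment = asgn, k = 2), weights = w)
  # direct computation over the 10 pairs
  xs <- c(); ys <- c(); ws <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    xs <- c(xs, d[i, j]); ys <- c(ys, as.numeric(asgn[i] != asgn[j]))
    ws <- c(ws, w[i] * w[j])
  }
  wm <- function(v) sum(ws * v) / sum(ws)
  r <- sum(ws * (xs - wm(xs)) * (ys - wm(ys))) /
    sqrt(sum(ws * (xs - wm(xs))^2) * sum(ws * (ys - wm(ys))^2))
  expect_equal(unname(qm["PBC"]), r, tolerance = 1e-12)
})

test_that("Hubert's Gamma matches a brute-force pair-of-pairs count", {
  set.seed(13)
  d <- rand_diss(8)
  w <- runif(8, 0.5, 2)
  asgn <- sample(1:3, 8, replace = TRUE)
  while (length(unique(asgn)) < 2) asgn <- sample(1:3, 8, replace = TRUE)
  qm <- quality_metrics(d, list(assignment = asgn, k = 3), weights = w)
  xs <- c(); same <- c(); ws <- c()
  n <- 8
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    xs <- c(xs, d[i, j]); same <- c(same, asgn[i] == asgn[j])
    ws <- c(ws, w[i] * w[j])
  }
  splus <- 0; sminus <- 0
  for (a in seq_along(xs)) for (b in seq_along(xs)) {
    if (same[a] && !same[b]) {
      if (xs[b] > xs[a]) splus <- splus + ws[a] * ws[b]
      if (xs[b] < xs[a]) sminus <- sminus + ws[a] * ws[b]
    }
  }
  expect_equal(unname(qm["HG"]), (splus - sminus) / (splus + sminus),
               tolerance = 1e-12)
})

test_that("quality metrics are invariant to weight rescaling", {
  set.seed(4)
  d <- rand_diss(12)
  w <- runif(12, 0.5, 3)
  sol <- pam(d, 3, weights = w)
  q1 <- quality_metrics(d, sol, weights = w)
  q2 <- quality_metrics(d, sol, weights = w * 137.5)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("select_k sweeps the range and reports one row per k", {
  gen <- small_gen(150, seed = 55)
  conv <- suppressMessages(records_to_sequences(gen$records))
  diss <- pairwise_matrix(conv$seqs, conv$records$weight)
  rep <- select_k(diss, 2:8)
  expect_equal(rep$table$k, 2:8)
  expect_equal(rep$selected_k, 6)
  expect_true(all(abs(rep$table$ASW) <= 1))
  expect_true(all(abs(rep$table$HG) <= 1 + 1e-12))
})

test_that("select_k abstains on degenerate input", {
  gen <- generate(generator_config(n_women = 20, noise_sub_prob = 0,
                                   jitter_max = 0,
                                   mixture_weights = c(
                                     "Quiet Calendar" = 1, "Family Builder 1" = 0,
                                     "Family Builder 2" = 0, "Modern Mother" = 0,
                                     "Consistently Covered Mother" = 0,
                                     "Traditional Mother" = 0),
                                   effect_spec = NULL, seed = 2))
  conv <- suppressMessages(records_to_sequences(gen$records))
  diss <- pairwise_matrix(conv$seqs)
  expect_warning(rep <- select_k(diss, 2:10), "abstain")
  expect_true(is.na(rep$selected_k))
})

test_that("cluster recovery is strong at low noise and labels are stable", {
  gen <- small_gen(400, seed = 91, noise = 0.05)
  conv <- suppressMessages(records_to_sequences(gen$records))
  diss <- pairwise_matrix(conv$seqs, conv$records$weight)
  sol <- pam(diss, 6)
  asgn <- expand_assignment(diss, sol)
  expect_gte(truth_assignment_accuracy(gen$truth$cluster, asgn), 0.85)
})
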