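make_design <- function(n, weight = rep(1, n)) {
  svy_design(weight, psu = seq_len(n), stratum = rep(1L, n))
}

test_that("2x2 fixture recovers the closed-form odds ratio", {
  # cells: (x=0,y=1)=10, (x=0,y=0)=20, (x=1,y=1)=20, (x=1,y=0)=10
  dat <- data.frame(
    x = factor(rep(c("a", "b"), c(30, 30))),
    y = c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10)))
  fit <- fit_membership(y ~ x, dat, make_design(60))
  # OR for x=b vs a: (20/10) / (10/20) = 4; for the transposed layout
  expect_equal(unname(fit$odds_ratios["xb"]), (20 * 20) / (10 * 10),
               tolerance = 1e-8)
  dat$y2 <- 1 - dat$y
  fit2 <- fit_membership(y2 ~ x, dat, make_design(60))
  expect_equal(unname(fit2$odds_ratios["xb"]), (10 * 10) / (20 * 20),
               tolerance = 1e-8)
  expect_equal(unname(coef(glm(y2 ~ x, binomial(), dat))["xb"]),
               log(0.25), tolerance = 1e-8)
})

test_that("unweighted one-PSU-per-row fit equals independent ML and HC1", {
  set.seed(61)
  n <- 400
  dat <- data.frame(x1 = rnorm(n), x2 = factor(sample(c("u", "v"), n, TRUE)))
  eta <- -0.3 + 0.8 * dat$x1 + 0.5 * (dat$x2 == "v")
  dat$y <- rbinom(n, 1, plogis(eta))
  fit <- fit_membership(y ~ x1 + x2, dat, make_design(n))

  # independent optimizer on the hand-coded log-likelihood
  X <- model.matrix(~ x1 + x2, dat)
  nll <- function(b) {
    lp <- drop(X %*% b)
    -sum(dat$y * lp - log1p(exp(lp)))
  }
  opt <- optim(rep(0, 3), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)

  skip_if_not_installed("sandwich")
  gfit <- glm(y ~ x1 + x2, binomial(), dat)
  vc <- sandwich::vcovHC(gfit, type = "HC1")
  expect_equal(unname(fit$vcov), unname(vc), tolerance = 1e-6)
})

test_that("estimates and linearized covariance are weight-scale invariant", {
  set.seed(62)
  n <- 200
  dat <- data.frame(x = rnorm(n))
  dat$y <- rbinom(n, 1, plogis(0.4 * dat$x))
  w <- runif(n, 0.5, 3)
  psu <- rep(1:40, each = 5); stratum <- rep(1:8, each = 25)
  f1 <- fit_membership(y ~ x, dat, svy_design(w, psu, stratum))
  f2 <- fit_membership(y ~ x, dat, svy_design(w * 1000, psu, stratum))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-10)
  expect_equal(f1$df, 40 - 8)
})

test_that("stratified PSU aggregation shrinks or grows variance sensibly", {
  set.seed(63)
  n <- 600
  psu <- rep(1:60, each = 10)
  stratum <- rep(1:6, each = 100)
  # cluster-level random effect induces intra-PSU correlation
  re <- rnorm(60, sd = 0.8)[psu]
  dat <- data.frame(x = rnorm(n))
  dat$y <- rbinom(n, 1, plogis(0.3 * dat$x + re))
  des <- svy_design(rep(1, n), psu, stratum)
  fit <- fit_membership(y ~ x, dat, des)
  # naive iid covariance from glm
  g <- glm(y ~ x, binomial(), dat)
  se_naive <- sqrt(diag(vcov(g)))
  # with positive ICC the design-based intercept SE must exceed the naive one
  expect_gt(fit$se[["(Intercept)"]], se_naive[["(Intercept)"]])
  expect_equal(fit$df, 60 - 6)
})

test_that("singleton-PSU strata are collapsed with a warning", {
  w <- rep(1, 30)
  psu <- c(rep(1:4, each = 7), 5, 6)
  stratum <- c(rep(1:2, each = 14), 3, 3)
  expect_silent(svy_design(w, psu, stratum))
  stratum2 <- c(rep(1:2, each = 14), 3, 4)  # strata 3 and 4 have one PSU each
  ws <- testthat::capture_warnings(des <- svy_design(w, psu, stratum2))
  expect_true(any(grepl("single PSU", ws)))
  expect_lt(length(unique(des$stratum)), 4)
})

test_that("perfect separation and empty cells raise advisory errors", {
  dat <- data.frame(x = factor(rep(c("a", "b"), each = 20)),
                    y = rep(c(0, 1), each = 20))
  expect_error(fit_membership(y ~ x, dat, make_design(40)), "separation")
  # aliased factor combination
  dat2 <- data.frame(x = factor(rep(c("a", "b"), each = 10)))
  dat2$z <- dat2$x  # duplicate of x
  dat2$y <- rep(c(0, 1), 10)
  expect_error(fit_membership(y ~ x + z, dat2, make_design(20)),
               "empty or aliased")
})

test_that("fit_all_clusters produces a term-by-cluster OR table", {
  gen <- small_gen(600, seed = 71)
  conv <- suppressMessages(records_to_sequences(gen$records))
  diss <- pairwise_matrix(conv$seqs, conv$records$weight)
  sol <- pam(diss, 6)
  asgn <- expand_assignment(diss, sol)
  des <- svy_design(conv$records$weight, conv$records$psu,
                    conv$records$stratum)
  res <- suppressWarnings(
    fit_all_clusters(asgn, ~ education + knowledge, conv$records, des))
  expect_s3_class(res, "membership_models")
  fitted <- !vapply(res$models, is.null, TRUE)
  expect_gte(sum(fitted), 4)  # small clusters may legitimately fail
  expect_true(!is.null(res$or_table))
  # one row per term incl. intercept: 1 + 2 (education) + 1 (knowledge)
  expect_equal(nrow(res$or_table), 4)
  or_cols <- grep("^OR_", names(res$or_table))
  expect_equal(length(or_cols), sum(fitted))
})

test_that("confidence intervals cover a null effect at the nominal rate", {
  set.seed(81)
  hits <- 0; reps <- 20
  for (r in 1:reps) {
    n <- 800
    dat <- data.frame(x = rnorm(n), z = factor(sample(c("p", "q"), n, TRUE)))
    dat$y <- rbinom(n, 1, plogis(0.5 * dat$x))  # z has zero true effect
    psu <- rep(1:80, each = 10); stratum <- rep(1:8, each = 100)
    fit <- fit_membership(y ~ x + z, dat,
                          svy_design(runif(n, 0.5, 2), psu, stratum))
    ci <- fit$coefficients["zq"] +
      c(-1, 1) * stats::qt(0.975, fit$df) * fit$se["zq"]
    if (ci[1] <= 0 && ci[2] >= 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)  # 95% nominal; binomial wiggle at 20 reps
})

test_that("collinearity diagnostics match closed forms", {
  # orthogonal balanced design
  dat <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")))
  dat <- dat[rep(1:4, 10), ]
  chk <- collinearity_check(~ a + b, dat)
  expect_equal(unname(chk$vif), c(1, 1), tolerance = 1e-10)
  expect_false(chk$singular)

  # duplicated column flags singularity
  dat$c <- dat$a
  expect_warning(chk2 <- collinearity_check(~ a + b + c, dat),
                 "linear dependence")
  expect_true(chk2$singular)

  # correlated continuous pair: VIF = 1/(1 - r^2)
  set.seed(91)
  x1 <- rnorm(500)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(500)
  dat3 <- data.frame(x1 = x1, x2 = x2)
  chk3 <- collinearity_check(~ x1 + x2, dat3)
  r2 <- stats::cor(x1, x2)^2
  expect_equal(unname(chk3$vif), rep(1 / (1 - r2), 2), tolerance = 1e-8)
})
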