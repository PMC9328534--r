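#' Complex survey design descriptor
#'
#' Weights, primary sampling units and strata for design-based (Taylor
#' linearized) variance estimation.  Strata containing a single PSU with
#' observations are collapsed into the nearest stratum (by stratum id) with
#' a warning — the common certainty-unit fix.
#'
#' @param weight positive survey weights.
#' @param psu PSU identifiers.
#' @param stratum stratum identifiers (default: one stratum).
#' @return Object of class `svy_design`.
#' @export
svy_design <- function(weight, psu, stratum = NULL) {
  n <- length(weight)
  if (is.null(stratum)) stratum <- rep(1L, n)
  stopifnot(length(psu) == n, length(stratum) == n, all(weight > 0))
  stratum <- as.character(stratum)
  psu <- paste(stratum, psu, sep = ".")
  # collapse singleton-PSU strata
  repeat {
    tab <- tapply(psu, stratum, function(x) length(unique(x)))
    singles <- names(tab)[tab < 2]
    if (length(singles) == 0 || length(tab) == 1) break
    s <- singles[1]
    others <- setdiff(names(tab), s)
    target <- others[which.min(abs(match(others, sort(names(tab))) -
                                     match(s, sort(names(tab)))))]
    warning("stratum '", s, "' has a single PSU; collapsed into stratum '",
            target, "'")
    stratum[stratum == s] <- target
  }
  structure(list(weight = as.numeric(weight), psu = psu, stratum = stratum),
            class = "svy_design")
}

# IRLS fit + linearized covariance, shared by fit_membership
svy_logit_fit <- function(X, y, design, max_iter = 100, tol = 1e-8) {
  w <- design$weight
  n <- nrow(X); p <- ncol(X)
  fit <- glm.fit(X, y, weights = w, family = stats::quasibinomial(),
                 control = list(maxit = max_iter, epsilon = tol))
  if (!fit$converged)
    stop("IRLS did not converge after ", max_iter,
         " iterations; last deviance ", format(fit$deviance))
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("design matrix is rank deficient; aliased terms: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  mu <- fit$fitted.values
  if (max(abs(beta)) > 15 || any(mu > 1 - 1e-10) || any(mu < 1e-10)) {
    if (max(abs(beta)) > 15)
      stop("possible perfect separation (|coefficient| > 15); ",
           "inspect covariate cells against the outcome")
  }
  # observed information (model-based bread)
  A <- crossprod(X, X * (w * mu * (1 - mu)))
  Ainv <- solve(A)
  # per-observation score contributions
  U <- X * (w * (y - mu))
  # aggregate scores to PSU totals, covariance between PSUs within strata
  psu_tot <- rowsum(U, design$psu)
  psu_str <- design$stratum[match(rownames(psu_tot), design$psu)]
  strata <- unique(design$stratum)
  V <- matrix(0, p, p)
  n_psu_total <- 0L
  for (h in strata) {
    Z <- psu_tot[psu_str == h, , drop = FALSE]
    m_h <- nrow(Z)
    n_psu_total <- n_psu_total + m_h
    if (m_h < 2) next
    Zc <- sweep(Z, 2, colMeans(Z))
    V <- V + (m_h / (m_h - 1)) * crossprod(Zc)
  }
  V <- V * (n - 1) / (n - p)
  vcov <- Ainv %*% V %*% Ainv
  df <- n_psu_total - length(strata)
  list(coefficients = beta, vcov = vcov, df = df, n = n,
       deviance = fit$deviance, fitted = mu)
}

#' Survey-weighted logistic regression of cluster membership
#'
#' Fits a binary logistic model by weighted maximum pseudo-likelihood
#' (iteratively reweighted least squares) and estimates the covariance of
#' the coefficients by Taylor linearization: per-observation score
#' contributions are aggregated to PSU totals and their between-PSU
#' covariance is accumulated within strata with the `m_h/(m_h - 1)` and
#' overall `(n - 1)/(n - p)` small-sample corrections.  Wald tests use a t
#' reference with design degrees of freedom (PSUs minus strata).
#'
#' Point estimates depend on weights only through relative magnitudes, and
#' the linearized covariance is likewise invariant to rescaling all weights.
#'
#' @param formula model formula; the response must be a 0/1 (or logical)
#'   membership indicator.
#' @param data data.frame of covariates (factors encode reference levels by
#'   their first level).
#' @param design a [svy_design()] aligned with `data`.
#' @param max_iter,tol IRLS controls (relative deviance tolerance).
#' @return Object of class `membership_fit`: `coefficients` (log-odds),
#'   `vcov`, `odds_ratios`, `se`, `p_values`, `df`, `n`, `table`
#'   (term/OR/se/p data.frame).
#' @export
fit_membership <- function(formula, data, design, max_iter = 100,
                           tol = 1e-8) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be a 0/1 membership indicator")
  X <- model.matrix(attr(mf, "terms"), mf)
  # empty covariate cells: factor level never observed alongside outcome
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("empty or aliased covariate cell(s) after encoding: ",
         paste(aliased, collapse = ", "))
  }
  fit <- svy_logit_fit(X, y, design, max_iter, tol)
  se <- sqrt(diag(fit$vcov))
  tval <- fit$coefficients / se
  pval <- 2 * pt(-abs(tval), df = fit$df)
  tab <- data.frame(term = colnames(X),
                    estimate = unname(fit$coefficients),
                    odds_ratio = unname(exp(fit$coefficients)),
                    se = unname(se), t = unname(tval),
                    p_value = unname(pval), stringsAsFactors = FALSE)
  structure(list(coefficients = fit$coefficients, vcov = fit$vcov,
                 odds_ratios = exp(fit$coefficients), se = se,
                 p_values = pval, df = fit$df, n = fit$n,
                 deviance = fit$deviance, table = tab, formula = formula),
            class = "membership_fit")
}

#' @export
print.membership_fit <- function(x, ...) {
  cat(sprintf("<membership_fit: n=%d, design df=%d>\n", x$n, x$df))
  print(transform(x$table, odds_ratio = round(odds_ratio, 3),
                  estimate = round(estimate, 3), se = round(se, 3),
                  t = round(t, 2), p_value = signif(p_value, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Per-cluster membership models and the combined odds-ratio table
#'
#' Fits one survey-weighted logistic model per cluster, with the binary
#' outcome "member of cluster c", and assembles a combined term-by-cluster
#' OR/p table.  A failure in one cluster model is reported but does not
#' block the others.
#'
#' @param cluster_id integer cluster assignment per woman.
#' @param formula right-hand-side formula of covariates, e.g.
#'   `~ education + knowledge`.
#' @param data covariate data.frame (one row per woman).
#' @param design a [svy_design()].
#' @return Object of class `membership_models`: `models` (list, NULL where
#'   a fit failed), `or_table` (term x cluster data.frame of OR and p),
#'   `errors` (named character).
#' @export
fit_all_clusters <- function(cluster_id, formula, data, design) {
  ks <- sort(unique(cluster_id))
  models <- list(); errors <- character(0)
  for (c in ks) {
    dat <- data
    dat$.member <- as.numeric(cluster_id == c)
    f <- stats::update.formula(formula, .member ~ .)
    res <- tryCatch(fit_membership(f, dat, design), error = function(e) e)
    if (inherits(res, "error")) {
      errors[as.character(c)] <- conditionMessage(res)
      models[as.character(c)] <- list(NULL)
      warning("cluster ", c, " model failed: ", conditionMessage(res))
    } else models[[as.character(c)]] <- res
  }
  ok <- !vapply(models, is.null, TRUE)
  or_table <- NULL
  if (any(ok)) {
    terms <- models[[which(ok)[1]]]$table$term
    or_table <- data.frame(term = terms, stringsAsFactors = FALSE)
    for (c in names(models)) {
      if (is.null(models[[c]])) next
      tb <- models[[c]]$table
      or_table[[paste0("OR_", c)]] <- tb$odds_ratio[match(terms, tb$term)]
      or_table[[paste0("p_", c)]] <- tb$p_value[match(terms, tb$term)]
    }
  }
  structure(list(models = models, or_table = or_table, errors = errors),
            class = "membership_models")
}

#' Collinearity diagnostics for a covariate specification
#'
#' Reports variance inflation factors (per design-matrix column, computed
#' against the remaining columns) and the condition number of the scaled
#' design matrix; warns above VIF 10 or condition number 30, and flags
#' exact singularity.
#'
#' @param formula RHS formula of covariates.
#' @param data covariate data.frame.
#' @return list `vif` (named), `condition_number`, `singular` (logical),
#'   `aliased` (columns involved in exact dependence, if any).
#' @export
collinearity_check <- function(formula, data) {
  X <- model.matrix(formula, data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  qrX <- qr(cbind(1, X))
  singular <- qrX$rank < p + 1
  aliased <- if (singular)
    colnames(cbind(`(Intercept)` = 1, X))[qrX$pivot[(qrX$rank + 1):(p + 1)]]
  else character(0)
  vif <- rep(NA_real_, p); names(vif) <- colnames(X)
  for (j in seq_len(p)) {
    yj <- X[, j]
    if (p == 1) { vif[j] <- 1; next }
    fitj <- lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    rss <- sum(fitj$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    vif[j] <- if (rss < 1e-12 * max(tss, 1)) Inf else tss / rss
  }
  Xs <- scale(X)
  Xs[is.nan(Xs)] <- 0
  sv <- svd(Xs, nu = 0, nv = 0)$d
  cond <- if (min(sv) < 1e-12) Inf else max(sv) / min(sv)
  if (singular) warning("exact linear dependence among covariate columns: ",
                        paste(aliased, collapse = ", "))
  else if (any(vif > 10, na.rm = TRUE))
    warning("VIF above 10 for: ",
            paste(names(vif)[vif > 10], collapse = ", "))
  else if (cond > 30)
    warning("condition number above 30 (", format(cond, digits = 4), ")")
  list(vif = vif, condition_number = cond, singular = singular,
       aliased = aliased)
}
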