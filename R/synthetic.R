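#' Default cluster archetypes
#'
#' Six archetypal 59-month sequences that mirror the published Burundi
#' cluster medoids in states and ordering: an all-nonuse "Quiet Calendar";
#' two "Family Builder" patterns with two 9-month pregnancy spells at
#' different timings; a "Modern Mother" whose pregnancy ends near month 24
#' followed by short-term modern use to the end; a "Consistently Covered
#' Mother" switching to a long-acting/permanent method; and a "Traditional
#' Mother" adopting a traditional method at the end of year 2.  Exact spell
#' boundaries within those patterns are configuration, not data.
#'
#' @return Named list of archetypes; each is a list with `name` and
#'   `spells`, a data.frame of `(state, duration)` summing to 59 months.
#' @export
default_archetypes <- function() {
  sp <- function(...) {
    x <- list(...)
    data.frame(state = vapply(x, `[[`, "", 1),
               duration = as.integer(vapply(x, `[[`, "", 2)),
               stringsAsFactors = FALSE)
  }
  a <- list(
    list(name = "Quiet Calendar",
         spells = sp(c("NONE", 59))),
    list(name = "Family Builder 1",
         spells = sp(c("NONE", 4), c("PREG", 9), c("NONE", 10),
                     c("PREG", 9), c("NONE", 27))),
    list(name = "Family Builder 2",
         spells = sp(c("NONE", 27), c("PREG", 9), c("NONE", 10),
                     c("PREG", 9), c("NONE", 4))),
    list(name = "Modern Mother",
         spells = sp(c("NONE", 15), c("PREG", 9), c("STM", 35))),
    list(name = "Consistently Covered Mother",
         spells = sp(c("NONE", 15), c("PREG", 9), c("LAPM", 35))),
    list(name = "Traditional Mother",
         spells = sp(c("NONE", 15), c("PREG", 9), c("TRAD", 35)))
  )
  names(a) <- vapply(a, `[[`, "", "name")
  for (ar in a)
    if (sum(ar$spells$duration) != SEQ_LENGTH)
      stop("archetype '", ar$name, "' durations do not sum to ", SEQ_LENGTH)
  a
}

archetype_states <- function(archetype) {
  state_codes(rep(archetype$spells$state, archetype$spells$duration))
}

#' Default cluster mixture weights (published sample shares)
#' @return Named numeric vector over the six archetypes, summing to 1.
#' @export
default_mixture_weights <- function() {
  c("Quiet Calendar" = 0.415, "Family Builder 1" = 0.249,
    "Family Builder 2" = 0.181, "Modern Mother" = 0.076,
    "Consistently Covered Mother" = 0.056, "Traditional Mother" = 0.023)
}

default_covariate_spec <- function() {
  list(
    education = c(none = 0.448, primary = 0.368, secondary_plus = 0.184),
    knowledge = c(low = 0.292, medhigh = 0.708),
    fertility_desire = c(soon = 0.25, after2 = 0.35, unsure = 0.15,
                         nomore = 0.25)
  )
}

default_effect_spec <- function() {
  list(
    mode = "binary",
    focal = "Quiet Calendar",
    intercept = NULL,  # solved so the marginal focal share equals its mixture weight
    coefficients = list(
      education = c(primary = log(1.10), secondary_plus = log(3.68)),
      knowledge = c(medhigh = log(0.70)),
      fertility_desire = c(after2 = log(0.35), unsure = log(4.21),
                           nomore = log(0.35))
    )
  )
}

#' Build (and validate) a synthetic-generator configuration
#'
#' Defaults encode the study conditions the pipeline is meant to recover:
#' the six archetypes, the published cluster shares as mixture weights,
#' moderate sequence noise (per-month substitution 0.03, spell-boundary
#' jitter up to 2 months), covariate margins matching the published sample
#' profile, a binary-mode membership model for the all-nonuse cluster with
#' published odds ratios as true effects, and a stratified two-stage design.
#'
#' @param n_women number of women to generate.
#' @param mixture_weights named nonnegative weights over archetypes, sum 1.
#' @param archetypes list as from [default_archetypes()].
#' @param noise_sub_prob per-month probability of substituting the true
#'   state by a uniformly random other state.
#' @param jitter_max maximum spell-boundary shift in months (uniform integer
#'   in `[-jitter_max, jitter_max]`, clamped so every spell keeps >= 1
#'   month).
#' @param design list: `n_strata`, `psus_per_stratum`, `weight_cv`
#'   (coefficient of variation of the lognormal survey weights, mean 1).
#' @param covariate_spec named list of categorical level probabilities
#'   (first level of each covariate is the reference).
#' @param effect_spec membership-model specification: `mode = "binary"`
#'   with a `focal` archetype, optional fixed `intercept` and per-covariate
#'   log-odds `coefficients`; or `mode = "mixture"` for covariate-free
#'   membership; or `mode = "multinomial"` with a coefficient list per
#'   non-reference cluster.
#' @param interview_cmc century-month code of the (common) interview month.
#' @param seed integer seed; all generator randomness flows through it.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_women = 1000,
                             mixture_weights = default_mixture_weights(),
                             archetypes = default_archetypes(),
                             noise_sub_prob = 0.03,
                             jitter_max = 2,
                             design = list(n_strata = 10,
                                           psus_per_stratum = 20,
                                           weight_cv = 0.5),
                             covariate_spec = default_covariate_spec(),
                             effect_spec = default_effect_spec(),
                             interview_cmc = 1405,
                             seed = 1) {
  cfg <- list(n_women = as.integer(n_women),
              mixture_weights = mixture_weights, archetypes = archetypes,
              noise_sub_prob = noise_sub_prob, jitter_max = as.integer(jitter_max),
              design = design, covariate_spec = covariate_spec,
              effect_spec = effect_spec,
              interview_cmc = as.integer(interview_cmc),
              seed = as.integer(seed))
  problems <- character(0)
  if (cfg$n_women < 1) problems <- c(problems, "n_women must be >= 1")
  if (length(cfg$mixture_weights) != length(cfg$archetypes) ||
      !setequal(names(cfg$mixture_weights), names(cfg$archetypes)))
    problems <- c(problems, "mixture_weights must be named by archetype")
  if (any(cfg$mixture_weights < 0) ||
      abs(sum(cfg$mixture_weights) - 1) > 1e-9)
    problems <- c(problems, "mixture_weights must be nonnegative and sum to 1")
  if (cfg$noise_sub_prob < 0 || cfg$noise_sub_prob > 1)
    problems <- c(problems, "noise_sub_prob must be in [0, 1]")
  if (cfg$jitter_max < 0) problems <- c(problems, "jitter_max must be >= 0")
  for (nm in c("n_strata", "psus_per_stratum", "weight_cv"))
    if (is.null(cfg$design[[nm]]))
      problems <- c(problems, paste0("design$", nm, " missing"))
  if (!is.null(cfg$design$women_per_psu)) {
    tot <- cfg$design$n_strata * cfg$design$psus_per_stratum *
      cfg$design$women_per_psu
    if (tot != cfg$n_women)
      problems <- c(problems, "design product != n_women")
  }
  for (cv in names(cfg$covariate_spec)) {
    p <- cfg$covariate_spec[[cv]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9 || is.null(names(p)))
      problems <- c(problems,
                    paste0("covariate_spec$", cv,
                           " must be named probabilities summing to 1"))
  }
  es <- cfg$effect_spec
  if (!is.null(es)) {
    if (!es$mode %in% c("binary", "mixture", "multinomial"))
      problems <- c(problems, "effect_spec$mode must be binary/mixture/multinomial")
    if (identical(es$mode, "binary") &&
        !isTRUE(es$focal %in% names(cfg$archetypes)))
      problems <- c(problems, "effect_spec$focal must name an archetype")
  }
  if (length(problems) > 0)
    stop("invalid generator config:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  n_women:", x$n_women, " seed:", x$seed,
      " interview_cmc:", x$interview_cmc, "\n")
  cat("  noise_sub_prob:", x$noise_sub_prob,
      " jitter_max:", x$jitter_max, "\n")
  cat("  mixture_weights:\n")
  for (nm in names(x$mixture_weights))
    cat(sprintf("    %-28s %.3f\n", nm, x$mixture_weights[[nm]]))
  cat("  design:", x$design$n_strata, "strata x",
      x$design$psus_per_stratum, "PSUs, weight CV",
      x$design$weight_cv, "\n")
  cat("  covariates:", paste(names(x$covariate_spec), collapse = ", "), "\n")
  if (!is.null(x$effect_spec))
    cat("  effect mode:", x$effect_spec$mode,
        if (identical(x$effect_spec$mode, "binary"))
          paste0("(focal: ", x$effect_spec$focal, ")") else "", "\n")
  invisible(x)
}

# realize one sequence: jitter spell boundaries then per-month substitution
realize_sequence <- function(archetype, jitter_max, noise_sub_prob) {
  sp <- archetype$spells
  m <- nrow(sp)
  states <- sp$state
  if (m > 1 && jitter_max > 0) {
    bounds <- cumsum(sp$duration)[-m]  # positions where spells end
    shift <- sample.int(2L * jitter_max + 1L, m - 1L, replace = TRUE) -
      (jitter_max + 1L)
    newb <- integer(m - 1L)
    prev <- 0L
    for (i in seq_len(m - 1L)) {
      lo <- prev + 1L
      hi <- SEQ_LENGTH - (m - i)
      newb[i] <- min(max(bounds[i] + shift[i], lo), hi)
      prev <- newb[i]
    }
    dur <- diff(c(0L, newb, SEQ_LENGTH))
  } else {
    dur <- sp$duration
  }
  x <- state_codes(rep(states, dur))
  if (noise_sub_prob > 0) {
    hit <- which(runif(SEQ_LENGTH) < noise_sub_prob)
    if (length(hit) > 0) {
      # uniformly random *other* state
      x[hit] <- ((x[hit] - 1L +
                    sample.int(length(CAL_STATES) - 1L, length(hit),
                               replace = TRUE)) %% length(CAL_STATES)) + 1L
    }
  }
  x
}

# characters used when emitting sequences as DHS-style calendar strings
emit_chars <- c(NONE = "0", STM = "3", LAPM = "N", TRAD = "8", PREG = "P")

draw_covariates <- function(n, spec) {
  out <- list()
  for (cv in names(spec)) {
    p <- spec[[cv]]
    out[[cv]] <- factor(names(p)[sample.int(length(p), n, replace = TRUE,
                                            prob = p)],
                        levels = names(p))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

effect_linear_predictor <- function(covars, coefficients) {
  lp <- rep(0, nrow(covars))
  for (cv in names(coefficients)) {
    beta <- coefficients[[cv]]
    lv <- as.character(covars[[cv]])
    lp <- lp + ifelse(lv %in% names(beta), beta[lv], 0)
  }
  lp
}

#' Generate synthetic calendar records with known truth
#'
#' For each woman: draw covariates; draw the true cluster (binary mode:
#' Bernoulli membership in the focal cluster through a logistic link, with
#' the remaining probability split over the other archetypes by their
#' renormalized mixture weights; mixture mode: direct multinomial draw;
#' multinomial mode: full multinomial logit); realize her sequence as the
#' archetype with jittered spell boundaries and per-month state
#' substitution; emit the DHS-style calendar string (leftmost column = most
#' recent month, 80 columns); assign PSU and stratum round-robin and
#' lognormal weights with the configured CV.  Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `records` (data.frame in the [read_records()]
#'   standardized layout plus covariate columns), `truth` (data.frame:
#'   `case_id`, `cluster` name, `archetype` index, plus the true model
#'   coefficients as attribute `coefficients`), `seqs` (the internal
#'   [state_sequences()] before calendar-string encoding, for round-trip
#'   checks), and `config`.
#' @export
generate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_women
  arch_names <- names(config$archetypes)
  covars <- draw_covariates(n, config$covariate_spec)
  es <- config$effect_spec
  truth_coef <- NULL

  if (is.null(es) || identical(es$mode, "mixture")) {
    cl <- sample.int(length(arch_names), n, replace = TRUE,
                     prob = config$mixture_weights[arch_names])
  } else if (identical(es$mode, "binary")) {
    offs <- effect_linear_predictor(covars, es$coefficients)
    target <- config$mixture_weights[[es$focal]]
    alpha <- if (!is.null(es$intercept)) es$intercept else
      uniroot(function(a) mean(plogis(a + offs)) - target,
              c(-20, 20), tol = 1e-10)$root
    p_focal <- plogis(alpha + offs)
    in_focal <- rbinom(n, 1L, p_focal) == 1L
    focal_idx <- match(es$focal, arch_names)
    others <- setdiff(seq_along(arch_names), focal_idx)
    wother <- config$mixture_weights[arch_names][others]
    cl <- integer(n)
    cl[in_focal] <- focal_idx
    if (any(!in_focal))
      cl[!in_focal] <- others[sample.int(length(others), sum(!in_focal),
                                         replace = TRUE,
                                         prob = wother / sum(wother))]
    truth_coef <- list(intercept = alpha, coefficients = es$coefficients,
                       focal = es$focal)
  } else { # multinomial logit over clusters, first archetype is reference
    w <- config$mixture_weights[arch_names]
    eta <- matrix(rep(log(w / w[1]), each = n), n)
    if (!is.null(es$coefficients)) {
      for (cname in names(es$coefficients)) {
        j <- match(cname, arch_names)
        eta[, j] <- eta[, j] +
          effect_linear_predictor(covars, es$coefficients[[cname]])
      }
    }
    pr <- exp(eta - apply(eta, 1, max))
    pr <- pr / rowSums(pr)
    cl <- vapply(seq_len(n),
                 function(i) sample.int(ncol(pr), 1, prob = pr[i, ]), 1L)
    truth_coef <- list(coefficients = es$coefficients)
  }

  seqs <- matrix(NA_integer_, n, SEQ_LENGTH)
  for (i in seq_len(n))
    seqs[i, ] <- realize_sequence(config$archetypes[[cl[i]]],
                                  config$jitter_max, config$noise_sub_prob)

  # calendar string: 80 columns, leftmost = interview month; the 21 months
  # before the window are nonuse
  letters59 <- matrix(emit_chars[CAL_STATES[seqs]], n)
  cal <- apply(letters59[, SEQ_LENGTH:1, drop = FALSE], 1, paste,
               collapse = "")
  cal <- paste0(cal, strrep("0", 80L - SEQ_LENGTH))

  start_cmc <- config$interview_cmc - (SEQ_LENGTH - 1L)
  age_months <- 15L * 12L + sample.int(30L * 12L, n, replace = TRUE) - 1L
  birth_cmc <- start_cmc - age_months

  n_psu <- config$design$n_strata * config$design$psus_per_stratum
  psu <- ((seq_len(n) - 1L) %% n_psu) + 1L
  stratum <- ((psu - 1L) %/% config$design$psus_per_stratum) + 1L
  cvw <- config$design$weight_cv
  if (cvw > 0) {
    sdlog <- sqrt(log(1 + cvw^2))
    weight <- rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else weight <- rep(1, n)

  case_id <- sprintf("W%06d", seq_len(n))
  records <- data.frame(case_id = case_id, calendar = cal,
                        interview_cmc = config$interview_cmc,
                        birth_cmc = birth_cmc, weight = weight,
                        psu = psu, stratum = stratum,
                        stringsAsFactors = FALSE)
  records <- cbind(records, covars)
  truth <- data.frame(case_id = case_id, cluster = arch_names[cl],
                      archetype = cl, stringsAsFactors = FALSE)
  attr(truth, "coefficients") <- truth_coef
  list(records = records, truth = truth,
       seqs = state_sequences(seqs, case_id, start_cmc), config = config)
}

#' Chance-adjusted agreement between two labelings (adjusted Rand index)
#'
#' 1 for identical partitions (up to label permutation), expectation about 0
#' for random labelings.
#'
#' @param truth,assigned two equal-length label vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
truth_assignment_accuracy <- function(truth, assigned) {
  if (length(truth) != length(assigned))
    stop("labelings have different lengths")
  tab <- table(truth, assigned)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  expected <- sum_a * sum_b / tot
  mx <- (sum_a + sum_b) / 2
  if (abs(mx - expected) < 1e-12) return(ifelse(sum_ij == mx, 1, 0))
  (sum_ij - expected) / (mx - expected)
}
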