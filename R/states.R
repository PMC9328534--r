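#' @useDynLib calseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate as.formula binomial coef glm model.matrix
#'   optim pt quantile rbinom rlnorm runif sd setNames uniroot var vcov
#'   lm.fit plogis qlogis rnorm
#' @importFrom utils read.csv write.csv
NULL

#' The five-state contraceptive calendar alphabet
#'
#' Calendar months are coded into five analysis states: no method use
#' (`NONE`), short-term modern method (`STM`: pill, injectable, condom,
#' lactational amenorrhea, emergency contraception, Standard Days Method and
#' similar), long-acting or permanent method (`LAPM`: IUD, implant,
#' sterilization), traditional method (`TRAD`: rhythm, withdrawal, folkloric)
#' and pregnancy/birth/termination (`PREG`).
#'
#' @format A character vector of length 5.
#' @export
CAL_STATES <- c("NONE", "STM", "LAPM", "TRAD", "PREG")

#' Single-letter labels used in sequence output files
#' @format Named character vector mapping state to letter (N, S, L, T, P).
#' @export
CAL_STATE_LETTERS <- c(NONE = "N", STM = "S", LAPM = "L", TRAD = "T",
                       PREG = "P")

# length of the analysis window, in months
SEQ_LENGTH <- 59L

state_codes <- function(x) {
  out <- match(x, CAL_STATES)
  if (anyNA(out)) stop("unknown state label(s): ",
                       paste(unique(x[is.na(match(x, CAL_STATES))]),
                             collapse = ", "))
  out
}

#' Construct a set of state sequences
#'
#' A thin container for aligned categorical sequences: an integer matrix with
#' one row per woman and one column per month (codes 1..5 into
#' [CAL_STATES]), plus per-row ids and the century-month code of month 1.
#'
#' @param states integer matrix (codes 1..5) or character matrix of state
#'   labels, one row per sequence, 59 columns for the standard window.
#' @param case_id character vector of row identifiers.
#' @param start_cmc integer vector (recycled) giving the CMC of month 1.
#' @return An object of class `state_seqs`.
#' @export
state_sequences <- function(states, case_id = NULL, start_cmc = NA_integer_) {
  if (is.character(states)) {
    states <- matrix(state_codes(states), nrow = nrow(states),
                     dimnames = dimnames(states))
  }
  storage.mode(states) <- "integer"
  if (any(states < 1L | states > 5L, na.rm = TRUE) || anyNA(states))
    stop("state codes must be integers in 1..5 with no missing values")
  if (is.null(case_id)) case_id <- as.character(seq_len(nrow(states)))
  rownames(states) <- as.character(case_id)
  structure(states,
            start_cmc = rep_len(as.integer(start_cmc), nrow(states)),
            class = c("state_seqs", "matrix", "array"))
}

#' @export
print.state_seqs <- function(x, ...) {
  cat(sprintf("<state_seqs: %d sequences x %d months>\n", nrow(x), ncol(x)))
  n <- min(5L, nrow(x))
  if (n > 0) {
    lab <- apply(unclass(x)[seq_len(n), , drop = FALSE], 1,
                 function(r) paste(CAL_STATE_LETTERS[CAL_STATES[r]],
                                   collapse = ""))
    for (i in seq_len(n)) cat(rownames(x)[i], ": ", lab[i], "\n", sep = "")
    if (nrow(x) > n) cat("...\n")
  }
  invisible(x)
}

seq_letters <- function(seqs) {
  m <- unclass(seqs)
  matrix(CAL_STATE_LETTERS[CAL_STATES[m]], nrow = nrow(m),
         dimnames = dimnames(m))
}
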