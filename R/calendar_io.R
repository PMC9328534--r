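#' Default month-code map for DHS-style contraceptive calendars
#'
#' Maps the single-character month codes of the DHS phase-7 calendar to the
#' five analysis states.  Pregnancy, birth and termination (`P`, `B`, `T`)
#' map to `PREG`; non-use (`0`) to `NONE`; pill, injectable, diaphragm,
#' male/female condom, LAM, emergency contraception, Standard Days Method,
#' foam/jelly and other modern methods to `STM`; IUD, implant and female/male
#' sterilization to `LAPM`; rhythm, withdrawal, abstinence and other
#' traditional methods to `TRAD`.  `?` and blank months are `MISSING` and are
#' resolved by the window-extraction policy.
#'
#' Note: the survey dialect has more modern codes than the six canonical
#' short-term methods; female condom (`C`), diaphragm (`4`) and foam/jelly
#' (`F`) default to `STM` here and can be overridden by editing the returned
#' map.
#'
#' @return Named character vector (class `code_map`): names are calendar
#'   characters, values are states or `"MISSING"`.
#' @export
#' @examples
#' m <- default_code_map()
#' m[["3"]]  # injectables -> "STM"
default_code_map <- function() {
  map <- c(
    "B" = "PREG", "P" = "PREG", "T" = "PREG",
    "0" = "NONE",
    "1" = "STM",   # pill
    "2" = "LAPM",  # IUD
    "3" = "STM",   # injectables
    "4" = "STM",   # diaphragm
    "5" = "STM",   # condom
    "6" = "LAPM",  # female sterilization
    "7" = "LAPM",  # male sterilization
    "8" = "TRAD",  # periodic abstinence / rhythm
    "9" = "TRAD",  # withdrawal
    "W" = "TRAD",  # other traditional
    "N" = "LAPM",  # implant
    "A" = "TRAD",  # abstinence
    "L" = "STM",   # lactational amenorrhea
    "C" = "STM",   # female condom
    "F" = "STM",   # foam / jelly
    "E" = "STM",   # emergency contraception
    "S" = "STM",   # Standard Days Method
    "M" = "STM",   # other modern
    "?" = "MISSING",
    " " = "MISSING"
  )
  structure(map, provenance = "DHS-7 recode manual vcal coding",
            class = "code_map")
}

#' Parse one calendar string into (cmc, state) pairs
#'
#' DHS calendars store one character per month with the *leftmost*
#' non-padding column being the most recent (interview) month.  The parsed
#' output is ordered earliest to latest.
#'
#' @param calendar calendar string (typically 80 columns, space padded).
#' @param interview_cmc century-month code of the interview month.
#' @param map a [default_code_map()]-style code map.
#' @return data.frame with columns `cmc` (integer) and `state` (character,
#'   one of the five states or `"MISSING"`), ordered earliest first.
#' @export
parse_calendar <- function(calendar, interview_cmc, map = default_code_map()) {
  stopifnot(is.character(calendar), length(calendar) == 1L,
            nzchar(calendar), is.finite(interview_cmc))
  chars <- strsplit(calendar, "", fixed = TRUE)[[1]]
  nonpad <- which(chars != " ")
  if (length(nonpad) == 0L) stop("calendar string is all padding")
  first <- min(nonpad); last <- max(nonpad)
  chars <- chars[first:last]
  states <- unname(map[chars])
  if (anyNA(states)) {
    bad <- which(is.na(states))[1]
    stop(sprintf("unknown calendar character '%s' at column %d",
                 chars[bad], first + bad - 1L))
  }
  n <- length(chars)
  # leftmost retained column = interview month; columns step back in time
  cmc <- as.integer(interview_cmc) - (seq_len(n) - 1L)
  data.frame(cmc = rev(cmc), state = rev(states),
             stringsAsFactors = FALSE)
}

#' Extract the 59-month analysis window ending at the interview month
#'
#' Months `interview_cmc - 58 .. interview_cmc` become months 1..59 (month 1
#' earliest).  `MISSING` months are resolved by `missing_policy`:
#' `"carry_backward"` (default) copies the state of the next later observed
#' month (trailing gaps are filled forward from the last observed month),
#' `"recode_none"` recodes them to `NONE`, `"error"` refuses.
#'
#' @param parsed output of [parse_calendar()].
#' @param interview_cmc CMC anchoring the window (its last month).
#' @param missing_policy one of `"carry_backward"`, `"recode_none"`,
#'   `"error"`.
#' @return list with `states` (integer codes, length 59), `start_cmc`, and
#'   `n_missing_filled`.
#' @export
extract_window <- function(parsed, interview_cmc,
                           missing_policy = c("carry_backward",
                                              "recode_none", "error")) {
  missing_policy <- match.arg(missing_policy)
  start_cmc <- as.integer(interview_cmc) - (SEQ_LENGTH - 1L)
  idx <- match(start_cmc:interview_cmc, parsed$cmc)
  if (anyNA(idx))
    stop(sprintf("calendar covers only %d of the %d window months",
                 sum(!is.na(idx)), SEQ_LENGTH),
         call. = FALSE)
  states <- parsed$state[idx]
  miss <- states == "MISSING"
  n_missing <- sum(miss)
  if (n_missing > 0L) {
    if (missing_policy == "error")
      stop(sprintf("%d MISSING month(s) in window under policy 'error'",
                   n_missing), call. = FALSE)
    if (missing_policy == "recode_none") {
      states[miss] <- "NONE"
    } else {
      if (all(miss)) stop("all window months MISSING", call. = FALSE)
      # carry backward in time: take the next later observed state
      for (i in rev(seq_len(SEQ_LENGTH - 1L)))
        if (states[i] == "MISSING") states[i] <- states[i + 1L]
      # trailing gap at the recent end: fill forward
      for (i in 2:SEQ_LENGTH)
        if (states[i] == "MISSING") states[i] <- states[i - 1L]
    }
  }
  list(states = state_codes(states), start_cmc = start_cmc,
       n_missing_filled = n_missing)
}

#' Keep women aged `min_age`..`max_age` (completed years) at window start
#'
#' Age at the start of the 59-month window is computed as
#' `floor((start_cmc - birth_cmc) / 12)` with
#' `start_cmc = interview_cmc - 58`, the standard completed-years demographic
#' convention.  The filter is idempotent.
#'
#' @param records calendar-record data.frame (see [read_records()]).
#' @param min_age,max_age inclusive bounds in completed years.
#' @return The eligible subset, with attribute `n_dropped`.
#' @export
filter_eligible <- function(records, min_age = 15, max_age = 44) {
  start_cmc <- records$interview_cmc - (SEQ_LENGTH - 1L)
  age <- floor((start_cmc - records$birth_cmc) / 12)
  keep <- age >= min_age & age <= max_age
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  if (any(!keep))
    message(sum(!keep), " record(s) outside age range ",
            min_age, "-", max_age, " dropped; ", sum(keep), " kept")
  out
}

mandatory_record_cols <- c(case_id = "case_id", calendar = "vcal",
                           interview_cmc = "v008", birth_cmc = "v011",
                           weight = "v005", psu = "v021", stratum = "v022")

#' Read woman-level calendar records from delimited text
#'
#' Expects the DHS-style columns `case_id`, `vcal` (calendar string), `v008`
#' (interview CMC), `v011` (birth CMC), `v005` (weight, times 1e6 per DHS
#' convention), `v021` (PSU), `v022` (stratum); any further columns are kept
#' as covariates.
#'
#' @param path CSV file path.
#' @param rescale_weight divide `v005` by 1e6 (default `TRUE`).
#' @return data.frame with standardized names (`case_id`, `calendar`,
#'   `interview_cmc`, `birth_cmc`, `weight`, `psu`, `stratum`, covariates).
#' @export
read_records <- function(path, rescale_weight = TRUE) {
  hdr <- names(read.csv(path, nrows = 1, stringsAsFactors = FALSE))
  cls <- setNames(rep("character", 2), c("vcal", "case_id"))
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = cls[intersect(names(cls), hdr)])
  missing_cols <- setdiff(unname(mandatory_record_cols), names(df))
  if (length(missing_cols) > 0)
    stop("input file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("input file '", path, "' has no rows")
  }
  out <- df
  names(out)[match(unname(mandatory_record_cols), names(out))] <-
    names(mandatory_record_cols)
  if (rescale_weight) out$weight <- out$weight / 1e6
  if (any(out$weight < 0)) stop("negative survey weights in input")
  out
}

#' Write calendar records in the package's input format
#' @param records standardized record data.frame.
#' @param path output CSV path.
#' @param rescale_weight multiply weight by 1e6 on output (DHS `v005`).
#' @export
write_records <- function(records, path, rescale_weight = TRUE) {
  out <- records
  names(out)[match(names(mandatory_record_cols), names(out))] <-
    unname(mandatory_record_cols)
  if (rescale_weight) out$v005 <- round(out$v005 * 1e6)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert raw records to 59-month state sequences
#'
#' Applies the eligibility filter, parses each calendar, extracts the
#' 59-month window and reports per-stage counts.
#'
#' @param records standardized record data.frame.
#' @param map code map (see [default_code_map()]).
#' @param missing_policy forwarded to [extract_window()].
#' @param min_age,max_age forwarded to [filter_eligible()].
#' @return list: `seqs` ([state_sequences()]), `records` (rows retained, in
#'   sequence order), `log` (counts of input/ineligible/unparseable/kept).
#' @export
records_to_sequences <- function(records, map = default_code_map(),
                                 missing_policy = "carry_backward",
                                 min_age = 15, max_age = 44) {
  n_in <- nrow(records)
  elig <- filter_eligible(records, min_age, max_age)
  n_inelig <- attr(elig, "n_dropped")
  states <- matrix(NA_integer_, nrow(elig), SEQ_LENGTH)
  ok <- rep(TRUE, nrow(elig))
  reasons <- character(0)
  filled <- 0L
  for (i in seq_len(nrow(elig))) {
    res <- tryCatch({
      p <- parse_calendar(elig$calendar[i], elig$interview_cmc[i], map)
      extract_window(p, elig$interview_cmc[i], missing_policy)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      ok[i] <- FALSE
      reasons <- c(reasons, sprintf("%s: %s", elig$case_id[i],
                                    conditionMessage(res)))
    } else {
      states[i, ] <- res$states
      filled <- filled + res$n_missing_filled
    }
  }
  if (any(!ok))
    message(sum(!ok), " record(s) excluded at window extraction:\n  ",
            paste(utils::head(reasons, 10), collapse = "\n  "))
  if (filled > 0)
    message(filled, " MISSING month(s) resolved by policy '",
            missing_policy, "'")
  kept <- elig[ok, , drop = FALSE]
  seqs <- state_sequences(states[ok, , drop = FALSE], kept$case_id,
                          kept$interview_cmc - (SEQ_LENGTH - 1L))
  list(seqs = seqs, records = kept,
       log = list(n_in = n_in, n_ineligible = n_inelig,
                  n_unparseable = sum(!ok), n_kept = nrow(kept),
                  n_missing_filled = filled))
}

#' Write state sequences as delimited text
#'
#' One row per woman: `case_id`, `start_cmc`, then 59 single-letter state
#' columns `m1..m59` (letters N, S, L, T, P; month 1 earliest).
#' @param seqs a `state_seqs` object.
#' @param path output CSV path.
#' @export
write_sequences <- function(seqs, path) {
  let <- seq_letters(seqs)
  colnames(let) <- paste0("m", seq_len(ncol(let)))
  df <- data.frame(case_id = rownames(seqs),
                   start_cmc = attr(seqs, "start_cmc"),
                   let, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read state sequences written by [write_sequences()]
#' @param path CSV path.
#' @return A `state_seqs` object.
#' @export
read_sequences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(case_id = "character"))
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  if (length(mcols) == 0L) stop("no month columns (m1, m2, ...) found")
  let <- as.matrix(df[, mcols, drop = FALSE])
  inv <- setNames(names(CAL_STATE_LETTERS), CAL_STATE_LETTERS)
  states <- matrix(inv[let], nrow = nrow(let))
  if (anyNA(states)) stop("unknown state letter in sequence file")
  state_sequences(states, df$case_id,
                  if ("start_cmc" %in% names(df)) df$start_cmc else NA)
}
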