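#' Respiratory state alphabet
#'
#' The four respiratory states used throughout the package, optionally with
#' the `MISSING` code that marks artifact-excluded seconds.
#'
#' @param include_missing include the `MISSING` code.
#' @return Character vector of state codes.
#' @export
#' @examples
#' state_alphabet()
state_alphabet <- function(include_missing = FALSE) {
  states <- c("NORMAL", "HYPOPNEA", "BRADYPNEA", "APNEA")
  if (include_missing) c(states, "MISSING") else states
}

#' Classify per-second monitoring samples into respiratory states
#'
#' Applies the capnography cut-offs to each second of monitoring. A second
#' flagged as artifact (talking, dislodged sampling cannula, ...) is coded
#' `MISSING`. Otherwise the second is `APNEA` when no waveform is present or
#' the end-tidal CO2 is zero; else `BRADYPNEA` when the capnography-derived
#' respiratory rate is below `rate_cutoff` breaths/min; else `HYPOPNEA` when
#' the waveform amplitude deviates from the pre-sedation baseline by more
#' than `amp_tol` (in either direction); else `NORMAL`. Precedence is exactly
#' this order: apnea subsumes any rate or amplitude reading.
#'
#' @param samples data.frame of per-second monitoring records with columns
#'   `resp_rate` (breaths/min), `etco2` (mmHg), `rel_amplitude` (waveform
#'   amplitude as a fraction of the pre-sedation baseline),
#'   `waveform_present` (logical) and `artifact` (logical).
#' @param rate_cutoff bradypnea threshold, breaths/min (strict `<`).
#' @param amp_tol hypopnea threshold on `|rel_amplitude - 1|` (strict `>`).
#' @return Character vector of state codes, one per row of `samples`.
#' @export
#' @examples
#' classify_states(data.frame(
#'   resp_rate = c(12, 7.9, 12, 12), etco2 = c(38, 38, 38, 0),
#'   rel_amplitude = c(1, 1, 0.85, 0),
#'   waveform_present = c(TRUE, TRUE, TRUE, FALSE),
#'   artifact = FALSE))
classify_states <- function(samples, rate_cutoff = 8, amp_tol = 0.10) {
  req <- c("resp_rate", "etco2", "rel_amplitude", "waveform_present", "artifact")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("monitoring samples lack required column(s): ", paste(miss, collapse = ", "))
  }
  rate <- samples$resp_rate
  etco2 <- samples$etco2
  amp <- samples$rel_amplitude
  bad <- which(rate < 0 | etco2 < 0 | amp < 0 |
                 is.na(rate) | is.na(etco2) | is.na(amp))
  if (length(bad)) {
    stop("invalid monitoring sample(s) (negative or missing measurement) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  st <- rep("NORMAL", nrow(samples))
  st[abs(amp - 1) > amp_tol] <- "HYPOPNEA"
  st[rate < rate_cutoff] <- "BRADYPNEA"
  st[!samples$waveform_present | etco2 == 0] <- "APNEA"
  st[as.logical(samples$artifact)] <- "MISSING"
  st
}

#' Build per-patient state sequences from monitoring records
#'
#' Splits a long monitoring table by patient, checks that each patient's
#' timestamps form a contiguous 0-based per-second grid, and classifies each
#' second with [classify_states()].
#'
#' @param samples long monitoring data.frame with `patient_id` and `t`
#'   columns in addition to the measurement columns of [classify_states()].
#' @inheritParams classify_states
#' @return Named list of per-patient character vectors of state codes.
#' @export
build_sequences <- function(samples, rate_cutoff = 8, amp_tol = 0.10) {
  if (!all(c("patient_id", "t") %in% names(samples))) {
    stop("monitoring samples need 'patient_id' and 't' columns")
  }
  states <- classify_states(samples, rate_cutoff = rate_cutoff, amp_tol = amp_tol)
  split_states <- split(states, samples$patient_id)
  split_t <- split(samples$t, samples$patient_id)
  out <- vector("list", length(split_states))
  names(out) <- names(split_states)
  for (id in names(split_states)) {
    tt <- split_t[[id]]
    o <- order(tt)
    tt <- tt[o]
    if (any(tt < 0) || !identical(as.integer(tt), seq_along(tt) - 1L)) {
      stop("patient ", id, ": timestamps are not a contiguous 0-based per-second grid")
    }
    out[[id]] <- split_states[[id]][o]
  }
  out[unique(as.character(samples$patient_id))]
}

#' Expand onset/offset state intervals to a per-second sequence
#'
#' Accepts the interval representation in which an observer marks the onset
#' and offset of each waveform abnormality, and expands it to per-second
#' codes. Intervals are half-open `[start_s, end_s)` in integer seconds,
#' 0-based. Seconds not covered by any interval are `NORMAL` when
#' `gap_fill = "normal"` (the observer marks abnormalities only); with
#' `gap_fill = "error"` any uncovered second is rejected.
#'
#' @param intervals data.frame with columns `state`, `start_s`, `end_s`.
#' @param total_length procedure length in seconds.
#' @param gap_fill `"normal"` (default) or `"error"`.
#' @return Character vector of `total_length` state codes.
#' @export
#' @examples
#' expand_intervals(data.frame(state = "APNEA", start_s = 10, end_s = 20), 30)
expand_intervals <- function(intervals, total_length,
                             gap_fill = c("normal", "error")) {
  gap_fill <- match.arg(gap_fill)
  total_length <- as.integer(total_length)
  if (total_length < 1L) stop("total_length must be >= 1")
  if (nrow(intervals)) {
    s <- as.integer(intervals$start_s)
    e <- as.integer(intervals$end_s)
    if (any(s < 0 | e > total_length | s >= e)) {
      stop("intervals must satisfy 0 <= start_s < end_s <= total_length")
    }
    o <- order(s)
    if (any(s[o][-1L] < e[o][-length(o)])) stop("overlapping intervals")
  }
  seq_states <- rep(NA_character_, total_length)
  for (i in seq_len(nrow(intervals))) {
    idx <- (intervals$start_s[i] + 1L):intervals$end_s[i]
    seq_states[idx] <- as.character(intervals$state[i])
  }
  if (anyNA(seq_states)) {
    if (gap_fill == "error") stop("uncovered seconds and gap_fill = \"error\"")
    seq_states[is.na(seq_states)] <- "NORMAL"
  }
  seq_states
}

#' Run-length encode a state sequence into intervals
#'
#' Inverse of [expand_intervals()]: each maximal run of one state becomes a
#' half-open `[start_s, end_s)` interval.
#'
#' @param states character vector of per-second state codes.
#' @return data.frame with columns `state`, `start_s`, `end_s`.
#' @export
seq_to_intervals <- function(states) {
  r <- rle(states)
  end_s <- cumsum(r$lengths)
  data.frame(state = r$values,
             start_s = c(0L, end_s[-length(end_s)]),
             end_s = end_s,
             stringsAsFactors = FALSE)
}
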