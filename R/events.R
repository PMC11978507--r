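#' Event detection parameters
#'
#' Window lengths and t-statistic thresholds for the two rolling detectors.
#' DNA chemistries use short windows `(3, 6)` with thresholds `(1.4, 9.0)`;
#' direct RNA sequences more slowly and uses longer windows `(7, 14)` with
#' thresholds `(2.5, 9.0)`.
#'
#' @param windows integer vector of two window lengths (samples).
#' @param thresholds numeric vector of two t-statistic thresholds.
#' @param chemistry shortcut: `"dna"` or `"rna"` presets.
#' @return list with `windows` and `thresholds`.
#' @export
event_params <- function(windows = NULL, thresholds = NULL,
                         chemistry = c("dna", "rna")) {
  chemistry <- match.arg(chemistry)
  if (is.null(windows))
    windows <- if (chemistry == "dna") c(3L, 6L) else c(7L, 14L)
  if (is.null(thresholds))
    thresholds <- if (chemistry == "dna") c(1.4, 9.0) else c(2.5, 9.0)
  stopifnot(length(windows) == length(thresholds), all(windows >= 1))
  list(windows = as.integer(windows), thresholds = as.numeric(thresholds))
}

#' Segment a raw signal into events
#'
#' Groups samples with similar current levels using rolling Welch t-tests:
#' for each window length `w`, the t-statistic compares the `w` samples
#' before each position against the `w` after; boundaries are placed at
#' local maxima exceeding the detector threshold (an accepted peak suppresses
#' further boundaries from the same detector for `w` samples). Events are the
#' intervals between consecutive boundaries and tile the signal exactly.
#'
#' @param signal numeric vector of (calibrated) current samples.
#' @param params an [event_params()] list.
#' @return data.frame with columns `start` (0-based sample index), `length`,
#'   `mean`, `sd` (population sd over the event's samples).
#' @export
detect_events <- function(signal, params = event_params()) {
  n <- length(signal)
  if (n < 2 * max(params$windows)) {
    warning("signal shorter than event windows; returning a single event")
    bounds <- integer(0)
  } else {
    bounds <- detect_boundaries_cpp(signal, params$windows, params$thresholds)
  }
  starts <- c(0L, bounds)
  ends <- c(bounds, n)
  cs <- c(0, cumsum(signal))
  cs2 <- c(0, cumsum(signal^2))
  len <- ends - starts
  m <- (cs[ends + 1L] - cs[starts + 1L]) / len
  v <- (cs2[ends + 1L] - cs2[starts + 1L]) / len - m^2
  data.frame(start = starts, length = len, mean = m, sd = sqrt(pmax(v, 0)))
}
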