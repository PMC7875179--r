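#' Harrell's concordance index for censored survival data
#'
#' Proportion of comparable patient pairs in which the higher risk score
#' belongs to the patient who experiences the event earlier. A pair is
#' comparable when the shorter observed time ends in an event; pairs tied on
#' time are comparable only when exactly one member is an event (the event
#' is then known to precede the censoring). Pairs tied on score count 0.5.
#'
#' @param times positive observed times (event or censoring).
#' @param event_flags 0/1 (or logical) event indicators.
#' @param scores risk scores; higher means predicted earlier event.
#' @return The concordance index in \[0, 1\]. If no pair is comparable the
#'   index is undefined and an error is signalled.
#' @export
#' @examples
#' harrells_c(c(2, 4, 5, 7), c(1, 0, 1, 1), c(0.9, 0.1, 0.2, 0.3))  # 0.75
harrells_c <- function(times, event_flags, scores) {
  n <- length(times)
  stopifnot(length(event_flags) == n, length(scores) == n, all(times > 0))
  event_flags <- as.numeric(event_flags)
  stopifnot(all(event_flags %in% c(0, 1)))

  ## pair (i, j) comparable iff t_i < t_j and event_i, or t_i = t_j and
  ## exactly one of the two is an event; evaluate all ordered pairs where
  ## i is the (potential) earlier event.
  dt <- outer(times, times, "<")
  te <- outer(times, times, "==")
  ei <- matrix(event_flags, n, n)            # event status of row subject
  ej <- t(ei)
  comparable <- (dt & ei == 1) | (te & ei == 1 & ej == 0)
  diag(comparable) <- FALSE

  ds <- outer(scores, scores, "-")           # score_i - score_j
  conc <- sum(comparable & ds > 0) + 0.5 * sum(comparable & ds == 0)
  n_comp <- sum(comparable)
  if (n_comp == 0) {
    stop("Harrell's C is undefined: no comparable pairs", call. = FALSE)
  }
  conc / n_comp
}
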