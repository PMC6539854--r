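#' Chair-contact events
#'
#' Ordered instants at which the participant is in contact with the chair at
#' reference (zero) height; the anchors of the zero-displacement update (ZDU)
#' drift correction. For an STS trial with `n` repetitions there are `n + 1`
#' contacts when the start of the trial counts as a seated contact.
#'
#' @param contact_times Strictly increasing numeric vector of times (s).
#' @param includes_start Whether the first element represents the initial
#'   seated posture rather than a detected descent completion.
#' @return An object of class `contact_events`.
#' @export
contact_events <- function(contact_times, includes_start = TRUE) {
  contact_times <- as.numeric(contact_times)
  if (length(contact_times) < 1) {
    stop("contact_events requires at least one contact time", call. = FALSE)
  }
  if (length(contact_times) >= 2 && any(diff(contact_times) <= 0)) {
    stop("contact times must be strictly increasing", call. = FALSE)
  }
  structure(list(contact_times = contact_times,
                 includes_start = isTRUE(includes_start)),
            class = "contact_events")
}

#' @export
print.contact_events <- function(x, ...) {
  cat(sprintf("<contact_events> %d contacts%s: %s\n",
              length(x$contact_times),
              if (x$includes_start) " (incl. start)" else "",
              paste(sprintf("%.2f", x$contact_times), collapse = ", ")))
  invisible(x)
}

#' Rise/descent phase boundaries
#'
#' Onset and offset instants of the chair-rise and chair-descent movements,
#' paired per cycle in temporal order (rise onset < rise offset <= descent
#' onset < descent offset within each cycle).
#'
#' @param rise_onsets,rise_offsets,descent_onsets,descent_offsets Numeric
#'   vectors of equal length, times in seconds.
#' @return An object of class `phase_events`.
#' @export
phase_events <- function(rise_onsets, rise_offsets, descent_onsets,
                         descent_offsets) {
  lists <- list(rise_onsets = as.numeric(rise_onsets),
                rise_offsets = as.numeric(rise_offsets),
                descent_onsets = as.numeric(descent_onsets),
                descent_offsets = as.numeric(descent_offsets))
  n <- lengths(lists)
  if (length(unique(n)) != 1) {
    stop("phase event lists must have equal lengths (paired cycles)", call. = FALSE)
  }
  for (nm in names(lists)) {
    v <- lists[[nm]]
    if (length(v) >= 2 && any(diff(v) <= 0)) {
      stop(sprintf("%s must be strictly increasing", nm), call. = FALSE)
    }
  }
  with(lists, {
    bad <- rise_onsets >= rise_offsets | rise_offsets > descent_onsets |
      descent_onsets >= descent_offsets
    if (any(bad)) {
      stop("phase events must interleave rise_onset < rise_offset <= descent_onset < descent_offset",
           call. = FALSE)
    }
  })
  structure(lists, class = "phase_events")
}

#' @export
print.phase_events <- function(x, ...) {
  cat(sprintf("<phase_events> %d rise/descent cycle(s), span %.2f-%.2f s\n",
              length(x$rise_onsets),
              if (length(x$rise_onsets)) x$rise_onsets[1] else NA,
              if (length(x$descent_offsets)) max(x$descent_offsets) else NA))
  invisible(x)
}

n_cycles <- function(phases) length(phases$rise_onsets)
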