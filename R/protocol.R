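# Intermittent stimulation schedules: cyclic ON/OFF exposure (bench
# experiments) and clock-anchored daily sessions (animal experiments).

#' Cyclic ON/OFF stimulation protocol
#'
#' Tiles ON/OFF pairs from time zero until the total span is exhausted; a
#' final partial ON interval is truncated at the span, not dropped.
#'
#' @param on_min,off_min ON and OFF durations (minutes), > 0.
#' @param total_span_h Total protocol span (hours), > 0.
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol_cyclic(15, 15, 12)   # 24 cycles over 12 h
#' @export
stim_protocol_cyclic <- function(on_min, off_min, total_span_h) {
  if (on_min <= 0 || off_min <= 0)
    stop("ON and OFF durations must be > 0", call. = FALSE)
  if (total_span_h <= 0)
    stop("total span must be > 0", call. = FALSE)
  structure(list(mode = "cyclic", on_min = on_min, off_min = off_min,
                 total_span_h = total_span_h),
            class = "stim_protocol")
}

#' Daily-session stimulation protocol
#'
#' Repeats clock-anchored sessions every day for a number of days. Clock
#' times are naive local times on a day grid; sessions within one day must
#' not overlap.
#'
#' @param session_start_hours Session start times as hours of the day
#'   (e.g. `c(6, 12, 18)` for 6:00, 12:00, 18:00).
#' @param session_min Session duration (minutes), > 0.
#' @param n_days Number of consecutive days, >= 1.
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol_daily(c(6, 12, 18), 15, 14)
#' @export
stim_protocol_daily <- function(session_start_hours, session_min, n_days) {
  if (session_min <= 0) stop("session duration must be > 0", call. = FALSE)
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  st <- sort(session_start_hours) * 60          # minutes into the day
  if (length(st) > 1 && any(diff(st) < session_min))
    stop("validation error: sessions within a day overlap", call. = FALSE)
  if (utils::tail(st, 1) + session_min > 24 * 60)
    stop("validation error: session crosses midnight", call. = FALSE)
  structure(list(mode = "daily_sessions",
                 session_start_min = st,
                 session_min = session_min,
                 n_days = n_days),
            class = "stim_protocol")
}

#' Build the ordered list of ON intervals of a protocol
#'
#' @param protocol A [stim_protocol_cyclic()] or [stim_protocol_daily()].
#' @return A data.frame with columns `start_min`, `end_min` (minutes on a
#'   continuous axis starting at protocol time zero), sorted and
#'   non-overlapping, plus attribute `span_min` (total protocol span).
#' @examples
#' nrow(build_schedule(stim_protocol_cyclic(15, 15, 12)))   # 24
#' @export
build_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$mode == "cyclic") {
    span <- protocol$total_span_h * 60
    period <- protocol$on_min + protocol$off_min
    n <- ceiling(span / period - 1e-9)
    starts <- (seq_len(n) - 1) * period
    ends <- pmin(starts + protocol$on_min, span)
    out <- data.frame(start_min = starts, end_min = ends)
  } else {
    span <- protocol$n_days * 24 * 60
    day0 <- rep((seq_len(protocol$n_days) - 1) * 24 * 60,
                each = length(protocol$session_start_min))
    starts <- day0 + rep(protocol$session_start_min, protocol$n_days)
    out <- data.frame(start_min = starts,
                      end_min = starts + protocol$session_min)
  }
  out <- out[order(out$start_min), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "span_min") <- span
  out
}

#' Summarize a stimulation schedule
#'
#' @param intervals Output of [build_schedule()] (or any data.frame with
#'   `start_min`/`end_min`).
#' @param span_min Span over which the duty cycle is computed; defaults to
#'   the schedule's `span_min` attribute, else the last interval end.
#' @return A list with `n_on` (interval count), `total_on_min` (summed ON
#'   minutes), and `duty_cycle` (fraction of the span spent ON).
#' @examples
#' schedule_summary(build_schedule(stim_protocol_cyclic(15, 15, 12)))
#' @export
schedule_summary <- function(intervals, span_min = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(list(n_on = 0L, total_on_min = 0, duty_cycle = 0))
  if (is.null(span_min)) span_min <- attr(intervals, "span_min")
  if (is.null(span_min)) span_min <- max(intervals$end_min)
  durations <- intervals$end_min - intervals$start_min
  if (any(durations < 0)) stop("malformed intervals", call. = FALSE)
  list(n_on = nrow(intervals),
       total_on_min = sum(durations),
       duty_cycle = sum(durations) / span_min)
}

#' Write a schedule as CSV
#'
#' @param intervals Output of [build_schedule()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(intervals, path) {
  utils::write.csv(intervals[, c("start_min", "end_min")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
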