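#' Growing-degree-day accumulation
#'
#' Phenology dates (heading, anthesis) are expressed as cumulative growing
#' degree days (GDD, base 32 F). Accumulation starts the day after the
#' first run of five consecutive days whose average temperature exceeds
#' 32 F (strict). Daily GDD uses min/max clamps at 32 F and 86 F:
#' `max(0, (max(t_min, 32) + min(t_max, 86)) / 2 - 32)`.
#'
#' @param ts a temperature series: data.frame with columns `date` (Date,
#'   consecutive days), `t_min_f`, `t_max_f` (Fahrenheit, `t_min_f <= t_max_f`).
#' @name gdd
NULL

check_temperature_series <- function(ts) {
  stopifnot(is.data.frame(ts),
            all(c("date", "t_min_f", "t_max_f") %in% names(ts)))
  if (any(ts$t_min_f > ts$t_max_f))
    stop("t_min above t_max on ", ts$date[which(ts$t_min_f > ts$t_max_f)[1]])
  if (nrow(ts) > 1 && any(diff(as.integer(as.Date(ts$date))) != 1))
    stop("temperature series dates must be consecutive days")
  invisible(ts)
}

#' @describeIn gdd Date on which GDD accumulation begins: the day after the
#'   first five consecutive days with average temperature strictly above
#'   32 F. Errors with "onset not reached" if no qualifying run exists.
#' @export
gdd_onset_day <- function(ts) {
  check_temperature_series(ts)
  if (nrow(ts) < 5) stop("need at least 5 days of temperatures")
  warm <- (ts$t_min_f + ts$t_max_f) / 2 > 32
  run <- 0L
  for (i in seq_along(warm)) {
    run <- if (warm[i]) run + 1L else 0L
    if (run == 5L) return(as.Date(ts$date[i]) + 1L)
  }
  stop("onset not reached: no 5-day run with average temperature > 32 F")
}

#' @describeIn gdd Degree-days for one day from its min/max temperatures (F).
#' @param t_min,t_max daily minimum and maximum temperature, Fahrenheit.
#' @export
daily_gdd <- function(t_min, t_max) {
  if (any(t_min > t_max)) stop("t_min must not exceed t_max")
  adj_min <- pmax(t_min, 32)
  adj_max <- pmin(t_max, 86)
  pmax(0, (adj_min + adj_max) / 2 - 32)
}

#' @describeIn gdd Cumulative GDD from the onset day through `event_date`
#'   inclusive; errors if the event precedes onset.
#' @param event_date the calendar date of the phenological event.
#' @export
cumulative_gdd <- function(ts, event_date) {
  check_temperature_series(ts)
  onset <- gdd_onset_day(ts)
  event_date <- as.Date(event_date)
  if (event_date < onset)
    stop("event date ", event_date, " precedes GDD onset ", onset)
  dates <- as.Date(ts$date)
  in_window <- dates >= onset & dates <= event_date
  if (!any(in_window)) return(0)
  sum(daily_gdd(ts$t_min_f[in_window], ts$t_max_f[in_window]))
}
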