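#' EMA schedule regime
#'
#' One of the three prescheduled assessment frequencies: thrice weekly
#' (Mon/Wed/Fri), daily, or thrice daily. Clock times default to
#' plausible waking-hours notification slots — 09:00 for single daily
#' occasions; 09:00, 14:00 and 20:00 for thrice daily — and are
#' configurable.
#'
#' @param kind `"thrice_weekly"`, `"daily"` or `"thrice_daily"`.
#' @param start a `Date` (or string) for the first study day; for the
#'   thrice-weekly regime occasions fall on the Mon/Wed/Fri of each
#'   study week beginning with the first Monday on or after `start`.
#' @param weeks study duration in weeks (default 12).
#' @param times character vector of `"HH:MM"` clock times per occasion
#'   day; defaults depend on `kind`.
#' @param tz time zone for the generated timestamps.
#' @return object of class `ema_regime`.
#' @export
ema_regime <- function(kind = c("thrice_weekly", "daily", "thrice_daily"),
                       start = as.Date("2022-07-18"), weeks = 12,
                       times = NULL, tz = "UTC") {
  kind <- match.arg(kind)
  stopifnot(weeks >= 0)
  if (is.null(times))
    times <- switch(kind,
                    thrice_weekly = "09:00",
                    daily = "09:00",
                    thrice_daily = c("09:00", "14:00", "20:00"))
  structure(list(kind = kind, start = as.Date(start),
                 weeks = weeks, times = times, tz = tz),
            class = "ema_regime")
}

#' @export
print.ema_regime <- function(x, ...) {
  cat(sprintf("<ema_regime> %s, %g week(s) from %s, times %s\n",
              x$kind, x$weeks, format(x$start),
              paste(x$times, collapse = "/")))
  invisible(x)
}

#' Generate the prescheduled occasion timestamps of a regime
#'
#' Deterministic: over `w` weeks a thrice-weekly regime yields `3 w`
#' occasions, a daily regime `7 w`, and a thrice-daily regime `21 w`.
#'
#' @param regime an [ema_regime()].
#' @return sorted `POSIXct` vector of occasion times (empty for a
#'   zero-week regime).
#' @examples
#' length(generate_schedule(ema_regime("daily", weeks = 12)))   # 84
#' @export
generate_schedule <- function(regime) {
  stopifnot(inherits(regime, "ema_regime"))
  if (regime$weeks == 0)
    return(as.POSIXct(character(0), tz = regime$tz))
  days <- switch(regime$kind,
    thrice_weekly = {
      # first Monday on or after start, then Mon/Wed/Fri of each week
      wd <- as.integer(format(regime$start, "%u"))  # 1 = Monday
      monday <- regime$start + (8L - wd) %% 7L
      as.vector(vapply(seq_len(regime$weeks) - 1L, function(w)
        monday + 7L * w + c(0L, 2L, 4L), numeric(3)))
    },
    regime$start + seq_len(7L * regime$weeks) - 1L)
  days <- as.Date(days, origin = "1970-01-01")
  stamps <- as.POSIXct(outer(as.character(days), regime$times, paste),
                       tz = regime$tz, format = "%Y-%m-%d %H:%M")
  sort(stamps)
}
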