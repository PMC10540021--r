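#' Latent symptom trajectory profile
#'
#' Two clinically motivated shapes for a simulated respondent's true
#' latent severity over a study window:
#' \describe{
#'   \item{`recovery`}{monotone exponential decay from a baseline
#'     toward an asymptote, emulating recovery from an injury with a
#'     good prognosis (e.g. a metacarpal fracture):
#'     `theta(t) = asymptote + (baseline - asymptote) exp(-rate t)`.}
#'   \item{`fluctuating`}{a baseline plus a sinusoidal diurnal swing,
#'     AR(1) occasion-to-occasion noise, and optionally a treatment
#'     "dip": severity falls linearly to `baseline - depth` over the
#'     first half of `rebound_days` after the intervention, then
#'     returns linearly to baseline — emulating a steroid injection in
#'     osteoarthritis whose benefit washes out over about 10 days.}
#' }
#' Time is measured in days from the study start.
#'
#' @param kind `"recovery"` or `"fluctuating"`.
#' @param baseline latent severity at day 0 (z-score scale).
#' @param asymptote recovery endpoint (recovery kind).
#' @param rate exponential recovery rate per day (recovery kind).
#' @param diurnal_amplitude half-range of the within-day sinusoid
#'   (fluctuating kind); severity peaks in the evening.
#' @param ar_sd innovation SD of the AR(1) occasion noise; 0 gives a
#'   deterministic trajectory.
#' @param ar_rho AR(1) autocorrelation between successive occasions.
#' @param intervention optional list `list(time, depth, rebound_days)`
#'   (fluctuating kind): intervention day, dip depth (z units), and
#'   days until return to baseline (> 0).
#' @return object of class `trajectory_profile`.
#' @export
trajectory_profile <- function(kind = c("recovery", "fluctuating"),
                               baseline = 1,
                               asymptote = -1, rate = 0.05,
                               diurnal_amplitude = 0.3,
                               ar_sd = 0.25, ar_rho = 0.7,
                               intervention = NULL) {
  kind <- match.arg(kind)
  stopifnot(ar_sd >= 0, ar_rho >= 0, ar_rho < 1)
  if (!is.null(intervention)) {
    stopifnot(all(c("time", "depth", "rebound_days") %in%
                    names(intervention)),
              intervention$rebound_days > 0)
  }
  structure(list(kind = kind, baseline = baseline, asymptote = asymptote,
                 rate = rate, diurnal_amplitude = diurnal_amplitude,
                 ar_sd = ar_sd, ar_rho = ar_rho,
                 intervention = intervention),
            class = "trajectory_profile")
}

#' @export
print.trajectory_profile <- function(x, ...) {
  cat(sprintf("<trajectory_profile> %s, baseline %.2f\n",
              x$kind, x$baseline))
  invisible(x)
}

#' Evaluate a latent trajectory at a set of occasion times
#'
#' Returns the true latent severity at each occasion. The systematic
#' part is a closed form of time; the stochastic part (fluctuating
#' kind only) is a stationary AR(1) process over the occasion sequence,
#' generated from `seed` so that a given `(profile, times, seed)`
#' triple is fully reproducible. Pass `times` as days since study
#' start (numeric) or as `POSIXct`.
#'
#' @param profile a [trajectory_profile()].
#' @param times numeric days since study start, or `POSIXct`
#'   timestamps (converted using the first element as applicable;
#'   `origin` overrides the study start).
#' @param seed integer seed for the AR(1) noise stream.
#' @param origin `POSIXct` study start used to convert timestamp input.
#' @return numeric vector of latent severities, one per time.
#' @examples
#' p <- trajectory_profile("recovery", baseline = 1.5, asymptote = -1)
#' latent_theta_at(p, c(0, 30, 1000))
#' @export
latent_theta_at <- function(profile, times, seed = 1L, origin = NULL) {
  if (inherits(times, "POSIXct")) {
    if (is.null(origin)) origin <- min(times)
    tday <- as.numeric(difftime(times, origin, units = "days"))
  } else tday <- as.numeric(times)
  n <- length(tday)
  if (n == 0L) return(numeric(0))
  if (profile$kind == "recovery") {
    mu <- profile$asymptote +
      (profile$baseline - profile$asymptote) * exp(-profile$rate * tday)
  } else {
    # diurnal sinusoid peaking at 18:00 (hour 18 of the day)
    hour <- (tday %% 1) * 24
    mu <- profile$baseline +
      profile$diurnal_amplitude * sin(2 * pi * (hour - 12) / 24)
    iv <- profile$intervention
    if (!is.null(iv)) {
      rel <- tday - iv$time
      half <- iv$rebound_days / 2
      dip <- numeric(n)
      within <- rel > 0 & rel <= iv$rebound_days
      dip[within] <- -iv$depth *
        (1 - abs(rel[within] - half) / half)   # V shape, trough at half
      mu <- mu + dip
    }
  }
  if (profile$kind == "fluctuating" && profile$ar_sd > 0) {
    noise <- with_preserved_seed(seed, {
      e <- stats::rnorm(n, 0, profile$ar_sd)
      x <- numeric(n)
      x[1] <- stats::rnorm(1, 0,
                           profile$ar_sd / sqrt(1 - profile$ar_rho^2))
      if (n > 1L)
        for (i in 2:n) x[i] <- profile$ar_rho * x[i - 1] + e[i]
      x
    })
    mu <- mu + noise
  }
  mu
}

#' Draw a response category from the measurement model
#'
#' Samples one response category for each item from the graded
#' response model at the given latent severity. Uses R's global RNG;
#' seed with `set.seed()` for reproducibility.
#'
#' @param theta latent severity (scalar).
#' @param bank an [item_bank()].
#' @param item item index or id (vectorized).
#' @return integer category (`1 .. K`), one per item.
#' @export
simulate_response <- function(theta, bank, item) {
  vapply(item, function(it) {
    i <- resolve_item(bank, it)
    p <- grm_category_probs(theta, bank, i)
    sample.int(length(p), 1L, prob = p)
  }, integer(1))
}

#' Define a simulated respondent
#'
#' A respondent couples a latent trajectory with compliance and
#' response-delay behaviour. Compliance is an independent Bernoulli
#' per scheduled occasion; the delay between notification and response
#' is log-normal, parameterized by its median in minutes (default 54,
#' a typical observed notification-to-response median) and a log-scale
#' SD chosen to give a wide right tail (IQR roughly 12 min to 3.5 h).
#'
#' @param id respondent identifier.
#' @param profile a [trajectory_profile()].
#' @param regime an [ema_regime()].
#' @param compliance probability of completing each scheduled occasion.
#' @param delay_median_min median response delay, minutes.
#' @param delay_sdlog log-scale SD of the delay distribution.
#' @param seed integer seed driving this respondent's trajectory noise.
#' @return object of class `sim_respondent`.
#' @export
sim_respondent <- function(id, profile, regime,
                           compliance = 0.9,
                           delay_median_min = 54, delay_sdlog = 2.1,
                           seed = 1L) {
  stopifnot(compliance >= 0, compliance <= 1, delay_median_min >= 0)
  structure(list(id = as.character(id), profile = profile,
                 regime = regime, compliance = compliance,
                 delay_median_min = delay_median_min,
                 delay_sdlog = delay_sdlog, seed = as.integer(seed)),
            class = "sim_respondent")
}

#' Build a simulated study cohort
#'
#' Mirrors a two-condition pilot design: respondents split between a
#' recovery-type condition (hand trauma) and a fluctuating-type
#' condition (thumb-base osteoarthritis), allocated across the three
#' EMA regimes. Default arm sizes 12 / 15 / 12 (thrice weekly / daily
#' / thrice daily) and arm-level compliance 0.63 / 0.93 / 0.43 follow
#' the response-rate medians such a deployment can expect: daily
#' prompts are the easiest to build into a routine, very frequent
#' prompts fatigue respondents.
#'
#' @param n_per_regime named integer vector of arm sizes
#'   (`thrice_weekly`, `daily`, `thrice_daily`).
#' @param compliance named numeric vector of per-arm compliance.
#' @param weeks study duration in weeks.
#' @param start study start date.
#' @param seed integer master seed; respondent-level seeds and profile
#'   parameters derive from it.
#' @return list of [sim_respondent()] objects.
#' @export
simulate_cohort <- function(n_per_regime = c(thrice_weekly = 12,
                                             daily = 15,
                                             thrice_daily = 12),
                            compliance = c(thrice_weekly = 0.63,
                                           daily = 0.93,
                                           thrice_daily = 0.43),
                            weeks = 12, start = as.Date("2022-07-18"),
                            seed = 1L) {
  kinds <- names(n_per_regime)
  stopifnot(all(kinds %in% c("thrice_weekly", "daily", "thrice_daily")))
  draws <- with_preserved_seed(seed, {
    n_tot <- sum(n_per_regime)
    list(baseline = stats::runif(n_tot, 0, 1.8),
         asymptote = stats::runif(n_tot, -1.8, -0.5),
         rate = stats::runif(n_tot, 0.03, 0.08),
         seeds = sample.int(.Machine$integer.max, n_tot))
  })
  out <- list()
  r <- 0L
  for (kind in kinds) {
    for (j in seq_len(n_per_regime[[kind]])) {
      r <- r + 1L
      # alternate conditions so each arm holds both trajectory types
      profile <- if (r %% 2L == 1L)
        trajectory_profile("recovery",
                           baseline = draws$baseline[r],
                           asymptote = draws$asymptote[r],
                           rate = draws$rate[r])
      else
        trajectory_profile("fluctuating",
                           baseline = draws$baseline[r],
                           intervention = list(time = 7 * weeks / 4,
                                               depth = 1.2,
                                               rebound_days = 10))
      out[[r]] <- sim_respondent(
        sprintf("resp%03d", r), profile,
        ema_regime(kind, start = start, weeks = weeks),
        compliance = compliance[[kind]],
        seed = draws$seeds[r])
    }
  }
  out
}
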