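#' Run a simulated EMA study
#'
#' Administers an adaptive assessment to every cohort member at every
#' scheduled occasion they comply with. For each respondent, the first
#' completed assessment uses the standard normal prior; under the
#' default dynamic-prior policy every later assessment starts from the
#' normal approximation to the previous completed assessment's
#' posterior. Full-length administrations of the whole bank can
#' additionally be simulated at fixed study weeks (default 0, 6 and
#' 12) on the same latent value as that day's state, yielding paired
#' CAT/full-length records.
#'
#' @param cohort list of [sim_respondent()] objects.
#' @param bank an [item_bank()].
#' @param control a [cat_control()]; `control$prior_policy` selects
#'   dynamic or static priors.
#' @param full_length_weeks integer vector of study weeks at which a
#'   full-length administration is simulated (set `numeric(0)` to
#'   disable).
#' @param seed integer master seed; all response draws, compliance
#'   draws and delays derive from it deterministically.
#' @return object of class `ema_study`: list with
#'   \describe{
#'     \item{`response_log`}{data frame, one row per administered item:
#'       `participant_id, assessment_id, scheduled_time, response_time,
#'       item_id, category, step_eap, step_se`.}
#'     \item{`assessments`}{data frame, one row per completed CAT
#'       assessment: `participant_id, assessment_id, scheduled_time,
#'       response_time, theta_true, eap, se, ci_low, ci_high, n_items,
#'       termination_reason`.}
#'     \item{`full_length`}{data frame of full-length administrations
#'       with the same summary columns.}
#'     \item{`scheduled`}{data frame of all scheduled occasions and
#'       whether each was completed.}
#'   }
#' @export
run_study <- function(cohort, bank, control = cat_control(),
                      full_length_weeks = c(0, 6, 12), seed = 1L) {
  if (length(cohort) == 0L) stop("empty cohort")
  set.seed(seed)
  logs <- list(); sums <- list(); fulls <- list(); sched <- list()
  for (resp in cohort) {
    stopifnot(inherits(resp, "sim_respondent"))
    occasions <- generate_schedule(resp$regime)
    origin <- as.POSIXct(paste(format(resp$regime$start), "00:00"),
                         tz = resp$regime$tz)
    done <- stats::runif(length(occasions)) < resp$compliance
    theta <- latent_theta_at(resp$profile, occasions, seed = resp$seed,
                             origin = origin)
    delays <- stats::rlnorm(length(occasions),
                            meanlog = log(resp$delay_median_min),
                            sdlog = resp$delay_sdlog)
    sched[[length(sched) + 1L]] <-
      data.frame(participant_id = resp$id,
                 scheduled_time = occasions, completed = done)
    prior <- normal_prior()
    a_id <- 0L
    for (o in seq_along(occasions)) {
      if (!done[o]) next
      a_id <- a_id + 1L
      aid <- sprintf("%s_a%04d", resp$id, a_id)
      th <- theta[o]
      res <- run_assessment(function(item_id)
        simulate_response(th, bank, item_id), bank, prior, control)
      rt <- occasions[o] + delays[o] * 60
      logs[[length(logs) + 1L]] <-
        data.frame(participant_id = resp$id, assessment_id = aid,
                   scheduled_time = occasions[o], response_time = rt,
                   item_id = res$steps$item_id,
                   category = res$steps$category,
                   step_eap = res$steps$eap, step_se = res$steps$se)
      sums[[length(sums) + 1L]] <-
        data.frame(participant_id = resp$id, assessment_id = aid,
                   scheduled_time = occasions[o], response_time = rt,
                   theta_true = th,
                   as.data.frame(res$final),
                   termination_reason = res$reason)
      if (control$prior_policy == "dynamic")
        prior <- dynamic_prior(res$final, control$inflation,
                               control$sd_floor)
    }
    # full-length administrations on the same latent value as that day
    for (wk in full_length_weeks) {
      ft <- origin + (7 * wk * 86400) + 9 * 3600
      if (wk == resp$regime$weeks)
        ft <- ft - 86400  # final administration on the last study day
      # reuse the latent value of a same-day scheduled occasion when
      # one exists, so paired CAT/full-length scores measure the same
      # momentary state; otherwise evaluate the trajectory at ft
      same_day <- which(as.Date(occasions) == as.Date(ft))
      th <- if (length(same_day) > 0L) theta[same_day[1L]]
            else latent_theta_at(resp$profile, ft, seed = resp$seed,
                                 origin = origin)
      responses <- data.frame(
        item_id = bank$item_id,
        category = simulate_response(th, bank, bank$item_id))
      fs <- score_full_length(responses, bank, normal_prior(),
                              control$grid)
      fulls[[length(fulls) + 1L]] <-
        data.frame(participant_id = resp$id,
                   assessment_id = sprintf("%s_full_w%02d", resp$id, wk),
                   scheduled_time = ft, response_time = ft,
                   theta_true = th, as.data.frame(fs),
                   termination_reason = "full_length")
    }
  }
  structure(list(response_log = do.call(rbind, logs),
                 assessments = do.call(rbind, sums),
                 full_length = do.call(rbind, fulls),
                 scheduled = do.call(rbind, sched)),
            class = "ema_study")
}

#' @export
print.ema_study <- function(x, ...) {
  cat(sprintf(
    "<ema_study> %d participant(s), %d completed CAT assessment(s), %d full-length\n",
    length(unique(x$scheduled$participant_id)),
    nrow(x$assessments),
    if (is.null(x$full_length)) 0L else nrow(x$full_length)))
  invisible(x)
}

#' Summary statistics of a simulated study
#'
#' Computes per-respondent response rates, the distribution of items
#' used per assessment, per-item exposure counts, and the median
#' notification-to-response delay.
#'
#' @param study an `ema_study` from [run_study()].
#' @return object of class `study_summary`: list with
#'   `response_rates` (data frame `participant_id, scheduled,
#'   completed, rate`), `items_per_assessment` (list `median, min,
#'   max`), `exposure` (data frame `item_id, times_administered`),
#'   and `median_delay_min`.
#' @export
summarize_study <- function(study) {
  if (is.null(study$assessments) || nrow(study$assessments) == 0L)
    stop("study contains no completed assessments")
  sch <- stats::aggregate(completed ~ participant_id, study$scheduled,
                          function(z) c(n = length(z), done = sum(z)))
  rates <- data.frame(participant_id = sch$participant_id,
                      scheduled = sch$completed[, "n"],
                      completed = sch$completed[, "done"])
  rates$rate <- ifelse(rates$scheduled > 0,
                       rates$completed / rates$scheduled, NA_real_)
  n_items <- study$assessments$n_items
  exposure <- as.data.frame(table(item_id = study$response_log$item_id),
                            responseName = "times_administered",
                            stringsAsFactors = FALSE)
  exposure <- exposure[order(-exposure$times_administered), ]
  rownames(exposure) <- NULL
  delay <- as.numeric(difftime(study$assessments$response_time,
                               study$assessments$scheduled_time,
                               units = "mins"))
  structure(list(response_rates = rates,
                 items_per_assessment = list(median = stats::median(n_items),
                                             min = min(n_items),
                                             max = max(n_items)),
                 exposure = exposure,
                 median_delay_min = stats::median(delay)),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  ipa <- x$items_per_assessment
  cat(sprintf(
    "<study_summary> median response rate %.0f%%; items/assessment median %g (range %g-%g)\n",
    100 * stats::median(x$response_rates$rate, na.rm = TRUE),
    ipa$median, ipa$min, ipa$max))
  cat(sprintf("  most used item: %s (%d administrations); median delay %.0f min\n",
              x$exposure$item_id[1], x$exposure$times_administered[1],
              x$median_delay_min))
  invisible(x)
}

#' Compare CAT scores with same-day full-length scores
#'
#' Pairs each full-length administration with a CAT assessment
#' completed by the same respondent on the same calendar day (the
#' nearest one if several), then reports agreement statistics on the
#' z-score scale: mean signed error (CAT minus full-length), mean
#' absolute error, RMSE, and the Pearson correlation.
#'
#' @param study an `ema_study`, or a data frame of pre-formed pairs
#'   with columns `cat_eap` and `full_eap`.
#' @return object of class `cat_full_comparison`: list with `pairs`
#'   (data frame), `n_pairs`, `mean_error`, `mae`, `rmse`, `correlation`
#'   (`NA` when undefined, e.g. zero variance).
#' @export
compare_cat_full_length <- function(study) {
  if (is.data.frame(study)) {
    pairs <- study
  } else {
    if (is.null(study$full_length) || nrow(study$full_length) == 0L)
      stop("study contains no full-length administrations")
    pairs <- list()
    for (r in seq_len(nrow(study$full_length))) {
      fl <- study$full_length[r, ]
      cand <- study$assessments[
        study$assessments$participant_id == fl$participant_id &
        as.Date(study$assessments$scheduled_time) ==
          as.Date(fl$scheduled_time), ]
      if (nrow(cand) == 0L) next
      gap <- abs(as.numeric(difftime(cand$scheduled_time,
                                     fl$scheduled_time, units = "mins")))
      cat_row <- cand[which.min(gap), ]
      pairs[[length(pairs) + 1L]] <-
        data.frame(participant_id = fl$participant_id,
                   day = as.Date(fl$scheduled_time),
                   cat_eap = cat_row$eap, cat_se = cat_row$se,
                   full_eap = fl$eap, full_se = fl$se)
    }
    pairs <- do.call(rbind, pairs)
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no same-day CAT / full-length pairs to compare")
  err <- pairs$cat_eap - pairs$full_eap
  corr <- if (nrow(pairs) < 2L ||
              stats::sd(pairs$cat_eap) == 0 ||
              stats::sd(pairs$full_eap) == 0) NA_real_
          else stats::cor(pairs$cat_eap, pairs$full_eap)
  structure(list(pairs = pairs, n_pairs = nrow(pairs),
                 mean_error = mean(err), mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)), correlation = corr),
            class = "cat_full_comparison")
}

#' @export
print.cat_full_comparison <- function(x, ...) {
  cat(sprintf(
    "<cat_full_comparison> %d pair(s): mean error %.4f, MAE %.4f, RMSE %.4f, r = %s\n",
    x$n_pairs, x$mean_error, x$mae, x$rmse,
    ifelse(is.na(x$correlation), "NA",
           sprintf("%.3f", x$correlation))))
  invisible(x)
}

#' Paired CAT versus full-length scoring simulation
#'
#' The score-recovery experiment: draw `n` respondents with latent
#' severities `theta ~ N(0, 1)`, simulate a complete response vector
#' for each from the bank, score it full-length by EAP, then replay an
#' adaptive assessment against the same recorded responses (so CAT and
#' full-length scores are computed from identical data). Used to check
#' that CAT scores track full-length scores with negligible mean
#' signed error and that the SE-threshold stopping rule is sound.
#'
#' @param bank an [item_bank()].
#' @param n number of simulated respondents.
#' @param control a [cat_control()] (static standard normal prior is
#'   used for every respondent: each is scored once).
#' @param seed integer seed.
#' @return data frame with one row per respondent: `theta`,
#'   `full_eap`, `full_se`, `cat_eap`, `cat_se`, `n_items`,
#'   `termination_reason`.
#' @export
cat_vs_full_simulation <- function(bank, n = 5000,
                                   control = cat_control(), seed = 1L) {
  set.seed(seed)
  theta <- stats::rnorm(n)
  # draw all response vectors first so CAT replays the same data
  cats <- matrix(0L, n, length(bank))
  for (j in seq_along(bank$item_id)) {
    P <- grm_category_probs(theta, bank, j)    # n x K
    u <- stats::runif(n)
    cats[, j] <- rowSums(u > t(apply(P, 1L, cumsum))) + 1L
  }
  grid <- control$grid
  cache <- bank_prob_cache(bank, grid)
  prior <- normal_prior()
  prior_log <- stats::dnorm(grid$theta, prior$mean, prior$sd, log = TRUE)
  out <- vector("list", n)
  for (r in seq_len(n)) {
    # full-length EAP from the precomputed cache
    logp <- prior_log
    for (j in seq_along(bank$item_id))
      logp <- logp + log(cache[[j]][, cats[r, j]])
    mom <- posterior_moments(exp(logp - max(logp)), grid)
    resp <- data.frame(item_id = bank$item_id, category = cats[r, ])
    res <- run_assessment(scripted_responses(resp), bank, prior, control)
    out[[r]] <- data.frame(theta = theta[r],
                           full_eap = mom$mean, full_se = mom$sd,
                           cat_eap = res$final$eap, cat_se = res$final$se,
                           n_items = res$final$n_items,
                           termination_reason = res$reason)
  }
  do.call(rbind, out)
}
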