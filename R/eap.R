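#' Normal prior for the latent trait
#'
#' The prior used for EAP scoring. The first assessment of a respondent
#' uses the standard normal prior `N(0, 1)`; subsequent assessments may
#' use a [dynamic_prior()] carried over from the previous posterior.
#' The standard deviation is clamped below at `sd_floor` to prevent
#' numerical collapse under repeated dynamic updating.
#'
#' @param mean prior mean on the z-score scale.
#' @param sd prior standard deviation (clamped to `sd_floor`).
#' @param sd_floor smallest admissible sd (default 0.1).
#' @return object of class `normal_prior` with elements `mean`, `sd`.
#' @export
normal_prior <- function(mean = 0, sd = 1, sd_floor = 0.1) {
  stopifnot(is.finite(mean), is.finite(sd), sd_floor > 0)
  structure(list(mean = mean, sd = max(sd, sd_floor)),
            class = "normal_prior")
}

#' @export
print.normal_prior <- function(x, ...) {
  cat(sprintf("<normal_prior> N(%.4g, %.4g^2)\n", x$mean, x$sd))
  invisible(x)
}

# unnormalized posterior over grid$theta (log-space accumulation for
# stability, shifted before exponentiation)
posterior_raw <- function(responses, bank, prior, grid, cache = NULL) {
  responses <- as.data.frame(responses)
  logp <- stats::dnorm(grid$theta, prior$mean, prior$sd, log = TRUE)
  if (nrow(responses) > 0L) {
    # accumulate in bank order so the result is independent of
    # administration order (exact full-bank/CAT agreement)
    responses <- responses[order(match(as.character(responses$item_id),
                                       bank$item_id)), , drop = FALSE]
    for (r in seq_len(nrow(responses))) {
      i <- resolve_item(bank, responses$item_id[r])
      k <- as.integer(responses$category[r])
      if (k < 1L || k > bank$n_categories[i])
        stop("response category ", k, " out of range for item ",
             bank$item_id[i])
      pk <- if (is.null(cache)) grm_category_probs(grid$theta, bank, i)[, k]
            else cache[[i]][, k]
      logp <- logp + ifelse(pk > 0, log(pk), -Inf)
    }
  }
  m <- max(logp)
  if (!is.finite(m))
    stop("degenerate posterior: zero density everywhere on the grid")
  exp(logp - m)
}

# EAP mean/sd from an unnormalized gridded density
posterior_moments <- function(dens, grid) {
  z <- sum(grid$weights * dens)
  if (!is.finite(z) || z <= 0)
    stop("degenerate posterior: zero density everywhere on the grid")
  m1 <- sum(grid$weights * grid$theta * dens) / z
  m2 <- sum(grid$weights * grid$theta^2 * dens) / z
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)), z = z)
}

#' Expected a posteriori (EAP) score summary
#'
#' Scores a response pattern by numerical integration on a quadrature
#' grid: the EAP estimate is the posterior mean
#' `eap = integral(theta L(theta) pi(theta)) / integral(L(theta) pi(theta))`,
#' the SE of measurement is the posterior standard deviation, and the
#' 95% credible interval uses the normal approximation
#' `eap +/- 1.959964 se`. With no responses the summary reproduces the
#' prior.
#'
#' @param responses data frame with columns `item_id`, `category`
#'   (1-based); may have zero rows.
#' @param bank an [item_bank()].
#' @param prior a [normal_prior()].
#' @param grid a [quad_grid()].
#' @return object of class `score_summary`: list with `eap`, `se`,
#'   `ci_low`, `ci_high`, `n_items`.
#' @examples
#' bank <- simulate_item_bank()
#' eap_summary(data.frame(item_id = "item06", category = 4), bank)
#' @export
eap_summary <- function(responses, bank, prior = normal_prior(),
                        grid = quad_grid()) {
  dens <- posterior_raw(responses, bank, prior, grid)
  mom <- posterior_moments(dens, grid)
  score_summary(mom$mean, mom$sd, nrow(as.data.frame(responses)))
}

score_summary <- function(eap, se, n_items, timestamp = NULL) {
  structure(list(eap = eap, se = se,
                 ci_low = eap - Z95 * se, ci_high = eap + Z95 * se,
                 n_items = as.integer(n_items), timestamp = timestamp),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf(
    "<score_summary> eap = %.3f, se = %.3f, 95%% CI [%.3f, %.3f], %d item%s\n",
    x$eap, x$se, x$ci_low, x$ci_high, x$n_items,
    if (x$n_items == 1L) "" else "s"))
  invisible(x)
}

#' @export
as.data.frame.score_summary <- function(x, ...) {
  data.frame(eap = x$eap, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, n_items = x$n_items)
}

#' Normalized posterior density over the quadrature grid
#'
#' The gridded probability density of the latent trait given the
#' responses and prior; its quadrature-weighted sum is 1 and its mean
#' and standard deviation equal the EAP and SE from [eap_summary()].
#'
#' @inheritParams eap_summary
#' @return numeric vector of density values over `grid$theta`.
#' @export
posterior_density <- function(responses, bank, prior = normal_prior(),
                              grid = quad_grid()) {
  dens <- posterior_raw(responses, bank, prior, grid)
  dens / sum(grid$weights * dens)
}

#' Score a complete (full-length) response vector
#'
#' EAP scoring of one response per bank item — the full-length
#' administration against which CAT scores are compared. Identical
#' computation to [eap_summary()]; errors if any bank item is missing
#' from the responses.
#'
#' @inheritParams eap_summary
#' @return a `score_summary` with `n_items` equal to the bank size.
#' @export
score_full_length <- function(responses, bank, prior = normal_prior(),
                              grid = quad_grid()) {
  responses <- as.data.frame(responses)
  missing <- setdiff(bank$item_id, as.character(responses$item_id))
  if (length(missing) > 0L)
    stop("incomplete full-length response set; missing item(s): ",
         paste(missing, collapse = ", "))
  eap_summary(responses, bank, prior, grid)
}

#' Marginal reliability implied by an SE of measurement
#'
#' On a unit-variance latent scale, marginal reliability is
#' `1 - se^2`; the conventional CAT stopping threshold se < 0.3
#' corresponds to a reliability of 0.91.
#'
#' @param se SE of measurement (posterior SD), nonnegative.
#' @return numeric reliability.
#' @examples
#' marginal_reliability(0.3)  # 0.91
#' @export
marginal_reliability <- function(se) {
  stopifnot(all(se >= 0))
  1 - se^2
}

#' Classical mean-score scale scoring with a missingness cap
#'
#' Scores a fixed-length (non-IRT) scale as the mean of its observed
#' item scores, excluding response sets that are missing more than
#' `max_missing` items — the rule used for engagement-scale subscales.
#'
#' @param item_scores numeric vector of item scores with `NA` for
#'   missing responses.
#' @param max_missing maximum number of missing items tolerated
#'   (default 1).
#' @return the mean of the observed scores, or `NA` if the response set
#'   is excluded (with attribute `excluded = TRUE`).
#' @examples
#' scale_mean_score(c(1, 2, 3, 4, NA))        # 2.5
#' scale_mean_score(c(rep(4, 8), NA, NA))     # excluded -> NA
#' @export
scale_mean_score <- function(item_scores, max_missing = 1) {
  if (length(item_scores) == 0L) stop("empty item score vector")
  n_miss <- sum(is.na(item_scores))
  if (n_miss > max_missing)
    return(structure(NA_real_, excluded = TRUE))
  mean(item_scores, na.rm = TRUE)
}
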