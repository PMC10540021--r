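#' Posterior state of an assessment in progress
#'
#' Bundles the prior, the responses collected so far, and the gridded
#' (unnormalized) posterior density that the adaptive algorithm updates
#' after every response. Item selection and stopping decisions are both
#' functions of this state.
#'
#' @param bank an [item_bank()].
#' @param prior a [normal_prior()].
#' @param grid a [quad_grid()].
#' @param responses data frame with columns `item_id`, `category`
#'   already collected (default: none).
#' @return object of class `posterior_state`.
#' @export
posterior_state <- function(bank, prior = normal_prior(),
                            grid = quad_grid(),
                            responses = data.frame(item_id = character(0),
                                                   category = integer(0))) {
  cache <- bank_prob_cache(bank, grid)
  dens <- posterior_raw(responses, bank, prior, grid, cache)
  structure(list(bank = bank, prior = prior, grid = grid,
                 responses = as.data.frame(responses),
                 dens = dens, cache = cache),
            class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  mom <- posterior_moments(x$dens, x$grid)
  cat(sprintf(
    "<posterior_state> %d response(s); posterior mean %.3f, sd %.3f\n",
    nrow(x$responses), mom$mean, mom$sd))
  invisible(x)
}

#' Update a posterior state with one observed response
#'
#' @param state a [posterior_state()].
#' @param item item index or id.
#' @param category observed category, `1 .. K`.
#' @return the updated `posterior_state`.
#' @export
update_posterior <- function(state, item, category) {
  i <- resolve_item(state$bank, item)
  k <- as.integer(category)
  if (k < 1L || k > state$bank$n_categories[i])
    stop("response category ", k, " out of range for item ",
         state$bank$item_id[i])
  state$dens <- state$dens * state$cache[[i]][, k]
  if (!any(state$dens > 0))
    stop("degenerate posterior: zero density everywhere on the grid")
  state$responses <- rbind(state$responses,
                           data.frame(item_id = state$bank$item_id[i],
                                      category = k))
  state
}

#' Posterior-predictive category probabilities for a candidate item
#'
#' The probability of each response category for an as-yet
#' unadministered item, averaged over the current posterior:
#' `P(X = k) = integral P(X = k | theta) posterior(theta) dtheta`.
#' These are the weights used by minimum-expected-posterior-variance
#' item selection.
#'
#' @param item item index or id, not yet administered.
#' @param state a [posterior_state()].
#' @return probability vector of length `K`, summing to 1.
#' @export
predictive_category_probs <- function(item, state) {
  i <- resolve_item(state$bank, item)
  P <- state$cache[[i]]
  m0 <- colSums(state$grid$weights * state$dens * P)
  m0 / sum(state$grid$weights * state$dens)
}

#' Expected posterior variance after administering a candidate item
#'
#' For each possible category `k` of the candidate item, the posterior
#' variance of theta that would result from observing `k` is computed,
#' and the variances are averaged with posterior-predictive weights:
#' `EPV = sum_k P(X = k) Var(theta | responses + (item, k))`.
#' By the law of total variance this never exceeds the current
#' posterior variance. The item minimizing EPV is the
#' minimum-expected-posterior-variance (MEPV) selection.
#'
#' @inheritParams predictive_category_probs
#' @return nonnegative scalar.
#' @export
expected_posterior_variance <- function(item, state) {
  i <- resolve_item(state$bank, item)
  P <- state$cache[[i]]
  w <- state$grid$weights
  th <- state$grid$theta
  cand <- state$dens * P                  # n_points x K candidate posteriors
  m0 <- colSums(w * cand)
  m1 <- colSums(w * th * cand)
  m2 <- colSums(w * th^2 * cand)
  ok <- m0 > 0
  vark <- numeric(ncol(P))
  vark[ok] <- pmax(m2[ok] / m0[ok] - (m1[ok] / m0[ok])^2, 0)
  pred <- m0 / sum(m0)                    # == predictive_category_probs
  sum(pred * vark)
}

#' Item selection criterion
#'
#' @param kind `"MEPV"` (minimum expected posterior variance, the
#'   default) or `"max_info"` (maximum Fisher information at the
#'   current EAP estimate).
#' @param randomesque_n exposure control: select uniformly at random
#'   among the `n` best items under the criterion. `1` (default) is
#'   fully deterministic.
#' @return object of class `select_criterion`.
#' @export
select_criterion <- function(kind = c("MEPV", "max_info"),
                             randomesque_n = 1L) {
  kind <- match.arg(kind)
  stopifnot(randomesque_n >= 1L)
  structure(list(kind = kind, randomesque_n = as.integer(randomesque_n)),
            class = "select_criterion")
}

#' Select the next item to administer
#'
#' Ranks the remaining items under the criterion — ascending expected
#' posterior variance for MEPV, descending Fisher information at the
#' current EAP for max-information — breaking ties by lowest bank
#' index, and returns the best item. With `randomesque_n > 1` the
#' selection is drawn uniformly from the `n` top-ranked items
#' (clamped to the number remaining), which diversifies item exposure.
#'
#' Randomesque draws use R's global RNG stream; seed with `set.seed()`
#' for reproducibility.
#'
#' @param state a [posterior_state()].
#' @param remaining character vector of item ids still available.
#' @param criterion a [select_criterion()].
#' @return the selected item id (length-1 character).
#' @export
select_next_item <- function(state, remaining,
                             criterion = select_criterion()) {
  if (length(remaining) == 0L) stop("no items remaining to select from")
  idx <- vapply(remaining, resolve_item, integer(1), bank = state$bank)
  score <- switch(criterion$kind,
    MEPV = vapply(idx, function(i)
      expected_posterior_variance(i, state), numeric(1)),
    max_info = {
      mom <- posterior_moments(state$dens, state$grid)
      -vapply(idx, function(i)
        item_information(mom$mean, state$bank, i), numeric(1))
    })
  # ascending criterion score, ties broken by lowest bank index
  ord <- order(score, idx)
  n_pick <- min(criterion$randomesque_n, length(remaining))
  pick <- if (n_pick == 1L) ord[1L]
          else ord[sample.int(n_pick, 1L)]
  state$bank$item_id[idx[pick]]
}

#' Stopping rule for adaptive assessments
#'
#' @param se_threshold stop once the SE of measurement (posterior SD)
#'   drops below this value (default 0.3, which corresponds to a
#'   marginal reliability of about 0.91).
#' @param max_items hard cap on items administered (`Inf` = bank size).
#' @param min_items minimum number of items before the SE rule is
#'   evaluated (default 1, so an assessment never terminates with zero
#'   items even under a very tight carried-over prior).
#' @return object of class `stopping_rule`.
#' @export
stopping_rule <- function(se_threshold = 0.3, max_items = Inf,
                          min_items = 1L) {
  stopifnot(se_threshold > 0, min_items >= 1L, min_items <= max_items)
  structure(list(se_threshold = se_threshold, max_items = max_items,
                 min_items = as.integer(min_items)),
            class = "stopping_rule")
}

#' Evaluate the stopping rule
#'
#' Stops when (a) at least `min_items` items have been administered and
#' the posterior SD has dropped below `se_threshold` (`"se_met"`), or
#' (b) `max_items` have been administered (`"max_items"`), or (c) no
#' items remain (`"bank_exhausted"`).
#'
#' @param se current SE of measurement (posterior SD).
#' @param n_administered items administered so far.
#' @param n_remaining items still available.
#' @param rule a [stopping_rule()].
#' @return list with `stop` (logical) and `reason`
#'   (`"se_met"`, `"max_items"`, `"bank_exhausted"`, or `NA` while
#'   continuing).
#' @export
should_stop <- function(se, n_administered, n_remaining,
                        rule = stopping_rule()) {
  if (n_administered >= rule$min_items && se < rule$se_threshold)
    return(list(stop = TRUE, reason = "se_met"))
  if (n_administered >= rule$max_items)
    return(list(stop = TRUE, reason = "max_items"))
  if (n_remaining == 0L)
    return(list(stop = TRUE, reason = "bank_exhausted"))
  list(stop = FALSE, reason = NA_character_)
}
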