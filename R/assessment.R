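#' Assessment configuration
#'
#' Bundles the estimator settings that define one CAT deployment. The
#' defaults mirror a typical precision-targeted deployment: EAP
#' scoring, MEPV item selection, stop once SE of measurement < 0.3
#' (marginal reliability about 0.91), at least one item per
#' assessment, standard normal first prior with dynamic priors
#' thereafter.
#'
#' @param criterion a [select_criterion()].
#' @param rule a [stopping_rule()].
#' @param grid a [quad_grid()].
#' @param prior_policy `"dynamic"` (carry each completed assessment's
#'   posterior forward as the next prior) or `"static"` (standard
#'   normal prior every time). Used by the repeated-assessment
#'   runners; a single [run_assessment()] takes its prior explicitly.
#' @param inflation between-assessment variance inflation for
#'   [dynamic_prior()] (default 0: the carried prior is the normal
#'   approximation to the previous posterior).
#' @param sd_floor smallest admissible prior sd.
#' @return object of class `cat_control`.
#' @export
cat_control <- function(criterion = select_criterion(),
                        rule = stopping_rule(),
                        grid = quad_grid(),
                        prior_policy = c("dynamic", "static"),
                        inflation = 0,
                        sd_floor = 0.1) {
  stopifnot(inflation >= 0)
  structure(list(criterion = criterion, rule = rule, grid = grid,
                 prior_policy = match.arg(prior_policy),
                 inflation = inflation, sd_floor = sd_floor),
            class = "cat_control")
}

#' Run one adaptive assessment
#'
#' The CAT loop: select the next item under the control's criterion,
#' pose it via `answer_fun`, update the posterior, record a step
#' summary, and repeat until the stopping rule fires. The final score
#' summary is identical to [eap_summary()] applied to all collected
#' responses.
#'
#' @param answer_fun callable `function(item_id)` returning the
#'   observed response category (`1 .. K`) for the posed item — an
#'   interactive prompt, a lookup into a recorded response vector, or
#'   a simulated respondent.
#' @param bank an [item_bank()].
#' @param prior a [normal_prior()]; the first assessment of a
#'   respondent uses the standard normal prior.
#' @param control a [cat_control()].
#' @return object of class `cat_assessment`: list with `steps` (data
#'   frame `item_id`, `category`, `eap`, `se` after each response),
#'   `final` (a `score_summary`), `reason` (`"se_met"`, `"max_items"`
#'   or `"bank_exhausted"`), and `prior`.
#' @examples
#' bank <- simulate_item_bank()
#' # a deterministic respondent who always answers category 4
#' res <- run_assessment(function(item_id) 4L, bank)
#' res$final
#' @export
run_assessment <- function(answer_fun, bank, prior = normal_prior(),
                           control = cat_control()) {
  rule <- control$rule
  max_items <- min(rule$max_items, length(bank))
  state <- posterior_state(bank, prior, control$grid)
  remaining <- bank$item_id
  steps <- vector("list", max_items)
  n <- 0L
  reason <- NA_character_
  repeat {
    item <- select_next_item(state, remaining, control$criterion)
    k <- answer_fun(item)
    k <- suppressWarnings(as.integer(k))
    i <- resolve_item(bank, item)
    if (is.na(k) || k < 1L || k > bank$n_categories[i])
      stop("administration error: invalid category for item ", item)
    state <- update_posterior(state, item, k)
    remaining <- setdiff(remaining, item)
    n <- n + 1L
    mom <- posterior_moments(state$dens, state$grid)
    steps[[n]] <- data.frame(item_id = item, category = k,
                             eap = mom$mean, se = mom$sd)
    dec <- should_stop(mom$sd, n, length(remaining),
                       stopping_rule(rule$se_threshold, max_items,
                                     rule$min_items))
    if (dec$stop) { reason <- dec$reason; break }
  }
  steps <- do.call(rbind, steps[seq_len(n)])
  # recompute the final summary from the collected responses so it is
  # bit-identical to eap_summary()/score_full_length() on the same data
  final <- eap_summary(steps[, c("item_id", "category")], bank, prior,
                       control$grid)
  structure(list(steps = steps,
                 final = final,
                 reason = reason,
                 prior = prior),
            class = "cat_assessment")
}

#' @export
print.cat_assessment <- function(x, ...) {
  cat(sprintf("<cat_assessment> %d item(s), terminated: %s\n",
              nrow(x$steps), x$reason))
  print(x$final)
  invisible(x)
}

#' Dynamic prior: carry a completed assessment forward
#'
#' Builds the prior for a respondent's next assessment from the normal
#' approximation to the previous assessment's posterior:
#' `N(eap, sqrt(se^2 + inflation^2))`. With `inflation = 0` the prior
#' is exactly the previous posterior's normal approximation; a positive
#' inflation widens it to acknowledge symptom change between
#' occasions. The sd is clamped to `sd_floor`.
#'
#' @param previous a `score_summary` from the completed assessment.
#' @param inflation nonnegative variance inflation (sd units).
#' @param sd_floor smallest admissible prior sd.
#' @return a [normal_prior()].
#' @examples
#' dynamic_prior(eap_summary(data.frame(item_id = "item06", category = 2),
#'                           simulate_item_bank()))
#' @export
dynamic_prior <- function(previous, inflation = 0, sd_floor = 0.1) {
  stopifnot(inherits(previous, "score_summary"), inflation >= 0)
  se <- max(previous$se, sd_floor)  # floor applies before inflation
  normal_prior(previous$eap, sqrt(se^2 + inflation^2),
               sd_floor = sd_floor)
}

#' Build a scripted response provider from recorded responses
#'
#' Turns a complete or partial response record (one category per item)
#' into the `answer_fun` callable that [run_assessment()] expects, so
#' that a CAT can be replayed against responses collected with the
#' full-length instrument.
#'
#' @param responses data frame with columns `item_id`, `category`.
#' @return `function(item_id)` returning the recorded category, or
#'   erroring if the item was never answered.
#' @export
scripted_responses <- function(responses) {
  responses <- as.data.frame(responses)
  lookup <- stats::setNames(as.integer(responses$category),
                            as.character(responses$item_id))
  function(item_id) {
    k <- lookup[[as.character(item_id)]]
    if (is.null(k) || is.na(k))
      stop("no recorded response for item ", item_id)
    k
  }
}
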