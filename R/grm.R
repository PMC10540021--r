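#' Graded response model cumulative probability
#'
#' Probability of responding in category `k + 1` or above,
#' `P(X >= k + 1 | theta) = logistic(a * (theta - b_k))`, the k-th
#' boundary curve of Samejima's graded response model in
#' slope-threshold parameterization with a pure logistic link (no 1.7
#' normal-ogive scaling constant).
#'
#' @param theta latent trait value(s), z-score scale.
#' @param bank an [item_bank()].
#' @param item item index or id within the bank.
#' @param k boundary index, `1 .. K - 1`.
#' @return numeric vector of probabilities, one per `theta`.
#' @examples
#' b <- item_bank("x", 2, list(c(-1, 0, 1)))
#' grm_cumulative(0, b, "x", 1)  # logistic(2 * (0 - -1)) = 0.8808
#' @export
grm_cumulative <- function(theta, bank, item, k) {
  i <- resolve_item(bank, item)
  b <- bank$thresholds[[i]]
  if (length(k) != 1L || k < 1L || k > length(b))
    stop("boundary index k must lie in 1..K-1 (item has ",
         length(b) + 1L, " categories)")
  stats::plogis(bank$a[i] * (theta - b[k]))
}

#' Graded response model category probabilities
#'
#' Adjacent differences of the cumulative boundary curves:
#' `P(X = k) = P(X >= k) - P(X >= k + 1)` with the conventions
#' `P(X >= 1) = 1` and `P(X >= K + 1) = 0`. Categories are numbered
#' `1 .. K`.
#'
#' @inheritParams grm_cumulative
#' @return for scalar `theta`, a probability vector of length `K`
#'   summing to 1; for vector `theta`, a `length(theta) x K` matrix.
#' @examples
#' b <- item_bank("x", 2, list(c(-1, 0, 1)))
#' grm_category_probs(0, b, "x")  # 0.1192 0.3808 0.3808 0.1192
#' @export
grm_category_probs <- function(theta, bank, item) {
  i <- resolve_item(bank, item)
  a <- bank$a[i]
  b <- bank$thresholds[[i]]
  cum <- stats::plogis(outer(theta, b, function(t, bb) a * (t - bb)))
  p <- cbind(1, cum) - cbind(cum, 0)
  if (length(theta) == 1L) drop(p) else p
}

#' Log-likelihood of a response pattern
#'
#' Sum of log category probabilities over independent items; an empty
#' response set has log-likelihood 0. A category with probability zero
#' at the given `theta` yields `-Inf` rather than an error.
#'
#' @param theta latent trait value(s).
#' @param bank an [item_bank()].
#' @param responses data frame (or list coercible to one) with columns
#'   `item_id` and `category` (1-based).
#' @return numeric vector, one log-likelihood per `theta`.
#' @export
grm_loglik <- function(theta, bank, responses) {
  responses <- as.data.frame(responses)
  ll <- numeric(length(theta))
  if (nrow(responses) == 0L) return(ll)
  for (r in seq_len(nrow(responses))) {
    i <- resolve_item(bank, responses$item_id[r])
    k <- as.integer(responses$category[r])
    if (k < 1L || k > bank$n_categories[i])
      stop("response category ", k, " out of range for item ",
           bank$item_id[i])
    p <- grm_category_probs(theta, bank, i)
    p <- if (is.matrix(p)) p[, k] else p[k]
    ll <- ll + ifelse(p > 0, log(p), -Inf)
  }
  ll
}

#' Fisher information of a graded item
#'
#' Expected information `I(theta) = sum_k P_k'(theta)^2 / P_k(theta)`,
#' where `P_k` are the category probabilities. For a dichotomous item
#' this reduces to the two-parameter-logistic closed form
#' `a^2 p (1 - p)`. Information is nonnegative and vanishes as
#' `|theta| -> Inf`.
#'
#' @inheritParams grm_cumulative
#' @return numeric vector of item information values, one per `theta`.
#' @export
item_information <- function(theta, bank, item) {
  i <- resolve_item(bank, item)
  a <- bank$a[i]
  b <- bank$thresholds[[i]]
  cum <- stats::plogis(outer(theta, b, function(t, bb) a * (t - bb)))
  dcum <- a * cum * (1 - cum)                  # boundary derivatives
  p <- cbind(1, cum) - cbind(cum, 0)           # category probabilities
  dp <- cbind(0, dcum) - cbind(dcum, 0)        # their derivatives
  info <- rowSums(ifelse(p > 0, dp^2 / p, 0))
  if (length(theta) == 1L) drop(info) else info
}

#' Quadrature grid for posterior integrals
#'
#' Equally spaced latent-trait points with trapezoid weights, used for
#' all EAP integrals. The default (161 points on `[-6, 6]`) keeps the
#' grid dense and wide enough that dynamic priors shifted well away
#' from 0 remain fully supported.
#'
#' @param lower,upper grid bounds on the z-score scale.
#' @param n_points number of points (>= 21).
#' @return object of class `quad_grid`: list with numeric `theta`
#'   (strictly increasing) and positive `weights`.
#' @export
quad_grid <- function(lower = -6, upper = 6, n_points = 161) {
  stopifnot(upper > lower, n_points >= 21)
  theta <- seq(lower, upper, length.out = n_points)
  h <- theta[2] - theta[1]
  w <- rep(h, n_points)
  w[c(1, n_points)] <- h / 2
  structure(list(theta = theta, weights = w), class = "quad_grid")
}

#' @export
print.quad_grid <- function(x, ...) {
  cat(sprintf("<quad_grid> %d points on [%g, %g], trapezoid weights\n",
              length(x$theta), min(x$theta), max(x$theta)))
  invisible(x)
}

# map an item id or index to its bank index
resolve_item <- function(bank, item) {
  if (is.character(item) || is.factor(item)) {
    i <- match(as.character(item), bank$item_id)
    if (is.na(i)) stop("unknown item_id: ", item)
  } else {
    i <- as.integer(item)
    if (is.na(i) || i < 1L || i > length(bank$item_id))
      stop("item index out of range: ", item)
  }
  i
}

# category-probability matrices for every item over a grid:
# list of length(bank) matrices, each n_points x K_i.
# Precomputed once per (bank, grid) pair and threaded through the CAT
# loop, where posterior updates reduce to elementwise products.
bank_prob_cache <- function(bank, grid) {
  lapply(seq_along(bank$item_id), function(i)
    grm_category_probs(grid$theta, bank, i))
}
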