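test_that("EAP with no responses reproduces the prior", {
  bank <- toy_bank()
  empty <- data.frame(item_id = character(0), category = integer(0))
  s <- eap_summary(empty, bank)
  expect_equal(s$eap, 0, tolerance = 1e-3)
  expect_equal(s$se, 1, tolerance = 1e-3)
  expect_identical(s$n_items, 0L)

  shifted <- eap_summary(empty, bank, normal_prior(1.2, 0.4))
  expect_equal(shifted$eap, 1.2, tolerance = 1e-3)
  expect_equal(shifted$se, 0.4, tolerance = 1e-3)
})

test_that("EAP summaries match a 10,001-point fine-grid oracle", {
  bank <- toy_bank()
  set.seed(42)
  for (rep in 1:8) {
    n_resp <- sample(1:5, 1)
    ids <- sample(bank$item_id, n_resp)
    resp <- data.frame(
      item_id = ids,
      category = vapply(ids, function(id)
        sample.int(bank$n_categories[match(id, bank$item_id)], 1),
        integer(1)))
    mu0 <- runif(1, -1, 1); sd0 <- runif(1, 0.3, 1.2)
    args <- bank_oracle_args(bank, resp)
    oracle <- oracle_posterior(args$a, args$b, args$k, mu0, sd0)
    s <- eap_summary(resp, bank, normal_prior(mu0, sd0))
    expect_equal(s$eap, oracle$mean, tolerance = 1e-4)
    expect_equal(s$se, oracle$sd, tolerance = 1e-4)
  }
})

test_that("score summaries carry the 95% normal-approximation interval", {
  bank <- toy_bank()
  s <- eap_summary(data.frame(item_id = "t1", category = 3), bank)
  expect_lt(s$ci_low, s$eap); expect_gt(s$ci_high, s$eap)
  expect_equal(s$ci_high - s$eap, 1.959964 * s$se, tolerance = 1e-9)
  expect_equal(s$eap - s$ci_low, 1.959964 * s$se, tolerance = 1e-9)
})

test_that("mirror responses to a symmetric dichotomous item give mirrored EAPs", {
  d <- item_bank("d", a = 2, thresholds = list(0))
  s1 <- eap_summary(data.frame(item_id = "d", category = 1), d)
  s2 <- eap_summary(data.frame(item_id = "d", category = 2), d)
  expect_equal(s1$eap, -s2$eap, tolerance = 1e-9)
  expect_equal(s1$se, s2$se, tolerance = 1e-9)
})

test_that("posterior density is normalized and consistent with the EAP summary", {
  bank <- toy_bank()
  resp <- data.frame(item_id = c("t1", "t4"), category = c(2, 3))
  grid <- quad_grid()
  dens <- posterior_density(resp, bank, grid = grid)
  expect_true(all(dens >= 0))
  expect_equal(sum(grid$weights * dens), 1, tolerance = 1e-9)

  s <- eap_summary(resp, bank, grid = grid)
  m <- sum(grid$weights * grid$theta * dens)
  v <- sum(grid$weights * grid$theta^2 * dens) - m^2
  expect_equal(m, s$eap, tolerance = 1e-9)
  expect_equal(sqrt(v), s$se, tolerance = 1e-9)

  # with no responses the density is proportional to the prior
  empty <- data.frame(item_id = character(0), category = integer(0))
  d0 <- posterior_density(empty, bank, normal_prior(0.5, 0.8), grid)
  ref <- dnorm(grid$theta, 0.5, 0.8)
  ref <- ref / sum(grid$weights * ref)
  expect_equal(d0, ref, tolerance = 1e-12)

  # an informative response concentrates the posterior
  s1 <- eap_summary(resp, bank)
  expect_lt(s1$se, 1)
})

test_that("predictive category probabilities match the fine-grid oracle", {
  bank <- toy_bank()
  resp <- data.frame(item_id = "t1", category = 3)
  state <- posterior_state(bank, responses = resp)
  for (item in c("t2", "t5")) {
    pred <- predictive_category_probs(item, state)
    expect_equal(sum(pred), 1, tolerance = 1e-9)
    args <- bank_oracle_args(bank, resp)
    o <- oracle_posterior(args$a, args$b, args$k)
    i <- match(item, bank$item_id)
    oracle_pred <- vapply(seq_len(bank$n_categories[i]), function(k)
      sum(o$weights * o$density * vapply(o$theta, function(t)
        oracle_cat_probs(t, bank$a[i], bank$thresholds[[i]])[k],
        numeric(1))), numeric(1))
    expect_equal(pred, oracle_pred, tolerance = 1e-6)
  }

  # near point-mass posterior: predictive probs approach the
  # category probabilities at the posterior mode
  tight <- posterior_state(bank, normal_prior(0.9, 0.1))
  expect_equal(predictive_category_probs("t3", tight),
               grm_category_probs(0.9, bank, "t3"), tolerance = 0.02)
})

test_that("expected posterior variance obeys the law of total variance and matches enumeration", {
  bank <- toy_bank()
  set.seed(7)
  for (rep in 1:6) {
    ids <- sample(bank$item_id, sample(0:3, 1))
    resp <- data.frame(
      item_id = ids,
      category = vapply(ids, function(id)
        sample.int(bank$n_categories[match(id, bank$item_id)], 1),
        integer(1)))
    state <- posterior_state(bank, responses = resp)
    cur_var <- posterior_density(resp, bank) |>
      (\(d) {
        g <- quad_grid()
        m <- sum(g$weights * g$theta * d)
        sum(g$weights * g$theta^2 * d) - m^2
      })()
    for (item in setdiff(bank$item_id, ids)) {
      epv <- expected_posterior_variance(item, state)
      expect_gte(epv, 0)
      expect_lte(epv, cur_var + 1e-12)
    }
  }

  # exhaustive enumeration oracle on a fixed state
  resp <- data.frame(item_id = "t1", category = 2)
  state <- posterior_state(bank, responses = resp)
  args <- bank_oracle_args(bank, resp)
  for (item in c("t2", "t3")) {
    i <- match(item, bank$item_id)
    o <- oracle_posterior(args$a, args$b, args$k)
    K <- bank$n_categories[i]
    pk <- vapply(seq_len(K), function(k)
      sum(o$weights * o$density * vapply(o$theta, function(t)
        oracle_cat_probs(t, bank$a[i], bank$thresholds[[i]])[k],
        numeric(1))), numeric(1))
    vk <- vapply(seq_len(K), function(k) {
      o2 <- oracle_posterior(c(args$a, bank$a[i]),
                             c(args$b, bank$thresholds[i]),
                             c(args$k, k))
      o2$sd^2
    }, numeric(1))
    expect_equal(expected_posterior_variance(item, state),
                 sum(pk * vk), tolerance = 1e-6)
  }

  # two identical items get identical values
  twin <- item_bank(c("u1", "u2"), a = c(2, 2),
                    thresholds = list(c(-0.5, 0.5), c(-0.5, 0.5)))
  st <- posterior_state(twin)
  expect_equal(expected_posterior_variance("u1", st),
               expected_posterior_variance("u2", st))
})

test_that("MEPV selection matches the enumeration oracle ranking", {
  bank <- toy_bank()
  resp <- data.frame(item_id = "t1", category = 2)
  state <- posterior_state(bank, responses = resp)
  remaining <- setdiff(bank$item_id, "t1")
  epvs <- vapply(remaining, function(it)
    expected_posterior_variance(it, state), numeric(1))
  best <- remaining[which.min(epvs)]
  expect_identical(select_next_item(state, remaining), best)

  # single remaining item is returned regardless of criterion
  expect_identical(select_next_item(state, "t4"), "t4")

  # deterministic when randomesque_n = 1, independent of RNG state
  set.seed(1); s1 <- select_next_item(state, remaining)
  set.seed(999); s2 <- select_next_item(state, remaining)
  expect_identical(s1, s2)

  # randomesque_n > 1 draws only from the top-n set
  crit <- select_criterion("MEPV", randomesque_n = 2)
  top2 <- remaining[order(epvs)][1:2]
  set.seed(5)
  draws <- replicate(30, select_next_item(state, remaining, crit))
  expect_true(all(draws %in% top2))
  expect_length(unique(draws), 2L)

  # max-information selection picks the information argmax at the EAP
  mi <- select_criterion("max_info")
  s <- eap_summary(resp, bank)
  infos <- vapply(remaining, function(it)
    item_information(s$eap, bank, it), numeric(1))
  expect_identical(select_next_item(state, remaining, mi),
                   remaining[which.max(infos)])

  expect_error(select_next_item(state, character(0)), "no items")
})

test_that("stopping rule fires on SE threshold, item cap, and exhaustion", {
  rule <- stopping_rule(se_threshold = 0.3, max_items = 5, min_items = 1)
  expect_identical(should_stop(0.29, 1, 4, rule),
                   list(stop = TRUE, reason = "se_met"))
  # not evaluated before the first item
  expect_false(should_stop(0.29, 0, 5, rule)$stop)
  expect_identical(should_stop(0.8, 5, 3, rule)$reason, "max_items")
  expect_identical(should_stop(0.8, 3, 0, rule)$reason, "bank_exhausted")
  expect_false(should_stop(0.31, 2, 3, rule)$stop)
  expect_error(stopping_rule(min_items = 4, max_items = 2), "min_items")
})

test_that("a CAT that exhausts the bank equals full-length scoring exactly", {
  bank <- toy_bank()
  responses <- data.frame(item_id = bank$item_id,
                          category = c(2, 1, 2, 3, 4))
  control <- cat_control(rule = stopping_rule(se_threshold = 1e-9,
                                              max_items = length(bank)))
  res <- run_assessment(scripted_responses(responses), bank,
                        control = control)
  expect_identical(res$final$n_items, 5L)
  full <- score_full_length(responses, bank)
  expect_identical(res$final$eap, full$eap)
  expect_identical(res$final$se, full$se)

  # the final summary equals eap_summary of the collected responses
  collected <- res$steps[, c("item_id", "category")]
  expect_identical(res$final$eap, eap_summary(collected, bank)$eap)
})

test_that("assessments are reproducible and record coherent steps", {
  bank <- toy_bank()
  provider <- function(theta) function(id) simulate_response(theta, bank, id)
  set.seed(33); r1 <- run_assessment(provider(0.4), bank)
  set.seed(33); r2 <- run_assessment(provider(0.4), bank)
  expect_identical(r1, r2)

  expect_false(any(duplicated(r1$steps$item_id)))
  expect_identical(nrow(r1$steps), r1$final$n_items)
  expect_equal(r1$steps$eap[nrow(r1$steps)], r1$final$eap,
               tolerance = 1e-12)
  if (r1$reason == "se_met") expect_lt(r1$final$se, 0.3)

  # invalid category from the provider names the item
  expect_error(run_assessment(function(id) 99L, bank),
               "administration error")
})

test_that("dynamic priors carry the previous posterior forward", {
  bank <- toy_bank()
  prev <- eap_summary(data.frame(item_id = "t1", category = 4), bank)
  p0 <- dynamic_prior(prev)
  expect_equal(p0$mean, prev$eap)
  expect_equal(p0$sd, prev$se)

  # closed-form inflation, with the sd floor applied first
  tiny <- promcat:::score_summary(1.2, 0, 5L)
  p1 <- dynamic_prior(tiny, inflation = 0.5)
  expect_equal(p1$sd, sqrt(0.1^2 + 0.5^2))
  expect_equal(dynamic_prior(promcat:::score_summary(1.2, 0.28, 3L))$sd,
               0.28)

  # a tight off-centre prior changes the first item selected, for a
  # bank whose information peaks are spread across the latent range
  wide <- simulate_item_bank()
  st_std <- posterior_state(wide, normal_prior())
  st_dyn <- posterior_state(wide, normal_prior(1.8, 0.32))
  expect_false(identical(select_next_item(st_std, wide$item_id),
                         select_next_item(st_dyn, wide$item_id)))
})

test_that("full-length scoring demands completeness and respects orientation", {
  bank <- toy_bank()
  responses <- data.frame(item_id = bank$item_id,
                          category = rep(1L, 5))
  s <- score_full_length(responses, bank)
  expect_lt(s$eap, 0)  # all-lowest responses sit at the mild end
  expect_error(score_full_length(responses[-2, ], bank),
               "missing item\\(s\\): t2")
})

test_that("marginal reliability and mean-score scaling follow their closed forms", {
  expect_equal(marginal_reliability(0.3), 0.91)
  expect_identical(marginal_reliability(0), 1)
  expect_identical(marginal_reliability(1), 0)

  expect_equal(scale_mean_score(c(1, 2, 3, 4, NA)), 2.5)
  expect_equal(scale_mean_score(rep(4, 8)), 4)
  excl <- scale_mean_score(c(rep(4, 8), NA, NA))
  expect_true(is.na(excl))
  expect_true(attr(excl, "excluded"))
  expect_error(scale_mean_score(numeric(0)), "empty")
})
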