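test_that("WAIC matches hand arithmetic on micro-instances", {
  # two draws, one cell
  ll <- matrix(c(log(0.5), log(0.25)), 2, 1)
  w <- waic(ll)
  expect_equal(w$lppd, log(0.375), tolerance = 1e-12)
  expect_equal(w$p_waic, var(c(log(0.5), log(0.25))), tolerance = 1e-12)
  expect_equal(w$waic, -2 * (log(0.375) - var(c(log(0.5), log(0.25)))),
               tolerance = 1e-12)

  # duplicated draws: zero variance, waic = -2 * sum ll
  ll2 <- rbind(c(log(0.3), log(0.8)), c(log(0.3), log(0.8)))
  w2 <- waic(ll2)
  expect_equal(w2$p_waic, 0)
  expect_equal(w2$waic, -2 * sum(log(c(0.3, 0.8))))

  # adding an identical independent cell doubles every term
  w3 <- waic(cbind(ll, ll))
  expect_equal(w3$lppd, 2 * w$lppd, tolerance = 1e-12)
  expect_equal(w3$p_waic, 2 * w$p_waic, tolerance = 1e-12)
})

test_that("WAIC accepts 3-d arrays, skips missing cells, rejects non-finite", {
  ll <- array(log(0.5), c(3, 2, 2))
  ll[, 1, 2] <- NA   # a missing response: whole cell NA
  w <- waic(ll)
  expect_equal(w$lppd, 3 * log(0.5))
  bad <- array(log(0.5), c(2, 1, 2))
  bad[2, 1, 2] <- -Inf
  expect_error(waic(bad), "draw 2, cell 2")
})

test_that("streaming WAIC equals the array version", {
  fx <- study_fixture(seed = 14, n_persons = 25)
  fit <- fit_model(fx$responses, fx$q, fx$cs, "mltmd",
                   config = sampler_config(chains = 2, warmup = 80, iter = 60,
                                           seed = 2))
  full <- waic(pointwise_loglik(fit, fx$responses))
  stream <- gmltmd:::waic_from_fit(fit, fx$responses, chunk = 17)
  expect_equal(stream$waic, full$waic, tolerance = 1e-8)
  expect_equal(stream$lppd, full$lppd, tolerance = 1e-8)
  expect_equal(stream$p_waic, full$p_waic, tolerance = 1e-8)
})

make_summary <- function(lower, eap, upper, dobs) {
  out <- data.frame(item = paste0("i", seq_along(lower)), lower = lower,
                    eap = eap, upper = upper, dobs = dobs)
  out$outside <- out$dobs < out$lower | out$dobs > out$upper
  class(out) <- c("predictive_summary", "data.frame")
  out
}

test_that("discordance rate counts items strictly outside their interval", {
  ps <- make_summary(rep(0.2, 4), rep(0.3, 4), rep(0.4, 4), rep(0.3, 4))
  expect_equal(discordance_rate(ps), 0)
  ps2 <- make_summary(rep(0.2, 4), rep(0.3, 4), rep(0.4, 4), rep(0.5, 4))
  expect_equal(discordance_rate(ps2), 1)
  # 27 items, 4 outside
  dobs <- rep(0.3, 27); dobs[c(2, 9, 17, 25)] <- 0.45
  ps3 <- make_summary(rep(0.2, 27), rep(0.3, 27), rep(0.4, 27), dobs)
  expect_equal(discordance_rate(ps3), 4 / 27)
  # invariant to item order
  perm <- sample(27)
  expect_equal(discordance_rate(ps3[perm, ]), 4 / 27)
})

test_that("interval bias is the mean exceedance beyond the interval", {
  ps <- make_summary(c(0.2, 0.2), c(0.3, 0.3), c(0.4, 0.4), c(0.3, 0.35))
  expect_equal(interval_bias(ps), 0)
  ps2 <- make_summary(c(0.2, 0.2), c(0.3, 0.3), c(0.4, 0.4), c(0.44, 0.3))
  expect_equal(interval_bias(ps2), 0.02)
  dobs <- rep(0.3, 10); dobs[3] <- 0.13; dobs[8] <- 0.52
  ps3 <- make_summary(rep(0.2, 10), rep(0.3, 10), rep(0.4, 10), dobs)
  expect_equal(interval_bias(ps3), mean(c(rep(0, 8), 0.07, 0.12)))
  expect_equal(interval_bias(ps3[sample(10), ]), interval_bias(ps3))
})

test_that("SRMR pools proportion and correlation residuals as an RMS", {
  J <- 27
  dp <- rep(0.1, J)
  dr <- rep(0, J * (J - 1) / 2)
  expect_equal(gmltmd:::srmr_pool(dp, dr),
               0.1 * sqrt(J / (J + J * (J - 1) / 2)), tolerance = 1e-12)
  # replicates identical to the observed data give zero
  set.seed(4)
  y <- matrix(rbinom(200, 1, 0.5), 20, 10)
  expect_equal(srmr(y, replicates = list(y)), 0)
})

test_that("SRMR excludes zero-variance items from the correlation set", {
  set.seed(5)
  y <- cbind(matrix(rbinom(60, 1, 0.5), 20, 3), rep(1, 20))
  expect_warning(val <- srmr(y, replicates = list(y)), "zero-variance")
  expect_equal(val, 0)
})

test_that("posterior predictive summaries behave under known draw dispersion", {
  ts <- tiny_structure()
  iter <- 300; N <- 40
  eta_point <- matrix(rep(c(0.4, -0.2), each = iter), iter, 2)
  set.seed(6)
  th <- array(rnorm(iter * N * 2), c(iter, N, 2))
  fit_point <- fake_fit(ts$q, ts$cs, list(eta_point, eta_point), list(th, th))
  y <- simulate_responses("mltmd", ts$q, ts$cs,
                          parameter_set(matrix(c(0.4, NA, NA, -0.2), 2, 2,
                                               dimnames = dimnames(ts$cs$incidence)),
                                        ts$cs),
                          n_persons = N, seed = 7, theta_source = "prior")
  ps_point <- posterior_predictive_marginals(fit_point, y, n_rep = 400, seed = 8)
  expect_true(all(ps_point$lower <= ps_point$eap & ps_point$eap <= ps_point$upper))
  expect_true(all(ps_point$dobs >= 0 & ps_point$dobs <= 1))

  # wider parameter dispersion gives (weakly) wider intervals
  eta_disp <- eta_point + rnorm(iter * 2, 0, 0.8)
  fit_disp <- fake_fit(ts$q, ts$cs, list(eta_disp, eta_disp), list(th, th))
  ps_disp <- posterior_predictive_marginals(fit_disp, y, n_rep = 400, seed = 8)
  expect_gt(mean(ps_disp$upper - ps_disp$lower),
            mean(ps_point$upper - ps_point$lower) - 1e-9)

  # with point-mass parameter draws the interval reflects pure binomial
  # replicate spread around the analytic marginal
  marg <- vapply(1:3, function(j) {
    composed <- compose_item_parameters(ts$q, parameter_set(
      matrix(c(0.4, NA, NA, -0.2), 2, 2, dimnames = dimnames(ts$cs$incidence)),
      ts$cs))
    f <- 1
    for (m in 1:2) {
      if (!composed$active[j, m]) next
      f <- f * stats::integrate(function(t) plogis(t - composed$difficulty[j, m]) * dnorm(t),
                                -Inf, Inf)$value
    }
    f
  }, numeric(1))
  binom_se <- sqrt(marg * (1 - marg) / N)
  # theta is re-drawn per replicate, so spread is binomial plus ability noise;
  # it must at least cover the binomial component and stay of its order
  width <- ps_point$upper - ps_point$lower
  expect_true(all(width > 2 * binom_se))
  expect_true(all(width < 12 * binom_se))
})

test_that("prior predictive proportions are coherent and reproducible", {
  fx <- fixture_structure()
  pp <- prior_predictive_check(prior_spec(), fx$q, fx$cs, "gmltmd",
                               n_sim = 150, seed = 9, n_persons = 120)
  expect_true(all(pp$proportions >= 0 & pp$proportions <= 1))
  expect_true(min(pp$quantiles$lower) > 0)   # the guessing floor keeps it off 0
  pp2 <- prior_predictive_check(prior_spec(), fx$q, fx$cs, "gmltmd",
                                n_sim = 150, seed = 9, n_persons = 120)
  expect_identical(pp$proportions, pp2$proportions)
})

test_that("point-mass priors collapse prior predictive quantiles to the analytic marginal", {
  ts <- tiny_structure()
  priors <- prior_spec(theta = c(0, 1), eta = c(0.5, 0))   # eta fixed at 0.5
  pp <- prior_predictive_check(priors, ts$q, ts$cs, "mltmd",
                               n_sim = 400, seed = 10, n_persons = 400)
  eta <- matrix(c(0.5, NA, NA, 0.5), 2, 2, dimnames = dimnames(ts$cs$incidence))
  composed <- compose_item_parameters(ts$q, parameter_set(eta, ts$cs))
  marg <- vapply(1:3, function(j) {
    f <- 1
    for (m in 1:2) {
      if (!composed$active[j, m]) next
      f <- f * stats::integrate(function(t) plogis(t - composed$difficulty[j, m]) * dnorm(t),
                                -Inf, Inf)$value
    }
    f
  }, numeric(1))
  expect_true(all(abs(pp$quantiles$median - marg) < 0.05))
  expect_true(all(pp$quantiles$upper - pp$quantiles$lower < 0.25))
})

test_that("component ICC curves have the textbook shape", {
  fx <- fixture_structure()
  composed <- compose_item_parameters(fx$q, fx$params)
  grid <- seq(-6, 6, by = 0.01)
  curves <- icc_curve("item11", composed, grid)
  expect_setequal(unique(curves$curve), c("global", "local", "joint"))

  # a component curve crosses 0.5 exactly at its difficulty
  g <- curves[curves$curve == "global", ]
  b <- composed$difficulty["item11", "global"]
  expect_equal(stats::approx(g$theta, g$p, xout = b)$y, 0.5, tolerance = 1e-6)

  # the joint curve's left asymptote is the guessing floor
  j <- curves[curves$curve == "joint", ]
  expect_equal(j$p[1], composed$guessing[["item11"]], tolerance = 1e-3)

  # larger discrimination steepens the slope at the difficulty
  steeper <- composed
  steeper$discrimination["item11", "global"] <- 2 * steeper$discrimination["item11", "global"]
  c2 <- icc_curve("item11", steeper, grid)
  g2 <- c2[c2$curve == "global", ]
  slope <- function(cv) {
    i <- which.min(abs(cv$theta - b))
    (cv$p[i + 1] - cv$p[i - 1]) / (cv$theta[i + 1] - cv$theta[i - 1])
  }
  expect_gt(slope(g2), slope(g))
})

test_that("model comparison tables are ranked by WAIC with name tiebreak", {
  fx <- study_fixture(seed = 15, n_persons = 25)
  fit <- fit_model(fx$responses, fx$q, fx$cs, "mltmd",
                   config = sampler_config(chains = 2, warmup = 60, iter = 40,
                                           seed = 3))
  one <- compare_models(list(only = fit), fx$responses, n_rep = 50, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(all(c("waic", "lppd", "p_waic", "srmr", "discordance",
                    "interval_bias") %in% colnames(one)))
  # identical fits tie; names break the tie alphabetically
  two <- compare_models(list(bbb = fit, aaa = fit), fx$responses,
                        n_rep = 50, seed = 1)
  expect_equal(two$model, c("aaa", "bbb"))
  expect_equal(two$waic[1], two$waic[2])
})
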