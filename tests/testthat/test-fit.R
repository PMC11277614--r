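# Structural and correctness contracts of the fitting machinery, on small
# samples with short chains (these tests check plumbing, not convergence).

test_that("the GMLTM-D fit instantiates the contracted parameter counts", {
  fit <- small_fit("gmltmd")
  # J = 27, K = 5, M = 2: 5 eta, 7 alpha groups (5 global + 2 local),
  # 27 guessing, 2N abilities
  expect_length(fit$eta_labels, 5L)
  expect_length(fit$alpha_labels, 7L)
  expect_length(fit$guess_labels, 27L)
  dm <- as_draws_matrix(fit, include_theta = TRUE)
  expect_equal(ncol(dm), 5L + 7L + 27L + 2L * 60L)
  expect_equal(nrow(dm), 2L * 100L)
})

test_that("the LLTM collapses to one component with K free difficulties", {
  fit <- small_fit("lltm")
  expect_length(fit$eta_labels, 5L)
  expect_length(fit$alpha_labels, 0L)
  expect_length(fit$guess_labels, 0L)
  expect_equal(length(fit$cs$component_ids), 1L)
  dm <- as_draws_matrix(fit, include_theta = TRUE)
  expect_equal(ncol(dm), 5L + 60L)
})

test_that("the constrained 2PL carries one discrimination per item", {
  fit <- small_fit("c2pl", iter = 50, warmup = 80)
  expect_length(fit$alpha_labels, 27L)
  expect_length(fit$guess_labels, 0L)
})

test_that("identical seed and config give identical draws", {
  f1 <- small_fit("gmltmd", n = 40, warmup = 80, iter = 40, seed = 7)
  f2 <- small_fit("gmltmd", n = 40, warmup = 80, iter = 40, seed = 7)
  expect_identical(f1$chains, f2$chains)
  f3 <- small_fit("gmltmd", n = 40, warmup = 80, iter = 40, seed = 8)
  expect_false(identical(f1$chains[[1]]$eta, f3$chains[[1]]$eta))
})

test_that("responses are matched to items by label, not position", {
  fx <- study_fixture(seed = 9, n_persons = 40)
  y <- fx$responses
  y_perm <- y[, rev(colnames(y))]
  cfg <- sampler_config(chains = 2, warmup = 80, iter = 40, seed = 3)
  f1 <- fit_model(y, fx$q, fx$cs, "mltmd", config = cfg)
  f2 <- fit_model(y_perm, fx$q, fx$cs, "mltmd", config = cfg)
  expect_identical(f1$chains, f2$chains)
  colnames(y_perm)[1] <- "nonexistent"
  expect_error(fit_model(y_perm, fx$q, fx$cs, "mltmd", config = cfg),
               "labels do not match")
})

test_that("missing responses drop out of the likelihood", {
  fx <- study_fixture(seed = 10, n_persons = 40)
  y <- fx$responses
  # making a column entirely missing must not break the fit
  y[, "item5"] <- NA
  fit <- fit_model(y, fx$q, fx$cs, "mltmd",
                   config = sampler_config(chains = 2, warmup = 80, iter = 40,
                                           seed = 3))
  expect_s3_class(fit, "gmltm_fit")
  ll <- pointwise_loglik(fit, y, draws = 1:3)
  expect_true(all(is.na(ll[, , "item5"])))
  expect_true(all(is.finite(ll[, , "item1"])))
})

test_that("pointwise log-likelihood equals the probability kernel", {
  fx <- study_fixture(seed = 11, n_persons = 30)
  fit <- fit_model(fx$responses, fx$q, fx$cs, "gmltmd",
                   config = sampler_config(chains = 2, warmup = 100, iter = 50,
                                           seed = 4))
  set.seed(12)
  draws <- sample.int(100, 50)
  ll <- pointwise_loglik(fit, fx$responses, draws = draws)
  for (si in c(1, 25, 50)) {
    ps <- gmltmd:::draw_parameter_set(fit, draws[si])
    composed <- compose_item_parameters(fx$q, ps)
    p <- success_prob_matrix(ps$theta, composed)
    expected <- ifelse(unclass(fx$responses) == 1L, p, 1 - p)
    expect_equal(exp(ll[si, , ]), expected, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("with no data the posterior reproduces the priors", {
  ts <- tiny_structure()
  y <- matrix(NA, 30, 3, dimnames = list(paste0("p", 1:30), rownames(ts$q)))
  fit <- fit_model(y, ts$q, ts$cs, "gmltmd",
                   config = sampler_config(chains = 2, warmup = 500,
                                           iter = 2000, seed = 5))
  dm <- as_draws_matrix(fit, include_theta = FALSE)
  thin <- seq(1, nrow(dm), by = 5)   # reduce autocorrelation for the KS test
  # MH chains repeat values when proposals are rejected; the resulting ties
  # only make the KS test conservative in the direction we assert
  ks_eta <- suppressWarnings(ks.test(dm[thin, "eta[c1,fA]"], "pnorm")$p.value)
  # half-normal via the folded cdf
  phalf <- function(x) 2 * stats::pnorm(x) - 1
  ks_alpha <- suppressWarnings(
    ks.test(dm[thin, fit$alpha_labels[1]], phalf)$p.value)
  ks_c <- suppressWarnings(
    ks.test(dm[thin, "c[t2]"], function(x) stats::pbeta(x, 3, 20))$p.value)
  expect_gt(ks_eta, 0.01)
  expect_gt(ks_alpha, 0.01)
  expect_gt(ks_c, 0.01)
})

test_that("posterior summaries are pure functions of the draws", {
  fit <- small_fit("mltmd", n = 40, warmup = 80, iter = 60)
  s1 <- summary(fit)
  s2 <- summary(fit)
  expect_identical(s1, s2)
  expect_true(all(s1$lower <= s1$eap & s1$eap <= s1$upper))
})
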