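test_that("simulation is seeded and reproducible", {
  fx <- fixture_structure()
  y1 <- simulate_responses("gmltmd", fx$q, fx$cs, fx$params, n_persons = 50,
                           seed = 3, theta_source = "prior")
  y2 <- simulate_responses("gmltmd", fx$q, fx$cs, fx$params, n_persons = 50,
                           seed = 3, theta_source = "prior")
  y3 <- simulate_responses("gmltmd", fx$q, fx$cs, fx$params, n_persons = 50,
                           seed = 4, theta_source = "prior")
  expect_identical(unclass(y1), unclass(y2))
  expect_false(identical(unclass(y1), unclass(y3)))
  expect_identical(attr(y1, "theta"), attr(y2, "theta"))
})

test_that("the guessing floor governs success at very low ability", {
  fx <- fixture_structure()
  p <- fx$params
  ps <- parameter_set(p$eta, fx$cs, alpha = p$alpha,
                      guessing = rep(0.3, 27), partition = p$partition,
                      theta = matrix(-10, 2000, 2))
  y <- simulate_responses("gmltmd", fx$q, fx$cs, ps, seed = 5,
                          theta_source = "given")
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_true(all(abs(colMeans(y) - 0.3) < 3 * se))
})

test_that("an examinee at the composed difficulty succeeds about half the time", {
  fx <- fixture_structure()
  cs1 <- derive_component_matrix(fx$q, matrix(1L, 5, 1))
  eta1 <- matrix(rowSums(fx$params$eta, na.rm = TRUE), ncol = 1,
                 dimnames = list(rownames(fx$params$eta), "comp1"))
  b1 <- compose_item_difficulties(fx$q, cs1, eta1)
  # simulate item by item with theta pinned at that item's difficulty
  n <- 3000
  se <- sqrt(0.25 / n)
  for (item in c("item1", "item11", "item24")) {
    ps <- parameter_set(eta1, cs1, theta = matrix(b1[item, 1], n, 1))
    y <- simulate_responses("lltm", fx$q, cs1, ps, seed = 8,
                            theta_source = "given")
    expect_lt(abs(mean(y[, item]) - 0.5), 3 * se)
  }
})

test_that("empirical item means match marginals from numerical integration", {
  # with independent standard-normal abilities the GMLTM-D marginal factors
  # per component, so a 1-D quadrature per component is an exact oracle
  fx <- fixture_structure()
  composed <- compose_item_parameters(fx$q, fx$params)
  marginal <- vapply(seq_len(27), function(j) {
    f <- 1
    for (m in 1:2) {
      if (!composed$active[j, m]) next
      f <- f * stats::integrate(function(t) {
        plogis(composed$discrimination[j, m] * (t - composed$difficulty[j, m])) *
          dnorm(t)
      }, -Inf, Inf)$value
    }
    composed$guessing[j] + (1 - composed$guessing[j]) * f
  }, numeric(1))
  n <- 5000
  y <- simulate_responses("gmltmd", fx$q, fx$cs, fx$params, n_persons = n,
                          seed = 21, theta_source = "prior")
  se <- sqrt(marginal * (1 - marginal) / n)
  expect_true(all(abs(colMeans(y) - marginal) < 3.5 * se))
})

test_that("success probabilities ignore abilities on inactive components", {
  fx <- fixture_structure()
  composed <- compose_item_parameters(fx$q, fx$params)
  set.seed(31)
  th <- matrix(rnorm(80), 40, 2)
  th2 <- th
  th2[, 2] <- rnorm(40)   # perturb the local ability
  p1 <- success_prob_matrix(th, composed)
  p2 <- success_prob_matrix(th2, composed)
  only_global <- fx$cs$component_matrix[, "local"] == 0L
  expect_identical(p1[, only_global], p2[, only_global])
})

test_that("the study fixture reproduces the published structure", {
  fx <- study_fixture(seed = 2, n_persons = 100)
  expect_equal(dim(fx$q), c(27L, 5L))
  expect_equal(unname(fx$q["item11", ]), c(0L, 1L, 1L, 1L, 1L))
  expect_equal(unname(fx$params$guessing[2]), 0.57)
  expect_equal(length(unique(fx$params$alpha)), 7L)
  expect_equal(dim(fx$responses), c(100L, 27L))
  expect_true(all(fx$responses %in% c(0L, 1L)))
  # same seed, same fixture
  fx2 <- study_fixture(seed = 2, n_persons = 100)
  expect_identical(unclass(fx$responses), unclass(fx2$responses))
})

test_that("response matrices reject malformed input", {
  expect_error(response_matrix(rbind(c(0, 2), c(1, 0))), "non-binary response")
  expect_error(response_matrix(diag(2), person_ids = c("a", "a")), "duplicate")
  y <- response_matrix(rbind(c(0, NA), c(1, 0)))
  expect_true(is.na(y[1, 2]))
})
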