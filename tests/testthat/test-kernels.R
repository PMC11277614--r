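test_that("the LLTM kernel is the logistic of ability minus composed difficulty", {
  # theta equal to the single rule's difficulty puts the item at 50%
  expect_equal(prob_lltm(0.53, c(1, 0, 0, 0, 0), c(0.53, 0.83, 0.43, 0.91, 0.03)),
               0.5)
  expect_equal(prob_lltm(1, c(1, 1), c(0.5, -0.5)), 0.7310586, tolerance = 1e-7)
  # extreme abilities stay finite with no overflow
  lo <- prob_lltm(-800, c(1, 0), c(0, 0))
  expect_true(is.finite(lo) && lo >= 0 && lo <= 1e-300)
  hi <- prob_lltm(800, c(1, 0), c(0, 0))
  expect_true(is.finite(hi) && hi <= 1)
})

test_that("the constrained 2PL scales the logit by a nonnegative slope", {
  th <- seq(-3, 3, by = 0.25)
  q_row <- c(1, 0, 1); eta <- c(0.4, 1, -0.2)
  expect_equal(prob_constrained_2pl(th, q_row, eta, 1), prob_lltm(th, q_row, eta))
  expect_equal(prob_constrained_2pl(th, q_row, eta, 0), rep(0.5, length(th)))
  expect_equal(prob_constrained_2pl(0.5, c(1), c(0), 2), 0.7310586,
               tolerance = 1e-7)
  expect_error(prob_constrained_2pl(0, c(1), c(0), -1), ">= 0")
})

test_that("MLTM-D multiplies component probabilities and ignores inactive ones", {
  fx <- fixture_structure()
  eta <- fx$params$eta
  b <- compose_item_difficulties(fx$q, fx$cs, eta)

  # both components at their difficulty: 0.5 * 0.5
  expect_equal(prob_mltmd(b["item11", ], "item11", fx$q, fx$cs, eta), 0.25)

  # item 3 uses only the global component: perturbing the local ability
  # leaves the probability bit-identical
  p1 <- prob_mltmd(c(0.3, -5), "item3", fx$q, fx$cs, eta)
  p2 <- prob_mltmd(c(0.3, 17), "item3", fx$q, fx$cs, eta)
  expect_identical(p1, p2)

  # with one component, MLTM-D is the LLTM
  cs1 <- derive_component_matrix(fx$q, matrix(1L, 5, 1))
  eta1 <- matrix(rowSums(eta, na.rm = TRUE), ncol = 1)
  rownames(eta1) <- rownames(eta)
  for (th in c(-2, 0, 1.5)) {
    expect_equal(prob_mltmd(th, "item9", fx$q, cs1, eta1),
                 prob_lltm(th, fx$q["item9", ], eta1[, 1]))
  }
})

test_that("GMLTM-D mixes the guessing floor with the noncompensatory product", {
  fx <- fixture_structure()
  composed <- compose_item_parameters(fx$q, fx$params)

  # at theta = b on both active components with c = 0.2: 0.2 + 0.8 * 0.25
  p <- fx$params
  p$guessing <- rep(0.2, 27)
  ps <- parameter_set(p$eta, fx$cs, alpha = p$alpha, guessing = p$guessing,
                      partition = p$partition)
  comp2 <- compose_item_parameters(fx$q, ps)
  expect_equal(prob_gmltmd(comp2$difficulty["item11", ], "item11", comp2), 0.4)

  # c = 0 and alpha = 1 reduces exactly to MLTM-D
  ps0 <- parameter_set(p$eta, fx$cs)
  comp0 <- compose_item_parameters(fx$q, ps0)
  for (i in 1:5) {
    th <- rnorm(2)
    expect_equal(prob_gmltmd(th, "item13", comp0),
                 prob_mltmd(th, "item13", fx$q, fx$cs, p$eta))
  }

  # the lower asymptote is the guessing value
  expect_equal(prob_gmltmd(c(-40, -40), "item11", composed),
               composed$guessing[["item11"]])
})

test_that("kernels are monotone in every active ability and bounded", {
  fx <- fixture_structure()
  composed <- compose_item_parameters(fx$q, fx$params)
  grid <- seq(-6, 6, by = 0.5)
  for (item in c("item4", "item11", "item18")) {
    for (m in 1:2) {
      if (!composed$active[item, m]) next
      th <- matrix(0, length(grid), 2)
      th[, m] <- grid
      p <- prob_gmltmd(th, item, composed)
      expect_true(all(diff(p) >= 0))
      cj <- composed$guessing[[item]]
      expect_true(all(p >= cj & p < 1))
    }
  }
})

test_that("the matrix kernel agrees with the scalar kernels cell by cell", {
  fx <- fixture_structure()
  composed <- compose_item_parameters(fx$q, fx$params)
  set.seed(99)
  theta <- matrix(rnorm(10), 5, 2)
  P <- success_prob_matrix(theta, composed)
  for (i in 1:5) for (item in c(1L, 4L, 11L, 27L)) {
    expect_equal(unname(P[i, item]), prob_gmltmd(theta[i, ], item, composed))
  }
  # log version matches
  expect_equal(log(P), success_prob_matrix(theta, composed, log.p = TRUE))
})
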