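# Probability kernels for the four nested models. All kernels accumulate the
# noncompensatory product in log space and exponentiate once, so extreme
# abilities never overflow.

# log plogis is the numerically safe route: plogis(x, log.p = TRUE) uses the
# appropriate branch for either sign of x.
log_logistic <- function(x) plogis(x, log.p = TRUE)

#' LLTM success probability
#'
#' `P(y = 1) = logistic(theta - sum_k q_k eta_k)`: a Rasch model whose item
#' difficulty is the sum of the difficulties of the features the item
#' contains.
#'
#' @param theta ability value(s), logit scale (vectorized).
#' @param q_row binary feature indicator vector for the item.
#' @param eta feature difficulty vector, same length as `q_row`.
#' @return success probability in (0, 1), same length as `theta`.
#' @export
prob_lltm <- function(theta, q_row, eta) {
  stopifnot(length(q_row) == length(eta))
  plogis(theta - sum(q_row * eta))
}

#' Constrained 2PL success probability
#'
#' The LLTM with a discrimination slope:
#' `P(y = 1) = logistic(alpha_j (theta - sum_k q_k eta_k))`. With
#' `alpha_j = 1` this reduces exactly to [prob_lltm()].
#'
#' @inheritParams prob_lltm
#' @param alpha_j nonnegative item discrimination.
#' @export
prob_constrained_2pl <- function(theta, q_row, eta, alpha_j) {
  if (alpha_j < 0) stop("alpha must be >= 0", call. = FALSE)
  plogis(alpha_j * (theta - sum(q_row * eta)))
}

#' MLTM-D success probability
#'
#' Noncompensatory product over components:
#' `P(y_j = 1) = prod_m logistic(theta_m - b_jm)^{C_jm}`, where
#' `b[j, m] = sum_k q[j, k] eta[k, m]` over component-`m` features. Components
#' with `C[j, m] = 0` contribute a factor of 1, so the value is invariant to
#' their abilities. With a single component this is exactly the LLTM.
#'
#' @param theta_row ability vector of length M (or an N x M matrix).
#' @param item item index or id.
#' @param q a [feature_matrix()].
#' @param cs a [derive_component_matrix()] structure.
#' @param eta K x M feature difficulty matrix (see
#'   [compose_item_difficulties()]).
#' @export
prob_mltmd <- function(theta_row, item, q, cs, eta) {
  b <- compose_item_difficulties(q, cs, eta)
  composed <- structure(
    list(difficulty = `attr<-`(b, "active", NULL),
         discrimination = matrix(1, nrow(b), ncol(b)),
         guessing = rep(0, nrow(b)), active = attr(b, "active")),
    class = "composed_item_parameters")
  prob_gmltmd(theta_row, item, composed)
}

#' GMLTM-D success probability
#'
#' The three-parameter generalization:
#' `P(y_j = 1) = c_j + (1 - c_j) prod_m logistic(alpha_jm (theta_m - b_jm))^{C_jm}`.
#' The guessing floor `c_j` is the success probability of an examinee who
#' masters none of the item's components; with `c_j = 0` and all
#' `alpha_jm = 1` the model reduces exactly to the MLTM-D.
#'
#' @param theta_row ability vector of length M (or an N x M matrix of rows).
#' @param item item index or id.
#' @param composed a [compose_item_parameters()] object.
#' @return probability in `[c_j, 1)`.
#' @export
prob_gmltmd <- function(theta_row, item, composed) {
  stopifnot(inherits(composed, "composed_item_parameters"))
  if (is.character(item)) item <- match(item, rownames(composed$difficulty))
  th <- if (is.matrix(theta_row)) theta_row else matrix(theta_row, nrow = 1)
  M <- ncol(composed$difficulty)
  stopifnot(ncol(th) == M)
  lp <- 0
  for (m in seq_len(M)) {
    if (!composed$active[item, m]) next   # inactive: factor 1, theta_m ignored
    lp <- lp + log_logistic(composed$discrimination[item, m] *
                              (th[, m] - composed$difficulty[item, m]))
  }
  cj <- composed$guessing[[item]]
  p <- guess_mix(lp, cj)
  if (!is.matrix(theta_row)) p <- as.vector(p)
  p
}

# p = c + (1-c) exp(lp), computed without leaving log space until the end;
# when c = 0 this is exp(lp) itself (no round trip through (1-p)).
guess_mix <- function(lp, cj) {
  if (cj == 0) exp(lp) else cj + (1 - cj) * exp(lp)
}

#' Success-probability matrix for a person-by-item design
#'
#' Vectorized GMLTM-D kernel: computes the full N x J matrix of success
#' probabilities given abilities and composed item parameters. The reduced
#' models are the special cases with unit discrimination and/or zero
#' guessing.
#'
#' @param theta N x M ability matrix.
#' @param composed a [compose_item_parameters()] object.
#' @param log.p return log probabilities of success instead.
#' @return N x J matrix.
#' @export
success_prob_matrix <- function(theta, composed, log.p = FALSE) {
  lp <- component_logprod(theta, composed)
  cj <- composed$guessing
  if (all(cj == 0)) {
    out <- if (log.p) lp else exp(lp)
  } else {
    p <- sweep(exp(lp), 2, 1 - cj, "*")
    p <- sweep(p, 2, cj, "+")
    out <- if (log.p) log(p) else p
  }
  colnames(out) <- rownames(composed$difficulty)
  out
}

# N x J matrix of sum_m C_jm log logistic(alpha_jm (theta_m - b_jm)):
# the log of the noncompensatory product, before the guessing mixture.
component_logprod <- function(theta, composed) {
  theta <- as.matrix(theta)
  J <- nrow(composed$difficulty)
  M <- ncol(composed$difficulty)
  stopifnot(ncol(theta) == M)
  lp <- matrix(0, nrow(theta), J)
  for (m in seq_len(M)) {
    act <- composed$active[, m]
    if (!any(act)) next
    z <- outer(theta[, m], composed$difficulty[act, m], "-")
    z <- sweep(z, 2, composed$discrimination[act, m], "*")
    lp[, act] <- lp[, act] + log_logistic(z)
  }
  lp
}

# Bernoulli log-likelihood matrix for observed responses; NA responses
# contribute 0. Both tails are computed in log space: with S the component
# log-product, log P(y=1) = log(c + (1-c) e^S) and
# log P(y=0) = log(1-c) + log(-expm1(S)).
bernoulli_loglik_matrix <- function(y, theta, composed) {
  lp <- component_logprod(theta, composed)
  cj <- composed$guessing
  if (all(cj == 0)) {
    lp1 <- lp
  } else {
    lp1 <- log(sweep(sweep(exp(lp), 2, 1 - cj, "*"), 2, cj, "+"))
    zero <- cj == 0                       # keep the deep tail exact there
    if (any(zero)) lp1[, zero] <- lp[, zero]
  }
  lp0 <- sweep(log(-expm1(lp)), 2, log1p(-cj), "+")
  ll <- ifelse(y == 1L, lp1, lp0)
  ll[is.na(y)] <- 0
  ll
}
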