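#' WAIC from a pointwise log-likelihood array
#'
#' `lppd = sum_cells log mean_s exp(ll)`, `p_waic = sum_cells var_s(ll)`
#' (sample variance over draws), `waic = -2 (lppd - p_waic)`. Lower is
#' better. The likelihood unit is the single person-item response; cells that
#' are entirely `NA` (missing responses) are skipped.
#'
#' @param ll draws x persons x items array (or draws x cells matrix) of
#'   pointwise log-likelihoods.
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(ll) {
  if (is.array(ll) && length(dim(ll)) == 3) {
    d <- dim(ll)
    dim(ll) <- c(d[1], d[2] * d[3])
  }
  ll <- as.matrix(ll)
  S <- nrow(ll)
  if (S < 2) stop("at least 2 draws are required for the variance term",
                  call. = FALSE)
  keep <- !apply(ll, 2, function(x) all(is.na(x)))
  ll <- ll[, keep, drop = FALSE]
  bad <- which(!is.finite(ll))
  if (length(bad)) {
    s <- ((bad[1] - 1) %% S) + 1
    cell <- ((bad[1] - 1) %/% S) + 1
    stop("non-finite log-likelihood at draw ", s, ", cell ", cell, ": ",
         ll[bad[1]], call. = FALSE)
  }
  mx <- apply(ll, 2, max)
  lppd_cells <- mx + log(colMeans(exp(sweep(ll, 2, mx, "-"))))
  p_cells <- apply(ll, 2, var)
  lppd <- sum(lppd_cells)
  p_waic <- sum(p_cells)
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

# Streaming WAIC over all posterior draws of a fit, in chunks, so the full
# S x N x J array is never materialized.
waic_from_fit <- function(fit, y, chunk = 200) {
  y <- align_responses(y, fit)
  S <- n_draws(fit)
  obs <- !is.na(y)
  lse <- NULL; n <- 0; mean_ll <- NULL; m2 <- NULL
  for (start in seq(1, S, by = chunk)) {
    idx <- start:min(start + chunk - 1, S)
    ll <- pointwise_loglik(fit, y, draws = idx)
    d <- dim(ll)
    dim(ll) <- c(d[1], d[2] * d[3])
    ll <- ll[, obs, drop = FALSE]
    if (any(!is.finite(ll))) stop("non-finite log-likelihood encountered",
                                  call. = FALSE)
    cmax <- apply(ll, 2, max)
    clse <- cmax + log(colSums(exp(sweep(ll, 2, cmax, "-"))))
    lse <- if (is.null(lse)) clse else pairwise_lse(lse, clse)
    cn <- nrow(ll); cmean <- colMeans(ll)
    cm2 <- colSums(sweep(ll, 2, cmean, "-")^2)
    if (n == 0) {
      mean_ll <- cmean; m2 <- cm2
    } else {
      delta <- cmean - mean_ll
      mean_ll <- mean_ll + delta * cn / (n + cn)
      m2 <- m2 + cm2 + delta^2 * n * cn / (n + cn)
    }
    n <- n + cn
  }
  lppd <- sum(lse - log(S))
  p_waic <- sum(m2 / (S - 1))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

pairwise_lse <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))

#' Prior predictive check on item marginal proportions
#'
#' Simulates whole datasets with all parameters drawn from the priors and
#' summarizes the distribution of each item's marginal success proportion — a
#' coherence check that the priors do not force implausible response
#' patterns.
#'
#' @param priors a [prior_spec()].
#' @param q,cs test structure.
#' @param model_kind model to simulate from.
#' @param n_sim number of simulated datasets (>= 100).
#' @param seed integer seed.
#' @param n_persons examinees per simulated dataset.
#' @return list of class `"prior_predictive"`: `proportions` (n_sim x J) and
#'   `quantiles` (per item: 2.5%, 50%, 97.5%).
#' @export
prior_predictive_check <- function(priors, q, cs,
                                   model_kind = c("gmltmd", "mltmd", "c2pl", "lltm"),
                                   n_sim = 500, seed = 1, n_persons = 383) {
  model_kind <- match.arg(model_kind)
  stopifnot(n_sim >= 100)
  set.seed(seed)
  part <- switch(model_kind,
                 gmltmd = discrimination_partition(q, cs),
                 c2pl = discrimination_partition(q, collapse_to_unidimensional(q),
                                                 per_item = TRUE),
                 NULL)
  props <- matrix(NA_real_, n_sim, nrow(q), dimnames = list(NULL, rownames(q)))
  for (s in seq_len(n_sim)) {
    ps <- draw_prior_parameter_set(priors, q, cs, model_kind, part, n_persons)
    composed <- composed_for_model(model_kind, q, cs, ps)
    p <- success_prob_matrix(ps$theta, composed)
    yrep <- matrix(rbinom(length(p), 1, p), nrow(p))
    props[s, ] <- colMeans(yrep)
  }
  qs <- t(apply(props, 2, quantile, c(0.025, 0.5, 0.975), names = FALSE))
  structure(list(proportions = props,
                 quantiles = data.frame(item = rownames(q), lower = qs[, 1],
                                        median = qs[, 2], upper = qs[, 3],
                                        row.names = NULL)),
            class = "prior_predictive")
}

# one parameter set drawn from the priors (sd = 0 gives a point mass); for the
# unidimensional models everything is drawn on the collapsed structure
draw_prior_parameter_set <- function(priors, q, cs, model_kind, part, n_persons) {
  cs_use <- if (model_kind %in% c("lltm", "c2pl")) {
    collapse_to_unidimensional(q)
  } else cs
  inc <- cs_use$incidence
  eta <- matrix(NA_real_, nrow(inc), ncol(inc), dimnames = dimnames(inc))
  eta[inc == 1L] <- rnorm(sum(inc), priors$eta[1], priors$eta[2])
  alpha <- NULL
  if (!is.null(part)) {
    alpha <- setNames(rtruncnorm_pos(part$n_groups, priors$alpha[1],
                                     priors$alpha[2]), part$labels)
  }
  guessing <- if (model_kind == "gmltmd") {
    rbeta(nrow(q), priors$guessing[1], priors$guessing[2])
  } else NULL
  theta <- matrix(rnorm(n_persons * ncol(inc), priors$theta[1], priors$theta[2]),
                  n_persons, ncol(inc))
  parameter_set(eta = eta, cs = cs_use, alpha = alpha, guessing = guessing,
                partition = part, theta = theta)
}

# normal(mean, sd) truncated to [0, Inf), by inversion; sd = 0 is a point mass
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Posterior predictive check on item marginal proportions
#'
#' For each of `n_rep` posterior draws, a replicate dataset is simulated using
#' that draw's abilities and item parameters (full propagation of posterior
#' uncertainty) with the observed missingness pattern, and each item's
#' marginal success proportion is recorded. The summary compares the central
#' 2.5%-97.5% interval of the replicated proportions with the observed
#' proportion Dobs.
#'
#' @param fit a [fit_model()] result.
#' @param y the observed response matrix.
#' @param n_rep number of replicates (at most the number of posterior draws).
#' @param seed integer seed.
#' @return data.frame of class `"predictive_summary"`: item, lower, eap,
#'   upper, dobs, outside; attribute `"n_rep"`.
#' @export
posterior_predictive_marginals <- function(fit, y, n_rep = 1000, seed = 1) {
  props <- replicate_proportions(fit, y, n_rep, seed)$props
  y <- align_responses(y, fit)
  dobs <- colMeans(y, na.rm = TRUE)
  lower <- apply(props, 2, quantile, 0.025, names = FALSE)
  upper <- apply(props, 2, quantile, 0.975, names = FALSE)
  out <- data.frame(item = colnames(y), lower = lower, eap = colMeans(props),
                    upper = upper, dobs = dobs, row.names = NULL)
  out$outside <- out$dobs < out$lower | out$dobs > out$upper
  attr(out, "n_rep") <- nrow(props)
  class(out) <- c("predictive_summary", "data.frame")
  out
}

# replicate item proportions (and optionally mean inter-item correlations)
replicate_proportions <- function(fit, y, n_rep, seed, correlations = FALSE) {
  stopifnot(inherits(fit, "gmltm_fit"))
  y <- align_responses(y, fit)
  S <- n_draws(fit)
  set.seed(seed)
  draws <- if (n_rep >= S) seq_len(S) else sort(sample.int(S, n_rep))
  miss <- is.na(y)
  props <- matrix(NA_real_, length(draws), ncol(y),
                  dimnames = list(NULL, colnames(y)))
  cor_sum <- NULL
  cor_n <- NULL
  for (si in seq_along(draws)) {
    ps <- draw_parameter_set(fit, draws[si])
    composed <- compose_item_parameters(fit$q, ps)
    p <- success_prob_matrix(ps$theta, composed)
    yrep <- matrix(rbinom(length(p), 1, p), nrow(p))
    yrep[miss] <- NA_integer_
    props[si, ] <- colMeans(yrep, na.rm = TRUE)
    if (correlations) {
      cc <- suppressWarnings(cor(yrep, use = "pairwise.complete.obs"))
      ok <- is.finite(cc)
      cc[!ok] <- 0
      if (is.null(cor_sum)) {
        cor_sum <- cc; cor_n <- 0 + ok
      } else {
        cor_sum <- cor_sum + cc; cor_n <- cor_n + ok
      }
    }
  }
  mean_cor <- if (correlations) cor_sum / pmax(cor_n, 1)
  list(props = props, mean_cor = mean_cor)
}

#' Discordance rate of a predictive summary
#'
#' Fraction of items whose observed marginal proportion falls strictly outside
#' the central posterior predictive interval.
#'
#' @param ps a [posterior_predictive_marginals()] summary.
#' @return proportion in `[0, 1]`.
#' @export
discordance_rate <- function(ps) {
  stopifnot(inherits(ps, "predictive_summary"))
  mean(ps$dobs < ps$lower | ps$dobs > ps$upper)
}

#' Interval bias of a predictive summary
#'
#' Mean over items of the distance from the observed proportion to the nearest
#' interval endpoint, counting 0 for items inside their interval: the average
#' exceedance beyond the posterior predictive interval.
#'
#' @inheritParams discordance_rate
#' @return nonnegative real.
#' @export
interval_bias <- function(ps) {
  stopifnot(inherits(ps, "predictive_summary"))
  mean(pmax(ps$lower - ps$dobs, ps$dobs - ps$upper, 0))
}

#' Standardized root mean square residual
#'
#' Residuals between observed and posterior-predictive-mean summary
#' statistics, pooled over the J item marginal proportions and the
#' J(J-1)/2 inter-item product-moment correlations, as a single root mean
#' square. Items with zero observed variance are excluded from the
#' correlation set with a warning.
#'
#' @param y observed response matrix.
#' @param fit a [fit_model()] result.
#' @param replicates number of posterior predictive replicates, or a list of
#'   pre-generated replicate matrices (same shape as `y`).
#' @param seed integer seed (used when `replicates` is a count).
#' @return nonnegative scalar.
#' @export
srmr <- function(y, fit = NULL, replicates = 500, seed = 1) {
  if (is.list(replicates)) {
    y <- as.matrix(y)
    imp_p <- Reduce(`+`, lapply(replicates, function(r) colMeans(r, na.rm = TRUE))) /
      length(replicates)
    cors <- lapply(replicates, function(r) {
      cc <- suppressWarnings(cor(r, use = "pairwise.complete.obs"))
      cc[!is.finite(cc)] <- 0
      cc
    })
    imp_r <- Reduce(`+`, cors) / length(replicates)
  } else {
    rep_stats <- replicate_proportions(fit, y, replicates, seed,
                                       correlations = TRUE)
    y <- align_responses(y, fit)
    imp_p <- colMeans(rep_stats$props)
    imp_r <- rep_stats$mean_cor
  }
  if (ncol(y) < 2) stop("SRMR requires at least 2 items", call. = FALSE)
  obs_p <- colMeans(y, na.rm = TRUE)
  sds <- apply(y, 2, sd, na.rm = TRUE)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < ncol(y)) {
    warning("excluding ", ncol(y) - length(keep),
            " zero-variance item(s) from the correlation residuals")
  }
  obs_r <- suppressWarnings(cor(y, use = "pairwise.complete.obs"))
  ut <- upper.tri(obs_r)
  sel <- ut & outer(seq_len(ncol(y)) %in% keep, seq_len(ncol(y)) %in% keep, "&")
  srmr_pool(obs_p - imp_p, obs_r[sel] - imp_r[sel])
}

# pooled RMS over proportion residuals and correlation residuals
srmr_pool <- function(dp, dr) sqrt(mean(c(dp^2, dr^2)))

#' Compare fitted models
#'
#' Computes WAIC (with lppd and the effective parameter count p_waic), SRMR,
#' discordance rate, and interval bias for each fit on the same data, ranked
#' by WAIC ascending (ties broken by model name).
#'
#' @param fits named list of [fit_model()] results on the same responses.
#' @param y the observed response matrix.
#' @param n_rep posterior predictive replicates for SRMR/discordance/bias.
#' @param seed integer seed.
#' @return data.frame of class `"gmltm_comparison"`.
#' @export
compare_models <- function(fits, y, n_rep = 500, seed = 1) {
  stopifnot(length(fits) >= 1)
  nms <- names(fits)
  if (is.null(nms) || any(nms == "")) {
    nms <- vapply(fits, function(f) f$model_kind, "")
  }
  rows <- lapply(seq_along(fits), function(i) {
    fit <- fits[[i]]
    w <- waic_from_fit(fit, y)
    ps <- posterior_predictive_marginals(fit, y, n_rep = n_rep, seed = seed + i)
    data.frame(model = nms[i], waic = w$waic, lppd = w$lppd,
               p_waic = w$p_waic,
               srmr = srmr(y, fit, replicates = n_rep, seed = seed + i),
               discordance = discordance_rate(ps),
               interval_bias = interval_bias(ps), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$waic, out$model), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gmltm_comparison", "data.frame")
  out
}

#' Item characteristic curves by component
#'
#' For each active component of an item, the two-parameter logistic curve
#' `logistic(alpha_jm (theta - b_jm))` over the ability grid, plus the joint
#' (guessing-floored, noncompensatory product) curve evaluated along the
#' diagonal where every active component shares the same ability value.
#'
#' @param item item index or id.
#' @param composed a [compose_item_parameters()] object.
#' @param theta_grid finite ability grid.
#' @return long data.frame: `curve`, `theta`, `p`.
#' @export
icc_curve <- function(item, composed, theta_grid = seq(-4, 4, by = 0.05)) {
  stopifnot(all(is.finite(theta_grid)))
  if (is.character(item)) item <- match(item, rownames(composed$difficulty))
  M <- ncol(composed$difficulty)
  comp_ids <- colnames(composed$difficulty)
  out <- list()
  for (m in seq_len(M)) {
    if (!composed$active[item, m]) next
    p <- plogis(composed$discrimination[item, m] *
                  (theta_grid - composed$difficulty[item, m]))
    out[[length(out) + 1]] <- data.frame(curve = comp_ids[m],
                                         theta = theta_grid, p = p)
  }
  th <- matrix(rep(theta_grid, M), ncol = M)
  joint <- prob_gmltmd(th, item, composed)
  out[[length(out) + 1]] <- data.frame(curve = "joint", theta = theta_grid,
                                       p = joint)
  do.call(rbind, out)
}
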