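#' Fit a multicomponent latent trait model
#'
#' Bayesian estimation of one of the four nested models by adaptive
#' Metropolis-within-Gibbs sampling. Response columns are matched to the Q
#' matrix's items by label. Missing responses are ignorable: their cells
#' simply drop out of the likelihood.
#'
#' Model kinds:
#' * `"lltm"` — single component (the structure is collapsed to M = 1),
#'   discrimination fixed at 1, no guessing;
#' * `"c2pl"` — single component, one free discrimination per item, no
#'   guessing;
#' * `"mltmd"` — multicomponent, discrimination fixed at 1, no guessing;
#' * `"gmltmd"` — multicomponent, discriminations shared within feature-pattern
#'   groups, per-item guessing.
#'
#' @param y binary person x item response matrix (may contain `NA`), columns
#'   named by item id.
#' @param q a [feature_matrix()].
#' @param cs a [derive_component_matrix()] structure (ignored in favour of a
#'   single-component collapse for `"lltm"` and `"c2pl"`).
#' @param model_kind one of `"lltm"`, `"c2pl"`, `"mltmd"`, `"gmltmd"`.
#' @param priors a [prior_spec()].
#' @param config a [sampler_config()].
#' @return object of class `"gmltm_fit"`: per-chain posterior draws of every
#'   parameter block, the model structure, convergence diagnostics
#'   (split R-hat, effective sample size, divergence count — identically 0
#'   for this sampler, reported for workflow compatibility), acceptance
#'   rates, and EAP/central-interval summaries via [summary()].
#' @export
fit_model <- function(y, q, cs, model_kind = c("gmltmd", "mltmd", "c2pl", "lltm"),
                      priors = prior_spec(), config = sampler_config()) {
  model_kind <- match.arg(model_kind)
  stopifnot(is_feature_matrix(q), inherits(priors, "prior_spec"),
            inherits(config, "sampler_config"))
  y <- as.matrix(y)
  if (is.null(colnames(y))) {
    if (ncol(y) != nrow(q)) stop("response columns do not match items", call. = FALSE)
    colnames(y) <- rownames(q)
  }
  if (!setequal(colnames(y), rownames(q))) {
    stop("response column labels do not match Q item labels; missing: ",
         paste(setdiff(rownames(q), colnames(y)), collapse = ", "),
         call. = FALSE)
  }
  y <- y[, rownames(q), drop = FALSE]
  bad <- which(!(y %in% c(0, 1)) & !is.na(y))
  if (length(bad)) stop("non-binary response value: ", y[bad[1]], call. = FALSE)

  if (model_kind %in% c("lltm", "c2pl")) cs <- collapse_to_unidimensional(q)
  if (!is_component_structure(cs)) stop("'cs' must be a component structure",
                                        call. = FALSE)
  part <- switch(model_kind,
                 gmltmd = discrimination_partition(q, cs),
                 c2pl = discrimination_partition(q, cs, per_item = TRUE),
                 NULL)
  est_alpha <- model_kind %in% c("gmltmd", "c2pl")
  est_guess <- model_kind == "gmltmd"

  inc <- cs$incidence
  idx <- which(inc == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  eta_labels <- paste0("eta[", cs$component_ids[idx[, "col"]], ",",
                       cs$feature_ids[idx[, "row"]], "]")
  group <- if (is.null(part)) {
    matrix(0L, nrow(q), length(cs$component_ids))
  } else {
    ig <- part$item_group
    ig[is.na(ig)] <- 0L
    ig
  }
  G <- if (is.null(part)) 0L else part$n_groups

  yint <- matrix(as.integer(y), nrow(y), ncol(y))
  yint[is.na(yint)] <- -1L
  prior_list <- list(theta_mean = priors$theta[1], theta_sd = priors$theta[2],
                     eta_mean = priors$eta[1], eta_sd = priors$eta[2],
                     alpha_mean = priors$alpha[1], alpha_sd = priors$alpha[2],
                     guess_shape1 = priors$guessing[1],
                     guess_shape2 = priors$guessing[2])

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, config$chains)
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(chain_seeds[ch])
    theta0 <- matrix(rnorm(nrow(y) * length(cs$component_ids), 0, 0.5),
                     nrow(y), length(cs$component_ids))
    eta0 <- rnorm(nrow(idx), 0, 0.25)
    alpha0 <- if (est_alpha) abs(rnorm(G, 1, 0.2)) else numeric(0)
    guess0 <- if (est_guess) {
      pmin(pmax(rbeta(nrow(q), priors$guessing[1], priors$guessing[2]), 1e-3),
           0.9)
    } else rep(0, nrow(q))
    chains[[ch]] <- .sample_chain(
      yint, unclass(q), cs$component_matrix,
      as.integer(idx[, "row"]) - 1L, as.integer(idx[, "col"]) - 1L,
      group, as.integer(G), est_alpha, est_guess, prior_list,
      config$warmup, config$iter, config$thin, config$struct_reps,
      theta0, eta0, alpha0, guess0)
  }

  alpha_labels <- if (is.null(part)) character(0) else paste0("alpha[", part$labels, "]")
  guess_labels <- if (est_guess) paste0("c[", rownames(q), "]") else character(0)
  structure(
    list(chains = chains, model_kind = model_kind, q = q, cs = cs,
         partition = part, est_alpha = est_alpha, est_guess = est_guess,
         priors = priors, config = config,
         person_ids = rownames(y), item_ids = rownames(q),
         eta_index = idx, eta_labels = eta_labels,
         alpha_labels = alpha_labels, guess_labels = guess_labels,
         divergences = rep(0L, config$chains)),
    class = "gmltm_fit")
}

#' @export
print.gmltm_fit <- function(x, ...) {
  cat("Bayesian", toupper(x$model_kind), "fit:",
      length(x$person_ids), "persons x", length(x$item_ids), "items,",
      x$config$chains, "chains x", x$config$iter, "kept iterations\n")
  cat("Parameters:", length(x$eta_labels), "eta,",
      length(x$alpha_labels), "alpha,", length(x$guess_labels), "guessing,",
      length(x$person_ids) * length(x$cs$component_ids), "theta\n")
  invisible(x)
}

# Flat (iterations x parameters) matrix for one chain, item/structural
# parameters only unless include_theta.
chain_matrix <- function(fit, ch, include_theta = TRUE) {
  chain <- fit$chains[[ch]]
  out <- chain$eta
  colnames(out) <- fit$eta_labels
  if (fit$est_alpha) {
    a <- chain$alpha; colnames(a) <- fit$alpha_labels
    out <- cbind(out, a)
  }
  if (fit$est_guess) {
    g <- chain$guess; colnames(g) <- fit$guess_labels
    out <- cbind(out, g)
  }
  if (include_theta) {
    th <- chain$theta
    d <- dim(th)
    flat <- matrix(th, d[1], d[2] * d[3])
    colnames(flat) <- paste0("theta[", rep(fit$person_ids, times = d[3]), ",",
                             rep(fit$cs$component_ids, each = d[2]), "]")
    out <- cbind(out, flat)
  }
  out
}

#' Posterior draws as a single matrix
#'
#' Stacks all chains into one (chains x iterations) by parameters matrix with
#' labelled columns.
#'
#' @param fit a [fit_model()] result.
#' @param include_theta include the person abilities (can be wide).
#' @return numeric matrix with attributes `chain` and `iteration`.
#' @export
as_draws_matrix <- function(fit, include_theta = TRUE) {
  stopifnot(inherits(fit, "gmltm_fit"))
  mats <- lapply(seq_along(fit$chains), chain_matrix, fit = fit,
                 include_theta = include_theta)
  out <- do.call(rbind, mats)
  attr(out, "chain") <- rep(seq_along(fit$chains), each = fit$config$iter)
  attr(out, "iteration") <- rep(seq_len(fit$config$iter), length(fit$chains))
  out
}

# parameter_set for one posterior draw (pooled draw index s in 1..chains*iter)
draw_parameter_set <- function(fit, s) {
  iter <- fit$config$iter
  ch <- (s - 1) %/% iter + 1
  it <- (s - 1) %% iter + 1
  chain <- fit$chains[[ch]]
  inc <- fit$cs$incidence
  eta <- matrix(NA_real_, nrow(inc), ncol(inc), dimnames = dimnames(inc))
  eta[fit$eta_index] <- chain$eta[it, ]
  alpha <- if (fit$est_alpha) setNames(chain$alpha[it, ], fit$partition$labels)
  guess <- if (fit$est_guess) chain$guess[it, ] else NULL
  theta <- chain$theta[it, , , drop = FALSE]
  theta <- matrix(theta, dim(chain$theta)[2], dim(chain$theta)[3],
                  dimnames = list(fit$person_ids, fit$cs$component_ids))
  parameter_set(eta = eta, cs = fit$cs, alpha = alpha, guessing = guess,
                theta = theta, partition = fit$partition)
}

n_draws <- function(fit) fit$config$iter * fit$config$chains

#' Pointwise log-likelihood array
#'
#' Evaluates `log p(y_ij | draw s)` for every posterior draw and observed
#' cell, using the same probability kernel as the model's simulator. Missing
#' cells carry `NA`.
#'
#' @param fit a [fit_model()] result.
#' @param y the response matrix the model was fitted to.
#' @param draws optional integer vector of pooled draw indices (default all).
#' @return array S x N x J.
#' @export
pointwise_loglik <- function(fit, y, draws = NULL) {
  stopifnot(inherits(fit, "gmltm_fit"))
  y <- align_responses(y, fit)
  if (is.null(draws)) draws <- seq_len(n_draws(fit))
  out <- array(NA_real_, c(length(draws), nrow(y), ncol(y)))
  for (si in seq_along(draws)) {
    ps <- draw_parameter_set(fit, draws[si])
    composed <- compose_item_parameters(fit$q, ps)
    ll <- bernoulli_loglik_matrix(y, ps$theta, composed)
    ll[is.na(y)] <- NA_real_
    out[si, , ] <- ll
  }
  dimnames(out) <- list(NULL, rownames(y), colnames(y))
  out
}

align_responses <- function(y, fit) {
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- fit$item_ids
  stopifnot(setequal(colnames(y), fit$item_ids))
  y[, fit$item_ids, drop = FALSE]
}

#' Posterior summaries of a fit
#'
#' @param object a [fit_model()] result.
#' @param ... unused.
#' @return data.frame with one row per structural parameter (eta, alpha,
#'   guessing): EAP (posterior mean) and central 2.5%/97.5% quantiles.
#' @export
summary.gmltm_fit <- function(object, ...) {
  dm <- as_draws_matrix(object, include_theta = FALSE)
  data.frame(
    parameter = colnames(dm),
    eap = colMeans(dm),
    lower = apply(dm, 2, quantile, 0.025, names = FALSE),
    upper = apply(dm, 2, quantile, 0.975, names = FALSE),
    row.names = NULL)
}
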