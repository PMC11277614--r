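#' Validate a binary response matrix
#'
#' @param entries matrix of 0/1 with `NA` for missing cells.
#' @param person_ids,item_ids unique labels; default from dimnames or
#'   generated.
#' @return integer matrix of class `"response_matrix"`.
#' @export
response_matrix <- function(entries, person_ids = NULL, item_ids = NULL) {
  entries <- as.matrix(entries)
  if (is.null(person_ids)) {
    person_ids <- rownames(entries)
    if (is.null(person_ids)) person_ids <- paste0("p", seq_len(nrow(entries)))
  }
  if (is.null(item_ids)) {
    item_ids <- colnames(entries)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(entries)))
  }
  if (anyDuplicated(person_ids)) stop("duplicate person ids", call. = FALSE)
  if (anyDuplicated(item_ids)) stop("duplicate item ids", call. = FALSE)
  bad <- which(!(entries %in% c(0, 1)) & !is.na(entries))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(entries)) + 1
    j <- ((bad[1] - 1) %/% nrow(entries)) + 1
    stop("non-binary response at person '", person_ids[i], "', item '",
         item_ids[j], "': ", entries[bad[1]], call. = FALSE)
  }
  out <- matrix(as.integer(entries), nrow(entries), ncol(entries),
                dimnames = list(person_ids, item_ids))
  class(out) <- c("response_matrix", class(out))
  out
}

#' Simulate binary responses from any of the four models
#'
#' Each response is Bernoulli with the success probability of the chosen
#' kernel. Abilities are either taken from `params$theta` or drawn from the
#' standard normal prior. The true abilities used are attached as attribute
#' `"theta"`.
#'
#' @param model_kind `"lltm"`, `"c2pl"`, `"mltmd"`, or `"gmltmd"`. For the
#'   reduced models, discriminations and/or guessing in `params` are ignored
#'   (fixed at 1 and 0), and for the unidimensional models the structure is
#'   collapsed to a single component.
#' @param q a [feature_matrix()].
#' @param cs a [derive_component_matrix()] structure.
#' @param params a [parameter_set()].
#' @param n_persons number of examinees (required when `theta_source` is
#'   `"prior"`; otherwise taken from `params$theta`).
#' @param seed integer seed.
#' @param theta_source `"given"` (use `params$theta`) or `"prior"`.
#' @return a [response_matrix()] with attribute `"theta"`.
#' @export
simulate_responses <- function(model_kind = c("gmltmd", "mltmd", "c2pl", "lltm"),
                               q, cs, params, n_persons = NULL, seed = 1,
                               theta_source = c("given", "prior")) {
  model_kind <- match.arg(model_kind)
  theta_source <- match.arg(theta_source)
  stopifnot(is_feature_matrix(q), inherits(params, "parameter_set"))
  composed <- composed_for_model(model_kind, q, cs, params)
  M <- ncol(composed$difficulty)
  set.seed(seed)
  if (theta_source == "given") {
    theta <- params$theta
    if (is.null(theta)) stop("theta_source = 'given' but params$theta is NULL",
                             call. = FALSE)
    theta <- as.matrix(theta)
    if (ncol(theta) != M) stop("params$theta has ", ncol(theta),
                               " columns but the model needs ", M, call. = FALSE)
  } else {
    if (is.null(n_persons)) stop("n_persons required for theta_source = 'prior'",
                                 call. = FALSE)
    theta <- matrix(rnorm(n_persons * M), n_persons, M)
  }
  p <- success_prob_matrix(theta, composed)
  y <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
  colnames(y) <- rownames(q)
  rownames(y) <- paste0("p", seq_len(nrow(y)))
  rownames(theta) <- rownames(y)
  out <- response_matrix(y)
  attr(out, "theta") <- theta
  out
}

# Model-specific composed item parameters: reduced models override alpha/c and
# may collapse the structure to one component.
composed_for_model <- function(model_kind, q, cs, params) {
  if (model_kind %in% c("lltm", "c2pl")) {
    cs1 <- collapse_to_unidimensional(q)
    eta1 <- matrix(rowSums(params$eta, na.rm = TRUE), ncol = 1,
                   dimnames = list(rownames(params$eta), cs1$component_ids))
    alpha <- NULL; part <- NULL
    if (model_kind == "c2pl" && !is.null(params$alpha)) {
      part <- discrimination_partition(q, cs1, per_item = TRUE)
      composed_full <- compose_item_parameters(q, params)
      a_item <- apply(composed_full$discrimination, 1, function(r) {
        act <- r[r > 0]
        if (length(act)) mean(act) else 1
      })
      alpha <- setNames(a_item[vapply(part$members, `[`, "", 1)], part$labels)
    }
    ps <- parameter_set(eta = eta1, cs = cs1, alpha = alpha, guessing = NULL,
                        partition = part)
    return(compose_item_parameters(q, ps))
  }
  stopifnot(is_component_structure(cs))
  if (model_kind == "mltmd") {
    ps <- parameter_set(eta = params$eta, cs = cs, alpha = NULL,
                        guessing = NULL)
    return(compose_item_parameters(q, ps))
  }
  compose_item_parameters(q, params)
}

#' The study-emulating fixture
#'
#' Builds the canonical synthetic dataset: the 27 x 5 figural-analogies Q
#' matrix, the global/local component assignment, the GMLTM-D point estimates
#' as true parameters, and responses simulated from the GMLTM-D for
#' `n_persons` examinees with standard-normal abilities.
#'
#' @param seed integer seed.
#' @param n_persons sample size; defaults to the original study's 383.
#' @return list with elements `q`, `cs`, `params`, and `responses` (with the
#'   true abilities in `attr(responses, "theta")`).
#' @export
study_fixture <- function(seed = 1, n_persons = 383) {
  q <- blum_q_matrix()
  cs <- derive_component_matrix(q, blum_component_assignment())
  params <- blum_gmltmd_parameters(q, cs)
  responses <- simulate_responses("gmltmd", q, cs, params,
                                  n_persons = n_persons, seed = seed,
                                  theta_source = "prior")
  list(q = q, cs = cs, params = params, responses = responses)
}

#' Parameter-recovery study
#'
#' Repeatedly simulates data from known parameters, refits the model, and
#' measures recovery: bias and RMSE of the EAPs, 95% interval coverage, and
#' the correlation between EAP and truth, per parameter block. One master
#' seed spawns an independent sub-seed per replication.
#'
#' @param model_kind model to simulate from and fit.
#' @param q,cs test structure.
#' @param true_params a [parameter_set()] holding the generating values.
#' @param n_persons examinees per replication.
#' @param n_reps number of replications.
#' @param config a [sampler_config()] (its seed is ignored; sub-seeds are
#'   derived from `seed`).
#' @param seed master seed.
#' @return list of class `"recovery_report"`: `blocks` (per-block pooled
#'   bias, RMSE, coverage, EAP-truth correlation), `reps` (per-replication
#'   diagnostics), and `details` (per-parameter, per-replication records).
#' @export
recovery_study <- function(model_kind, q, cs, true_params, n_persons = 500,
                           n_reps = 5, config = sampler_config(), seed = 1) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2 * n_reps)
  details <- list(); reps <- list()
  for (r in seq_len(n_reps)) {
    y <- simulate_responses(model_kind, q, cs, true_params,
                            n_persons = n_persons, seed = sub_seeds[2 * r - 1],
                            theta_source = "prior")
    cfg <- config
    cfg$seed <- sub_seeds[2 * r]
    fit <- tryCatch(
      fit_model(y, q, cs, model_kind, config = cfg),
      error = function(e) stop("replication ", r, " failed: ",
                               conditionMessage(e), call. = FALSE))
    conv <- check_convergence(fit)
    reps[[r]] <- data.frame(rep = r, max_rhat = max(conv$table$rhat, na.rm = TRUE),
                            min_ess = min(conv$table$ess, na.rm = TRUE),
                            divergences = sum(conv$divergences))
    truth <- true_parameter_records(fit, true_params, attr(y, "theta"))
    est <- summary_with_theta(fit)
    rec <- merge(truth, est, by = "parameter", sort = FALSE)
    rec$rep <- r
    details[[r]] <- rec
  }
  details <- do.call(rbind, details)
  details$covered <- details$truth >= details$lower & details$truth <= details$upper
  blocks <- do.call(rbind, lapply(split(details, details$block), function(d) {
    data.frame(block = d$block[1],
               bias = mean(d$eap - d$truth),
               rmse = sqrt(mean((d$eap - d$truth)^2)),
               coverage = mean(d$covered),
               eap_truth_cor = if (var(d$truth) > 0) cor(d$eap, d$truth) else NA_real_,
               row.names = NULL)
  }))
  structure(list(blocks = blocks, reps = do.call(rbind, reps),
                 details = details),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", max(x$details$rep), "replication(s)\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

# truth records (parameter label, block, true value) matching the fit's labels
true_parameter_records <- function(fit, true_params, theta_true) {
  eta_truth <- if (fit$model_kind %in% c("lltm", "c2pl")) {
    # the fitted structure is the single-component collapse
    rowSums(true_params$eta, na.rm = TRUE)[fit$eta_index[, "row"]]
  } else {
    true_params$eta[fit$eta_index]
  }
  recs <- data.frame(parameter = fit$eta_labels, block = "eta",
                     truth = eta_truth)
  if (fit$est_alpha && !is.null(true_params$alpha) &&
      length(true_params$alpha) == length(fit$alpha_labels)) {
    recs <- rbind(recs, data.frame(parameter = fit$alpha_labels, block = "alpha",
                                   truth = as.numeric(true_params$alpha)))
  }
  if (fit$est_guess && !is.null(true_params$guessing)) {
    recs <- rbind(recs, data.frame(parameter = fit$guess_labels, block = "c",
                                   truth = as.numeric(true_params$guessing)))
  }
  M <- length(fit$cs$component_ids)
  th_labels <- paste0("theta[", rep(fit$person_ids, times = M), ",",
                      rep(fit$cs$component_ids, each = length(fit$person_ids)), "]")
  rbind(recs, data.frame(parameter = th_labels,
                         block = paste0("theta:", rep(fit$cs$component_ids,
                                                      each = length(fit$person_ids))),
                         truth = as.numeric(theta_true)))
}

summary_with_theta <- function(fit) {
  dm <- as_draws_matrix(fit, include_theta = TRUE)
  data.frame(parameter = colnames(dm), eap = colMeans(dm),
             lower = apply(dm, 2, quantile, 0.025, names = FALSE),
             upper = apply(dm, 2, quantile, 0.975, names = FALSE),
             row.names = NULL)
}
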