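#' Split R-hat for a single parameter
#'
#' The potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift is detected as well as between-chain
#' disagreement. Values near 1 indicate the chains agree; 1.01 is the usual
#' threshold.
#'
#' @param draws iterations x chains matrix for one parameter.
#' @return scalar R-hat (NA if the parameter is constant).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W == 0) {
    return(if (isTRUE(all.equal(var(as.vector(split)), 0))) NA_real_ else Inf)
  }
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Convergence report for a fitted model
#'
#' Computes split R-hat and effective sample size for every parameter
#' (abilities included) and flags parameters above the threshold. This
#' sampler has no divergent-transition concept, so the divergence count per
#' chain is identically zero; it is reported for workflow compatibility.
#'
#' @param fit a [fit_model()] result with at least two chains.
#' @param rhat_max pass/fail threshold on split R-hat.
#' @return list of class `"gmltm_convergence"`: `table` (parameter, rhat,
#'   ess), `pass`, `failed` (parameter names above threshold), and
#'   `divergences` per chain.
#' @export
check_convergence <- function(fit, rhat_max = 1.01) {
  stopifnot(inherits(fit, "gmltm_fit"))
  if (fit$config$chains < 2) {
    stop("at least 2 chains are required to compute R-hat", call. = FALSE)
  }
  dm <- as_draws_matrix(fit, include_theta = TRUE)
  iter <- fit$config$iter
  nch <- fit$config$chains
  rhat <- vapply(seq_len(ncol(dm)), function(p) {
    split_rhat(matrix(dm[, p], iter, nch))
  }, numeric(1))
  ess <- vapply(seq_len(ncol(dm)), function(p) {
    sum(vapply(seq_len(nch), function(ch) {
      as.numeric(coda::effectiveSize(dm[(ch - 1) * iter + seq_len(iter), p]))
    }, numeric(1)))
  }, numeric(1))
  tab <- data.frame(parameter = colnames(dm), rhat = rhat, ess = ess,
                    row.names = NULL)
  failed <- tab$parameter[!is.na(tab$rhat) & tab$rhat > rhat_max]
  structure(list(table = tab, pass = length(failed) == 0, failed = failed,
                 rhat_max = rhat_max, divergences = fit$divergences),
            class = "gmltm_convergence")
}

#' @export
print.gmltm_convergence <- function(x, ...) {
  cat("Convergence:", if (x$pass) "PASS" else "FAIL",
      sprintf("(max split R-hat %.4f, threshold %.3f)\n",
              max(x$table$rhat, na.rm = TRUE), x$rhat_max))
  cat("Divergences per chain:", paste(x$divergences, collapse = ", "), "\n")
  if (!x$pass) {
    cat("Parameters above threshold:",
        paste(utils::head(x$failed, 10), collapse = ", "),
        if (length(x$failed) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' EAP ability scores with credible intervals
#'
#' @param fit a [fit_model()] result.
#' @return data.frame: person, component, eap, lower (2.5%), upper (97.5%).
#' @export
eap_abilities <- function(fit) {
  stopifnot(inherits(fit, "gmltm_fit"))
  M <- length(fit$cs$component_ids)
  N <- length(fit$person_ids)
  th <- do.call(abind_iter, lapply(fit$chains, function(ch) ch$theta))
  out <- vector("list", M)
  for (m in seq_len(M)) {
    x <- th[, , m, drop = FALSE]
    dim(x) <- c(dim(th)[1], N)
    out[[m]] <- data.frame(
      person = fit$person_ids, component = fit$cs$component_ids[m],
      eap = colMeans(x),
      lower = apply(x, 2, quantile, 0.025, names = FALSE),
      upper = apply(x, 2, quantile, 0.975, names = FALSE),
      row.names = NULL)
  }
  do.call(rbind, out)
}

# bind chain arrays (iter x N x M) along the iteration axis
abind_iter <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(total, d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
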