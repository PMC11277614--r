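#' Prior specification
#'
#' Defaults follow the standard weakly-informative pattern for this model
#' family: abilities and feature difficulties standard normal, discriminations
#' half-normal (a normal truncated to the nonnegative slope axis), and the
#' guessing floor Beta(3, 20), which concentrates below 0.3 with mean about
#' 0.13 — plausible for multiple-choice items with reasonable distractors.
#'
#' @param theta `c(mean, sd)` of the normal prior on each ability.
#' @param eta `c(mean, sd)` of the normal prior on each feature difficulty.
#' @param alpha `c(mean, sd)` of the normal prior on each discrimination,
#'   truncated to `[0, Inf)`.
#' @param guessing `c(shape1, shape2)` of the beta prior on each guessing
#'   value.
#' @return list of class `"prior_spec"`.
#' @export
prior_spec <- function(theta = c(0, 1), eta = c(0, 1), alpha = c(0, 1),
                       guessing = c(3, 20)) {
  stopifnot(length(theta) == 2, length(eta) == 2, length(alpha) == 2,
            length(guessing) == 2,
            theta[2] >= 0, eta[2] >= 0, alpha[2] >= 0,
            guessing[1] > 0, guessing[2] > 0)
  structure(list(theta = as.numeric(theta), eta = as.numeric(eta),
                 alpha = as.numeric(alpha), guessing = as.numeric(guessing)),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' @param chains number of independent chains (>= 2 needed for R-hat).
#' @param warmup adaptation iterations discarded per chain.
#' @param iter kept iterations per chain.
#' @param seed integer master seed; fully determines the draws.
#' @param thin keep every `thin`-th post-warmup sweep; `iter` counts kept
#'   draws, so the chain runs `warmup + iter * thin` sweeps. Thinning trades
#'   storage for mixing when the slow directions need many sweeps per
#'   effectively independent draw.
#' @param struct_reps how many times the item-level blocks (feature
#'   difficulties, discriminations, guessing) are refreshed per ability
#'   sweep; the item blocks are few but slow-mixing relative to the
#'   abilities, so refreshing them more often buys effective sample size
#'   cheaply.
#' @return list of class `"sampler_config"`.
#' @export
sampler_config <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1,
                           thin = 1, struct_reps = 1) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, thin >= 1, struct_reps >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 thin = as.integer(thin), struct_reps = as.integer(struct_reps)),
            class = "sampler_config")
}
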