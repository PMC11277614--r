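# Shared structures built in code.

# the worked 10-item, 6-feature, 2-component block-diagonal example
# (features 1-3 -> component 1, features 4-6 -> component 2), optionally with
# item 1 cross-loading on feature 4
block_example_q <- function(cross_loading = FALSE) {
  q1 <- rbind(c(1, 1, 1), c(1, 0, 0), c(1, 0, 1), c(0, 1, 1), c(0, 1, 0))
  q2 <- rbind(c(1, 0, 1), c(1, 0, 0), c(0, 1, 1), c(0, 0, 1), c(1, 1, 0))
  q <- rbind(cbind(q1, matrix(0, 5, 3)), cbind(matrix(0, 5, 3), q2))
  if (cross_loading) q[1, 4] <- 1
  validate_feature_matrix(q, item_ids = paste0("i", 1:10),
                          feature_ids = paste0("f", 1:6))
}

block_example_incidence <- function(feature4_in_both = FALSE) {
  inc <- cbind(comp1 = c(1, 1, 1, 0, 0, 0), comp2 = c(0, 0, 0, 1, 1, 1))
  if (feature4_in_both) inc[4, 1] <- 1
  rownames(inc) <- paste0("f", 1:6)
  inc
}

fixture_structure <- function() {
  q <- blum_q_matrix()
  cs <- derive_component_matrix(q, blum_component_assignment())
  list(q = q, cs = cs, params = blum_gmltmd_parameters(q, cs))
}

# a quick small-sample fit on the study structure, for structural tests
small_fit <- function(model_kind = "gmltmd", n = 60, chains = 2,
                      warmup = 150, iter = 100, seed = 42) {
  fx <- study_fixture(seed = seed, n_persons = n)
  fit_model(fx$responses, fx$q, fx$cs, model_kind,
            config = sampler_config(chains = chains, warmup = warmup,
                                    iter = iter, seed = seed))
}

# a synthetic fit object holding prescribed draws, for tests of pure
# functions of the posterior (EAP, predictive summaries, WAIC plumbing)
fake_fit <- function(q, cs, eta_draws_by_chain, theta_draws_by_chain,
                     alpha_draws_by_chain = NULL, guess_draws_by_chain = NULL,
                     model_kind = "mltmd") {
  part <- if (!is.null(alpha_draws_by_chain)) discrimination_partition(q, cs)
  inc <- cs$incidence
  idx <- which(inc == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  n_chain <- length(eta_draws_by_chain)
  iter <- nrow(eta_draws_by_chain[[1]])
  N <- dim(theta_draws_by_chain[[1]])[2]
  chains <- lapply(seq_len(n_chain), function(ch) {
    list(theta = theta_draws_by_chain[[ch]],
         eta = eta_draws_by_chain[[ch]],
         alpha = if (!is.null(alpha_draws_by_chain)) alpha_draws_by_chain[[ch]] else matrix(0, 0, 0),
         guess = if (!is.null(guess_draws_by_chain)) guess_draws_by_chain[[ch]] else matrix(0, 0, 0))
  })
  structure(
    list(chains = chains, model_kind = model_kind, q = q, cs = cs,
         partition = part,
         est_alpha = !is.null(alpha_draws_by_chain),
         est_guess = !is.null(guess_draws_by_chain),
         priors = prior_spec(),
         config = sampler_config(chains = n_chain, warmup = 0, iter = iter),
         person_ids = paste0("p", seq_len(N)), item_ids = rownames(q),
         eta_index = idx,
         eta_labels = paste0("eta[", cs$component_ids[idx[, "col"]], ",",
                             cs$feature_ids[idx[, "row"]], "]"),
         alpha_labels = if (!is.null(part)) paste0("alpha[", part$labels, "]") else character(0),
         guess_labels = if (!is.null(guess_draws_by_chain)) paste0("c[", rownames(q), "]") else character(0),
         divergences = rep(0L, n_chain)),
    class = "gmltm_fit")
}

# tiny 3-item, 2-feature, 2-component structure for cheap fits
tiny_structure <- function() {
  q <- validate_feature_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)),
                               item_ids = paste0("t", 1:3),
                               feature_ids = c("fA", "fB"))
  inc <- cbind(c1 = c(1, 0), c2 = c(0, 1))
  rownames(inc) <- c("fA", "fB")
  list(q = q, cs = derive_component_matrix(q, inc))
}
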