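# File interface: everything on disk is comma-delimited text with a header
# row (decimal point, no thousands separators), plus JSON for configs,
# parameter sets, and the run manifest.

#' Read a binary response matrix from CSV
#'
#' Expected layout: header row of item ids, first column the person id, cells
#' 0/1 with empty or `NA` for missing.
#'
#' @param path file path.
#' @return a [response_matrix()].
#' @export
read_response_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expected a person-id column plus item columns",
                         call. = FALSE)
  person_ids <- df[[1]]
  items <- colnames(df)[-1]
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "" | m == "NA"] <- NA
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(!is.na(m) & (is.na(num) | !(num %in% c(0, 1))))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop("non-binary response at person '", person_ids[i], "', item '",
         items[j], "': ", m[bad[1]], call. = FALSE)
  }
  y <- response_matrix(num, person_ids = person_ids, item_ids = items)
  message(sprintf("read %d persons x %d items (%.1f%% missing)",
                  nrow(y), ncol(y), 100 * mean(is.na(y))))
  y
}

#' Write a response matrix to CSV
#'
#' @param y a [response_matrix()] (or compatible binary matrix).
#' @param path file path.
#' @export
write_response_matrix <- function(y, path) {
  df <- data.frame(person = rownames(y), unclass(y), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read the test structure: Q matrix plus feature-component assignment
#'
#' The Q file has items in rows (first column the item id, remaining columns
#' the features). The assignment file has two columns, `feature` and
#' `component`; a feature may be listed under several components. An optional
#' third file adds cross-loadings to the derived C matrix (columns `item`,
#' `component`); additions must obey the additive override rule of
#' [derive_component_matrix()].
#'
#' @param q_path path to the Q matrix CSV.
#' @param assignment_path path to the feature-component assignment CSV.
#' @param override_path optional path to the C-matrix additions CSV.
#' @return list with `q` (a [feature_matrix()]) and `cs` (a component
#'   structure).
#' @export
read_feature_structure <- function(q_path, assignment_path,
                                   override_path = NULL) {
  qdf <- read.csv(q_path, check.names = FALSE)
  q <- validate_feature_matrix(as.matrix(qdf[, -1, drop = FALSE]),
                               item_ids = as.character(qdf[[1]]))
  adf <- read.csv(assignment_path, check.names = FALSE,
                  colClasses = "character")
  if (!all(c("feature", "component") %in% colnames(adf))) {
    stop("assignment file needs columns 'feature' and 'component'",
         call. = FALSE)
  }
  missing_feats <- setdiff(colnames(q), adf$feature)
  if (length(missing_feats)) {
    stop("feature(s) in Q missing from the assignment: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(adf$feature, colnames(q))
  if (length(unknown)) {
    stop("assignment lists unknown feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  comps <- sort(unique(adf$component))
  inc <- matrix(0L, ncol(q), length(comps),
                dimnames = list(colnames(q), comps))
  inc[cbind(adf$feature, adf$component)] <- 1L
  override <- NULL
  if (!is.null(override_path)) {
    odf <- read.csv(override_path, check.names = FALSE,
                    colClasses = "character")
    if (!all(c("item", "component") %in% colnames(odf))) {
      stop("override file needs columns 'item' and 'component'", call. = FALSE)
    }
    derived <- derive_component_matrix(q, inc)
    override <- derived$component_matrix
    override[cbind(odf$item, odf$component)] <- 1L
  }
  cs <- derive_component_matrix(q, inc, override = override)
  list(q = q, cs = cs)
}

#' Read a run configuration (JSON)
#'
#' Strict: unknown keys anywhere in the file are rejected, so typos never
#' silently fall back to defaults. See the packaged example in the CLI help.
#'
#' @param path JSON file.
#' @return list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("paths", "model", "priors", "sampler", "ppc_replicates", "seed")
  check_keys(cfg, allowed, "top level")
  check_keys(cfg$paths, c("responses", "q", "assignment", "override",
                          "out_dir"), "paths")
  check_keys(cfg$priors, c("theta", "eta", "alpha", "guessing"), "priors")
  check_keys(cfg$sampler, c("chains", "warmup", "iter", "seed", "thin",
                            "struct_reps"), "sampler")
  defaults <- list(model = "gmltmd", ppc_replicates = 1000, seed = 1)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  pr <- prior_spec()
  for (k in names(cfg$priors)) pr[[k]] <- as.numeric(cfg$priors[[k]])
  cfg$priors <- pr
  sc <- sampler_config(seed = cfg$seed)
  for (k in names(cfg$sampler)) sc[[k]] <- as.integer(cfg$sampler[[k]])
  cfg$sampler <- sc
  class(cfg) <- "run_config"
  cfg
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible()
}

#' Write a run configuration to JSON
#'
#' @param cfg a `run_config`-style list.
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$priors <- unclass(out$priors)
  out$sampler <- unclass(out$sampler)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a parameter set to JSON
#'
#' @param params a [parameter_set()].
#' @param path output file.
#' @export
write_parameter_set <- function(params, path) {
  inc <- params$cs$incidence
  act <- which(inc == 1L, arr.ind = TRUE)
  out <- list(
    eta = data.frame(component = colnames(inc)[act[, "col"]],
                     feature = rownames(inc)[act[, "row"]],
                     value = params$eta[act]),
    alpha = if (!is.null(params$alpha)) {
      data.frame(group = names(params$alpha), value = as.numeric(params$alpha))
    },
    guessing = if (!is.null(params$guessing)) {
      data.frame(item = params$cs$item_ids, value = params$guessing)
    })
  jsonlite::write_json(out[!vapply(out, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter set written by [write_parameter_set()]
#'
#' @param path JSON file.
#' @param q,cs the structure the parameters refer to.
#' @return a [parameter_set()].
#' @export
read_parameter_set <- function(path, q, cs) {
  pj <- jsonlite::read_json(path, simplifyVector = TRUE)
  inc <- cs$incidence
  eta <- matrix(NA_real_, nrow(inc), ncol(inc), dimnames = dimnames(inc))
  eta[cbind(pj$eta$feature, pj$eta$component)] <- pj$eta$value
  alpha <- NULL; part <- NULL
  if (!is.null(pj$alpha)) {
    part <- discrimination_partition(q, cs)
    alpha <- setNames(pj$alpha$value, pj$alpha$group)
  }
  guessing <- if (!is.null(pj$guessing)) {
    setNames(pj$guessing$value, pj$guessing$item)[cs$item_ids]
  }
  parameter_set(eta = eta, cs = cs, alpha = alpha, guessing = guessing,
                partition = part)
}

#' Write the standard output files of a fitted run
#'
#' Writes `parameter_summary.csv` (EAP and 2.5/97.5% interval per structural
#' parameter), `abilities.csv` (EAP abilities), `draws.csv` (long format:
#' chain, draw, parameter, value — structural parameters), `manifest.json`
#' (model, seed, config, versions), and, when supplied in `summaries`,
#' `ppc_table.csv` and `comparison.csv`.
#'
#' @param fit a [fit_model()] result.
#' @param summaries optional list with elements `ppc` (a
#'   [posterior_predictive_marginals()] table) and/or `comparison` (a
#'   [compare_models()] table).
#' @param out_dir writable output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(fit, summaries = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    # default quoting: parameter labels contain commas
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(summary(fit), "parameter_summary.csv")
  wr(eap_abilities(fit), "abilities.csv")
  dm <- as_draws_matrix(fit, include_theta = FALSE)
  long <- data.frame(chain = rep(attr(dm, "chain"), ncol(dm)),
                     draw = rep(attr(dm, "iteration"), ncol(dm)),
                     parameter = rep(colnames(dm), each = nrow(dm)),
                     value = as.vector(dm))
  wr(long, "draws.csv")
  thm <- as_draws_matrix(fit, include_theta = TRUE)
  thm <- thm[, setdiff(colnames(thm), colnames(dm)), drop = FALSE]
  wr(data.frame(chain = attr(dm, "chain"), draw = attr(dm, "iteration"),
                thm, check.names = FALSE), "theta_draws.csv")
  if (!is.null(summaries$ppc)) wr(summaries$ppc, "ppc_table.csv")
  if (!is.null(summaries$comparison)) wr(summaries$comparison, "comparison.csv")
  manifest <- list(
    model = fit$model_kind,
    seed = fit$config$seed,
    sampler = unclass(fit$config),
    priors = unclass(fit$priors),
    n_persons = length(fit$person_ids),
    n_items = length(fit$item_ids),
    discrimination_groups = if (!is.null(fit$partition)) {
      lapply(seq_along(fit$partition$labels), function(g) {
        list(label = fit$partition$labels[g],
             component = fit$partition$component[g],
             pattern = fit$partition$patterns[g],
             items = fit$partition$members[[g]])
      })
    },
    versions = list(package = as.character(packageVersion("gmltmd")),
                    r = as.character(getRversion()))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mp)
  invisible(files)
}

#' Rebuild a fit object from an output directory
#'
#' Reconstructs the posterior draws written by [write_outputs()]
#' (`draws.csv` plus `theta_draws.csv`) so predictive checks, WAIC, and
#' comparisons can run in a later session or process.
#'
#' @param out_dir directory written by [write_outputs()].
#' @param y the response matrix of the original run.
#' @param q,cs the test structure.
#' @param model_kind the fitted model.
#' @return a `"gmltm_fit"`-compatible object.
#' @export
read_draws <- function(out_dir, y, q, cs, model_kind) {
  long <- read.csv(file.path(out_dir, "draws.csv"), check.names = FALSE)
  stopifnot(all(c("chain", "draw", "parameter", "value") %in% colnames(long)))
  thw <- read.csv(file.path(out_dir, "theta_draws.csv"), check.names = FALSE)
  chains_id <- sort(unique(long$chain))
  iter <- max(long$draw)
  # skeleton via a 0-iteration-like shell: reuse fit_model plumbing manually
  if (model_kind %in% c("lltm", "c2pl")) cs <- collapse_to_unidimensional(q)
  part <- switch(model_kind,
                 gmltmd = discrimination_partition(q, cs),
                 c2pl = discrimination_partition(q, cs, per_item = TRUE),
                 NULL)
  inc <- cs$incidence
  idx <- which(inc == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  eta_labels <- paste0("eta[", cs$component_ids[idx[, "col"]], ",",
                       cs$feature_ids[idx[, "row"]], "]")
  alpha_labels <- if (is.null(part)) character(0) else paste0("alpha[", part$labels, "]")
  est_guess <- model_kind == "gmltmd"
  guess_labels <- if (est_guess) paste0("c[", rownames(q), "]") else character(0)
  N <- nrow(y); M <- ncol(inc)
  th_labels <- paste0("theta[", rep(rownames(y), times = M), ",",
                      rep(cs$component_ids, each = N), "]")
  chains <- lapply(chains_id, function(ch) {
    sub <- long[long$chain == ch, ]
    get_block <- function(labels) {
      m <- matrix(NA_real_, iter, length(labels))
      for (i in seq_along(labels)) {
        m[, i] <- sub$value[sub$parameter == labels[i]][seq_len(iter)]
      }
      m
    }
    tsub <- as.matrix(thw[thw$chain == ch, th_labels, drop = FALSE])
    list(theta = array(tsub, c(iter, N, M)),
         eta = get_block(eta_labels),
         alpha = if (length(alpha_labels)) get_block(alpha_labels) else matrix(0, 0, 0),
         guess = if (est_guess) get_block(guess_labels) else matrix(0, 0, 0))
  })
  structure(
    list(chains = chains, model_kind = model_kind, q = q, cs = cs,
         partition = part, est_alpha = length(alpha_labels) > 0,
         est_guess = est_guess,
         priors = prior_spec(),
         config = sampler_config(chains = length(chains_id), warmup = 0,
                                 iter = iter),
         person_ids = rownames(y), item_ids = rownames(q),
         eta_index = idx, eta_labels = eta_labels,
         alpha_labels = alpha_labels, guess_labels = guess_labels,
         divergences = rep(0L, length(chains_id))),
    class = "gmltm_fit")
}
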