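#' Compose item difficulties from feature difficulties
#'
#' Item difficulty within each component is the sum of the difficulties of the
#' component's features the item contains: `b[j, m] = sum_k q[j, k] eta[k, m]`
#' over the features `k` assigned to component `m`. This is the
#' `beta = Q eta` decomposition of the LLTM, applied per component.
#'
#' @param q a [feature_matrix()].
#' @param cs a [derive_component_matrix()] structure.
#' @param eta K x M numeric matrix of feature difficulties; entries must be
#'   present (non-`NA`) exactly where `cs$incidence` is 1, and `NA` (or 0)
#'   elsewhere — a feature that is not assigned to a component has no
#'   difficulty parameter there (noncompensatory structure).
#' @return a J x M numeric matrix of composed difficulties with an
#'   `"active"` attribute (the logical C matrix); inactive cells are reported
#'   as 0.
#' @export
compose_item_difficulties <- function(q, cs, eta) {
  stopifnot(is_feature_matrix(q), is_component_structure(cs))
  eta <- as.matrix(eta)
  inc <- cs$incidence
  if (!identical(dim(eta), dim(inc))) {
    stop("eta must be ", nrow(inc), " features x ", ncol(inc), " components",
         call. = FALSE)
  }
  missing_eta <- which(inc == 1L & is.na(eta))
  if (length(missing_eta)) {
    k <- ((missing_eta[1] - 1) %% nrow(inc)) + 1
    m <- ((missing_eta[1] - 1) %/% nrow(inc)) + 1
    stop("eta value missing for feature '", rownames(inc)[k],
         "' in component '", colnames(inc)[m], "'", call. = FALSE)
  }
  eta_active <- ifelse(inc == 1L, eta, 0)
  b <- unclass(q) %*% eta_active
  active <- cs$component_matrix == 1L
  b[!active] <- 0
  dimnames(b) <- list(rownames(q), colnames(inc))
  attr(b, "active") <- active
  b
}

#' Partition items into discrimination-sharing groups
#'
#' In the GMLTM-D, discrimination is a property of the feature combination an
#' item carries within a component: two items whose Q rows, restricted to the
#' component's features, are identical share one discrimination parameter.
#' This function computes that partition per component.
#'
#' Group labels are deterministic: within each component, groups are ordered
#' by their binary feature pattern read as a bit string in Q column order and
#' labelled `"<component>/g<rank>"`, so parameter indexing is reproducible
#' across runs.
#'
#' @inheritParams compose_item_difficulties
#' @param per_item if `TRUE`, every active item gets its own group (the
#'   constrained-2PL limit of one discrimination per item).
#' @return a list of class `"discrimination_partition"` with:
#'   `item_group` (J x M integer matrix of global group indices, `NA` where
#'   `C[j, m] = 0`), `labels` (global group labels), `patterns` (the bit
#'   string defining each group), `component` (component id of each group),
#'   `members` (list of item-id vectors per group), and `n_groups`.
#' @export
discrimination_partition <- function(q, cs, per_item = FALSE) {
  stopifnot(is_feature_matrix(q), is_component_structure(cs))
  J <- nrow(q)
  M <- length(cs$component_ids)
  item_group <- matrix(NA_integer_, J, M,
                       dimnames = list(rownames(q), cs$component_ids))
  labels <- character(0); patterns <- character(0)
  component <- character(0); members <- list()
  g_global <- 0L
  for (m in seq_len(M)) {
    feats <- which(cs$incidence[, m] == 1L)
    active <- which(cs$component_matrix[, m] == 1L)
    if (!length(active)) next
    if (per_item) {
      keys <- rownames(q)[active]           # one group per item
      pat <- apply(unclass(q)[active, feats, drop = FALSE], 1, paste, collapse = "")
      ord <- order(keys)
    } else {
      pat_all <- apply(unclass(q)[active, feats, drop = FALSE], 1, paste, collapse = "")
      keys <- pat_all
      pat <- pat_all
      ord <- NULL
    }
    uniq <- sort(unique(keys))              # lexicographic bit-string order
    for (u in uniq) {
      g_global <- g_global + 1L
      in_g <- active[keys == u]
      item_group[in_g, m] <- g_global
      labels <- c(labels, paste0(cs$component_ids[m], "/g",
                                 match(u, uniq),
                                 if (per_item) paste0(":", u) else ""))
      patterns <- c(patterns, unique(pat[keys == u]))
      component <- c(component, cs$component_ids[m])
      members <- c(members, list(rownames(q)[in_g]))
    }
  }
  names(members) <- labels
  structure(
    list(item_group = item_group, labels = labels, patterns = patterns,
         component = component, members = members, n_groups = g_global,
         per_item = per_item),
    class = "discrimination_partition"
  )
}

#' @export
print.discrimination_partition <- function(x, ...) {
  cat("Discrimination partition:", x$n_groups, "groups\n")
  for (g in seq_len(x$n_groups)) {
    cat(sprintf("  %-12s pattern %-6s items: %s\n", x$labels[g], x$patterns[g],
                paste(x$members[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Bundle model parameters
#'
#' @param theta N x M ability matrix (persons by components, logit scale), or
#'   `NULL` when abilities are to be drawn from their prior.
#' @param eta K x M feature difficulty matrix, `NA` where the feature is not
#'   assigned to the component.
#' @param alpha named nonnegative vector of discrimination values, one per
#'   group of `partition` (names must match `partition$labels`); `NULL` fixes
#'   all discriminations at 1.
#' @param guessing length-J vector of lower asymptotes in `[0, 1)`; `NULL`
#'   fixes all at 0.
#' @param cs the [derive_component_matrix()] structure the parameters refer to.
#' @param partition the [discrimination_partition()] that `alpha` indexes.
#' @return list of class `"parameter_set"`.
#' @export
parameter_set <- function(eta, cs, alpha = NULL, guessing = NULL,
                          theta = NULL, partition = NULL) {
  stopifnot(is_component_structure(cs))
  eta <- as.matrix(eta)
  inc <- cs$incidence
  if (!identical(dim(eta), dim(inc))) {
    stop("eta must match the incidence dimensions", call. = FALSE)
  }
  extra <- which(inc == 0L & !is.na(eta) & eta != 0)
  if (length(extra)) {
    k <- ((extra[1] - 1) %% nrow(inc)) + 1
    m <- ((extra[1] - 1) %/% nrow(inc)) + 1
    stop("eta carries a value for feature '", rownames(inc)[k],
         "' in component '", colnames(inc)[m],
         "', but that pair is not in the incidence (noncompensatory: the ",
         "parameter does not exist)", call. = FALSE)
  }
  eta[inc == 0L] <- NA_real_
  if (!is.null(alpha)) {
    if (is.null(partition)) stop("'partition' required when alpha is supplied",
                                 call. = FALSE)
    if (any(alpha < 0)) stop("alpha values must be >= 0", call. = FALSE)
    if (is.null(names(alpha)) || !setequal(names(alpha), partition$labels)) {
      stop("alpha must be named by the partition's group labels", call. = FALSE)
    }
    alpha <- alpha[partition$labels]
  }
  J <- length(cs$item_ids)
  if (!is.null(guessing)) {
    if (length(guessing) != J) stop("guessing must have one value per item",
                                    call. = FALSE)
    if (any(guessing < 0 | guessing >= 1)) {
      stop("guessing values must lie in [0, 1)", call. = FALSE)
    }
  }
  if (!is.null(theta)) {
    theta <- as.matrix(theta)
    if (ncol(theta) != ncol(inc)) stop("theta must have one column per component",
                                       call. = FALSE)
  }
  structure(list(theta = theta, eta = eta, alpha = alpha, guessing = guessing,
                 cs = cs, partition = partition),
            class = "parameter_set")
}

#' Expand a parameter set to per-item composed parameters
#'
#' Produces the item-level view: composed difficulties `b[j, m]`, group-shared
#' discriminations expanded to a J x M matrix, and the guessing vector.
#' Inactive cells (where `C[j, m] = 0`) are reported as 0 and flagged.
#'
#' @param q a [feature_matrix()].
#' @param params a [parameter_set()].
#' @return list of class `"composed_item_parameters"` with elements
#'   `difficulty`, `discrimination`, `guessing`, and `active`.
#' @export
compose_item_parameters <- function(q, params) {
  stopifnot(inherits(params, "parameter_set"))
  cs <- params$cs
  b <- compose_item_difficulties(q, cs, params$eta)
  active <- attr(b, "active")
  J <- nrow(q); M <- ncol(cs$incidence)
  a <- matrix(0, J, M, dimnames = dimnames(b))
  if (is.null(params$alpha)) {
    a[active] <- 1
  } else {
    ig <- params$partition$item_group
    a[active] <- params$alpha[ig[active]]
  }
  g <- params$guessing
  if (is.null(g)) g <- rep(0, J)
  names(g) <- rownames(q)
  structure(list(difficulty = `attr<-`(b, "active", NULL),
                 discrimination = a, guessing = g, active = active),
            class = "composed_item_parameters")
}
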