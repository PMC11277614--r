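#' Validate and construct a feature (Q) matrix
#'
#' The Q matrix is the binary item-by-feature incidence matrix at the heart of
#' all the models in this package: entry `q[j, k] = 1` means item `j` contains
#' feature `k`, so feature difficulties add into the item's difficulty.
#'
#' Validation enforces three structural rules: every entry must be 0 or 1,
#' every item must contain at least one feature (an item with none would have
#' an empty product in the multicomponent models, forcing its success
#' probability to 1 regardless of ability), and every feature must appear in
#' at least one item (otherwise its difficulty is not identified).
#'
#' @param raw integer or numeric matrix, items in rows, features in columns.
#' @param item_ids character labels for the rows; defaults to existing
#'   rownames or `"item<j>"`.
#' @param feature_ids character labels for the columns; defaults to existing
#'   colnames or `"feature<k>"`.
#' @return an integer matrix of class `"feature_matrix"` with row and column
#'   names set.
#' @export
#' @examples
#' q <- feature_matrix(rbind(c(1, 0), c(1, 1)))
validate_feature_matrix <- function(raw, item_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  if (is.null(item_ids)) {
    item_ids <- rownames(raw)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(nrow(raw)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(raw)
    if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(raw)))
  }
  if (length(item_ids) != nrow(raw)) {
    stop("length of 'item_ids' (", length(item_ids), ") != number of rows (",
         nrow(raw), ")", call. = FALSE)
  }
  if (length(feature_ids) != ncol(raw)) {
    stop("length of 'feature_ids' (", length(feature_ids),
         ") != number of columns (", ncol(raw), ")", call. = FALSE)
  }
  if (anyDuplicated(item_ids)) stop("duplicate item ids", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids", call. = FALSE)
  bad <- which(!(raw %in% c(0, 1)) | is.na(raw))
  if (length(bad)) {
    j <- ((bad[1] - 1) %% nrow(raw)) + 1
    k <- ((bad[1] - 1) %/% nrow(raw)) + 1
    stop("non-binary Q entry at item '", item_ids[j], "', feature '",
         feature_ids[k], "': ", raw[bad[1]], call. = FALSE)
  }
  zr <- which(rowSums(raw) == 0)
  if (length(zr)) {
    stop("item(s) with no features (all-zero Q row): ",
         paste(item_ids[zr], collapse = ", "),
         "; such an item's success probability would not depend on ability",
         call. = FALSE)
  }
  zc <- which(colSums(raw) == 0)
  if (length(zc)) {
    stop("feature(s) present in no item (all-zero Q column): ",
         paste(feature_ids[zc], collapse = ", "), call. = FALSE)
  }
  q <- matrix(as.integer(raw), nrow(raw), ncol(raw),
              dimnames = list(item_ids, feature_ids))
  class(q) <- c("feature_matrix", class(q))
  q
}

#' @rdname validate_feature_matrix
#' @export
feature_matrix <- validate_feature_matrix

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature (Q) matrix:", nrow(x), "items x", ncol(x), "features\n")
  print(unclass(x), ...)
  invisible(x)
}

is_feature_matrix <- function(x) inherits(x, "feature_matrix")

#' Derive the item-by-component C matrix from Q and a feature-component map
#'
#' Each feature is assigned to one or more latent components through a binary
#' incidence matrix (features in rows, components in columns). The C matrix
#' then marks, for each item, which components are required to solve it:
#' `C[j, m] = 1` exactly when item `j` contains at least one feature assigned
#' to component `m`. In the noncompensatory models the component-`m`
#' probability enters the item's success probability only when `C[j, m] = 1`.
#'
#' An `override` may add 1-entries to the derived C (cross-loadings), but only
#' where component `m` shares at least one feature with the item, and it may
#' never remove a derived 1: removing one would contradict the definition of
#' C above. To make an item load on a component that shares none of its
#' features, first extend the incidence so one of its features maps to that
#' component (multi-component features are allowed).
#'
#' @param q a [feature_matrix()].
#' @param incidence binary K x M matrix, features in rows, components in
#'   columns; every feature must map to at least one component.
#' @param override optional binary J x M matrix replacing the derived C;
#'   must be additive as described above.
#' @return a list of class `"component_structure"` with elements `incidence`,
#'   `component_matrix` (the C matrix), `derived_flag`, and the id vectors.
#' @export
derive_component_matrix <- function(q, incidence, override = NULL) {
  stopifnot(is_feature_matrix(q))
  incidence <- as.matrix(incidence)
  if (nrow(incidence) != ncol(q)) {
    stop("incidence has ", nrow(incidence), " feature rows but Q has ",
         ncol(q), " features", call. = FALSE)
  }
  if (!all(incidence %in% c(0, 1))) stop("incidence must be binary", call. = FALSE)
  if (any(rowSums(incidence) == 0)) {
    stop("feature(s) mapped to no component: ",
         paste(colnames(q)[rowSums(incidence) == 0], collapse = ", "),
         call. = FALSE)
  }
  component_ids <- colnames(incidence)
  if (is.null(component_ids)) component_ids <- paste0("comp", seq_len(ncol(incidence)))
  incidence <- matrix(as.integer(incidence), nrow(incidence), ncol(incidence),
                      dimnames = list(colnames(q), component_ids))
  derived <- 1L * ((unclass(q) %*% incidence) > 0)
  dimnames(derived) <- list(rownames(q), component_ids)
  cmat <- derived
  derived_flag <- TRUE
  if (!is.null(override)) {
    override <- as.matrix(override)
    if (!identical(dim(override), dim(derived))) {
      stop("override must be ", nrow(derived), " x ", ncol(derived), call. = FALSE)
    }
    if (!all(override %in% c(0, 1))) stop("override must be binary", call. = FALSE)
    removed <- which(derived == 1L & override == 0L)
    if (length(removed)) {
      stop("override removes derived C entries; C entries may only be added",
           call. = FALSE)
    }
    added <- which(derived == 0L & override == 1L)
    for (cell in added) {
      j <- ((cell - 1) %% nrow(derived)) + 1
      m <- ((cell - 1) %/% nrow(derived)) + 1
      shared <- any(unclass(q)[j, ] == 1L & incidence[, m] == 1L)
      if (!shared) {
        stop("override sets C[", rownames(q)[j], ", ", component_ids[m],
             "] = 1 but component '", component_ids[m],
             "' shares no feature with the item; extend the incidence first",
             call. = FALSE)
      }
    }
    cmat <- matrix(as.integer(override), nrow(derived), ncol(derived),
                   dimnames = dimnames(derived))
    derived_flag <- identical(cmat, derived)
  }
  structure(
    list(incidence = incidence, component_matrix = cmat,
         derived_flag = derived_flag, item_ids = rownames(q),
         feature_ids = colnames(q), component_ids = component_ids),
    class = "component_structure"
  )
}

#' @export
print.component_structure <- function(x, ...) {
  cat("Component structure:", length(x$feature_ids), "features ->",
      length(x$component_ids), "components",
      if (x$derived_flag) "(C derived)" else "(C overridden)", "\n")
  print(x$component_matrix, ...)
  invisible(x)
}

is_component_structure <- function(x) inherits(x, "component_structure")

# Collapse any structure to a single component (the LLTM / constrained-2PL
# view): all features feed one trait, C is a column of ones.
collapse_to_unidimensional <- function(q) {
  inc <- matrix(1L, ncol(q), 1, dimnames = list(colnames(q), "comp1"))
  derive_component_matrix(q, inc)
}
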