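#' Extract tree arrays from a randomForest regression fit
#'
#' Converts the forest into the flat per-tree arrays the TreeSHAP kernel
#' consumes, computing each node's cover (training weight reaching it) from
#' the tree's own in-bag bootstrap counts. Requires the forest to have been
#' grown with `keep.forest = TRUE` and `keep.inbag = TRUE`.
#'
#' @param rf a `randomForest` regression object.
#' @param x_train the training predictor matrix the forest was grown on.
#' @return list of per-tree lists (`left`, `right`, `feature`, `threshold`,
#'   `value`, `cover`), 0-based indices, children `-1` at leaves.
#' @keywords internal
rf_tree_arrays <- function(rf, x_train) {
  if (is.null(rf$forest)) stop("forest not kept (keep.forest = TRUE required)",
                               call. = FALSE)
  if (is.null(rf$inbag)) stop("in-bag counts not kept (keep.inbag = TRUE required)",
                              call. = FALSE)
  x_train <- as.matrix(x_train)
  fo <- rf$forest
  lapply(seq_len(fo$ntree), function(k) {
    nn <- fo$ndbigtree[k]
    left <- fo$leftDaughter[seq_len(nn), k]
    right <- fo$rightDaughter[seq_len(nn), k]
    leaf <- left == 0L
    tree <- list(left = ifelse(leaf, -1L, left - 1L),
                 right = ifelse(leaf, -1L, right - 1L),
                 feature = ifelse(leaf, 0L, fo$bestvar[seq_len(nn), k] - 1L),
                 threshold = fo$xbestsplit[seq_len(nn), k],
                 value = fo$nodepred[seq_len(nn), k])
    tree$cover <- treeshap_cover(tree$left, tree$right, tree$feature,
                                 tree$threshold, x_train,
                                 as.numeric(rf$inbag[, k]))
    tree
  })
}

#' Exact TreeSHAP values for a randomForest regression model
#'
#' Computes, for every row of `newdata`, the exact Shapley attribution of each
#' predictor under the path-dependent tree formulation: absent features are
#' marginalized using the cover-weighted flow of the tree's in-bag training
#' sample. Attributions satisfy the efficiency (additivity) axiom:
#' `rowSums(phi) + base` equals the forest prediction.
#'
#' @param rf a `randomForest` regression object (`keep.forest`, `keep.inbag`).
#' @param x_train training predictor matrix (defines the background).
#' @param newdata matrix/data.frame of rows to explain; defaults to `x_train`.
#' @return list with `phi` (n x p matrix, columns named as predictors) and
#'   `base` (scalar expected value).
#' @export
shap_values <- function(rf, x_train, newdata = x_train) {
  x_train <- as.matrix(x_train)
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), colnames(x_train)))
    newdata <- newdata[, colnames(x_train), drop = FALSE]
  trees <- rf_tree_arrays(rf, x_train)
  res <- treeshap_forest(trees, newdata)
  colnames(res$phi) <- colnames(x_train)
  res
}
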