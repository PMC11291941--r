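#' Split-gain variable importance for a trained surrogate
#'
#' Total split gain per feature across the ensemble, normalized to sum to 1,
#' with descending ranks; ties (including never-used features, which get
#' importance 0) are broken by the proxy's feature order.
#'
#' @param proxy A `trained_proxy`.
#' @return Data frame of class `importance_table`: `feature`, `importance`,
#'   `rank`.
#' @export
gain_importance <- function(proxy) {
  stopifnot(inherits(proxy, "trained_proxy"))
  imp <- xgboost::xgb.importance(model = proxy$booster)
  gain <- stats::setNames(rep(0, length(proxy$feature_order)),
                          proxy$feature_order)
  if (!is.null(imp) && nrow(imp))
    gain[imp$Feature] <- imp$Gain
  total <- sum(gain)
  if (total > 0) gain <- gain / total
  ord <- order(-gain, match(names(gain), proxy$feature_order))
  out <- data.frame(feature = names(gain), importance = unname(gain),
                    rank = NA_integer_, row.names = NULL)
  out$rank[ord] <- seq_along(ord)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Per-prediction Shapley attributions
#'
#' Path-dependent tree-Shapley attributions computed from the trained
#' ensemble's own structure. Satisfies local accuracy: for every row, the
#' base value plus the feature attributions equals the model prediction.
#' Missing feature cells are flagged in `missing_mask` (they still receive
#' attributions via the trees' default split directions).
#'
#' @param proxy A `trained_proxy`.
#' @param newdata Cohort or feature data frame (see
#'   [predict.trained_proxy()]).
#' @return A list of class `attribution_matrix`: `attributions`
#'   (rows x features), `base_value` (scalar expected prediction),
#'   `prediction`, `feature_values`, `missing_mask`, `ids`.
#' @export
shap_attributions <- function(proxy, newdata) {
  stopifnot(inherits(proxy, "trained_proxy"))
  nd_names <- names(newdata)
  feats <- if (setequal(nd_names, proxy$feature_order)) {
    newdata[proxy$feature_order]
  } else if (all(proxy$feature_order %in% nd_names)) {
    stop("unknown feature key(s): ",
         paste(setdiff(nd_names, proxy$feature_order), collapse = ", "))
  } else {
    do.call(assemble_features,
            c(list(newdata, proxy$tier), proxy$assemble_args))
  }
  X <- as.matrix(as.data.frame(feats)[proxy$feature_order])
  storage.mode(X) <- "double"
  dm <- xgboost::xgb.DMatrix(X, missing = NA)
  contrib <- stats::predict(proxy$booster, dm, predcontrib = TRUE)
  bias_col <- ncol(contrib)
  structure(list(attributions = contrib[, -bias_col, drop = FALSE],
                 base_value = unname(contrib[1, bias_col]),
                 prediction = rowSums(contrib),
                 feature_values = X,
                 missing_mask = is.na(X),
                 ids = attr(feats, "id") %||%
                   (if ("id" %in% nd_names) newdata$id else seq_len(nrow(X)))),
            class = "attribution_matrix")
}

#' Long-format beeswarm export of Shapley attributions
#'
#' One row per (participant, feature) pair, suitable for beeswarm plotting.
#' Missing feature values are carried as an explicit category (`missing =
#' TRUE`, `feature_value = NA`), never dropped.
#'
#' @param attr An [shap_attributions()] result.
#' @return Data frame: `id`, `feature`, `attribution`, `feature_value`,
#'   `missing`.
#' @export
beeswarm_export <- function(attr) {
  stopifnot(inherits(attr, "attribution_matrix"))
  n <- nrow(attr$attributions)
  p <- ncol(attr$attributions)
  features <- colnames(attr$attributions)
  data.frame(
    id = rep(attr$ids, times = p),
    feature = rep(features, each = n),
    attribution = as.vector(attr$attributions),
    feature_value = as.vector(attr$feature_values),
    missing = as.vector(attr$missing_mask),
    row.names = NULL)
}
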