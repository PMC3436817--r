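#' Reliability index from a path confidence
#'
#' The raw confidence of a prediction is the product of the per-node
#' reliabilities along the root-to-leaf path, a number in `[0, 1]`. On a
#' 0-100 scale the product carries no signal below 20 (every binary
#' decision contributes at least 0.5), so the index is re-normalized by the
#' affine map `[20, 100] -> [0, 100]` and rounded to an integer:
#' `RI = round(100 * (100 * raw_confidence - 20) / 80)`, clipped to
#' `[0, 100]`.
#'
#' @param raw_confidence Numeric vector in `[0, 1]`.
#' @return Integer vector of reliability indices in `[0, 100]`, monotone
#'   non-decreasing in `raw_confidence`.
#' @export
#' @examples
#' reliability_index(c(0.15, 0.72, 1))
reliability_index <- function(raw_confidence) {
  if (any(raw_confidence < 0 | raw_confidence > 1, na.rm = TRUE)) {
    stop("raw_confidence must lie in [0, 1]", call. = FALSE)
  }
  raw <- 100 * raw_confidence
  as.integer(pmin(100, pmax(0, round(100 * (raw - 20) / 80))))
}

# Descend the tree for pre-computed kernel columns. kvals: matrix of
# kernel values, rows named by training ids, one column per query.
descend_tree <- function(model, kvals, query_ids) {
  topo <- model$topology
  out <- vector("list", length(query_ids))
  for (qi in seq_along(query_ids)) {
    col <- kvals[, qi]
    node <- topo$root
    steps <- list()
    conf <- 1
    while (!is_leaf(topo, node)) {
      nm <- model$node_models[[node]]
      f <- decision_values(nm, col)
      p <- platt_probability(nm, f)
      if (p == 0.5) {
        warning("tie (p = 0.5) at node '", node, "' for query '",
                query_ids[qi], "'; choosing class A child", call. = FALSE)
      }
      choose_a <- p >= 0.5
      rel <- node_reliability(p)
      child <- topo$children[[node]][if (choose_a) 1L else 2L]
      steps[[length(steps) + 1L]] <- tibble::tibble(
        node = node, chosen_child = child,
        probability = if (choose_a) p else 1 - p,
        reliability = rel)
      conf <- conf * rel
      node <- child
    }
    out[[qi]] <- tibble::tibble(
      id = query_ids[qi],
      predicted_class = node,
      raw_confidence = conf,
      ri = reliability_index(conf),
      path = list(dplyr::bind_rows(steps)))
  }
  dplyr::bind_rows(out)
}

#' Predict subcellular localization for query profiles
#'
#' Starting at the root, each node's SVM decision value is computed from
#' kernel evaluations against the stored training profiles, mapped to a
#' probability through the node's Platt sigmoid, and the child with
#' probability above 0.5 is followed until a leaf is reached. The leaf is
#' the predicted class; per-node reliabilities multiply into the raw
#' confidence from which the reliability index is derived.
#'
#' @param object A trained `hierloc_model`.
#' @param newdata Either a single [sequence_profile()], a list of them, or
#'   a data frame with a `profile` list column.
#' @param ... Unused.
#' @return A tibble with one row per query: `id`, `predicted_class`,
#'   `raw_confidence`, `ri` and a `path` list column of per-node tibbles
#'   (`node`, `chosen_child`, `probability`, `reliability`).
#' @export
predict.hierloc_model <- function(object, newdata, ...) {
  queries <- if (inherits(newdata, "hierloc_profile")) {
    list(newdata)
  } else if (is.data.frame(newdata)) {
    stopifnot("profile" %in% names(newdata))
    newdata$profile
  } else {
    newdata
  }
  check_profiles(queries, object$params$k, "queries")
  train_profiles <- object$profiles
  raw <- pk_cross_cpp(lapply(train_profiles, `[[`, "costs"),
                      lapply(queries, `[[`, "costs"),
                      object$params$k, object$params$sigma)
  if (object$params$normalize) {
    dq <- pk_self_cpp(lapply(queries, `[[`, "costs"),
                      object$params$k, object$params$sigma)
    raw <- cosine_normalize(raw, object$self_k, dq)
  }
  rownames(raw) <- names(train_profiles)
  descend_tree(object, raw, profile_ids(queries))
}

#' Predict a batch of queries and write a prediction table
#'
#' Per-query failures (e.g. sequences shorter than k) are logged as
#' warnings and skipped rather than aborting the batch. Output columns:
#' `id`, `predicted_class`, `ri` and `path` formatted as
#' `node:probability;...`.
#'
#' @param model A trained `hierloc_model`.
#' @param queries List of [sequence_profile()] objects or data frame with
#'   a `profile` column.
#' @param out_path Optional TSV path to write.
#' @return The prediction tibble (with `raw_confidence` and the formatted
#'   `path` string), invisibly when `out_path` is given.
#' @export
predict_batch <- function(model, queries, out_path = NULL) {
  if (is.data.frame(queries)) queries <- queries$profile
  ok <- vapply(queries, function(p) nchar(p$sequence) >= model$params$k,
               logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " query sequence(s) shorter than k = ",
            model$params$k, " skipped: ",
            paste(profile_ids(queries[!ok]), collapse = ", "),
            call. = FALSE)
  }
  if (sum(ok) == 0L) {
    preds <- tibble::tibble(id = character(0),
                            predicted_class = character(0),
                            raw_confidence = numeric(0),
                            ri = integer(0), path = character(0))
  } else {
    preds <- predict(model, queries[ok])
    preds$path <- vapply(preds$path, function(p) {
      paste(sprintf("%s:%.4f", p$node, p$probability), collapse = ";")
    }, character(1))
  }
  if (!is.null(out_path)) {
    utils::write.table(
      preds[, c("id", "predicted_class", "ri", "path")],
      out_path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(preds))
  }
  preds
}
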