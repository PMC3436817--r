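#' Confusion matrix of localization predictions
#'
#' Rows are observed classes, columns predicted classes.
#'
#' @param observed,predicted Character vectors of equal length.
#' @param classes Optional ordered class set (defaults to the union).
#' @return An object of class `hierloc_confusion`: a square integer matrix
#'   with class dimnames.
#' @export
confusion_matrix <- function(observed, predicted, classes = NULL) {
  stopifnot(length(observed) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(c(observed, predicted)))
  bad <- setdiff(unique(c(observed, predicted)), classes)
  if (length(bad) > 0L) {
    stop("class(es) outside the declared set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- table(factor(observed, levels = classes),
             factor(predicted, levels = classes))
  structure(unclass(m), dimnames = dimnames(m),
            class = c("hierloc_confusion", "matrix"))
}

check_class <- function(cm, class_name) {
  if (!class_name %in% rownames(cm)) {
    stop("unknown class: ", class_name, call. = FALSE)
  }
}

#' Per-class accuracy, coverage and their geometric average
#'
#' For a localization class L, accuracy is the fraction of proteins
#' predicted in L that are observed in L (precision); coverage is the
#' fraction of proteins observed in L that are predicted in L (recall);
#' gAv is `sqrt(accuracy * coverage)`. Undefined ratios (empty column or
#' row) are reported as `NA`, not as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param class_name A class in `cm`.
#' @return Numeric scalar (or `NA`).
#' @export
class_accuracy <- function(cm, class_name) {
  check_class(cm, class_name)
  pred <- sum(cm[, class_name])
  if (pred == 0) return(NA_real_)
  cm[class_name, class_name] / pred
}

#' @rdname class_accuracy
#' @export
class_coverage <- function(cm, class_name) {
  check_class(cm, class_name)
  obs <- sum(cm[class_name, ])
  if (obs == 0) return(NA_real_)
  cm[class_name, class_name] / obs
}

#' @rdname class_accuracy
#' @export
gav <- function(cm, class_name) {
  a <- class_accuracy(cm, class_name)
  c <- class_coverage(cm, class_name)
  if (is.na(a) || is.na(c)) return(NA_real_)
  sqrt(a * c)
}

#' Per-class metric table
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble with columns `class`, `n_obs`, `accuracy`, `coverage`,
#'   `gav`.
#' @export
class_metrics <- function(cm) {
  cls <- rownames(cm)
  tibble::tibble(
    class = cls,
    n_obs = as.integer(rowSums(cm)),
    accuracy = vapply(cls, function(l) class_accuracy(cm, l), numeric(1)),
    coverage = vapply(cls, function(l) class_coverage(cm, l), numeric(1)),
    gav = vapply(cls, function(l) gav(cm, l), numeric(1))
  )
}

#' Overall n-class accuracy Qn
#'
#' Correctly predicted proteins across the chosen classes divided by the
#' proteins observed in those classes.
#'
#' @param cm A [confusion_matrix()].
#' @param class_subset Classes to include (default all).
#' @return Numeric scalar in `[0, 1]`.
#' @export
overall_q <- function(cm, class_subset = rownames(cm)) {
  if (length(class_subset) == 0L) stop("empty class subset", call. = FALSE)
  bad <- setdiff(class_subset, rownames(cm))
  if (length(bad) > 0L) {
    stop("unknown class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(diag(cm)[class_subset]) / sum(cm[class_subset, ])
}

#' Evaluation configuration
#'
#' @param n_folds Cross-validation folds (default 5).
#' @param n_bootstrap Bootstrap sets for standard errors (default 1000).
#' @param bootstrap_fraction Fraction of proteins drawn, without
#'   replacement, into each bootstrap set (default 0.5).
#' @param seed RNG seed for folds and bootstrap.
#' @param min_class_size_report Classes with fewer observed members are
#'   excluded from the reported metrics (default 20).
#' @param se_mode `"literal"` divides the bootstrap standard deviation by
#'   `sqrt(n_bootstrap)`; `"sd"` reports the plain standard deviation.
#' @return An object of class `hierloc_eval_config`.
#' @export
eval_config <- function(n_folds = 5L, n_bootstrap = 1000L,
                        bootstrap_fraction = 0.5, seed = 1L,
                        min_class_size_report = 20L,
                        se_mode = c("literal", "sd")) {
  stopifnot(n_folds >= 2L, n_bootstrap >= 1L,
            bootstrap_fraction > 0, bootstrap_fraction < 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_bootstrap = as.integer(n_bootstrap),
                 bootstrap_fraction = bootstrap_fraction,
                 seed = as.integer(seed),
                 min_class_size_report = as.integer(min_class_size_report),
                 se_mode = match.arg(se_mode)),
            class = "hierloc_eval_config")
}

metric_fun <- function(statistic) {
  if (is.function(statistic)) return(statistic)
  switch(statistic,
    qn = function(obs, pred) overall_q(confusion_matrix(obs, pred)),
    accuracy = function(obs, pred) mean(obs == pred),
    stop("unknown statistic: ", statistic, call. = FALSE))
}

#' Bootstrap standard error of an evaluation statistic
#'
#' Draws `n_bootstrap` subsets of size
#' `ceiling(bootstrap_fraction * N)` without replacement from the
#' (observed, predicted) pairs, evaluates the statistic on each, and
#' returns the standard deviation of the estimates divided by
#' `sqrt(n_bootstrap)` (`se_mode = "literal"`), or the plain standard
#' deviation (`se_mode = "sd"`). Subsets on which the statistic is
#' undefined (`NA`) are redrawn, with a message.
#'
#' @param predictions Data frame with columns `observed` and `predicted`.
#' @param statistic `"qn"`, `"accuracy"`, or a
#'   `function(observed, predicted)`.
#' @param config An [eval_config()] (supplies `n_bootstrap`,
#'   `bootstrap_fraction`, `seed`, `se_mode`).
#' @return Numeric standard error; deterministic for a fixed seed.
#' @export
bootstrap_se <- function(predictions, statistic = "qn",
                         config = eval_config()) {
  stopifnot(all(c("observed", "predicted") %in% names(predictions)))
  n <- nrow(predictions)
  if (n < 2L) stop("need at least 2 proteins to bootstrap", call. = FALSE)
  m <- ceiling(config$bootstrap_fraction * n)
  fun <- metric_fun(statistic)
  vals <- numeric(config$n_bootstrap)
  n_redraw <- 0L
  with_seed(config$seed, {
    for (b in seq_len(config$n_bootstrap)) {
      for (tries in 1:100) {
        idx <- sample.int(n, m, replace = FALSE)
        v <- fun(predictions$observed[idx], predictions$predicted[idx])
        if (!is.na(v)) break
        n_redraw <- n_redraw + 1L
      }
      vals[b] <- v
    }
  })
  if (n_redraw > 0L) {
    message(n_redraw, " bootstrap subset(s) redrawn (undefined statistic)")
  }
  s <- stats::sd(vals)
  if (config$se_mode == "literal") s / sqrt(config$n_bootstrap) else s
}

#' Stratified k-fold split
#'
#' Partitions ids into folds so that per-class counts differ by at most
#' one across folds. Classes with fewer members than folds are spread
#' best-effort with a warning.
#'
#' @param labeled Data frame with columns `id` and `class`.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return List of `n_folds` elements, each `list(train_ids, test_ids)`.
#' @export
stratified_kfold <- function(labeled, n_folds = 5L, seed = 1L) {
  stopifnot(all(c("id", "class") %in% names(labeled)))
  n <- nrow(labeled)
  if (n < n_folds) stop("fewer proteins than folds", call. = FALSE)
  small <- names(which(table(labeled$class) < n_folds))
  if (length(small) > 0L) {
    warning("class(es) with fewer members than folds: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in sample(unique(labeled$class))) {
      idx <- sample(which(labeled$class == cl))
      # rotate the starting fold between classes so small classes do not
      # all pile into fold 1
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  lapply(seq_len(n_folds), function(fd) {
    list(train_ids = labeled$id[fold != fd],
         test_ids = labeled$id[fold == fd])
  })
}

#' Stratified cross-validation of the full hierarchy
#'
#' Trains the tree on each training split (including the Platt inner CV)
#' and predicts the held-out fold; test-fold predictions are concatenated
#' into one confusion matrix. Nothing from a test split enters the
#' corresponding training phase: the profile kernel is a fixed pairwise
#' function of the profiles, so its precomputed Gram matrix carries no
#' label information. Classes with fewer than
#' `config$min_class_size_report` members are excluded from the reported
#' per-class table and from Qn, with a message.
#'
#' @param data Data frame with `id`, `class`, `profile` columns.
#' @param topology A `hierloc_topology`.
#' @param params [kernel_params()].
#' @param config An [eval_config()].
#' @param regularization_c,platt_cv_folds Passed to [train_tree()].
#' @return An object of class `hierloc_cv`: list with `predictions`
#'   (tibble: `id`, `fold`, `observed`, `predicted`, `raw_confidence`,
#'   `ri`), `confusion`, `metrics` (per-class tibble over reported
#'   classes), `qn`, `reported_classes` and `config`.
#' @export
cross_validate <- function(data, topology, params = kernel_params(),
                           config = eval_config(), regularization_c = 1,
                           platt_cv_folds = 3L) {
  stopifnot(all(c("id", "class", "profile") %in% names(data)))
  gram <- kernel_matrix(stats::setNames(data$profile, data$id), params)
  folds <- stratified_kfold(data, config$n_folds, config$seed)
  preds <- vector("list", length(folds))
  for (fd in seq_along(folds)) {
    tr <- data[data$id %in% folds[[fd]]$train_ids, ]
    te <- data[data$id %in% folds[[fd]]$test_ids, ]
    model <- tryCatch(
      train_tree(tr, topology, params, regularization_c, platt_cv_folds,
                 seed = config$seed + fd, gram = gram),
      error = function(e) stop("training failed in fold ", fd, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    # kernel columns for the test fold come from the same Gram matrix;
    # identical to kernel_row against the stored profiles
    kvals <- sub_kernel(gram, tr$id, te$id)
    p <- descend_tree(model, kvals, te$id)
    preds[[fd]] <- tibble::tibble(
      id = p$id, fold = fd, observed = te$class[match(p$id, te$id)],
      predicted = p$predicted_class, raw_confidence = p$raw_confidence,
      ri = p$ri)
  }
  preds <- dplyr::bind_rows(preds)
  cm <- confusion_matrix(preds$observed, preds$predicted,
                         classes = topology$leaves)
  sizes <- rowSums(cm)
  reported <- names(sizes)[sizes >= config$min_class_size_report]
  dropped <- setdiff(names(sizes)[sizes > 0], reported)
  if (length(dropped) > 0L) {
    message("class(es) below the reporting threshold excluded: ",
            paste(dropped, collapse = ", "))
  }
  if (length(reported) == 0L) {
    stop("no class reaches min_class_size_report = ",
         config$min_class_size_report, call. = FALSE)
  }
  metrics <- class_metrics(cm)
  metrics <- metrics[metrics$class %in% reported, ]
  structure(
    list(predictions = preds, confusion = cm, metrics = metrics,
         qn = overall_q(cm, reported), reported_classes = reported,
         config = config, params = params, topology = topology),
    class = "hierloc_cv"
  )
}

#' @export
print.hierloc_cv <- function(x, ...) {
  cat("<hierloc_cv> ", x$config$n_folds, "-fold CV, ",
      nrow(x$predictions), " proteins, Q", length(x$reported_classes),
      " = ", sprintf("%.3f", x$qn), "\n", sep = "")
  invisible(x)
}

#' Accuracy/coverage as a function of the reliability-index threshold
#'
#' For each threshold t in 0..100, predictions with `RI >= t` are kept:
#' true positives are correct kept predictions, false positives wrong kept
#' predictions, false negatives correct predictions below the threshold.
#' Accuracy `TP/(TP+FP)` is `NA` where nothing is kept; coverage
#' `TP/(TP+FN)` is monotone non-increasing in the threshold.
#'
#' @param predictions Data frame with columns `observed`, `predicted`,
#'   `ri`.
#' @return An object of classes `hierloc_ri_curves`/`tbl_df`: tibble with
#'   columns `threshold`, `n_above`, `accuracy`, `coverage`.
#' @export
ri_curves <- function(predictions) {
  stopifnot(all(c("observed", "predicted", "ri") %in% names(predictions)))
  if (any(predictions$ri < 0 | predictions$ri > 100)) {
    stop("ri must lie in [0, 100]", call. = FALSE)
  }
  correct <- predictions$observed == predictions$predicted
  rows <- lapply(0:100, function(t) {
    above <- predictions$ri >= t
    tp <- sum(correct & above)
    fp <- sum(!correct & above)
    fn <- sum(correct & !above)
    tibble::tibble(threshold = t, n_above = sum(above),
                   accuracy = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
                   coverage = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hierloc_ri_curves", class(out))
  out
}
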