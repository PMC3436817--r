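#' Assemble the binary training set of an internal node
#'
#' Proteins labeled with any leaf class under the node's first child form
#' class A, those under the second child class B; proteins whose class
#' lies elsewhere in the tree are excluded. At the archaeal root, for
#' example, the non-cytosolic child gathers the EXT- and PM-labeled
#' proteins (class A) against the CYT-labeled proteins (class B).
#'
#' @param topology A `hierloc_topology`.
#' @param node_id Internal node name.
#' @param labeled Data frame with columns `id` and `class`.
#' @return List with character vectors `a_ids` and `b_ids`.
#' @export
assemble_node_dataset <- function(topology, node_id, labeled) {
  if (is_leaf(topology, node_id)) {
    stop("'", node_id, "' is a leaf, not a decision node", call. = FALSE)
  }
  if (!node_id %in% topology$internal) {
    stop("unknown node: ", node_id, call. = FALSE)
  }
  stopifnot(all(c("id", "class") %in% names(labeled)))
  unknown <- setdiff(unique(labeled$class), topology$leaves)
  if (length(unknown) > 0L) {
    stop("label(s) not in topology: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  kids <- topology$children[[node_id]]
  a_ids <- labeled$id[labeled$class %in% leaves_under(topology, kids[1])]
  b_ids <- labeled$id[labeled$class %in% leaves_under(topology, kids[2])]
  if (length(a_ids) == 0L || length(b_ids) == 0L) {
    stop("empty branch at node '", node_id, "'", call. = FALSE)
  }
  list(a_ids = a_ids, b_ids = b_ids)
}

sub_kernel <- function(km, row_ids, col_ids = row_ids) {
  missing <- setdiff(unique(c(row_ids, col_ids)), km$ids)
  if (length(missing) > 0L) {
    stop("ids absent from kernel matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  km$values[row_ids, col_ids, drop = FALSE]
}

#' Train one node's binary SVM on a precomputed kernel
#'
#' Solves the soft-margin SVM dual on the sub-kernel spanned by the two
#' id sets and returns the dual expansion. Sign convention: positive
#' decision value means class A.
#'
#' @param km A `hierloc_kernel_matrix` covering all ids.
#' @param a_ids,b_ids Disjoint, non-empty id sets.
#' @param regularization_c Soft-margin cost C (default 1).
#' @param node_id Name recorded on the model.
#' @return An object of class `hierloc_node_model`: list with `node_id`,
#'   `support_ids`, `dual_coef`, `bias`, `platt_a`, `platt_b` (NA until
#'   calibrated) and `regularization_c`.
#' @export
train_node <- function(km, a_ids, b_ids, regularization_c = 1,
                       node_id = "node") {
  stopifnot(inherits(km, "hierloc_kernel_matrix"))
  if (length(a_ids) == 0L || length(b_ids) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  both <- intersect(a_ids, b_ids)
  if (length(both) > 0L) {
    stop("ids in both classes: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  ids <- c(a_ids, b_ids)
  Ksub <- sub_kernel(km, ids)
  y <- factor(c(rep("A", length(a_ids)), rep("B", length(b_ids))),
              levels = c("A", "B"))
  fit <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(Ksub), y,
                  C = regularization_c, prob.model = FALSE),
    error = function(e) {
      ev <- eigen(Ksub, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev))) {
        stop("sub-kernel is not positive semi-definite (min eigenvalue ",
             signif(min(ev), 3), "); add diagonal jitter to the kernel",
             call. = FALSE)
      }
      stop("SVM training failed at node '", node_id, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  sv <- kernlab::SVindex(fit)
  coefs <- unlist(kernlab::coef(fit))
  bias <- -kernlab::b(fit)
  f <- drop(Ksub[, sv, drop = FALSE] %*% coefs) + bias
  # kernlab's mapping of factor levels to the +/-1 side is an internal
  # detail; orient so that positive f means class A
  if (mean(f[y == "A"]) < mean(f[y == "B"])) {
    coefs <- -coefs
    bias <- -bias
  }
  structure(
    list(node_id = node_id,
         support_ids = ids[sv],
         dual_coef = stats::setNames(coefs, ids[sv]),
         bias = bias,
         platt_a = NA_real_, platt_b = NA_real_,
         regularization_c = regularization_c),
    class = "hierloc_node_model"
  )
}

#' Decision values of a node model
#'
#' `f(q) = sum_i dual_coef[i] * K(support_i, q) + bias`, evaluated from a
#' kernel block whose rows cover the support ids.
#'
#' @param node_model A `hierloc_node_model`.
#' @param kvals Numeric matrix of kernel values with rownames covering
#'   `support_ids` (columns = queries), or a named vector for one query.
#' @return Numeric vector of decision values, one per query column.
#' @export
decision_values <- function(node_model, kvals) {
  if (is.null(dim(kvals))) kvals <- matrix(kvals, ncol = 1,
                                           dimnames = list(names(kvals), NULL))
  drop(crossprod(kvals[node_model$support_ids, , drop = FALSE],
                 node_model$dual_coef)) + node_model$bias
}

#' Platt scaling: sigmoid calibration of SVM decision values
#'
#' Fits `P(class A | f) = 1 / (1 + exp(a*f + b))` by minimising the
#' cross-entropy against Platt's smoothed targets
#' `t+ = (N+ + 1)/(N+ + 2)` and `t- = 1/(N- + 2)`, using a damped Newton
#' iteration on the convex objective. When larger `f` means class A the
#' fitted `a` is negative.
#'
#' @param decision_values Numeric vector of decision values.
#' @param labels Vector distinguishing the two classes: `+1`/`-1`,
#'   logical, or the strings `"A"`/`"B"` (A is the positive class).
#' @return Named numeric vector `c(a = , b = )`.
#' @export
fit_platt <- function(decision_values, labels) {
  f <- as.numeric(decision_values)
  if (is.character(labels) || is.factor(labels)) {
    pos <- as.character(labels) == "A"
  } else if (is.logical(labels)) {
    pos <- labels
  } else {
    pos <- labels > 0
  }
  stopifnot(length(f) == length(pos))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to fit the sigmoid", call. = FALSE)
  }
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(pos, hi, lo)

  # F(a,b) = sum t*log(1+e^z) + (1-t)*log(1+e^{-z}), z = a*f + b,
  # written with a stable log(1+e^z)
  obj <- function(a, b) {
    z <- a * f + b
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  # Newton iteration (damped) on (a, b)
  a <- 0; b <- log((n_neg + 1) / (n_pos + 1))
  best <- obj(a, b)
  for (it in 1:200) {
    z <- a * f + b
    p <- 1 / (1 + exp(z))        # P(class A)
    # gradient of F wrt (a, b): dF/dz = (1 - t) - (1 - p)... derive:
    # F = sum t*log(1+e^z) + (1-t)*log(1+e^{-z}); dF/dz = t*(1-p) - (1-t)*p
    d <- t * (1 - p) - (1 - t) * p
    g <- c(sum(d * f), sum(d))
    w <- p * (1 - p)
    H <- matrix(c(sum(w * f * f), sum(w * f), sum(w * f), sum(w)), 2) +
      diag(1e-12, 2)
    step <- solve(H, g)
    lambda <- 1
    repeat {
      a2 <- a - lambda * step[1]; b2 <- b - lambda * step[2]
      v <- obj(a2, b2)
      if (v <= best + 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    moved <- abs(a2 - a) + abs(b2 - b)
    a <- a2; b <- b2; best <- v
    if (moved < 1e-12 || sum(abs(g)) < 1e-10) break
  }
  c(a = a, b = b)
}

#' Node probability and reliability
#'
#' `platt_probability()` maps a decision value through the node's fitted
#' sigmoid to `P(class A | f)`; `node_reliability()` converts a
#' probability into the node's reliability `max(p, 1 - p)`, which lies in
#' `[0.5, 1]` and belongs to whichever child the decision selects.
#'
#' @param node_model A calibrated `hierloc_node_model`.
#' @param f Decision value(s).
#' @return Probabilities in (0, 1), or reliabilities in `[0.5, 1]`.
#' @export
platt_probability <- function(node_model, f) {
  if (!is.finite(node_model$platt_a)) {
    stop("node '", node_model$node_id, "' is not calibrated", call. = FALSE)
  }
  1 / (1 + exp(node_model$platt_a * f + node_model$platt_b))
}

#' @rdname platt_probability
#' @param p Probability in (0, 1).
#' @export
node_reliability <- function(p) {
  pmax(p, 1 - p)
}

# stratified fold labels for the Platt inner CV: each side dealt
# round-robin after a seeded shuffle
platt_folds <- function(is_a, n_folds, seed) {
  fold <- integer(length(is_a))
  with_seed(seed, {
    for (side in c(TRUE, FALSE)) {
      idx <- sample(which(is_a == side))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Train the full hierarchy of node SVMs
#'
#' Trains one binary SVM per internal node of the topology on the
#' precomputed profile-kernel matrix, then calibrates each node with Platt
#' scaling. Calibration decision values come from an internal stratified
#' cross-validation at the node (default 3 folds), so the sigmoid is not
#' fitted on the scores of the proteins the final SVM was trained on.
#'
#' @param data Data frame with columns `id`, `class` and `profile` (a list
#'   column of [sequence_profile()] objects).
#' @param topology A `hierloc_topology`; every `class` must be one of its
#'   leaves.
#' @param params [kernel_params()].
#' @param regularization_c Global soft-margin cost C (default 1);
#'   a named vector supplies per-node overrides.
#' @param platt_cv_folds Folds for the internal calibration CV; values
#'   below 2 fall back to calibrating on training decision values.
#' @param seed Seed for the internal calibration folds.
#' @param gram Optional precomputed `hierloc_kernel_matrix` over
#'   `data$id` (computed if missing).
#' @return An object of class `hierloc_model`: list with `topology`,
#'   `params`, `node_models`, `train` (id/class tibble), `profiles`
#'   (named list) and `self_k` (unnormalized self-kernels).
#' @export
train_tree <- function(data, topology, params = kernel_params(),
                       regularization_c = 1, platt_cv_folds = 3L,
                       seed = 1L, gram = NULL) {
  stopifnot(inherits(topology, "hierloc_topology"),
            all(c("id", "class", "profile") %in% names(data)))
  labeled <- tibble::tibble(id = data$id, class = data$class)
  profiles <- stats::setNames(data$profile, data$id)
  unknown <- setdiff(unique(labeled$class), topology$leaves)
  if (length(unknown) > 0L) {
    stop("label(s) not in topology: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # every side of every decision needs at least 2 proteins, checked before
  # any SVM call
  splits <- list()
  for (nd in topology$internal) {
    ds <- assemble_node_dataset(topology, nd, labeled)
    if (length(ds$a_ids) < 2L || length(ds$b_ids) < 2L) {
      stop("node '", nd, "' has a side with fewer than 2 training proteins",
           call. = FALSE)
    }
    splits[[nd]] <- ds
  }
  if (is.null(gram)) {
    gram <- kernel_matrix(profiles, params)
  } else {
    stopifnot(inherits(gram, "hierloc_kernel_matrix"))
    if (!all(labeled$id %in% gram$ids)) {
      stop("precomputed gram does not cover all training ids", call. = FALSE)
    }
  }
  c_for <- function(nd) {
    if (length(regularization_c) > 1L && nd %in% names(regularization_c)) {
      regularization_c[[nd]]
    } else unname(regularization_c[1])
  }

  node_models <- list()
  for (nd in topology$internal) {
    ds <- splits[[nd]]
    ids <- c(ds$a_ids, ds$b_ids)
    is_a <- c(rep(TRUE, length(ds$a_ids)), rep(FALSE, length(ds$b_ids)))
    nm <- train_node(gram, ds$a_ids, ds$b_ids, c_for(nd), node_id = nd)

    n_eff <- min(platt_cv_folds, length(ds$a_ids), length(ds$b_ids))
    if (n_eff >= 2L) {
      fold <- platt_folds(is_a, n_eff, seed + match(nd, topology$internal))
      fcal <- numeric(length(ids)); ycal <- is_a
      for (fd in seq_len(n_eff)) {
        tr <- fold != fd
        sub <- train_node(gram, ids[tr & is_a], ids[tr & !is_a],
                          c_for(nd), node_id = nd)
        fcal[fold == fd] <-
          decision_values(sub, sub_kernel(gram, sub$support_ids,
                                          ids[fold == fd]))
      }
    } else {
      fcal <- decision_values(nm, sub_kernel(gram, nm$support_ids, ids))
      ycal <- is_a
    }
    ab <- fit_platt(fcal, ycal)
    nm$platt_a <- ab[["a"]]; nm$platt_b <- ab[["b"]]
    node_models[[nd]] <- nm
  }
  structure(
    list(topology = topology, params = params, node_models = node_models,
         train = labeled, profiles = profiles,
         self_k = gram$self[labeled$id]),
    class = "hierloc_model"
  )
}

#' @export
print.hierloc_model <- function(x, ...) {
  cat("<hierloc_model> ", x$topology$domain, " tree: ",
      length(x$node_models), " calibrated decision nodes, ",
      nrow(x$train), " training proteins, k = ", x$params$k,
      ", sigma = ", x$params$sigma, "\n", sep = "")
  invisible(x)
}
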