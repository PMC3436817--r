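#' Fragment cleavage operators
#'
#' Worst-case models of sequencing/gene-prediction errors applied to a
#' sequence profile: drop the first `n` residues, drop the last `n`
#' residues, or remove a contiguous block of `floor(length/3)` residues
#' starting at a seeded random position. Cost rows are cleaved together
#' with the sequence.
#'
#' @param profile A [sequence_profile()].
#' @param n Number of terminal residues removed (default 30).
#' @return A cleaved [sequence_profile()] (same id).
#' @export
cleave_nterm <- function(profile, n = 30L) {
  stopifnot(inherits(profile, "hierloc_profile"))
  L <- nchar(profile$sequence)
  if (L <= n) {
    stop("sequence '", profile$id, "' too short to cleave ", n,
         " N-terminal residues", call. = FALSE)
  }
  keep <- (n + 1L):L
  sequence_profile(profile$id, substr(profile$sequence, n + 1L, L),
                   profile$costs[keep, , drop = FALSE],
                   profile$row_offsets[keep])
}

#' @rdname cleave_nterm
#' @export
cleave_cterm <- function(profile, n = 30L) {
  stopifnot(inherits(profile, "hierloc_profile"))
  L <- nchar(profile$sequence)
  if (L <= n) {
    stop("sequence '", profile$id, "' too short to cleave ", n,
         " C-terminal residues", call. = FALSE)
  }
  keep <- 1L:(L - n)
  sequence_profile(profile$id, substr(profile$sequence, 1L, L - n),
                   profile$costs[keep, , drop = FALSE],
                   profile$row_offsets[keep])
}

#' @rdname cleave_nterm
#' @param seed RNG seed choosing the cleaved block's position.
#' @export
cleave_random_third <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "hierloc_profile"))
  L <- nchar(profile$sequence)
  if (L < 3L) {
    stop("sequence '", profile$id, "' shorter than 3 residues",
         call. = FALSE)
  }
  m <- L %/% 3L
  start <- with_seed(seed, sample.int(L - m + 1L, 1L))
  keep <- setdiff(seq_len(L), start:(start + m - 1L))
  sequence_profile(profile$id,
                   paste(strsplit(profile$sequence, "")[[1]][keep],
                         collapse = ""),
                   profile$costs[keep, , drop = FALSE],
                   profile$row_offsets[keep])
}

cleave_dataset <- function(data, mode, n = 30L, seed = 1L) {
  out <- data
  keep <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(data))) {
    p <- data$profile[[i]]
    frag <- tryCatch(switch(mode,
      intact = p,
      nterm = cleave_nterm(p, n),
      cterm = cleave_cterm(p, n),
      random = cleave_random_third(p, seed + i)),
      error = function(e) NULL)
    if (is.null(frag) || nchar(frag$sequence) < 1L) {
      keep[i] <- FALSE
    } else {
      out$profile[[i]] <- frag
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " protein(s) skipped in '", mode,
            "' cleavage (too short)", call. = FALSE)
  }
  out[keep, ]
}

#' Fragment-robustness benchmark
#'
#' Runs the same prediction pipeline on intact proteins and on their
#' N-cleaved, C-cleaved and randomly cleaved fragments, reporting the
#' overall Qn and per-class metrics for each cleavage model. Proteins too
#' short to cleave (or whose fragment drops below the k-mer length) are
#' skipped with a warning.
#'
#' @param model A trained `hierloc_model`.
#' @param data Labeled data frame (`id`, `class`, `profile`) to predict.
#' @param n_term Residues removed by the terminal cleavages (default 30).
#' @param seed Seed for the random-third cleavage positions.
#' @param class_subset Classes entering Qn (default: the topology's
#'   leaves present in `data`).
#' @return An object of class `hierloc_fragments`: list with `summary`
#'   (tibble: `variant`, `n`, `qn`), `metrics` (per-variant per-class
#'   tibble) and `predictions`.
#' @export
fragment_benchmark <- function(model, data, n_term = 30L, seed = 1L,
                               class_subset = NULL) {
  stopifnot(inherits(model, "hierloc_model"),
            all(c("id", "class", "profile") %in% names(data)))
  if (is.null(class_subset)) {
    class_subset <- intersect(model$topology$leaves, unique(data$class))
  }
  variants <- c("intact", "nterm", "cterm", "random")
  summaries <- list(); metrics <- list(); predictions <- list()
  for (v in variants) {
    dv <- cleave_dataset(data, v, n_term, seed)
    dv <- dv[vapply(dv$profile,
                    function(p) nchar(p$sequence) >= model$params$k,
                    logical(1)), ]
    pr <- predict(model, dv)
    cm <- confusion_matrix(dv$class[match(pr$id, dv$id)],
                           pr$predicted_class,
                           classes = model$topology$leaves)
    summaries[[v]] <- tibble::tibble(
      variant = v, n = nrow(pr), qn = overall_q(cm, class_subset))
    mt <- class_metrics(cm)
    mt <- mt[mt$class %in% class_subset, ]
    metrics[[v]] <- dplyr::mutate(mt, variant = v, .before = 1)
    predictions[[v]] <- dplyr::mutate(
      tibble::tibble(id = pr$id,
                     observed = dv$class[match(pr$id, dv$id)],
                     predicted = pr$predicted_class, ri = pr$ri),
      variant = v, .before = 1)
  }
  structure(
    list(summary = dplyr::bind_rows(summaries),
         metrics = dplyr::bind_rows(metrics),
         predictions = dplyr::bind_rows(predictions)),
    class = "hierloc_fragments"
  )
}

#' @export
print.hierloc_fragments <- function(x, ...) {
  cat("<hierloc_fragments>\n")
  print(x$summary)
  invisible(x)
}
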