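#' Specification for a synthetic labeled sequence-profile set
#'
#' The generator emulates the structure the classifier exploits: each
#' localization class carries a short class-specific motif (a stand-in for
#' a sorting signal) inserted into random background sequence, and each
#' sequence comes with a one-hot-derived cost profile perturbed by
#' additive noise. Auto-generated motifs are pairwise distinct at Hamming
#' distance at least `ceiling(motif_length / 2)`.
#'
#' @param topology A `hierloc_topology` naming the classes.
#' @param motif_length Motif length in residues (default 5, within the
#'   ~5-35 residue range of known sorting signals).
#' @param motifs Optional named character vector class -> motif.
#' @param motif_copies Motif insertions per sequence (default 3).
#' @param seq_length Sequence length (default 120).
#' @param n_per_class Sequences per class (default 50).
#' @param background Residue frequency vector over [aa_alphabet()]
#'   (default uniform); must sum to 1.
#' @param profile_noise Standard deviation of the additive cost jitter
#'   (default 0 = clean one-hot profiles).
#' @param motif_placement Where motifs go: `"nterm"` (within the first 35
#'   residues), `"cterm"` (last 35) or `"uniform"` (anywhere).
#' @param mismatch_cost Cost of a non-observed residue in the clean
#'   profile (default 4).
#' @param seed RNG seed; generation is fully deterministic for a fixed
#'   specification object.
#' @return An object of class `hierloc_synth_spec`.
#' @export
synthetic_spec <- function(topology, motif_length = 5L, motifs = NULL,
                           motif_copies = 3L, seq_length = 120L,
                           n_per_class = 50L, background = NULL,
                           profile_noise = 0, motif_placement = "uniform",
                           mismatch_cost = 4, seed = 1L) {
  stopifnot(inherits(topology, "hierloc_topology"),
            motif_length >= 1L, motif_length <= seq_length,
            motif_copies >= 0L, n_per_class >= 0L, profile_noise >= 0)
  motif_placement <- match.arg(motif_placement,
                               c("uniform", "nterm", "cterm"))
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), aa_alphabet())
  }
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-9)
  if (!is.null(motifs)) {
    stopifnot(setequal(names(motifs), topology$leaves),
              all(nchar(motifs) == motif_length))
    check_motif_separation(motifs, motif_length)
  }
  structure(
    list(topology = topology, motif_length = as.integer(motif_length),
         motifs = motifs, motif_copies = as.integer(motif_copies),
         seq_length = as.integer(seq_length),
         n_per_class = as.integer(n_per_class), background = background,
         profile_noise = profile_noise, motif_placement = motif_placement,
         mismatch_cost = mismatch_cost, seed = as.integer(seed)),
    class = "hierloc_synth_spec"
  )
}

min_motif_separation <- function(motif_length) ceiling(motif_length / 2)

check_motif_separation <- function(motifs, motif_length) {
  cls <- names(motifs)
  for (i in seq_along(cls)) for (j in seq_len(i - 1L)) {
    d <- sum(strsplit(motifs[[cls[i]]], "")[[1]] !=
             strsplit(motifs[[cls[j]]], "")[[1]])
    if (d < min_motif_separation(motif_length)) {
      stop("motifs of '", cls[i], "' and '", cls[j],
           "' are closer than Hamming distance ",
           min_motif_separation(motif_length), call. = FALSE)
    }
  }
  invisible(motifs)
}

random_motifs <- function(classes, motif_length) {
  need <- min_motif_separation(motif_length)
  for (attempt in 1:100) {
    cand <- vapply(classes, function(cl) {
      paste(sample(aa_alphabet(), motif_length, replace = TRUE),
            collapse = "")
    }, character(1))
    ok <- tryCatch({
      check_motif_separation(cand, motif_length); TRUE
    }, error = function(e) FALSE)
    if (ok) return(cand)
  }
  stop("could not generate motifs with pairwise Hamming distance >= ",
       need, " in 100 attempts", call. = FALSE)
}

# non-overlapping motif start positions within the allowed placement band
motif_starts <- function(spec) {
  L <- spec$seq_length; ml <- spec$motif_length
  band <- switch(spec$motif_placement,
    uniform = c(1L, L - ml + 1L),
    nterm = c(1L, min(35L, L) - ml + 1L),
    cterm = c(max(1L, L - 35L + 1L), L - ml + 1L))
  starts <- integer(0)
  avail <- band[1]:band[2]
  for (cp in seq_len(spec$motif_copies)) {
    avail <- setdiff(avail, unlist(lapply(starts, function(s)
      (s - ml + 1L):(s + ml - 1L))))
    if (length(avail) == 0L) break
    s <- if (length(avail) == 1L) avail else sample(avail, 1L)
    starts <- c(starts, s)
  }
  sort(starts)
}

#' Generate a labeled synthetic sequence-profile dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `id`, `class`, `sequence` and `profile`
#'   (list of [sequence_profile()]); byte-identical across runs for a
#'   fixed spec.
#' @export
#' @examples
#' spec <- synthetic_spec(default_topology("archaea"), n_per_class = 3)
#' generate_dataset(spec)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "hierloc_synth_spec"))
  classes <- spec$topology$leaves
  with_seed(spec$seed, {
    motifs <- spec$motifs
    if (is.null(motifs) && spec$motif_copies > 0L) {
      motifs <- random_motifs(classes, spec$motif_length)
    }
    rows <- list()
    for (cl in classes) {
      for (r in seq_len(spec$n_per_class)) {
        chars <- sample(aa_alphabet(), spec$seq_length, replace = TRUE,
                        prob = spec$background)
        if (spec$motif_copies > 0L) {
          mchars <- strsplit(motifs[[cl]], "")[[1]]
          for (s in motif_starts(spec)) {
            chars[s:(s + spec$motif_length - 1L)] <- mchars
          }
        }
        seqstr <- paste(chars, collapse = "")
        costs <- one_hot_costs(seqstr, spec$mismatch_cost)
        if (spec$profile_noise > 0) {
          costs <- costs + matrix(
            abs(stats::rnorm(length(costs), sd = spec$profile_noise)),
            nrow = nrow(costs))
        }
        id <- sprintf("%s_%03d", cl, r)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = id, class = cl, sequence = seqstr,
          profile = list(sequence_profile(id, seqstr, costs)))
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "motifs") <- motifs
    out
  })
}

#' Permute the class labels of a dataset (null model)
#'
#' Sequences and profiles are untouched; the label multiset is preserved.
#'
#' @param data A dataset tibble with a `class` column.
#' @param seed RNG seed.
#' @return The dataset with permuted `class`.
#' @export
shuffle_labels <- function(data, seed = 1L) {
  stopifnot("class" %in% names(data), nrow(data) > 0L)
  out <- data
  out$class <- with_seed(seed, sample(data$class))
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `sequences.fasta`, `labels.tsv` (id, class) and one profile TSV
#' per protein under `profiles/`.
#'
#' @param data Dataset tibble from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  writeLines(unlist(lapply(seq_len(nrow(data)), function(i) {
    c(paste0(">", data$id[i]), data$sequence[i])
  })), file.path(dir, "sequences.fasta"))
  utils::write.table(data[, c("id", "class")],
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(data))) {
    write_profile_tsv(data$profile[[i]],
                      file.path(dir, "profiles", paste0(data$id[i], ".tsv")))
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A dataset tibble (`id`, `class`, `sequence`, `profile`).
#' @export
read_dataset <- function(dir) {
  labels <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  fa <- read_fasta(file.path(dir, "sequences.fasta"))
  profs <- lapply(labels$id, function(id) {
    read_profile_tsv(file.path(dir, "profiles", paste0(id, ".tsv")), id = id)
  })
  tibble::tibble(id = labels$id, class = labels$class,
                 sequence = fa$sequence[match(labels$id, fa$id)],
                 profile = profs)
}
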