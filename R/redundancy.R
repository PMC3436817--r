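#' Redundancy-reduction configuration
#'
#' Two proteins count as redundant when their alignment is at least
#' `min_alignment_length` residues long (about the maximal length of known
#' localization signals) and either the length-dependent identity
#' threshold is exceeded (`hval > hval_max`) or the alignment E-value,
#' when available, is at most `eval_max`.
#'
#' @param hval_max HVAL threshold (default 0).
#' @param eval_max E-value threshold (default 1e-3).
#' @param min_alignment_length Minimum alignment length in residues
#'   (default 35).
#' @return An object of class `hierloc_redundancy_config`.
#' @export
redundancy_config <- function(hval_max = 0, eval_max = 1e-3,
                              min_alignment_length = 35L) {
  stopifnot(min_alignment_length >= 1L)
  structure(list(hval_max = hval_max, eval_max = eval_max,
                 min_alignment_length = as.integer(min_alignment_length)),
            class = "hierloc_redundancy_config")
}

# 480 * L^(-0.32 * (1 + exp(-L/1000))): the length-dependent decay of the
# twilight-zone identity curve
hssp_raw <- function(alignment_length) {
  480 * alignment_length^(-0.32 * (1 + exp(-alignment_length / 1000)))
}

# offset anchoring the asymptote at exactly 20% identity for alignments
# of >= 250 residues
hssp_offset <- function() hssp_raw(250) - 20

#' Length-dependent percent-identity threshold (HSSP curve)
#'
#' The maximal percent identity two unrelated proteins are expected to
#' reach by chance, as a function of alignment length: 100% for very
#' short alignments, decaying as `480 * L^(-0.32 * (1 + exp(-L/1000)))`
#' (shifted so the curve reaches its floor of 20% at 250 aligned
#' residues and stays there). `hval` is the observed identity minus this
#' threshold; `hval > 0` marks a pair as likely homologous.
#'
#' @param alignment_length Alignment length(s) in residues (>= 1).
#' @return Percent-identity threshold(s) in `[20, 100]`, monotone
#'   non-increasing in length.
#' @export
#' @examples
#' hssp_threshold(c(20, 100, 250, 450))
hssp_threshold <- function(alignment_length) {
  stopifnot(all(alignment_length >= 1))
  # the decay formula describes the twilight zone only up to its floor;
  # from 250 residues on the threshold is the 20% asymptote
  ifelse(alignment_length >= 250, 20,
         pmin(100, pmax(20, hssp_raw(alignment_length) - hssp_offset())))
}

#' @rdname hssp_threshold
#' @param percent_identity Observed percent identity in `[0, 100]`.
#' @export
hval <- function(percent_identity, alignment_length) {
  percent_identity - hssp_threshold(alignment_length)
}

#' Is a protein pair redundant?
#'
#' @param pair A one-row data frame (or list) with `percent_identity`,
#'   `alignment_length` and optionally `evalue` (NA = not available).
#' @param config A [redundancy_config()].
#' @return Logical.
#' @export
is_redundant <- function(pair, config = redundancy_config()) {
  if (pair$alignment_length < config$min_alignment_length) return(FALSE)
  if (hval(pair$percent_identity, pair$alignment_length) > config$hval_max) {
    return(TRUE)
  }
  ev <- pair$evalue
  !is.null(ev) && !is.na(ev) && ev <= config$eval_max
}

#' Greedy sequence-unique set selection
#'
#' Builds the redundancy graph from the pairwise statistics and
#' iteratively drops the protein with the most unresolved redundant
#' partners until no redundant pair remains. Ties are broken by dropping
#' the shorter sequence, then the lexicographically later id, making the
#' result deterministic and invariant to input order. Pairs absent from
#' `pairs` are treated as non-redundant.
#'
#' @param proteins Data frame with columns `id` and `sequence` (sequence
#'   lengths feed the tie-break; a `length` column may replace
#'   `sequence`).
#' @param pairs Data frame of pairwise stats: `id1`, `id2`,
#'   `percent_identity`, `alignment_length`, optional `evalue`.
#' @param config A [redundancy_config()].
#' @return Character vector of retained ids, in the input order of
#'   `proteins`.
#' @export
unique_set <- function(proteins, pairs, config = redundancy_config()) {
  stopifnot("id" %in% names(proteins))
  ids <- proteins$id
  len <- if ("length" %in% names(proteins)) {
    proteins$length
  } else {
    nchar(proteins$sequence)
  }
  names(len) <- ids
  adj <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(pairs) > 0L) {
    if (!"evalue" %in% names(pairs)) pairs$evalue <- NA_real_
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, ]
      if (!p$id1 %in% ids || !p$id2 %in% ids || p$id1 == p$id2) next
      if (is_redundant(p, config)) {
        adj[[p$id1]] <- union(adj[[p$id1]], p$id2)
        adj[[p$id2]] <- union(adj[[p$id2]], p$id1)
      }
    }
  }
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  repeat {
    deg <- vapply(ids, function(i) {
      if (!alive[i]) return(0L)
      length(intersect(adj[[i]], ids[alive]))
    }, integer(1))
    if (max(deg) == 0L) break
    cand <- ids[deg == max(deg)]
    if (length(cand) > 1L) {
      cand <- cand[len[cand] == min(len[cand])]
      cand <- sort(cand, decreasing = TRUE)[1]
    }
    alive[cand] <- FALSE
  }
  ids[alive[ids]]
}

#' Pairwise percent identity from a local alignment
#'
#' Smith-Waterman local alignment with affine gaps (BLOSUM62,
#' configurable penalties); identity is the fraction of identical aligned
#' positions over the alignment length (gap columns included).
#'
#' @param id1,id2 Protein ids.
#' @param seq1,seq2 Amino-acid strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param substitution_matrix Scoring matrix name (default "BLOSUM62").
#' @return One-row tibble: `id1`, `id2`, `percent_identity`,
#'   `alignment_length`, `evalue` (`NA`; supply externally computed
#'   E-values if available).
#' @export
percent_identity <- function(id1, id2, seq1, seq2, gap_opening = 10,
                             gap_extension = 0.5,
                             substitution_matrix = "BLOSUM62") {
  stopifnot(nzchar(seq1), nzchar(seq2))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  alen <- Biostrings::nchar(al)
  tibble::tibble(
    id1 = id1, id2 = id2,
    percent_identity = if (alen == 0) 0 else
      100 * Biostrings::nmatch(al) / alen,
    alignment_length = as.integer(alen),
    evalue = NA_real_)
}

#' All-vs-all identity statistics for a protein table
#'
#' @param proteins Data frame with columns `id` and `sequence`.
#' @param ... Passed to [percent_identity()].
#' @return Tibble of pairwise stats for all unordered pairs.
#' @export
pairwise_identity <- function(proteins, ...) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  n <- nrow(proteins)
  out <- list()
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      out[[length(out) + 1L]] <- percent_identity(
        proteins$id[i], proteins$id[j],
        proteins$sequence[i], proteins$sequence[j], ...)
    }
  }
  dplyr::bind_rows(out)
}

#' Read pairwise hits in BLAST tabular (outfmt 6) layout
#'
#' Consumes the first 12 standard columns and keeps query id, subject id,
#' percent identity, alignment length and E-value.
#'
#' @param path Path to a tab-separated hits file (no header).
#' @return Tibble with columns `id1`, `id2`, `percent_identity`,
#'   `alignment_length`, `evalue`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 11L) {
    stop("expected BLAST tabular columns (qid sid pident length ... evalue)",
         call. = FALSE)
  }
  tibble::tibble(id1 = as.character(df[[1]]), id2 = as.character(df[[2]]),
                 percent_identity = as.numeric(df[[3]]),
                 alignment_length = as.integer(df[[4]]),
                 evalue = as.numeric(df[[11]]))
}
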