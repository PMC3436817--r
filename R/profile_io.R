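#' Sequence profile: a protein plus its per-position residue costs
#'
#' The kernel's substrate. A profile couples a protein sequence with an
#' `L x 20` matrix of non-negative substitution costs, one row per sequence
#' position, columns ordered as [aa_alphabet()]. Smaller cost means the
#' residue is more compatible with the position; every row is shifted so its
#' minimum is exactly 0.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid string (20-letter alphabet plus `X`).
#' @param costs Numeric matrix, `nchar(sequence)` rows by 20 columns.
#'   Column names, if present, must be a permutation of [aa_alphabet()] and
#'   are used to reorder the columns canonically.
#' @param row_offsets Optional numeric vector (one per position) recording
#'   the per-row maximum of the original log-odds scores, so that PSSMs can
#'   be written back exactly (`score = offset - cost`).
#'
#' @return An object of class `hierloc_profile`: a list with elements `id`,
#'   `sequence`, `costs` (row-min-normalised) and `row_offsets`.
#' @export
#' @examples
#' p <- sequence_profile("p1", "MKV", one_hot_costs("MKV"))
#' p$costs["1", "M"]
sequence_profile <- function(id, sequence, costs, row_offsets = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("sequence must have length >= 1", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c(aa_alphabet(), "X"))
  if (length(bad) > 0L) {
    stop("sequence of '", id, "' contains letters outside the alphabet: ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  costs <- as.matrix(costs)
  if (nrow(costs) != n || ncol(costs) != 20L) {
    stop("costs must be ", n, " x 20 for '", id, "'", call. = FALSE)
  }
  if (!is.null(colnames(costs))) {
    if (!setequal(colnames(costs), aa_alphabet())) {
      stop("cost columns must name the 20 standard residues", call. = FALSE)
    }
    costs <- costs[, aa_alphabet(), drop = FALSE]
  } else {
    colnames(costs) <- aa_alphabet()
  }
  if (any(!is.finite(costs))) stop("costs must be finite", call. = FALSE)
  mins <- apply(costs, 1L, min)
  costs <- costs - mins
  if (is.null(row_offsets)) row_offsets <- rep(0, n)
  rownames(costs) <- as.character(seq_len(n))
  structure(
    list(id = id, sequence = sequence, costs = costs,
         row_offsets = as.numeric(row_offsets)),
    class = "hierloc_profile"
  )
}

#' @export
print.hierloc_profile <- function(x, ...) {
  cat("<hierloc_profile> ", x$id, ": ", nchar(x$sequence),
      " residues\n", sep = "")
  invisible(x)
}

#' One-hot cost matrix for a bare sequence
#'
#' Cost 0 for the observed residue and `mismatch_cost` for the 19 others;
#' positions holding `X` get a flat row (the mean of the 20 costs).
#'
#' @param sequence Amino-acid string.
#' @param mismatch_cost Cost charged to a non-observed residue (default 4).
#' @return Numeric matrix `nchar(sequence)` x 20.
#' @export
one_hot_costs <- function(sequence, mismatch_cost = 4) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  m <- matrix(mismatch_cost, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, aa_alphabet()))
  for (i in seq_along(chars)) {
    if (chars[i] == "X") {
      m[i, ] <- mismatch_cost * 19 / 20
    } else {
      m[i, chars[i]] <- 0
    }
  }
  m
}

#' Read a FASTA file into a protein table
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` (uppercased), one row
#'   per entry, input order preserved. Letters outside the 20-residue
#'   alphabet are mapped to `X` with a warning. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  cleaned <- vapply(seqs, function(s) {
    gsub(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), "X", s)
  }, character(1), USE.NAMES = FALSE)
  n_mapped <- sum(nchar(gsub(sprintf("[%sX]", paste(aa_alphabet(), collapse = "")),
                             "", seqs)))
  if (n_mapped > 0L) {
    warning(n_mapped, " non-standard residue letter(s) mapped to X",
            call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = cleaned)
}

#' Read a PSI-BLAST ASCII PSSM into a sequence profile
#'
#' Parses the classic ASCII layout produced by PSI-BLAST (`-Q` /
#' `-out_ascii_pssm`): a header naming 20 residue columns in PSI-BLAST
#' order, then one row per position carrying the position index, the query
#' residue and 20 integer log-odds scores. Trailing weighted-percentage and
#' information-content columns are ignored. Scores are canonicalised to
#' costs by `cost = max(score in row) - score`, so the per-row minimum cost
#' is 0 and smaller cost means more compatible.
#'
#' @param path Path to the PSSM file.
#' @param id Identifier for the resulting profile; defaults to the file
#'   name without extension.
#' @return A [sequence_profile()].
#' @export
read_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  # locate the column-header line: >= 20 single-letter tokens
  is_header <- function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    length(toks) >= 20L && all(toks[1:20] %in% aa_alphabet())
  }
  hdr <- which(vapply(lines, is_header, logical(1)))[1]
  if (is.na(hdr)) stop("not a PSI-BLAST ASCII PSSM: ", path, call. = FALSE)
  col_res <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][1:20]

  rows <- list(); res <- character(0)
  for (ln in seq(hdr + 1L, length(lines))) {
    l <- trimws(lines[ln])
    if (!nzchar(l)) next
    toks <- strsplit(l, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", toks[1])) break  # footer (K/lambda block)
    if (length(toks) < 22L) {
      stop("malformed PSSM row at line ", ln, ": expected 20 score columns",
           call. = FALSE)
    }
    sc <- suppressWarnings(as.numeric(toks[3:22]))
    if (any(is.na(sc))) {
      stop("malformed PSSM row at line ", ln, ": non-numeric score",
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- sc
    res <- c(res, toupper(toks[2]))
  }
  if (length(rows) == 0L) stop("PSSM has no position rows: ", path,
                               call. = FALSE)
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_res
  scores <- scores[, aa_alphabet(), drop = FALSE]
  offsets <- apply(scores, 1L, max)
  costs <- offsets - scores
  sequence_profile(id, paste(res, collapse = ""), costs,
                   row_offsets = offsets)
}

#' Write a sequence profile back to PSI-BLAST ASCII PSSM layout
#'
#' Inverse of [read_pssm()]: emits `score = row_offset - cost` as integers
#' in PSI-BLAST column order, so a read/write/read cycle reproduces the
#' scores exactly.
#'
#' @param profile A [sequence_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "hierloc_profile"))
  scores <- profile$row_offsets - profile$costs
  scores <- scores[, psiblast_order(), drop = FALSE]
  chars <- strsplit(profile$sequence, "")[[1]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("      ", paste(sprintf("%3s", psiblast_order()),
                                    collapse = " ")), con)
  for (i in seq_along(chars)) {
    writeLines(paste0(sprintf("%4d %s ", i, chars[i]),
                      paste(sprintf("%3d", round(scores[i, ])),
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Build a fallback profile from a bare sequence
#'
#' When no alignment-derived profile is available, position costs are taken
#' from the substitution-matrix row of the observed residue, negated and
#' shifted into non-negative costs, then blended with a flat pseudocount
#' row. `pseudocount_weight = 0` gives pure substitution costs;
#' `pseudocount_weight = 1` gives a completely flat profile.
#'
#' @param id,sequence Protein identifier and amino-acid string.
#' @param substitution_matrix Symmetric 20x20 similarity matrix with residue
#'   dimnames (default BLOSUM62 from Biostrings).
#' @param pseudocount_weight Blend weight in `[0, 1]`.
#' @return A [sequence_profile()].
#' @export
#' @examples
#' profile_from_sequence("q", "MKVL", pseudocount_weight = 0.2)
profile_from_sequence <- function(id, sequence,
                                  substitution_matrix = NULL,
                                  pseudocount_weight = 0) {
  if (pseudocount_weight < 0 || pseudocount_weight > 1) {
    stop("pseudocount_weight must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(substitution_matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution_matrix <- e$BLOSUM62
  }
  S <- substitution_matrix[aa_alphabet(), aa_alphabet()]
  if (max(abs(S - t(S))) > 1e-9) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  # per-residue cost rows: shift the similarity row so the best residue
  # costs 0 and less similar residues cost more
  cost_rows <- t(apply(S, 1L, function(r) max(r) - r))
  flat <- mean(cost_rows)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  costs <- matrix(0, nrow = length(chars), ncol = 20L,
                  dimnames = list(NULL, aa_alphabet()))
  for (i in seq_along(chars)) {
    base <- if (chars[i] == "X") colMeans(cost_rows) else cost_rows[chars[i], ]
    costs[i, ] <- (1 - pseudocount_weight) * base + pseudocount_weight * flat
  }
  sequence_profile(id, sequence, costs)
}

#' Serialize sequence profiles to/from a TSV dialect
#'
#' Plain-text interchange format: columns `pos`, `residue`, then the 20
#' cost columns in canonical alphabet order.
#'
#' @param profile A [sequence_profile()].
#' @param path File path.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a [sequence_profile()].
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "hierloc_profile"))
  df <- data.frame(pos = seq_len(nchar(profile$sequence)),
                   residue = strsplit(profile$sequence, "")[[1]],
                   profile$costs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param id Identifier for the profile read back (defaults to file name).
#' @export
read_profile_tsv <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (!all(aa_alphabet() %in% colnames(df))) {
    stop("profile TSV must carry the 20 residue cost columns", call. = FALSE)
  }
  sequence_profile(id, paste(df$residue, collapse = ""),
                   as.matrix(df[, aa_alphabet()]))
}
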