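#' Profile-kernel parameters
#'
#' @param k k-mer length (>= 1). Default 5, on the order of the shortest
#'   sorting-signal motifs.
#' @param sigma Strictly positive score threshold: a k-mer belongs to a
#'   window's neighborhood when the window's cumulative substitution cost is
#'   strictly below `sigma`.
#' @param normalize Cosine-normalize Gram matrices (default `TRUE`), which
#'   removes the dependence on sequence length.
#' @return An object of class `hierloc_kernel_params`.
#' @export
kernel_params <- function(k = 5L, sigma = 7.5, normalize = TRUE) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L, length(sigma) == 1L, sigma > 0,
            is.logical(normalize), length(normalize) == 1L)
  structure(list(k = k, sigma = sigma, normalize = normalize),
            class = "hierloc_kernel_params")
}

#' @export
print.hierloc_kernel_params <- function(x, ...) {
  cat("<kernel params> k =", x$k, " sigma =", x$sigma,
      " normalize =", x$normalize, "\n")
  invisible(x)
}

check_profiles <- function(profiles, k, what = "profiles") {
  if (length(profiles) == 0L) stop("empty profile list", call. = FALSE)
  ok <- vapply(profiles, inherits, logical(1), "hierloc_profile")
  if (!all(ok)) stop(what, " must be hierloc_profile objects", call. = FALSE)
  short <- vapply(profiles, function(p) nchar(p$sequence) < k, logical(1))
  if (any(short)) {
    stop("sequence(s) shorter than k = ", k, ": ",
         paste(vapply(profiles[short], `[[`, "", "id"), collapse = ", "),
         call. = FALSE)
  }
  invisible(profiles)
}

profile_ids <- function(profiles) {
  vapply(profiles, `[[`, character(1), "id")
}

#' Cumulative substitution cost of a k-mer against a profile window
#'
#' The cost of matching `kmer` at window `start` is the sum of the
#' per-position costs of the k-mer's residues; a k-mer counts as present in
#' the window when this cost falls strictly below the threshold `sigma`.
#'
#' @param profile A [sequence_profile()].
#' @param start 0-based window start.
#' @param kmer k-mer string over the 20-letter alphabet.
#' @return Non-negative numeric cost.
#' @export
window_cost <- function(profile, start, kmer) {
  stopifnot(inherits(profile, "hierloc_profile"))
  k <- nchar(kmer)
  if (k < 1L) stop("kmer must be non-empty", call. = FALSE)
  if (start < 0 || start + k > nchar(profile$sequence)) {
    stop("window [", start, ", ", start + k, ") out of range for '",
         profile$id, "'", call. = FALSE)
  }
  letters_k <- strsplit(toupper(kmer), "")[[1]]
  if (!all(letters_k %in% aa_alphabet())) {
    stop("kmer contains letters outside the 20-residue alphabet",
         call. = FALSE)
  }
  sum(profile$costs[cbind(start + seq_len(k), match(letters_k, aa_alphabet()))])
}

# enumerate, for one window, all k-mers with accumulated cost < sigma,
# by depth-first recursion with the same monotone pruning as the trie
enumerate_window <- function(cost_rows, sigma) {
  k <- nrow(cost_rows)
  out <- character(0)
  recurse <- function(depth, prefix, acc) {
    row <- cost_rows[depth, ]
    for (j in which(acc + row < sigma)) {
      nxt <- paste0(prefix, aa_alphabet()[j])
      if (depth == k) out[[length(out) + 1L]] <<- nxt
      else recurse(depth + 1L, nxt, acc + row[j])
    }
  }
  recurse(1L, "", 0)
  out
}

#' k-mer feature vector of a profile (brute-force enumeration)
#'
#' Maps a sequence profile into the space indexed by all 20^k k-mers:
#' entry beta counts the windows whose cumulative cost against beta is
#' strictly below `sigma`. This is the direct, enumeration-based route; the
#' trie traversal in [kernel_matrix()] computes the same inner products
#' without materialising the vectors.
#'
#' @param profile A [sequence_profile()].
#' @param params [kernel_params()].
#' @return Named integer vector of k-mer counts (only nonzero entries).
#' @export
kmer_features <- function(profile, params = kernel_params()) {
  stopifnot(inherits(profile, "hierloc_profile"))
  L <- nchar(profile$sequence)
  if (L < params$k) {
    warning("sequence '", profile$id, "' shorter than k; empty feature vector",
            call. = FALSE)
    return(integer(0))
  }
  kmers <- character(0)
  for (start in 0:(L - params$k)) {
    rows <- profile$costs[start + seq_len(params$k), , drop = FALSE]
    kmers <- c(kmers, enumerate_window(rows, params$sigma))
  }
  if (length(kmers) == 0L) return(integer(0))
  tab <- table(kmers)
  stats::setNames(as.integer(tab), names(tab))
}

#' Profile kernel between two sequence profiles (oracle route)
#'
#' Dot product of the two k-mer feature vectors, computed by explicit
#' enumeration via [kmer_features()]. Symmetric in its arguments. With
#' `params$normalize` the value is cosine-normalized, 0/0 defined as 0.
#'
#' @param p1,p2 [sequence_profile()] objects.
#' @param params [kernel_params()].
#' @return Numeric kernel value.
#' @export
profile_kernel <- function(p1, p2, params = kernel_params()) {
  v1 <- kmer_features(p1, params)
  v2 <- kmer_features(p2, params)
  common <- intersect(names(v1), names(v2))
  raw <- sum(as.numeric(v1[common]) * as.numeric(v2[common]))
  if (!params$normalize) return(raw)
  s1 <- sum(as.numeric(v1)^2); s2 <- sum(as.numeric(v2)^2)
  if (s1 == 0 || s2 == 0) return(0)
  raw / sqrt(s1 * s2)
}

cosine_normalize <- function(K, d1 = diag(K), d2 = d1) {
  den <- sqrt(outer(d1, d2))
  out <- K / den
  out[den == 0] <- 0
  out
}

#' Full kernel matrix by pruned trie traversal
#'
#' Computes the symmetric Gram matrix of the profile kernel over a protein
#' set in a single depth-first traversal of the k-mer trie. Each trie node
#' carries the (protein, window, accumulated cost) triples still alive for
#' its prefix; triples at or above the threshold are pruned, and at depth-k
#' leaves the surviving per-protein window counts are multiplied pairwise.
#' Identical to the matrix of pairwise [profile_kernel()] calls.
#'
#' @param profiles List of [sequence_profile()] objects.
#' @param params [kernel_params()].
#' @return An object of class `hierloc_kernel_matrix`: list with `ids`,
#'   `values` (named symmetric matrix, cosine-normalized when requested),
#'   `self` (unnormalized diagonal) and `params`.
#' @export
kernel_matrix <- function(profiles, params = kernel_params()) {
  check_profiles(profiles, params$k)
  ids <- profile_ids(profiles)
  if (anyDuplicated(ids)) {
    stop("duplicate profile ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  K <- pk_gram_cpp(lapply(profiles, `[[`, "costs"), params$k, params$sigma)
  self <- diag(K)
  if (params$normalize) K <- cosine_normalize(K)
  dimnames(K) <- list(ids, ids)
  structure(list(ids = ids, values = K, self = stats::setNames(self, ids),
                 params = params),
            class = "hierloc_kernel_matrix")
}

#' @export
print.hierloc_kernel_matrix <- function(x, ...) {
  cat("<kernel matrix> ", length(x$ids), " proteins, k = ", x$params$k,
      ", sigma = ", x$params$sigma,
      if (x$params$normalize) ", cosine-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Cross-kernel block between two profile sets
#'
#' Kernel values between every profile in `rows` and every profile in
#' `cols`, by the same pruned trie traversal as [kernel_matrix()].
#'
#' @param rows,cols Lists of [sequence_profile()] objects.
#' @param params [kernel_params()].
#' @return Numeric matrix `length(rows)` x `length(cols)` with id dimnames.
#' @export
kernel_cross <- function(rows, cols, params = kernel_params()) {
  check_profiles(rows, params$k, "rows")
  check_profiles(cols, params$k, "cols")
  K <- pk_cross_cpp(lapply(rows, `[[`, "costs"),
                    lapply(cols, `[[`, "costs"),
                    params$k, params$sigma)
  if (params$normalize) {
    dr <- pk_self_cpp(lapply(rows, `[[`, "costs"), params$k, params$sigma)
    dc <- pk_self_cpp(lapply(cols, `[[`, "costs"), params$k, params$sigma)
    K <- cosine_normalize(K, dr, dc)
  }
  dimnames(K) <- list(profile_ids(rows), profile_ids(cols))
  K
}

#' Kernel row of a query against a model's profiles
#'
#' @param model_profiles List of [sequence_profile()] objects (e.g. the
#'   stored training profiles of a tree model).
#' @param query A single [sequence_profile()].
#' @param params [kernel_params()].
#' @return Named numeric vector, entry j = kernel(model_profiles[j], query).
#' @export
kernel_row <- function(model_profiles, query, params = kernel_params()) {
  drop(kernel_cross(model_profiles, list(query), params))
}

#' Serialize a kernel matrix to TSV
#'
#' Writes the ids header plus the lower triangle (including diagonal) as
#' `id_i id_j value` rows, with the kernel parameters in comment lines.
#'
#' @param km A `hierloc_kernel_matrix`.
#' @param path Output path.
#' @return `path` invisibly; `read_kernel_tsv()` returns the matrix object.
#' @export
write_kernel_tsv <- function(km, path) {
  stopifnot(inherits(km, "hierloc_kernel_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# k=%d sigma=%.10g normalize=%d", km$params$k,
                     km$params$sigma, as.integer(km$params$normalize)), con)
  writeLines(paste0("# ids\t", paste(km$ids, collapse = "\t")), con)
  writeLines(paste0("# self\t",
                    paste(sprintf("%.10g", km$self), collapse = "\t")), con)
  n <- length(km$ids)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    writeLines(sprintf("%s\t%s\t%.12g", km$ids[i], km$ids[j],
                       km$values[i, j]), con)
  }
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- stats::setNames(sub(".*=", "", hdr), sub("=.*", "", hdr))
  params <- kernel_params(as.integer(kv["k"]), as.numeric(kv["sigma"]),
                          as.integer(kv["normalize"]) == 1L)
  ids <- strsplit(lines[2], "\t")[[1]][-1]
  self <- as.numeric(strsplit(lines[3], "\t")[[1]][-1])
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (l in lines[-(1:3)]) {
    f <- strsplit(l, "\t")[[1]]
    K[f[1], f[2]] <- K[f[2], f[1]] <- as.numeric(f[3])
  }
  structure(list(ids = ids, values = K, self = stats::setNames(self, ids),
                 params = params),
            class = "hierloc_kernel_matrix")
}
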