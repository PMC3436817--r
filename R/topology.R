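#' Localization-class hierarchies
#'
#' Each domain of life gets its own rooted binary sorting tree: every leaf
#' is a localization class, every internal node a binary decision
#' (ultimately an SVM). The shipped defaults mimic the biological sorting
#' machinery: for archaea the root separates cytosolic from non-cytosolic
#' proteins (the latter splitting into extra-cellular and plasma membrane);
#' for bacteria the non-cytosolic branch follows the export pathway
#' (plasma membrane, periplasm, outer membrane, then extra-cellular vs
#' fimbrium); for eukaryota the root first separates transmembrane from
#' non-membrane proteins, and each branch then splits secreted (EXT / PM)
#' from intracellular compartments.
#'
#' Topologies are plain newick files with named internal nodes, so
#' alternative wirings are one config edit away.
#'
#' @param domain_of_life One of `"archaea"`, `"bacteria"`, `"eukaryota"`.
#' @return An object of class `hierloc_topology`: list with `domain`,
#'   `root`, `leaves`, `internal` and `children` (named list mapping each
#'   internal node to its two children, first child = class A side).
#' @export
#' @examples
#' topo <- default_topology("bacteria")
#' topo$leaves
default_topology <- function(domain_of_life) {
  domain_of_life <- match.arg(domain_of_life,
                              c("archaea", "bacteria", "eukaryota"))
  path <- system.file("extdata", "topologies",
                      paste0(domain_of_life, ".nwk"), package = "hierloc")
  read_topology(path, domain = domain_of_life)
}

#' Read a topology from a newick config file
#'
#' @param path Newick file with unique leaf labels and named internal
#'   nodes.
#' @param domain Optional domain-of-life tag (defaults to the file name).
#' @return A `hierloc_topology`.
#' @export
read_topology <- function(path, domain = NULL) {
  if (!file.exists(path)) stop("no such topology file: ", path,
                               call. = FALSE)
  if (is.null(domain)) domain <- sub("\\.[^.]*$", "", basename(path))
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse newick: ", path, call. = FALSE)
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    stop("topology must be a rooted binary tree", call. = FALSE)
  }
  ntip <- length(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf classes in topology", call. = FALSE)
  }
  if (is.null(tr$node.label) || any(!nzchar(tr$node.label)) ||
      anyDuplicated(tr$node.label)) {
    stop("every internal node needs a unique name", call. = FALSE)
  }
  node_name <- function(i) {
    if (i <= ntip) tr$tip.label[i] else tr$node.label[i - ntip]
  }
  children <- list()
  for (i in (ntip + 1L):(ntip + tr$Nnode)) {
    kids <- tr$edge[tr$edge[, 1] == i, 2]
    children[[node_name(i)]] <- vapply(kids, node_name, character(1))
  }
  structure(
    list(domain = domain,
         root = node_name(ntip + 1L),
         leaves = tr$tip.label,
         internal = tr$node.label,
         children = children),
    class = "hierloc_topology"
  )
}

#' @export
print.hierloc_topology <- function(x, ...) {
  cat("<hierloc_topology> ", x$domain, ": ", length(x$leaves),
      " classes, ", length(x$internal), " decision nodes\n", sep = "")
  cat("  leaves:", paste(x$leaves, collapse = " "), "\n")
  invisible(x)
}

is_leaf <- function(topology, node) node %in% topology$leaves

#' Leaf classes below a node
#'
#' @param topology A `hierloc_topology`.
#' @param node A node name (leaf or internal).
#' @return Character vector of leaf classes in the subtree rooted at
#'   `node`.
#' @export
leaves_under <- function(topology, node) {
  if (!(node %in% c(topology$leaves, topology$internal))) {
    stop("unknown node: ", node, call. = FALSE)
  }
  if (is_leaf(topology, node)) return(node)
  unlist(lapply(topology$children[[node]],
                function(ch) leaves_under(topology, ch)),
         use.names = FALSE)
}
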