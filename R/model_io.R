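#' Serialize a trained hierarchy model to a directory of text files
#'
#' Layout (all plain text, versioned): `topology.nwk` (newick),
#' `params.tsv` (kernel and training parameters), `train.tsv` (id,
#' class), `nodes/<node>.tsv` (one row per support vector: id, dual
#' coefficient; header comments carry bias, Platt parameters and C) and
#' `profiles/<id>.tsv` cost tables.
#'
#' @param model A `hierloc_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tree_model <- function(model, dir) {
  stopifnot(inherits(model, "hierloc_model"))
  dir.create(file.path(dir, "nodes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)
  writeLines(topology_newick(model$topology), file.path(dir, "topology.nwk"))
  p <- model$params
  utils::write.table(
    data.frame(key = c("format_version", "domain", "k", "sigma", "normalize"),
               value = c("1", model$topology$domain, p$k,
                         sprintf("%.10g", p$sigma),
                         as.integer(p$normalize))),
    file.path(dir, "params.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(id = model$train$id, class = model$train$class,
               self_k = sprintf("%.12g", model$self_k[model$train$id])),
    file.path(dir, "train.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (nm in model$node_models) {
    con <- file(file.path(dir, "nodes", paste0(nm$node_id, ".tsv")), "w")
    writeLines(sprintf("# bias=%.12g platt_a=%.12g platt_b=%.12g C=%.10g",
                       nm$bias, nm$platt_a, nm$platt_b,
                       nm$regularization_c), con)
    writeLines("id\tdual_coef", con)
    writeLines(sprintf("%s\t%.12g", nm$support_ids, nm$dual_coef), con)
    close(con)
  }
  for (id in model$train$id) {
    write_profile_tsv(model$profiles[[id]],
                      file.path(dir, "profiles", paste0(id, ".tsv")))
  }
  invisible(dir)
}

topology_newick <- function(topology) {
  emit <- function(node) {
    if (is_leaf(topology, node)) return(node)
    kids <- topology$children[[node]]
    paste0("(", emit(kids[1]), ",", emit(kids[2]), ")", node)
  }
  paste0(emit(topology$root), ";")
}

#' Read back a model written by [write_tree_model()]
#'
#' @param dir Model directory.
#' @return A `hierloc_model`.
#' @export
read_tree_model <- function(dir) {
  pv <- utils::read.table(file.path(dir, "params.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  kv <- stats::setNames(as.character(pv$value), pv$key)
  topology <- read_topology(file.path(dir, "topology.nwk"),
                            domain = kv[["domain"]])
  params <- kernel_params(as.integer(kv[["k"]]), as.numeric(kv[["sigma"]]),
                          as.integer(kv[["normalize"]]) == 1L)
  tr <- utils::read.table(file.path(dir, "train.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  profiles <- stats::setNames(lapply(tr$id, function(id) {
    read_profile_tsv(file.path(dir, "profiles", paste0(id, ".tsv")), id = id)
  }), tr$id)
  node_models <- list()
  for (f in list.files(file.path(dir, "nodes"), full.names = TRUE)) {
    node_id <- sub("\\.tsv$", "", basename(f))
    lines <- readLines(f)
    hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
    h <- stats::setNames(as.numeric(sub(".*=", "", hdr)),
                         sub("=.*", "", hdr))
    df <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    node_models[[node_id]] <- structure(
      list(node_id = node_id, support_ids = df$id,
           dual_coef = stats::setNames(df$dual_coef, df$id),
           bias = h[["bias"]], platt_a = h[["platt_a"]],
           platt_b = h[["platt_b"]], regularization_c = h[["C"]]),
      class = "hierloc_node_model")
  }
  missing <- setdiff(topology$internal, names(node_models))
  if (length(missing) > 0L) {
    stop("model directory lacks node file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(topology = topology, params = params,
         node_models = node_models[topology$internal],
         train = tibble::tibble(id = tr$id, class = tr$class),
         profiles = profiles,
         self_k = stats::setNames(as.numeric(tr$self_k), tr$id)),
    class = "hierloc_model"
  )
}
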