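# Graph export for the miRNA-target networks: GraphML (for generic graph
# tools), SIF and a plain edge TSV.

as_igraph <- function(net) {
  nodes <- data.frame(
    name = c(net$mirnas$name, net$proteins$protein_id),
    node_type = c(rep("mirna", nrow(net$mirnas)),
                  rep("protein", nrow(net$proteins))),
    direction = c(net$mirnas$direction, net$proteins$direction),
    n_predicting_mirnas = c(rep(NA_integer_, nrow(net$mirnas)),
                            net$proteins$n_predicting_mirnas),
    stringsAsFactors = FALSE)
  edges <- net$edges[, c("mirna", "protein_id", "support", "algorithms")]
  names(edges)[1:2] <- c("from", "to")
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Write a miRNA-target network to disk
#'
#' GraphML carries the node attributes (`node_type`, `direction`,
#' `n_predicting_mirnas`) and edge attributes (`support`, `algorithms`) and
#' can be re-read by any generic graph reader; SIF uses the interaction
#' label `targets`; `edge_tsv` is a plain table of miRNA, protein, support
#' count and algorithm names.
#'
#' @param net a `mir_target_network`.
#' @param path destination file.
#' @param format one of `"graphml"`, `"sif"`, `"edge_tsv"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "edge_tsv")) {
  if (!inherits(net, "mir_target_network")) stop_("net must be a mir_target_network")
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(net$edges)) {
      sprintf("%s\ttargets\t%s", net$edges$mirna, net$edges$protein_id)
    } else character(0)
    writeLines(lines, path)
  } else {
    out <- net$edges[, c("mirna", "protein_id", "support", "algorithms")]
    names(out) <- c("mirna", "protein", "n_algorithms", "algorithm_names")
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-read a GraphML network written by [write_network()]
#'
#' @param path a GraphML file.
#' @return a `mir_target_network` (the `min_support` attribute is restored
#'   as the smallest edge support present).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, "vertices")
  ed <- igraph::as_data_frame(g, "edges")
  is_mir <- vd$node_type == "mirna"
  edges <- data.frame(mirna = ed$from, protein_id = ed$to,
                      support = as.integer(ed$support),
                      algorithms = ed$algorithms, stringsAsFactors = FALSE)
  structure(list(
    mirnas = data.frame(name = vd$name[is_mir], direction = vd$direction[is_mir],
                        stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = vd$name[!is_mir],
                          direction = vd$direction[!is_mir],
                          n_predicting_mirnas = as.integer(vd$n_predicting_mirnas[!is_mir]),
                          stringsAsFactors = FALSE),
    edges = edges,
    min_support = if (nrow(edges)) min(edges$support) else NA_integer_,
    direction = NA_character_), class = "mir_target_network")
}

#' Write a crossmatch report as TSV
#'
#' One row per transfection, mirroring the published summary table's
#' columns.
#'
#' @param reports a `crossmatch_report` or a list of them.
#' @param path destination TSV.
#' @return invisibly, `path`.
#' @export
write_crossmatch <- function(reports, path) {
  if (inherits(reports, "crossmatch_report")) reports <- list(reports)
  out <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
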