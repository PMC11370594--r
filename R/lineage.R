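## Stepwise glycan-accumulation lineage graphs: a sub-DAG of the 4-cube in
## which an edge parent -> child exists only when the child's glycan set is
## the parent's plus exactly one glycan, weighted by percent co-occurrence.

#' Per-unit occurrence sets of signature codes
#'
#' A code "occurs" in a unit (spatial cluster or tumor) when at least
#' \code{threshold} of the unit's cells carry it (inclusive: exactly 5%
#' counts with the default).
#'
#' @param comp Composition data frame (from \code{\link{roi_composition}})
#'   or a unit-by-code fraction matrix.
#' @param threshold Minimum occurring fraction (default 0.05).
#' @return Named list: per unit, the character vector of occurring codes.
#' @export
occurrence_sets <- function(comp, threshold = 0.05) {
  m <- if (is.data.frame(comp)) composition_matrix(comp) else as.matrix(comp)
  apply(m >= threshold, 1, function(row) colnames(m)[row], simplify = FALSE)
}

## is `child` = `parent` plus exactly one set bit?
is_step_child <- function(parent, child) {
  pb <- strsplit(parent, "")[[1]] == "1"
  cb <- strsplit(child, "")[[1]] == "1"
  all(cb[pb]) && sum(cb) == sum(pb) + 1L
}

#' Build a stepwise-accumulation lineage graph
#'
#' Nodes are signature codes weighted by the number of units in which they
#' occur. A directed edge parent -> child exists when the child's bit set
#' equals the parent's plus exactly one glycan (Hamming distance 1, adding
#' a glycan), weighted by percent co-occurrence: the fraction of units
#' containing the child that also contain the parent. Codes occurring in no
#' unit are dropped unless \code{keep_empty}.
#'
#' @param occ Occurrence sets from \code{\link{occurrence_sets}}.
#' @param keep_empty Keep zero-occurrence codes as isolated nodes.
#' @return Object of class \code{lineage_graph}: list with \code{nodes}
#'   (code, n_units) and \code{edges} (parent, child, weight,
#'   n_child_units, n_co_units).
#' @examples
#' occ <- list(A = c("0100", "1100"), B = "1100")
#' build_lineage_graph(occ)$edges   # 0100 -> 1100 with weight 0.5
#' @export
build_lineage_graph <- function(occ, keep_empty = FALSE) {
  k <- if (length(occ) && length(occ[[1]])) nchar(occ[[1]][1]) else 4L
  cds <- all_codes(k)
  counts <- vapply(cds, function(cd)
    sum(vapply(occ, function(s) cd %in% s, TRUE)), 0L)
  nodes <- data.frame(code = cds, n_units = counts,
                      stringsAsFactors = FALSE, row.names = NULL)
  if (!keep_empty) nodes <- nodes[nodes$n_units > 0, , drop = FALSE]
  edges <- list()
  parents_ok <- if (keep_empty) cds else cds[counts > 0]
  for (child in cds[counts > 0]) {
    for (parent in parents_ok) {
      if (!is_step_child(parent, child)) next
      co <- sum(vapply(occ, function(s) child %in% s && parent %in% s, TRUE))
      edges[[length(edges) + 1L]] <-
        data.frame(parent = parent, child = child,
                   weight = co / counts[child],
                   n_child_units = counts[child], n_co_units = co,
                   stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(parent = character(0), child = character(0),
                  weight = numeric(0), n_child_units = integer(0),
                  n_co_units = integer(0))
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, level = NA_character_),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat("Lineage graph:", nrow(x$nodes), "codes,", nrow(x$edges),
      "stepwise edges\n")
  if (nrow(x$edges)) {
    e <- x$edges[order(-x$edges$weight), ]
    print(utils::head(e, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Export a lineage graph
#'
#' \code{lineage_edges} returns the edge list as a data frame;
#' \code{write_lineage_dot} writes the graph in the DOT graph-exchange
#' text format for viewers.
#'
#' @param graph A \code{lineage_graph}.
#' @param path Output file.
#' @return \code{write_lineage_dot}: the path, invisibly.
#' @export
lineage_edges <- function(graph) graph$edges

#' @rdname lineage_edges
#' @export
write_lineage_dot <- function(graph, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("digraph lineage {", con)
  with(graph$nodes, writeLines(sprintf(
    '  "%s" [label="%s (%d)"];', code, code, n_units), con))
  if (nrow(graph$edges))
    with(graph$edges, writeLines(sprintf(
      '  "%s" -> "%s" [label="%.2f"];', parent, child, weight), con))
  writeLines("}", con)
  invisible(path)
}
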