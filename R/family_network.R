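# E-value-weighted family/repeat homology networks: repeat-role assignment
# for hits, bidirectional deduplication, and weighted graph construction
# with thick/thin edge classes.

#' Assign the repeat role of a hit
#'
#' The hit-side aligned span is attributed to the repeat (N or C) containing
#' the majority of its residues; an exact tie gives role `"full"` with a tie
#' flag. Spans falling entirely outside both repeats also map to `"full"`.
#'
#' @param hit_span integer `(start, end)` of the aligned span on the hit
#'   family's chain.
#' @param hit_repeats `repeat_annotation` of the hit family.
#' @param chain_length hit chain length (for the coordinate check).
#' @return list `role` (`"N"`, `"C"` or `"full"`) and `tie` (logical).
#' @export
assign_hit_repeat <- function(hit_span, hit_repeats, chain_length = Inf) {
  stopifnot(length(hit_span) == 2L, hit_span[1] <= hit_span[2])
  if (hit_span[1] < 1L || hit_span[2] > chain_length)
    stop("aligned span outside the hit chain")
  overlap <- function(span) {
    max(0L, min(hit_span[2], span[2]) - max(hit_span[1], span[1]) + 1L)
  }
  n_ov <- overlap(hit_repeats$n_repeat)
  c_ov <- overlap(hit_repeats$c_repeat)
  if (n_ov == c_ov) {
    list(role = "full", tie = n_ov > 0L)
  } else if (n_ov > c_ov) {
    list(role = "N", tie = FALSE)
  } else {
    list(role = "C", tie = FALSE)
  }
}

#' Deduplicate bidirectional hits
#'
#' HHsearch-style searches report both directions of a pair; for every
#' unordered pair of unit ids the record with the lowest E-value is kept.
#'
#' @param hits data.frame with columns `query`, `hit`, `e_value` (other
#'   columns pass through).
#' @return deduplicated data.frame, one row per unordered pair.
#' @export
dedupe_bidirectional <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- vapply(seq_len(nrow(hits)), function(i) {
    paste(sort(c(hits$query[i], hits$hit[i])), collapse = "\r")
  }, character(1))
  keep <- vapply(split(seq_len(nrow(hits)), key), function(idx) {
    idx[which.min(hits$e_value[idx])]
  }, integer(1))
  out <- hits[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the weighted family network
#'
#' One edge per deduplicated pair with `e_value` below `e_threshold`; the
#' edge weight is `log10(e_value)` and the class is `"thick"` below
#' `thick_threshold`, `"thin"` otherwise. Declared nodes with no edge are
#' retained as isolated vertices, so loosely connected families stay
#' visible.
#'
#' @param hits deduplicated hit data.frame (`query`, `hit`, `e_value`).
#' @param nodes optional data.frame of declared nodes (`id`, optional
#'   `fold_type`, `role`); defaults to the ids present in `hits`.
#' @param e_threshold no edge at or above this E-value (default 0.1).
#' @param thick_threshold thick-edge E-value bound (default 0.001).
#' @return an `igraph` graph with vertex attributes `fold_type`, `role` and
#'   edge attributes `e_value`, `weight`, `class`.
#' @export
build_network <- function(hits, nodes = NULL, e_threshold = 0.1,
                          thick_threshold = 0.001) {
  if (nrow(hits) > 0L && any(hits$e_value <= 0))
    stop("non-positive E-value in hit table")
  edges <- hits[hits$e_value < e_threshold, , drop = FALSE]
  edges <- edges[order(edges$query, edges$hit), , drop = FALSE]
  ids <- if (is.null(nodes)) {
    sort(unique(c(hits$query, hits$hit)))
  } else nodes$id
  missing <- setdiff(unique(c(edges$query, edges$hit)), ids)
  ids <- c(ids, sort(missing))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$query, to = edges$hit),
    directed = FALSE,
    vertices = data.frame(name = ids))
  igraph::E(g)$e_value <- edges$e_value
  igraph::E(g)$weight <- log10(edges$e_value)
  igraph::E(g)$class <- ifelse(edges$e_value < thick_threshold,
                               "thick", "thin")
  if (!is.null(nodes)) {
    if (!is.null(nodes$fold_type))
      igraph::V(g)$fold_type <-
        nodes$fold_type[match(ids, nodes$id)]
    if (!is.null(nodes$role))
      igraph::V(g)$role <- nodes$role[match(ids, nodes$id)]
  }
  g
}

#' Write a family network to GraphML and an edge-list TSV
#'
#' @param g network from [build_network()].
#' @param graphml_path,edgelist_path output paths (NULL to skip either).
#' @return invisibly, the edge-list data.frame.
#' @export
write_network <- function(g, graphml_path = NULL, edgelist_path = NULL) {
  el <- igraph::as_edgelist(g)
  tab <- data.frame(from = el[, 1], to = el[, 2],
                    e_value = igraph::E(g)$e_value,
                    weight = igraph::E(g)$weight,
                    class = igraph::E(g)$class)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path))
    utils::write.table(tab, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
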