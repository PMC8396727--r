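# Evolution-guided topology annotation: project per-sequence topology
# predictions onto the seed MSA, reorder rows by the phylogenetic tree,
# detect topology-consistent subfamilies, and build consensus ("initial")
# topologies.

#' Multiple topology alignment
#'
#' Container pairing an MSA with per-row gapped topology strings, an optional
#' rooted tree over the rows, and a display row order.
#'
#' @param seq_rows named character vector of gapped sequence rows.
#' @param topo_rows named character vector of gapped per-residue topology
#'   strings, parallel to `seq_rows` (same names, same lengths, gaps in the
#'   same columns).
#' @param tree optional `ape::phylo` whose tip labels equal the row names.
#' @param row_order permutation of the row names (default storage order).
#' @return a `multiple_topology_alignment`.
#' @export
multiple_topology_alignment <- function(seq_rows, topo_rows, tree = NULL,
                                        row_order = names(seq_rows)) {
  stopifnot(!is.null(names(seq_rows)),
            identical(sort(names(seq_rows)), sort(names(topo_rows))))
  topo_rows <- topo_rows[names(seq_rows)]
  widths <- unique(c(nchar(seq_rows), nchar(topo_rows)))
  if (length(widths) != 1L)
    stop("all rows must share one aligned length; got ",
         paste(widths, collapse = ", "))
  for (id in names(seq_rows)) {
    gs <- gregexpr("-", seq_rows[[id]], fixed = TRUE)[[1]]
    gt <- gregexpr("-", topo_rows[[id]], fixed = TRUE)[[1]]
    if (!identical(as.integer(gs), as.integer(gt)))
      stop("gap columns of sequence and topology rows differ for row ", id)
  }
  if (!is.null(tree)) {
    d <- c(setdiff(tree$tip.label, names(seq_rows)),
           setdiff(names(seq_rows), tree$tip.label))
    if (length(d))
      stop("tree tips and alignment rows differ: ", paste(d, collapse = ", "))
  }
  stopifnot(identical(sort(row_order), sort(names(seq_rows))))
  structure(list(column_count = widths, row_ids = names(seq_rows),
                 seq_rows = seq_rows, topo_rows = topo_rows, tree = tree,
                 row_order = row_order),
            class = "multiple_topology_alignment")
}

#' @export
print.multiple_topology_alignment <- function(x, ...) {
  cat(sprintf("<multiple_topology_alignment> %d rows x %d columns%s\n",
              length(x$row_ids), x$column_count,
              if (is.null(x$tree)) "" else ", with tree"))
  invisible(x)
}

#' Project a per-residue topology onto a gapped alignment row
#'
#' Places topology characters at the non-gap columns of the row and `-` at
#' its gap columns, so that degapping the result recovers the per-residue
#' topology string exactly.
#'
#' @param msa_row gapped sequence row.
#' @param topo a `topology` or per-residue topology string whose length
#'   equals the degapped row length.
#' @return gapped topology string of the same width as `msa_row`.
#' @export
project_topology <- function(msa_row, topo) {
  ts <- if (inherits(topo, "topology")) serialize_topology(topo) else topo
  chars <- strsplit(msa_row, "", fixed = TRUE)[[1]]
  res <- chars != "-"
  if (sum(res) != nchar(ts))
    stop(sprintf(
      "projection error: degapped row has %d residues but topology covers %d",
      sum(res), nchar(ts)))
  out <- rep("-", length(chars))
  out[res] <- strsplit(ts, "", fixed = TRUE)[[1]]
  paste(out, collapse = "")
}

#' Remove gaps from an aligned row
#' @param x gapped string.
#' @return ungapped string.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

# left-to-right tip order of a (rooted) tree, as drawn
.tree_tip_order <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  tips <- tree$edge[, 2][tree$edge[, 2] <= ape::Ntip(tree)]
  tree$tip.label[tips]
}

#' Reorder alignment rows by tree branching order
#'
#' Sets the row order to the left-to-right leaf order of the tree (cladewise
#' traversal). Row content is untouched — only `row_order` changes.
#'
#' @param mta a `multiple_topology_alignment` with a tree.
#' @return the reordered `multiple_topology_alignment`.
#' @export
reorder_by_tree <- function(mta) {
  if (is.null(mta$tree)) stop("no tree attached to the alignment")
  mta$row_order <- .tree_tip_order(mta$tree)
  mta
}

# tips (labels) under each internal node, preorder from the root
.clade_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  tree <- stats::reorder(tree, "cladewise")
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- list()
  walk <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    tips <- unlist(lapply(kids[[as.character(node)]], walk))
    out[[as.character(node)]] <<- tips
    tips
  }
  walk(ntip + 1L)
  # preorder: root first, then deeper nodes in traversal order
  nodes <- c(ntip + 1L,
             tree$edge[, 2][tree$edge[, 2] > ntip])
  out[as.character(nodes)]
}

#' Detect topology-consistent subfamilies
#'
#' Walks the tree from the root and accepts each maximal clade in which at
#' least `min_clade_fraction` of the members share one topology label and the
#' clade has at least `min_group_size` members. Minority members inside an
#' accepted clade, and rows in no qualifying clade, are flagged as deviants
#' (putative topology-prediction errors). Without a tree the function falls
#' back to grouping by label equality alone (degraded mode, with a warning).
#'
#' @param mta a `multiple_topology_alignment`.
#' @param min_clade_fraction fraction of a clade that must share one label
#'   (default 0.75).
#' @param min_group_size minimum members per subfamily (default 3).
#' @return a `subfamily_partition`: list with `groups` (each
#'   `list(label, member_ids, supporting_clade)`) and `deviants` (ids).
#' @export
detect_topology_groups <- function(mta, min_clade_fraction = 0.75,
                                   min_group_size = 3L) {
  labels <- vapply(mta$topo_rows, function(s) {
    tryCatch(format(topology_label(parse_topology_string(degap(s)))),
             error = function(e) NA_character_)
  }, character(1))
  groups <- list()
  consumed <- character()
  add_group <- function(ids, clade_id) {
    tab <- sort(table(labels[ids]), decreasing = TRUE)
    lab <- names(tab)[1]
    members <- ids[!is.na(labels[ids]) & labels[ids] == lab]
    groups[[length(groups) + 1L]] <<-
      list(label = lab, member_ids = members, supporting_clade = clade_id)
    consumed <<- c(consumed, ids)
  }
  if (is.null(mta$tree)) {
    warning("no tree: grouping by label equality only (degraded mode)")
    for (lab in names(table(labels))) {
      ids <- mta$row_ids[!is.na(labels) & labels == lab]
      if (length(ids) >= min_group_size) add_group(ids, NA_character_)
    }
  } else {
    clades <- .clade_tips(mta$tree)
    for (nm in names(clades)) {
      ids <- clades[[nm]]
      if (any(ids %in% consumed)) next
      if (length(ids) < min_group_size) next
      ok <- !is.na(labels[ids])
      if (!any(ok)) next
      tab <- table(labels[ids][ok])
      if (max(tab) / length(ids) >= min_clade_fraction) add_group(ids, nm)
    }
  }
  deviants <- setdiff(mta$row_ids,
                      unlist(lapply(groups, `[[`, "member_ids")))
  structure(list(groups = groups, deviants = deviants,
                 labels = labels),
            class = "subfamily_partition")
}

#' @export
print.subfamily_partition <- function(x, ...) {
  cat(sprintf("<subfamily_partition> %d group(s), %d deviant(s)\n",
              length(x$groups), length(x$deviants)))
  for (g in x$groups)
    cat(sprintf("  %s: %d members\n", g$label, length(g$member_ids)))
  invisible(x)
}

#' Pick the representative row of a group
#'
#' The member with the fewest gap columns, ties broken by id.
#'
#' @param mta a `multiple_topology_alignment`.
#' @param ids member ids.
#' @return a single row id.
#' @export
group_representative <- function(mta, ids = mta$row_ids) {
  gaps <- vapply(mta$seq_rows[ids],
                 function(s) sum(strsplit(s, "")[[1]] == "-"), numeric(1))
  ids[order(gaps, ids)][1]
}

#' Consensus ("initial") topology of a subfamily
#'
#' Per-column majority state over the group's gapped topology rows (ties
#' resolved toward the representative row), degapped on the representative,
#' then smoothed — interior runs shorter than `min_run` are merged into the
#' longer flanking run — and side-repaired by N-terminal propagation toward
#' the majority orientation. Fails with a `consensus_failure` condition when
#' the smoothed string leaves two helix runs adjacent (no loop in between).
#'
#' @param mta a `multiple_topology_alignment`.
#' @param ids member ids of the group (default all rows).
#' @param representative row id to degap on (default [group_representative()]).
#' @param min_run smoothing window in residues (default 5).
#' @return a `topology` with source `"consensus"`.
#' @export
consensus_topology <- function(mta, ids = mta$row_ids,
                               representative = group_representative(mta, ids),
                               min_run = 5L) {
  stopifnot(length(ids) >= 1L, representative %in% ids)
  mat <- do.call(rbind, strsplit(unlist(mta$topo_rows[ids]), ""))
  rep_chars <- strsplit(mta$topo_rows[[representative]], "")[[1]]
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    top <- names(tab)[tab == max(tab)]
    if (rep_chars[j] %in% top) rep_chars[j] else top[1]
  }, character(1))
  keep <- rep_chars != "-"
  chars <- cons[keep]
  chars[chars == "-"] <- rep_chars[keep][chars == "-"]
  chars <- .smooth_runs(chars, min_run)
  s <- paste(chars, collapse = "")
  # majority orientation: side of the N-terminus voted over member rows
  sides <- vapply(mta$topo_rows[ids], function(row) {
    cc <- strsplit(degap(row), "")[[1]]
    first <- cc[cc %in% c("i", "o")][1]
    if (is.na(first)) NA_character_ else if (first == "i") "in" else "out"
  }, character(1))
  side <- names(sort(table(sides), decreasing = TRUE))[1]
  s <- repair_topology_sides(s, side)
  r <- rle(strsplit(s, "")[[1]])
  helix_run <- r$values %in% c("M", "B", "R", "S")
  if (any(helix_run[-1] & helix_run[-length(helix_run)])) {
    j <- which(helix_run[-1] & helix_run[-length(helix_run)])[1]
    ends <- cumsum(r$lengths)
    stop(structure(
      class = c("consensus_failure", "error", "condition"),
      list(message = sprintf(
        "consensus leaves adjacent helix runs around columns %d..%d",
        ends[j] - r$lengths[j] + 1L, ends[j + 1L]), call = sys.call())))
  }
  parse_topology_string(s, source = "consensus")
}

# merge interior runs shorter than min_run into the longer flanking run;
# terminal loop runs are kept (short chain tails are legitimate)
.smooth_runs <- function(chars, min_run) {
  repeat {
    r <- rle(chars)
    n <- length(r$values)
    if (n <= 2L) break
    short <- which(r$lengths < min_run)
    short <- short[short > 1L & short < n]
    if (length(short) == 0L) break
    j <- short[which.min(r$lengths[short])]
    left <- r$lengths[j - 1L]; right <- r$lengths[j + 1L]
    r$values[j] <- if (left >= right) r$values[j - 1L] else r$values[j + 1L]
    chars <- inverse.rle(r)
  }
  chars
}

#' UPGMA guide tree from pairwise identities
#'
#' Convenience builder for fixtures and examples when no externally inferred
#' tree is available: average-linkage clustering on `1 - identity` distances
#' between alignment rows. Not a substitute for a proper phylogeny.
#'
#' @param msa named character vector of aligned rows.
#' @return a rooted `ape::phylo`.
#' @export
upgma_from_identity <- function(msa) {
  n <- length(msa)
  stopifnot(n >= 2L)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- 1 - pairwise_identity(msa[[i]], msa[[j]],
                                                aligned = TRUE)
  }
  ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
}
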