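# Data products behind the figures: E-value-coloured alignment dotplots and
# CA-CA distance maps. Canonical outputs are plain tables; rendering is
# optional.

#' Alignment dotplot data
#'
#' One point per aligned residue pair across a set of alternative alignments
#' of the same sequence pair, coloured by the order of magnitude of each
#' alignment's E-value (`floor(log10(E))`). Helix spans of both topologies
#' are attached for axis annotation (TM vs reentrant/broken drawn
#' differently by consumers).
#'
#' @param alignments list of `pairwise_alignment` objects sharing one
#'   query/template pair.
#' @param q_topology,t_topology optional topologies for axis annotations.
#' @return an `alignment_dotplot`: list with `points` (data.frame `q_pos`,
#'   `t_pos`, `log10_e`, `alignment`) and `q_helices`/`t_helices`.
#' @export
alignment_dotplot <- function(alignments, q_topology = NULL,
                              t_topology = NULL) {
  if (inherits(alignments, "pairwise_alignment"))
    alignments <- list(alignments)
  pair <- unique(t(vapply(alignments,
                          function(a) c(a$query_id, a$template_id),
                          character(2))))
  if (nrow(pair) != 1L)
    stop("all alignments must share the same sequence pair")
  pts <- do.call(rbind, lapply(seq_along(alignments), function(k) {
    a <- alignments[[k]]
    cols <- a$columns
    cols <- cols[!is.na(cols$q_pos) & !is.na(cols$t_pos), , drop = FALSE]
    data.frame(q_pos = cols$q_pos, t_pos = cols$t_pos,
               log10_e = rep(floor(log10(a$e_value)), nrow(cols)),
               alignment = rep(k, nrow(cols)))
  }))
  hx <- function(t) if (is.null(t)) NULL else
    helices(t)[, c("kind", "start", "end", "helix_index")]
  structure(list(points = pts, query_id = pair[1, 1],
                 template_id = pair[1, 2],
                 q_helices = hx(q_topology), t_helices = hx(t_topology)),
            class = "alignment_dotplot")
}

#' @export
print.alignment_dotplot <- function(x, ...) {
  cat(sprintf("<alignment_dotplot> %s vs %s: %d points (%d alignment(s))\n",
              x$query_id, x$template_id, nrow(x$points),
              length(unique(x$points$alignment))))
  invisible(x)
}

#' Read CA coordinates from a PDB file
#'
#' First model, first alternate location, CA atoms only. Positions without a
#' CA are skipped with a warning.
#'
#' @param path PDB file.
#' @return matrix with columns x, y, z, one row per residue with a CA.
#' @export
read_ca_coords <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required to read PDB files")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  # first altLoc only
  if (!is.null(atoms$alt)) {
    keep <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno)), , drop = FALSE]
  as.matrix(atoms[, c("x", "y", "z")])
}

#' CA-CA distance map
#'
#' Euclidean distances between CA coordinates: the full all-vs-all matrix by
#' default, or only the aligned-pair trace when a residue map is supplied.
#' Raw distances are preserved; `clip` gives the rendering range (values
#' outside `[lo, hi]` are clamped for display only).
#'
#' @param coords_a,coords_b numeric matrices (rows = residues, cols = xyz).
#' @param residue_map optional data.frame (`a_pos`, `b_pos`) of aligned
#'   indices.
#' @param clip rendering clip range in Angstrom (default `c(4, 10)`).
#' @return a `distance_map`: list with `distances` (matrix, or data.frame of
#'   aligned pairs) and `clip`.
#' @export
distance_map <- function(coords_a, coords_b = coords_a, residue_map = NULL,
                         clip = c(4, 10)) {
  stopifnot(ncol(coords_a) == 3L, ncol(coords_b) == 3L)
  if (is.null(residue_map)) {
    d <- matrix(0, nrow(coords_a), nrow(coords_b))
    for (i in seq_len(nrow(coords_a))) {
      diff <- sweep(coords_b, 2, coords_a[i, ])
      d[i, ] <- sqrt(rowSums(diff^2))
    }
    res <- d
  } else {
    stopifnot(all(residue_map$a_pos >= 1),
              all(residue_map$a_pos <= nrow(coords_a)),
              all(residue_map$b_pos >= 1),
              all(residue_map$b_pos <= nrow(coords_b)))
    dd <- sqrt(rowSums((coords_a[residue_map$a_pos, , drop = FALSE] -
                          coords_b[residue_map$b_pos, , drop = FALSE])^2))
    res <- data.frame(a_pos = residue_map$a_pos, b_pos = residue_map$b_pos,
                      distance = dd)
  }
  structure(list(distances = res, clip = clip), class = "distance_map")
}

#' Clipped (display) values of a distance map
#'
#' @param dm a `distance_map`.
#' @return distances clamped to the clip range, same shape as stored.
#' @export
clip_distances <- function(dm) {
  v <- if (is.data.frame(dm$distances)) dm$distances$distance else
    dm$distances
  v <- pmin(pmax(v, dm$clip[1]), dm$clip[2])
  if (is.data.frame(dm$distances)) {
    out <- dm$distances
    out$distance <- v
    out
  } else {
    m <- dm$distances
    m[] <- v
    m
  }
}

#' @export
print.distance_map <- function(x, ...) {
  if (is.data.frame(x$distances)) {
    cat(sprintf("<distance_map> %d aligned pairs, clip [%g, %g] A\n",
                nrow(x$distances), x$clip[1], x$clip[2]))
  } else {
    cat(sprintf("<distance_map> %d x %d matrix, clip [%g, %g] A\n",
                nrow(x$distances), ncol(x$distances), x$clip[1], x$clip[2]))
  }
  invisible(x)
}

#' Difference of intra-chain distance matrices
#'
#' Alternative distance-map mode: given two chains and an alignment between
#' them, computes `|d_a(i,j) - d_b(i',j')|` over aligned index pairs —
#' the discrepancy between the two internal distance geometries.
#'
#' @param coords_a,coords_b coordinate matrices.
#' @param residue_map data.frame (`a_pos`, `b_pos`).
#' @param clip rendering clip range (default `c(4, 10)`).
#' @return a `distance_map` whose matrix is the absolute difference over the
#'   aligned positions.
#' @export
distance_map_difference <- function(coords_a, coords_b, residue_map,
                                    clip = c(4, 10)) {
  da <- distance_map(coords_a[residue_map$a_pos, , drop = FALSE])$distances
  db <- distance_map(coords_b[residue_map$b_pos, , drop = FALSE])$distances
  structure(list(distances = abs(da - db), clip = clip),
            class = "distance_map")
}
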