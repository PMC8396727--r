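# Seeded generator of ground-truth membrane-transporter families: a topology
# blueprint is expanded into an ancestral sequence, diverged along a random
# coalescent tree (substitutions within residue class, indels in loops only),
# and paired with noisy "predicted" topologies that stochastically miss
# non-canonical helices, merge helices or flip the orientation — the error
# modes real topology predictors show on these proteins.

.residue_sets <- list(
  hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"),
  polar = c("G", "S", "T", "N", "Q", "P", "H"),
  positive = c("K", "R"),
  negative = c("D", "E"))

.residue_class <- local({
  cls <- character()
  for (nm in names(.residue_sets)) cls[.residue_sets[[nm]]] <- nm
  cls
})

# sampling distributions per segment kind
.sample_residues <- function(kind, n, core_gly_pro = 0) {
  if (kind %in% c("tm_helix", "broken_helix", "signal_peptide")) {
    probs <- c(L = .24, I = .15, V = .15, A = .12, F = .10, G = .06,
               M = .05, T = .04, S = .04, W = .02, Y = .02, C = .01)
    out <- sample(names(probs), n, replace = TRUE, prob = probs)
  } else if (kind == "reentrant_helix") {
    probs <- c(L = .14, I = .09, V = .09, A = .12, S = .12, T = .10,
               G = .12, N = .08, Q = .06, M = .04, F = .04)
    out <- sample(names(probs), n, replace = TRUE, prob = probs)
    mid <- seq.int(max(1L, floor(n / 3) + 1L), ceiling(2 * n / 3))
    enrich <- mid[runif(length(mid)) < core_gly_pro]
    out[enrich] <- sample(c("G", "P"), length(enrich), replace = TRUE,
                          prob = c(0.75, 0.25))
  } else {
    probs <- c(S = .13, T = .10, N = .09, Q = .08, G = .11, P = .08,
               D = .07, E = .07, A = .08, H = .04, L = .05, V = .04,
               K = .03, R = .03)
    out <- sample(names(probs), n, replace = TRUE, prob = probs)
  }
  out
}

#' Topology blueprint from a label
#'
#' Expands a topology label such as `"10H-2RH-Nout"` into a concrete segment
#' plan: an N-terminal tail, alternating helices and loops, a C-terminal
#' tail, with the non-canonical helix placed as the middle helix of each
#' repeat's three-helix core subdomain and a matching repeat/subdomain
#' annotation (helices split evenly between the repeats, any odd helix going
#' to the N repeat as an extra scaffold helix).
#'
#' @param label a `topology_label` or label string.
#' @param helix_len TM/broken helix length (default 21).
#' @param reentrant_len reentrant helix length (default 16).
#' @param loop_len loop length between helices (default 15).
#' @param tail_len N-/C-terminal tail length (default 20).
#' @return a `family_blueprint`: list with `segments` (kind, length),
#'   `n_term_side`, `label`, and `annotation` (`repeat_annotation` or NULL
#'   for labels without non-canonical helices).
#' @export
blueprint_from_label <- function(label, helix_len = 21L, reentrant_len = 16L,
                                 loop_len = 15L, tail_len = 20L) {
  if (is.character(label)) label <- parse_topology_label(label)
  u <- total_helix_count(label)
  m <- label$n_noncanonical
  nc_kind <- switch(label$noncanonical_kind, BH = "broken_helix",
                    RH = "reentrant_helix", none = NA_character_)
  kinds <- rep("tm_helix", u)
  n_units <- if (m == 2L) ceiling(u / 2) else u
  units_per_repeat <- c(n_units, u - n_units)
  if (m == 2L) {
    stopifnot(min(units_per_repeat) >= 3L)
    # middle helix of each repeat's 3-helix core = second-to-last unit
    kinds[n_units - 1L] <- nc_kind
    kinds[u - 1L] <- nc_kind
  } else if (m != 0L) {
    stop("only 0 or 2 non-canonical helices are supported")
  }
  seg_kinds <- c("loop", rbind(kinds, "loop"))
  seg_len <- integer(length(seg_kinds))
  seg_len[seg_kinds == "loop"] <- loop_len
  seg_len[1] <- tail_len
  seg_len[length(seg_len)] <- tail_len
  seg_len[seg_kinds == "tm_helix"] <- helix_len
  seg_len[seg_kinds == "broken_helix"] <- helix_len + 4L
  seg_len[seg_kinds == "reentrant_helix"] <- reentrant_len
  segments <- data.frame(kind = seg_kinds, length = seg_len)
  annotation <- NULL
  if (m == 2L) {
    start <- cumsum(c(1L, seg_len[-length(seg_len)]))
    end <- cumsum(seg_len)
    helix_rows <- which(seg_kinds != "loop")
    # repeat boundaries at loop midpoints around each repeat's helices
    lastN <- helix_rows[n_units]; firstC <- helix_rows[n_units + 1L]
    linker_mid <- (end[lastN] + start[firstC]) %/% 2L
    n_start <- start[helix_rows[1]] - tail_len %/% 2L
    c_end <- end[helix_rows[u]] + tail_len %/% 2L
    tags <- character(u)
    for (r in 1:2) {
      idx <- if (r == 1) seq_len(n_units) else (n_units + 1L):u
      tags[idx] <- c(rep("scaffold", length(idx) - 3L), rep("core", 3L))
    }
    annotation <- repeat_annotation(
      n_repeat = c(n_start, linker_mid),
      c_repeat = c(linker_mid + 1L, c_end),
      helix_tags = tags,
      helix_repeat = rep(c("N", "C"), units_per_repeat))
  }
  structure(list(segments = segments, n_term_side = label$n_term_side,
                 label = format(label), annotation = annotation),
            class = "family_blueprint")
}

# per-residue truth string and topology object of a blueprint
.blueprint_topology <- function(bp) {
  side <- if (bp$n_term_side == "Nin") "in" else "out"
  chars <- character()
  for (i in seq_len(nrow(bp$segments))) {
    k <- bp$segments$kind[i]; len <- bp$segments$length[i]
    ch <- switch(k, loop = if (side == "in") "i" else "o",
                 tm_helix = "M", broken_helix = "B",
                 reentrant_helix = "R", signal_peptide = "S")
    chars <- c(chars, rep(ch, len))
    if (k %in% c("tm_helix", "broken_helix", "signal_peptide"))
      side <- if (side == "in") "out" else "in"
  }
  paste(chars, collapse = "")
}

#' Specification of a synthetic transporter family
#'
#' Bundles the topology blueprint with the evolutionary and compositional
#' parameters of the generator. Defaults describe a typical seed family:
#' 20 sequences, moderate divergence, a positive-inside excess of two K/R
#' per inside loop and glycine/proline-enriched reentrant cores.
#'
#' @param blueprint a `family_blueprint` (or label string, expanded via
#'   [blueprint_from_label()]).
#' @param n_sequences rows to generate (default 20).
#' @param tree_depth mean root-to-tip divergence (substitutions per site
#'   scale, default 0.4).
#' @param substitution_rate per-site substitution probability per unit
#'   branch length (default 0.6).
#' @param indel_rate per-loop, per-tip probability of one indel
#'   (default 0.1).
#' @param positive_inside_strength expected excess K/R per inside loop
#'   (default 2).
#' @param core_gly_pro_enrichment G/P enrichment of the reentrant core
#'   middle third (default 0.3).
#' @param p_miss_noncanonical per-row, per-helix probability that a
#'   predicted topology misses a broken/reentrant helix (default 0).
#' @param p_merge per-row probability of merging two adjacent predicted
#'   helices (default 0).
#' @param p_flip_orientation per-row probability of a flipped predicted
#'   orientation (default 0).
#' @param seed RNG seed fixing every draw.
#' @return a `family_spec` list.
#' @export
family_spec <- function(blueprint, n_sequences = 20L, tree_depth = 0.4,
                        substitution_rate = 0.6, indel_rate = 0.1,
                        positive_inside_strength = 2,
                        core_gly_pro_enrichment = 0.3,
                        p_miss_noncanonical = 0, p_merge = 0,
                        p_flip_orientation = 0, seed = 1L) {
  if (is.character(blueprint)) blueprint <- blueprint_from_label(blueprint)
  probs <- c(indel_rate, p_miss_noncanonical, p_merge, p_flip_orientation)
  stopifnot(all(probs >= 0), all(probs <= 1), n_sequences >= 1L)
  structure(list(blueprint = blueprint, n_sequences = as.integer(n_sequences),
                 tree_depth = tree_depth,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 positive_inside_strength = positive_inside_strength,
                 core_gly_pro_enrichment = core_gly_pro_enrichment,
                 p_miss_noncanonical = p_miss_noncanonical,
                 p_merge = p_merge,
                 p_flip_orientation = p_flip_orientation,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# build one ancestral sequence for a blueprint; returns chars + kind chars
.ancestor_sequence <- function(spec) {
  bp <- spec$blueprint
  topo_chars <- strsplit(.blueprint_topology(bp), "", fixed = TRUE)[[1]]
  seq_chars <- character(length(topo_chars))
  r <- rle(topo_chars)
  pos <- 1L
  for (j in seq_along(r$values)) {
    len <- r$lengths[j]
    kind <- unname(.kind_for_char[r$values[j]])
    chars <- .sample_residues(kind, len, spec$core_gly_pro_enrichment)
    if (kind == "inside_loop" && spec$positive_inside_strength > 0) {
      extra <- min(rpois(1L, spec$positive_inside_strength), len)
      if (extra > 0L) {
        where <- sample.int(len, extra)
        chars[where] <- sample(c("K", "R"), extra, replace = TRUE)
      }
    }
    seq_chars[pos:(pos + len - 1L)] <- chars
    pos <- pos + len
  }
  list(seq = seq_chars, topo = topo_chars)
}

# substitute within residue class at probability p per site
.mutate_chars <- function(chars, p) {
  hit <- which(runif(length(chars)) < p)
  for (i in hit) {
    cls <- .residue_class[[chars[i]]]
    pool <- setdiff(.residue_sets[[cls]], chars[i])
    if (length(pool)) chars[i] <- sample(pool, 1L)
  }
  chars
}

#' Generate a synthetic transporter family
#'
#' Expands the spec's blueprint into an ancestor, evolves it along a random
#' coalescent tree (substitutions stay within residue class so the
#' hydrophobicity/charge architecture is preserved; indels are confined to
#' loops with geometric length of mean 2), and produces per-row true and
#' noisy "predicted" topologies. The alignment is exact by construction.
#'
#' @param spec a [family_spec()].
#' @return a `synthetic_family`: list with `msa` (named gapped rows),
#'   `truth` (per-row degapped true topology strings), `predicted` (per-row
#'   degapped predicted topology strings), `tree` (`ape::phylo`),
#'   `blueprint`, `annotation`, and `ancestor` (list seq/topo strings).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  anc <- .ancestor_sequence(spec)
  L <- length(anc$seq)
  n <- spec$n_sequences
  ids <- sprintf("seq%02d", seq_len(n))
  if (n >= 2L) {
    tree <- ape::rcoal(n, tip.label = sample(ids))
    tree$edge.length <- tree$edge.length *
      (spec$tree_depth / mean(ape::node.depth.edgelength(tree)[seq_len(n)]))
  } else {
    tree <- NULL
  }
  # tree-recursive substitution on the fixed-length ancestor
  rows <- matrix("", nrow = n, ncol = L, dimnames = list(ids, NULL))
  if (is.null(tree)) {
    rows[1, ] <- .mutate_chars(anc$seq, spec$substitution_rate *
                                 spec$tree_depth)
  } else {
    ntip <- n
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    walk <- function(node, chars) {
      for (ei in kids[[as.character(node)]]) {
        child <- tree$edge[ei, 2]
        mutated <- .mutate_chars(chars, spec$substitution_rate *
                                   tree$edge.length[ei])
        if (child <= ntip) {
          rows[tree$tip.label[child], ] <<- mutated
        } else {
          walk(child, mutated)
        }
      }
    }
    walk(ntip + 1L, anc$seq)
  }
  # loop-only indels per tip: deletions gap the row; insertions add columns
  loop_runs <- local({
    r <- rle(strsplit(.blueprint_topology(spec$blueprint), "",
                      fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts, end = ends,
               loop = r$values %in% c("i", "o"))[r$values %in% c("i", "o"), ]
  })
  insertions <- list()  # list of (after_col, id, chars, topo_char)
  for (id in ids) {
    for (k in seq_len(nrow(loop_runs))) {
      if (runif(1) >= spec$indel_rate) next
      lo <- loop_runs$start[k]; hi <- loop_runs$end[k]
      len <- min(rgeom(1L, 1 / 3) + 1L, hi - lo - 3L)
      if (len < 1L) next
      if (runif(1) < 0.5) {  # deletion
        at <- sample(lo:(hi - len + 1L), 1L)
        rows[id, at:(at + len - 1L)] <- "-"
      } else {               # insertion after a random loop column
        after <- sample(lo:(hi - 1L), 1L)
        side_char <- substr(.blueprint_topology(spec$blueprint),
                            after, after)
        insertions[[length(insertions) + 1L]] <- list(
          after = after, id = id,
          chars = .sample_residues("inside_loop", len), topo_char = side_char)
      }
    }
  }
  anc_topo <- strsplit(.blueprint_topology(spec$blueprint), "",
                       fixed = TRUE)[[1]]
  if (length(insertions)) {
    blocks <- split(insertions,
                    vapply(insertions, `[[`, numeric(1), "after"))
    mat_list <- list(); topo_list <- list()
    for (cc in seq_len(L)) {
      mat_list[[length(mat_list) + 1L]] <- rows[, cc]
      topo_list[[length(topo_list) + 1L]] <- anc_topo[cc]
      bl <- blocks[[as.character(cc)]]
      if (!is.null(bl)) for (ins in bl) {
        for (ch_i in seq_along(ins$chars)) {
          col <- setNames(rep("-", n), ids)
          col[ins$id] <- ins$chars[ch_i]
          mat_list[[length(mat_list) + 1L]] <- col
          topo_list[[length(topo_list) + 1L]] <- ins$topo_char
        }
      }
    }
    rows <- do.call(cbind, mat_list)
    rownames(rows) <- ids
    anc_topo <- unlist(topo_list)
  }
  msa <- setNames(apply(rows, 1, paste, collapse = ""), ids)
  truth <- vapply(ids, function(id) {
    keep <- rows[id, ] != "-"
    paste(anc_topo[keep], collapse = "")
  }, character(1))
  predicted <- vapply(ids, function(id) {
    .corrupt_prediction(truth[[id]], spec)
  }, character(1))
  structure(list(msa = msa, truth = truth, predicted = predicted,
                 tree = tree, blueprint = spec$blueprint,
                 annotation = spec$blueprint$annotation,
                 ancestor = list(seq = paste(anc$seq, collapse = ""),
                                 topo = .blueprint_topology(spec$blueprint)),
                 spec = spec),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("<synthetic_family> %s: %d rows x %d columns\n",
              x$blueprint$label, length(x$msa), nchar(x$msa[[1]])))
  invisible(x)
}

# apply the prediction-error model to one true per-residue string
.corrupt_prediction <- function(s, spec) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_side <- {
    first <- chars[chars %in% c("i", "o")][1]
    if (first == "i") "in" else "out"
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # miss non-canonical helices
  for (j in which(r$values %in% c("B", "R"))) {
    if (runif(1) < spec$p_miss_noncanonical)
      chars[starts[j]:ends[j]] <- "i"  # side fixed by repair below
  }
  # merge two adjacent helices across a short loop
  if (spec$p_merge > 0 && runif(1) < spec$p_merge) {
    r2 <- rle(chars)
    ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1L
    helix <- which(r2$values %in% c("M", "B", "R"))
    cand <- if (length(helix) >= 2L) helix[which(diff(helix) == 2L)] else
      integer()
    cand <- cand[r2$lengths[cand + 1L] <= 20L]
    if (length(cand)) {
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      chars[starts2[j + 1L]:ends2[j + 1L]] <- "M"
    }
  }
  out <- repair_topology_sides(paste(chars, collapse = ""), n_side)
  if (runif(1) < spec$p_flip_orientation) out <- chartr("io", "oi", out)
  out
}

#' Randomly corrupt a per-residue topology string
#'
#' Per-position noise model used in consensus-recovery experiments: each
#' residue's character is replaced, with the given probability, by a
#' different character drawn uniformly from `{i, o, M, B, R}`. The result
#' need not be a valid topology; consensus and smoothing operate on the raw
#' characters.
#'
#' @param s per-residue topology string (ungapped).
#' @param rate per-position corruption probability.
#' @return corrupted string of the same length.
#' @export
corrupt_topology_string <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  pool <- c("i", "o", "M", "B", "R")
  for (i in hit) chars[i] <- sample(setdiff(pool, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate a two-clade family with distinct topologies
#'
#' Generates one family per spec and joins them under a common root so the
#' merged alignment holds two clades with different topology labels — the
#' situation that forces a subfamily split.
#'
#' @param spec_a,spec_b `family_spec`s with different labels.
#' @param prefix_a,prefix_b id prefixes keeping the rows distinct.
#' @return a `synthetic_family`-like list (`msa`, `truth`, `predicted`,
#'   `tree`, `clades` giving the true partition).
#' @export
generate_subfamily_mixture <- function(spec_a, spec_b,
                                       prefix_a = "a_", prefix_b = "b_") {
  stopifnot(spec_a$blueprint$label != spec_b$blueprint$label)
  fa <- generate_family(spec_a)
  fb <- generate_family(spec_b)
  rename <- function(x, prefix) setNames(x, paste0(prefix, names(x)))
  wa <- nchar(fa$msa[[1]]); wb <- nchar(fb$msa[[1]])
  msa <- c(rename(vapply(fa$msa, function(s) paste0(s, strrep("-", wb)),
                         character(1)), prefix_a),
           rename(vapply(fb$msa, function(s) paste0(strrep("-", wa), s),
                         character(1)), prefix_b))
  relab <- function(tr, prefix) {
    tr$tip.label <- paste0(prefix, tr$tip.label); tr
  }
  ta <- relab(fa$tree, prefix_a); tb <- relab(fb$tree, prefix_b)
  na <- sub(";\\s*$", "", ape::write.tree(ta))
  nb <- sub(";\\s*$", "", ape::write.tree(tb))
  tree <- ape::read.tree(text = paste0("(", na, ":0.5,", nb, ":0.5);"))
  list(msa = msa,
       truth = c(rename(fa$truth, prefix_a), rename(fb$truth, prefix_b)),
       predicted = c(rename(fa$predicted, prefix_a),
                     rename(fb$predicted, prefix_b)),
       tree = tree,
       clades = list(a = paste0(prefix_a, names(fa$msa)),
                     b = paste0(prefix_b, names(fb$msa))),
       labels = c(a = fa$blueprint$label, b = fb$blueprint$label))
}

#' Generate a synthetic family-network hit table
#'
#' Draws pairwise hits realising a designed cluster/outlier structure:
#' within-cluster pairs get strongly significant E-values (below the thick
#' threshold), satellite links fall in the thin band, and outlier pairs are
#' non-significant. A fraction of pairs is emitted in both directions with
#' distinct E-values to exercise deduplication.
#'
#' @param clusters list of character vectors of unit ids (one per cluster).
#' @param satellites character vector of ids attached thinly to the first
#'   cluster.
#' @param outliers character vector of ids with only non-significant hits.
#' @param bidirectional_fraction fraction of pairs emitted both ways
#'   (default 0.3).
#' @param seed RNG seed.
#' @return data.frame `query`, `hit`, `e_value`.
#' @export
generate_hit_table <- function(clusters, satellites = character(),
                               outliers = character(),
                               bidirectional_fraction = 0.3, seed = 1L) {
  set.seed(seed)
  out <- list()
  emit <- function(a, b, log10_range) {
    e <- 10^runif(1, log10_range[1], log10_range[2])
    out[[length(out) + 1L]] <<- data.frame(query = a, hit = b, e_value = e)
    if (runif(1) < bidirectional_fraction) {
      e2 <- 10^runif(1, log10_range[1], log10_range[2])
      out[[length(out) + 1L]] <<- data.frame(query = b, hit = a,
                                             e_value = e2)
    }
  }
  for (cl in clusters) {
    if (length(cl) >= 2L) {
      pairs <- utils::combn(cl, 2L)
      for (k in seq_len(ncol(pairs)))
        emit(pairs[1, k], pairs[2, k], c(-40, log10(0.001) - 0.2))
    }
  }
  anchor <- clusters[[1]]
  for (s in satellites)
    emit(s, sample(anchor, 1L), c(log10(0.001), log10(0.1) - 0.01))
  all_sig <- c(unlist(clusters), satellites)
  for (o in outliers) {
    partners <- if (length(all_sig)) all_sig else setdiff(outliers, o)
    if (length(partners) == 0L) next
    emit(o, if (length(partners) == 1L) partners else
      sample(partners, 1L), c(log10(0.1), 1))
  }
  do.call(rbind, out)
}

#' Build a structure-template scenario from a generated family
#'
#' Constructs a known-structure "template" for a family by prepending extra
#' scaffold helices to the representative's true topology — the template
#' then carries the non-canonical helices that noisy predictions miss, and
#' its pairwise alignment to the representative is exact by construction.
#' The returned pieces are synthetic stand-ins for a solved structure and
#' its curated annotation.
#'
#' @param fam a `synthetic_family`.
#' @param representative row id (default first).
#' @param n_extra_scaffold extra N-terminal template helices (default 1).
#' @param e_value E-value to stamp on the alignment (default 1e-40).
#' @param helix_len,loop_len geometry of the prepended unit.
#' @return list with `alignment` (`pairwise_alignment` query=representative,
#'   template), `topology` (template `topology`), `annotation` (template
#'   `repeat_annotation`), `type` (`"broken"`/`"reentrant"`).
#' @export
make_structure_template <- function(fam, representative = names(fam$msa)[1],
                                    n_extra_scaffold = 1L, e_value = 1e-40,
                                    helix_len = 21L, loop_len = 15L) {
  rep_seq <- degap(fam$msa[[representative]])
  rep_topo <- fam$truth[[representative]]
  first_side <- substr(rep_topo, 1L, 1L)
  prefix_topo <- ""
  prefix_seq <- ""
  side <- first_side
  for (k in seq_len(n_extra_scaffold)) {
    side <- if (side == "i") "o" else "i"
    prefix_topo <- paste0(strrep(side, loop_len), strrep("M", helix_len),
                          prefix_topo)
    prefix_seq <- paste0(
      paste(.sample_residues("inside_loop", loop_len), collapse = ""),
      paste(.sample_residues("tm_helix", helix_len), collapse = ""),
      prefix_seq)
  }
  t_seq <- paste0(prefix_seq, rep_seq)
  t_topo_str <- paste0(prefix_topo, rep_topo)
  t_topology <- parse_topology_string(t_topo_str, source = "template")
  aln <- pairwise_alignment(
    query_id = representative, template_id = "template",
    q_aln = paste0(strrep("-", nchar(prefix_seq)), rep_seq),
    t_aln = t_seq, e_value = e_value, identity = 1.0)
  ann <- fam$annotation
  t_ann <- NULL
  if (!is.null(ann)) {
    off <- nchar(prefix_seq)
    t_ann <- repeat_annotation(
      n_repeat = c(1L, ann$n_repeat[2] + off),
      c_repeat = ann$c_repeat + off,
      helix_tags = c(rep("scaffold", n_extra_scaffold), ann$helix_tags),
      helix_repeat = c(rep("N", n_extra_scaffold), ann$helix_repeat))
  }
  lab <- topology_label(t_topology)
  list(alignment = aln, topology = t_topology, annotation = t_ann,
       type = switch(lab$noncanonical_kind, BH = "broken",
                     RH = "reentrant", none = NA_character_),
       e_value = e_value)
}
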