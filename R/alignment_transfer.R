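# Pairwise topology alignment against families of known structure:
# helix-alignment classification, transporter-type choice by best E-value,
# missing-helix inference ("final topology"), and repeat/subdomain transfer.

#' Pairwise (query-template) alignment
#'
#' Built from two gapped strings of equal width. Column `q_pos`/`t_pos` maps
#' are derived; both are strictly increasing along the alignment.
#'
#' @param query_id,template_id sequence identifiers.
#' @param q_aln,t_aln gapped aligned strings of equal width.
#' @param e_value positive E-value of the alignment.
#' @param identity optional fractional identity.
#' @return a `pairwise_alignment` with a `columns` data.frame
#'   (`column`, `q_pos`, `t_pos`; NA at gaps).
#' @export
pairwise_alignment <- function(query_id, template_id, q_aln, t_aln,
                               e_value, identity = NA_real_) {
  stopifnot(nchar(q_aln) == nchar(t_aln), e_value > 0)
  qc <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  tc <- strsplit(t_aln, "", fixed = TRUE)[[1]]
  cols <- data.frame(column = seq_along(qc),
                     q_pos = ifelse(qc == "-", NA_integer_,
                                    cumsum(qc != "-")),
                     t_pos = ifelse(tc == "-", NA_integer_,
                                    cumsum(tc != "-")))
  structure(list(query_id = query_id, template_id = template_id,
                 q_aln = q_aln, t_aln = t_aln, columns = cols,
                 e_value = e_value, identity = identity,
                 aligned_columns = sum(!is.na(cols$q_pos) &
                                         !is.na(cols$t_pos))),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: %d columns, %d aligned, E=%g\n",
              x$query_id, x$template_id, nrow(x$columns),
              x$aligned_columns, x$e_value))
  invisible(x)
}

.state_at <- function(topology, pos) {
  seg <- topology$segments
  seg$kind[seg$start <= pos & seg$end >= pos]
}

#' Classify template helices against a query topology
#'
#' A template membrane helix is `aligned` when at least `min_overlap`
#' residues of it are aligned to residues of one query helix (five by
#' convention — at least five residues of both helices aligned). Otherwise
#' its class is the dominating query composition over the template-helix
#' columns: `gap`, `inside_loop`, `outside_loop` or `signal_peptide`, ties
#' broken in that order of precedence.
#'
#' @param aln a `pairwise_alignment`.
#' @param q_topology query `topology` (chain length = degapped query).
#' @param t_topology template `topology` (chain length = degapped template).
#' @param min_overlap aligned-residue threshold (default 5).
#' @return data.frame, one row per template membrane helix: `template_helix`,
#'   `template_kind`, `class`, `overlap_residues`, `query_helix`,
#'   `query_start`, `query_end`.
#' @export
classify_helices <- function(aln, q_topology, t_topology, min_overlap = 5L) {
  cols <- aln$columns
  if (max(cols$q_pos, na.rm = TRUE) > q_topology$chain_length ||
      max(cols$t_pos, na.rm = TRUE) > t_topology$chain_length)
    stop("alignment references positions outside a chain")
  th <- helices(t_topology)
  qh <- helices(q_topology)
  out <- lapply(seq_len(nrow(th)), function(i) {
    span <- cols[!is.na(cols$t_pos) & cols$t_pos >= th$start[i] &
                   cols$t_pos <= th$end[i], , drop = FALSE]
    # aligned-residue overlap with each query helix
    best_overlap <- 0L; best_qh <- NA_integer_
    if (nrow(qh)) for (j in seq_len(nrow(qh))) {
      ov <- sum(!is.na(span$q_pos) & span$q_pos >= qh$start[j] &
                  span$q_pos <= qh$end[j])
      if (ov > best_overlap) { best_overlap <- ov; best_qh <- j }
    }
    if (best_overlap >= min_overlap) {
      qs <- span$q_pos[!is.na(span$q_pos) & span$q_pos >= qh$start[best_qh] &
                         span$q_pos <= qh$end[best_qh]]
      return(data.frame(template_helix = th$helix_index[i],
                        template_kind = th$kind[i], class = "aligned",
                        overlap_residues = best_overlap,
                        query_helix = best_qh,
                        query_start = min(qs), query_end = max(qs)))
    }
    states <- vapply(span$q_pos, function(p) {
      if (is.na(p)) return("gap")
      k <- .state_at(q_topology, p)
      if (k %in% c("inside_loop", "outside_loop", "signal_peptide")) k
      else "helix_below_threshold"
    }, character(1))
    classes <- c("gap", "inside_loop", "outside_loop", "signal_peptide")
    counts <- vapply(classes, function(cl) sum(states == cl), integer(1))
    cl <- classes[which.max(counts)]  # which.max keeps precedence order
    qs <- span$q_pos[!is.na(span$q_pos)]
    data.frame(template_helix = th$helix_index[i],
               template_kind = th$kind[i], class = cl,
               overlap_residues = best_overlap,
               query_helix = NA_integer_,
               query_start = if (length(qs)) min(qs) else NA_integer_,
               query_end = if (length(qs)) max(qs) else NA_integer_)
  })
  do.call(rbind, out)
}

#' Choose the transporter type from structural hits
#'
#' The broken/reentrant type is taken from the known-structure hit with the
#' lowest E-value. An exact tie between hits of different types raises an
#' `ambiguous_type` condition — KR-bias arbitration is then required.
#'
#' @param hits data.frame with columns `template_type`
#'   (`"broken"`/`"reentrant"`) and `e_value`.
#' @return `"broken"` or `"reentrant"`.
#' @export
choose_transporter_type <- function(hits) {
  stopifnot(nrow(hits) >= 1L, all(hits$e_value > 0),
            all(hits$template_type %in% c("broken", "reentrant")))
  best <- min(hits$e_value)
  types <- unique(hits$template_type[hits$e_value == best])
  if (length(types) > 1L)
    stop(structure(
      class = c("ambiguous_type", "error", "condition"),
      list(message = sprintf(
        "tie at E=%g between types %s; KR-bias arbitration required",
        best, paste(types, collapse = "/")), call = sys.call())))
  types
}

#' Infer the final topology by adding template helices missing in the query
#'
#' Every template membrane helix classified as aligned to a query loop is
#' inserted into the query topology at its mapped span (clipped to the loop,
#' minimum length 5), after which all loop sides are re-propagated from the
#' N-terminus — inserting a crossing helix flips every downstream side.
#' Applying the function a second time (after re-classification) is a
#' no-op: the inserted helices now align.
#'
#' @param q_initial query `topology` (the consensus/"initial" topology).
#' @param t_topology template `topology`.
#' @param records output of [classify_helices()] against `q_initial`.
#' @param aln the `pairwise_alignment` the records came from.
#' @param min_insert minimum inserted helix length (default 5).
#' @return a `topology` with source `"final"`.
#' @export
infer_final_topology <- function(q_initial, t_topology, records, aln,
                                 min_insert = 5L) {
  chars <- strsplit(serialize_topology(q_initial), "", fixed = TRUE)[[1]]
  n_side <- if (topology_label(q_initial)$n_term_side == "Nin") "in" else "out"
  miss <- records[records$class %in% c("inside_loop", "outside_loop"), ,
                  drop = FALSE]
  seg <- q_initial$segments
  for (i in seq_len(nrow(miss))) {
    qs <- miss$query_start[i]; qe <- miss$query_end[i]
    if (is.na(qs) || is.na(qe)) next
    mid <- (qs + qe) %/% 2L
    loop <- seg[seg$start <= mid & seg$end >= mid, , drop = FALSE]
    if (nrow(loop) != 1L ||
        !(loop$kind %in% c("inside_loop", "outside_loop")))
      stop(structure(
        class = c("inference_conflict", "error", "condition"),
        list(message = sprintf(
          "mapped span %d..%d for template helix %d does not sit in a loop",
          qs, qe, miss$template_helix[i]), call = sys.call())))
    start <- max(qs, loop$start)
    end <- min(qe, loop$end)
    if (end - start + 1L < min_insert) {
      need <- min_insert - (end - start + 1L)
      start <- max(loop$start, start - need)
      end <- min(loop$end, start + min_insert - 1L)
    }
    if (end - start + 1L < min_insert)
      stop(structure(
        class = c("inference_conflict", "error", "condition"),
        list(message = sprintf(
          "loop %d..%d too short to hold an inserted helix",
          loop$start, loop$end), call = sys.call())))
    ch <- unname(.char_for_kind[miss$template_kind[i]])
    chars[start:end] <- ch
  }
  s <- repair_topology_sides(paste(chars, collapse = ""), n_side)
  parse_topology_string(s, source = "final")
}

#' Transfer repeat and subdomain annotations from a template
#'
#' Each query helix aligned to a template helix inherits the template's
#' scaffold/core tag and repeat membership; unaligned query helices inherit
#' from the nearest aligned neighbour and are flagged as extrapolated. When
#' query N-terminal helices systematically align to template C-repeat
#' helices (and vice versa) a repeat-shuffle flag is set. The transfer is
#' refused when fewer than `min_aligned_fraction` of the template helices
#' are aligned.
#'
#' @param t_annotation template `repeat_annotation`.
#' @param t_topology template `topology`.
#' @param records [classify_helices()] records against the final query
#'   topology.
#' @param q_final query `topology` (post-inference).
#' @param min_aligned_fraction quality gate (default 0.5).
#' @return a `repeat_annotation` for the query with attributes
#'   `extrapolated` (logical per helix) and `shuffled` (logical flag).
#' @export
transfer_subdomains <- function(t_annotation, t_topology, records, q_final,
                                min_aligned_fraction = 0.5) {
  th <- helices(t_topology)
  qh <- helices(q_final)
  aligned <- records[records$class == "aligned", , drop = FALSE]
  if (nrow(aligned) / nrow(th) < min_aligned_fraction)
    stop(sprintf(
      "transfer refused: only %d/%d template helices aligned (< %.0f%%)",
      nrow(aligned), nrow(th), 100 * min_aligned_fraction))
  t_memb <- helix_repeat_membership(t_topology, t_annotation)
  q_tags <- rep(NA_character_, nrow(qh))
  q_repeat <- rep(NA_character_, nrow(qh))
  extrapolated <- rep(FALSE, nrow(qh))
  for (i in seq_len(nrow(aligned))) {
    qi <- aligned$query_helix[i]
    ti <- aligned$template_helix[i]
    q_tags[qi] <- t_annotation$helix_tags[ti]
    q_repeat[qi] <- t_memb[ti]
  }
  # shuffle detection: order of repeat tags along the query chain
  seen <- q_repeat[!is.na(q_repeat) & q_repeat != "linker"]
  shuffled <- length(seen) > 1L &&
    match("C", seen, nomatch = length(seen) + 1L) <
      match("N", seen, nomatch = length(seen) + 1L)
  # fill unaligned helices from the nearest aligned neighbour
  known <- which(!is.na(q_tags))
  if (length(known) == 0L) stop("no aligned helices to transfer from")
  for (j in which(is.na(q_tags))) {
    nb <- known[which.min(abs(known - j))]
    q_tags[j] <- q_tags[nb]
    q_repeat[j] <- q_repeat[nb]
    extrapolated[j] <- TRUE
  }
  span_of <- function(ru) {
    idx <- which(q_repeat == ru)
    c(min(qh$start[idx]), max(qh$end[idx]))
  }
  n_span <- span_of(if (shuffled) "C" else "N")
  c_span <- span_of(if (shuffled) "N" else "C")
  # spans must be orderable N before C on the query chain
  if (n_span[1] > c_span[1]) { tmp <- n_span; n_span <- c_span; c_span <- tmp }
  ord <- order(qh$start)
  ann <- repeat_annotation(n_repeat = n_span, c_repeat = c_span,
                           helix_tags = q_tags[ord],
                           helix_repeat = q_repeat[ord])
  attr(ann, "extrapolated") <- extrapolated[ord]
  attr(ann, "shuffled") <- shuffled
  ann
}

#' Best N-vs-C repeat similarity of a family
#'
#' Minimum E-value among self-hits between the N- and C-terminal repeat of
#' one family — lower values indicate a more recent internal duplication.
#'
#' @param self_hits data.frame with columns `query_role`, `hit_role`
#'   (`"N"`/`"C"`) and `e_value`.
#' @return the minimum N-vs-C `e_value`, or `NA_real_` when no such hit.
#' @export
repeat_similarity <- function(self_hits) {
  if (is.null(self_hits) || nrow(self_hits) == 0L) return(NA_real_)
  nc <- self_hits[(self_hits$query_role == "N" & self_hits$hit_role == "C") |
                    (self_hits$query_role == "C" & self_hits$hit_role == "N"),
                  , drop = FALSE]
  if (nrow(nc) == 0L) return(NA_real_)
  min(nc$e_value)
}

#' Read a hit table
#'
#' TSV with columns `query_id`, `template_id`, `e_value`, `identity`,
#' `q_aln`, `t_aln` (gapped strings).
#'
#' @param path file path.
#' @return list of `pairwise_alignment` objects.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    pairwise_alignment(tab$query_id[i], tab$template_id[i],
                       tab$q_aln[i], tab$t_aln[i],
                       e_value = tab$e_value[i], identity = tab$identity[i])
  })
}
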