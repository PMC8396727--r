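# End-to-end annotation pipeline: evolution-guided consensus -> subfamily
# handling -> template comparison and missing-helix inference -> subdomain
# transfer -> KR-bias validation, with a provenance record of every decision.

#' Annotate the topology of a family
#'
#' Runs the integrated annotation pipeline on one family: per-sequence
#' predicted topologies are projected onto the seed MSA, rows are reordered
#' by the tree, topology-consistent groups are detected and the largest
#' group's consensus becomes the "initial" topology; the structural template
#' then contributes any broken/reentrant helices the predictions missed
#' (yielding the "final" topology), its repeat/subdomain annotation is
#' transferred, and the result is validated by KR-bias model selection
#' between the chosen and the alternative non-canonical type.
#'
#' @param msa named character vector of gapped sequence rows (seed MSA).
#' @param predicted_topologies named per-row degapped per-residue topology
#'   strings.
#' @param tree optional `ape::phylo` over the row ids; without it grouping
#'   degrades to label equality (with a warning).
#' @param template list with `alignment` (`pairwise_alignment` of the
#'   representative against the template), `topology`, `annotation`
#'   (optional) and `type` (`"broken"`/`"reentrant"`) — e.g. the output of
#'   [make_structure_template()]. May be NULL to stop at the initial
#'   topology.
#' @param hits optional data.frame (`template_type`, `e_value`) of all
#'   structural hits; when given, the transporter type comes from the best
#'   (lowest-E-value) hit, with KR-bias arbitrating exact ties.
#' @param params a [kr_window_params()].
#' @param min_clade_fraction,min_group_size passed to
#'   [detect_topology_groups()].
#' @return an `annotation_result`: list with `initial`, `final`
#'   (`topology`), `label` (string), `annotation` (`repeat_annotation` or
#'   NULL), `kr_profile`, `partition`, `representative` and `provenance`
#'   (named list of the decisions taken).
#' @export
annotate_family <- function(msa, predicted_topologies, tree = NULL,
                            template = NULL, hits = NULL,
                            params = kr_window_params(),
                            min_clade_fraction = 0.75, min_group_size = 3L) {
  prov <- list()
  topo_rows <- vapply(names(msa), function(id) {
    project_topology(msa[[id]], predicted_topologies[[id]])
  }, character(1))
  mta <- multiple_topology_alignment(msa, topo_rows, tree = tree)
  if (!is.null(tree)) mta <- reorder_by_tree(mta)
  part <- detect_topology_groups(mta, min_clade_fraction, min_group_size)
  prov$n_groups <- length(part$groups)
  prov$split <- length(part$groups) > 1L
  prov$deviants <- part$deviants
  if (length(part$groups) == 0L)
    stop("no topology-consistent group found in the family")
  sizes <- vapply(part$groups, function(g) length(g$member_ids), integer(1))
  main <- part$groups[[which.max(sizes)]]
  prov$main_group_label <- main$label
  # the template alignment fixes the representative coordinates; fall back
  # to the least-gapped member when no template constrains the choice
  representative <- if (!is.null(template) &&
                        template$alignment$query_id %in% main$member_ids) {
    template$alignment$query_id
  } else {
    group_representative(mta, main$member_ids)
  }
  prov$representative <- representative
  initial <- consensus_topology(mta, main$member_ids,
                                representative = representative)
  result <- list(initial = initial, final = initial,
                 label = format(topology_label(initial)),
                 annotation = NULL, kr_profile = NULL, partition = part,
                 representative = representative)
  if (is.null(template)) {
    result$provenance <- prov
    return(structure(result, class = "annotation_result"))
  }
  # transporter type: best structural hit, KR-bias on exact tie
  type <- NULL
  if (!is.null(hits)) {
    type <- tryCatch(choose_transporter_type(hits),
                     error = function(e) {
                       if (inherits(e, "ambiguous_type")) NULL else stop(e)
                     })
    prov$type_source <- if (is.null(type)) "kr_arbitration" else "e_value"
  } else {
    type <- template$type
    prov$type_source <- "single_template"
  }
  records <- classify_helices(template$alignment, initial,
                              template$topology)
  missing_n <- sum(records$class %in% c("inside_loop", "outside_loop"))
  prov$missing_helices_added <- missing_n
  final <- if (missing_n > 0L) {
    infer_final_topology(initial, template$topology, records,
                         template$alignment)
  } else initial
  final$source <- "final"
  result$final <- final
  result$label <- format(topology_label(final))
  if (!is.null(template$annotation)) {
    records2 <- classify_helices(template$alignment, final,
                                 template$topology)
    result$annotation <- tryCatch(
      transfer_subdomains(template$annotation, template$topology,
                          records2, final),
      error = function(e) { prov$transfer_refused <<- conditionMessage(e)
        NULL })
  }
  # KR validation between the two non-canonical models
  lab <- topology_label(final)
  if (lab$noncanonical_kind != "none") {
    chosen_type <- if (lab$noncanonical_kind == "BH") "broken" else
      "reentrant"
    other_type <- setdiff(c("broken", "reentrant"), chosen_type)
    alt <- alternative_type_model(final)
    prof <- select_topology_model(
      msa, final, alt, representative = representative, params = params,
      model_names = c(chosen_type, other_type))
    result$kr_profile <- prof
    prov$kr_verdict <- prof$selected_model
    if (is.null(type) && prof$selected_model %in% c("broken", "reentrant"))
      type <- prof$selected_model
    prov$kr_conflict <- !is.null(type) && !is.na(type) &&
      prof$selected_model != "ambiguous" && prof$selected_model != type
    if (isTRUE(prov$kr_conflict))
      warning("E-value type (", type, ") and KR-bias verdict (",
              prof$selected_model, ") disagree")
  }
  prov$type <- type
  result$provenance <- prov
  structure(result, class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> label %s (initial %s)\n",
              x$label, format(topology_label(x$initial))))
  if (!is.null(x$provenance$type))
    cat("  type:", x$provenance$type,
        sprintf("(source: %s)", x$provenance$type_source), "\n")
  if (!is.null(x$kr_profile))
    cat("  KR verdict:", x$kr_profile$selected_model, "\n")
  invisible(x)
}

# ---- file formats -----------------------------------------------------------

#' Read/write the two-record topology FASTA format
#'
#' Each entry holds a sequence record (`>id`) immediately followed by a
#' same-length per-residue topology record (`>id|topology`).
#'
#' @param path file path.
#' @return named list with `seq` and `topo` named character vectors.
#' @export
read_topology_fasta <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  ids <- sub("^>", "", lines[heads])
  starts <- heads + 1L
  ends <- c(heads[-1] - 1L, length(lines))
  entries <- setNames(vapply(seq_along(heads), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1)), ids)
  topo <- grepl("\\|topology$", ids)
  seqs <- entries[!topo]
  topos <- entries[topo]
  names(topos) <- sub("\\|topology$", "", names(topos))
  stopifnot(identical(sort(names(seqs)), sort(names(topos))))
  list(seq = seqs, topo = topos[names(seqs)])
}

#' @rdname read_topology_fasta
#' @param seqs,topos parallel named character vectors.
#' @export
write_topology_fasta <- function(seqs, topos, path) {
  stopifnot(identical(sort(names(seqs)), sort(names(topos))))
  out <- unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]],
      paste0(">", id, "|topology"), topos[[id]])
  }))
  writeLines(out, path)
  invisible(path)
}
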