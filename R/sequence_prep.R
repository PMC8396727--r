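# Family-set preprocessing: domain-coverage filtering, redundancy removal,
# greedy identity clustering and the Meff effective-sequence count.

#' Pairwise sequence identity
#'
#' Fraction of identical aligned positions over the shorter ungapped length.
#' Pre-aligned inputs (equal length, `-` gaps) are compared column-wise;
#' unaligned inputs are first globally aligned with unit scores (match = 1,
#' everything else 0) via Biostrings.
#'
#' @param a,b sequences (plain strings), aligned or not.
#' @param aligned TRUE when `a` and `b` are rows of the same alignment.
#' @return identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, aligned = NULL) {
  if (is.null(aligned)) aligned <- nchar(a) == nchar(b) &&
      (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
  la <- nchar(gsub("-", "", a, fixed = TRUE))
  lb <- nchar(gsub("-", "", b, fixed = TRUE))
  if (la == 0L || lb == 0L) return(0)
  if (aligned && nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    matches <- sum(ca == cb & ca != "-")
  } else {
    ab <- unique(strsplit(paste0(gsub("-", "", a, fixed = TRUE),
                                 gsub("-", "", b, fixed = TRUE)), "")[[1]])
    unit <- diag(1, length(ab))
    dimnames(unit) <- list(ab, ab)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::BString(gsub("-", "", a, fixed = TRUE)),
      Biostrings::BString(gsub("-", "", b, fixed = TRUE)),
      type = "global", substitutionMatrix = unit,
      gapOpening = 0, gapExtension = 0)
    sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    matches <- sum(sa == sb & sa != "-")
  }
  matches / min(la, lb)
}

#' Filter a family sequence set
#'
#' Applies the two preprocessing rules used to build seed family sets:
#' sequences covering less than 75% of the annotated domain are removed as
#' `low_coverage` (fragments), and of any pair above 90% identity the later
#' sequence in scan order is removed as `redundant`. Thresholds follow the
#' printed inequalities: coverage `>= min_coverage` is kept, identity strictly
#' `> max_identity` is removed.
#'
#' @param records data.frame with columns `id`, `residues`,
#'   `domain_start`, `domain_end`.
#' @param domain_length length of the reference domain.
#' @param min_coverage minimum domain coverage kept (default 0.75).
#' @param max_identity maximum pairwise identity kept (default 0.90).
#' @return a `filter_report`: list with `kept` (ids) and `removed`
#'   (data.frame id, reason in `fragment`/`low_coverage`/`redundant`).
#' @export
filter_family <- function(records, domain_length, min_coverage = 0.75,
                          max_identity = 0.90) {
  stopifnot(domain_length > 0)
  if (nrow(records) == 0L)
    return(structure(list(kept = character(),
                          removed = data.frame(id = character(),
                                               reason = character())),
                     class = "filter_report"))
  span <- records$domain_end - records$domain_start + 1L
  coverage <- span / domain_length
  low <- coverage < min_coverage
  removed <- data.frame(id = records$id[low],
                        reason = rep("low_coverage", sum(low)))
  keep <- records[!low, , drop = FALSE]
  kept_ids <- character()
  kept_seqs <- character()
  for (i in seq_len(nrow(keep))) {
    red <- FALSE
    for (j in seq_along(kept_seqs)) {
      if (pairwise_identity(kept_seqs[j], keep$residues[i]) > max_identity) {
        red <- TRUE; break
      }
    }
    if (red) {
      removed <- rbind(removed,
                       data.frame(id = keep$id[i], reason = "redundant"))
    } else {
      kept_ids <- c(kept_ids, keep$id[i])
      kept_seqs <- c(kept_seqs, keep$residues[i])
    }
  }
  structure(list(kept = kept_ids, removed = removed), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d, removed %d (%s)\n",
              length(x$kept), nrow(x$removed),
              paste(names(table(x$removed$reason)), table(x$removed$reason),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Greedy identity clustering
#'
#' cd-hit-style greedy scheme: sequences are scanned in descending length
#' order (ties by id), each becoming a member of the first existing cluster
#' whose centroid it matches at or above the identity threshold, otherwise
#' founding a new cluster. Centroids are therefore mutually below the
#' threshold under the scan order, and clustering is deterministic.
#'
#' @param seqs named character vector of sequences (aligned rows or plain).
#' @param identity_threshold clustering identity in `(0, 1)`.
#' @param aligned treat sequences as rows of one alignment (identity by
#'   column, over the shorter ungapped length).
#' @return list of clusters, each `list(centroid = id, members = ids)`.
#' @export
greedy_cluster <- function(seqs, identity_threshold, aligned = FALSE) {
  stopifnot(identity_threshold > 0, identity_threshold < 1)
  if (length(seqs) == 0L) return(list())
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ung <- nchar(gsub("-", "", seqs, fixed = TRUE))
  ord <- order(-ung, names(seqs))
  seqs <- seqs[ord]
  clusters <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      cen <- clusters[[k]]$centroid
      if (pairwise_identity(seqs[[cen]], seqs[[i]],
                            aligned = aligned) >= identity_threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, names(seqs)[i])
        placed <- TRUE; break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <-
        list(centroid = names(seqs)[i], members = names(seqs)[i])
  }
  clusters
}

#' Effective number of sequences (Meff)
#'
#' Number of clusters obtained by greedy clustering of the alignment rows at
#' 62% ungapped pairwise identity — the usual measure of alignment depth for
#' contact prediction.
#'
#' @param msa named character vector of equal-length aligned rows.
#' @param identity_threshold clustering identity (default 0.62).
#' @return integer cluster count; a single-row alignment gives 1.
#' @export
compute_meff <- function(msa, identity_threshold = 0.62) {
  stopifnot(length(msa) >= 1L)
  if (length(unique(nchar(msa))) != 1L)
    stop("alignment rows must all have the same aligned length")
  if (length(msa) == 1L) return(1L)
  length(greedy_cluster(msa, identity_threshold, aligned = TRUE))
}
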