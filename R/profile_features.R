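# Core-helix sequence features: sub-MSA extraction for the non-canonical
# (broken/reentrant) helix of each repeat, position frequency/information
# matrices, and an additive insertion free-energy (dG) score.

#' Extract the core-helix sub-alignment of one repeat
#'
#' Slices out the columns spanned, on the representative row, by the
#' non-canonical (broken or reentrant) helix of the chosen repeat — the
#' middle helix of that repeat's core subdomain. Gap-only columns inside the
#' span are retained.
#'
#' @param msa named character vector of aligned rows.
#' @param rep_topology representative `topology` (degapped coordinates of
#'   `representative`).
#' @param annotation `repeat_annotation` for the representative.
#' @param repeat_unit `"N"` or `"C"`.
#' @param representative row id carrying the topology (default first row).
#' @return list with `msa` (sliced rows) and `columns` (original column
#'   indices).
#' @export
extract_core_helix_submsa <- function(msa, rep_topology, annotation,
                                      repeat_unit = c("N", "C"),
                                      representative = names(msa)[1]) {
  repeat_unit <- match.arg(repeat_unit)
  h <- helices(rep_topology)
  memb <- helix_repeat_membership(rep_topology, annotation)
  idx <- which(memb == repeat_unit &
                 h$kind %in% c("broken_helix", "reentrant_helix"))
  if (length(idx) == 0L)
    stop("no non-canonical core helix in repeat ", repeat_unit)
  span <- c(h$start[idx[1]], h$end[idx[1]])
  rep_chars <- strsplit(msa[[representative]], "", fixed = TRUE)[[1]]
  res_cols <- which(rep_chars != "-")
  cols <- res_cols[span[1]]:res_cols[span[2]]
  sliced <- vapply(msa, function(row) {
    paste(strsplit(row, "", fixed = TRUE)[[1]][cols], collapse = "")
  }, character(1))
  list(msa = sliced, columns = cols, helix_span = span)
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Position frequency and information-content matrix
#'
#' Per-column amino-acid frequencies (gaps excluded from the denominator)
#' with a uniform pseudocount, plus the per-column information content in
#' bits, `IC = log2(20) - H` with `H` the Shannon entropy of the column.
#'
#' @param sub_msa character vector of equal-length aligned rows.
#' @param pseudocount added to each of the 20 cells per column
#'   (default 0.025 = 0.5/20).
#' @return a `motif_matrix`: list with `freq` (positions x 20),
#'   `ic` (bits per position) and `n_sequences`.
#' @export
motif <- function(sub_msa, pseudocount = 0.5 / 20) {
  stopifnot(length(sub_msa) >= 1L)
  mat <- do.call(rbind, strsplit(sub_msa, ""))
  ncolu <- ncol(mat)
  freq <- matrix(0, nrow = ncolu, ncol = length(AMINO_ACIDS),
                 dimnames = list(NULL, AMINO_ACIDS))
  ic <- numeric(ncolu)
  for (j in seq_len(ncolu)) {
    counts <- table(factor(mat[, j], levels = AMINO_ACIDS))
    f <- (as.numeric(counts) + pseudocount)
    f <- f / sum(f)
    freq[j, ] <- f
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic[j] <- log2(20) - h
  }
  structure(list(freq = freq, ic = ic, n_sequences = length(sub_msa)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %d positions, %d sequences, mean IC %.2f bits\n",
              nrow(x$freq), x$n_sequences, mean(x$ic)))
  invisible(x)
}

.dg_scale <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "dg_insertion_scale.tsv",
                          package = "cpatopo")
      tab <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
      cache <<- stats::setNames(tab$dg_app, tab$residue)
    }
    cache
  }
})

#' Additive insertion free energy of a helix
#'
#' Sum of per-residue contributions from the packaged biological
#' hydrophobicity scale (position-independent form; see
#' `inst/extdata/dg_insertion_scale.tsv` for the source of the
#' coefficients). Lower (more negative) values mean more favourable membrane
#' insertion; reentrant cores typically score higher (less hydrophobic) than
#' true TM helices.
#'
#' @param helix_residues residue string, 9 to 40 residues.
#' @return numeric score on the kcal/mol scale.
#' @export
delta_g <- function(helix_residues) {
  stopifnot(is.character(helix_residues), length(helix_residues) == 1L)
  n <- nchar(helix_residues)
  if (n == 0L) stop("empty helix")
  if (n < 9L || n > 40L)
    stop("helix length ", n, " outside the supported range 9..40")
  chars <- strsplit(helix_residues, "", fixed = TRUE)[[1]]
  scale <- .dg_scale()
  known <- chars %in% names(scale)
  if (!all(known)) {
    warning("skipping non-standard residues: ",
            paste(unique(chars[!known]), collapse = ", "))
    chars <- chars[known]
  }
  sum(scale[chars])
}

#' Per-fold-type summaries of core-helix features
#'
#' For labelled groups of core-helix sequences, summarises the distribution
#' of insertion free energy and of glycine/proline content — the features
#' separating reentrant from broken cores.
#'
#' @param families named list: one character vector of (degapped) core-helix
#'   sequences per group.
#' @return data.frame with one row per group: mean/quantiles of `delta_g`
#'   and mean G/P frequency.
#' @export
fold_type_feature_summary <- function(families) {
  stopifnot(length(families) >= 2L)
  out <- lapply(names(families), function(nm) {
    seqs <- families[[nm]]
    seqs <- seqs[nchar(seqs) >= 9L & nchar(seqs) <= 40L]
    dg <- vapply(seqs, delta_g, numeric(1))
    gp <- vapply(seqs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      mean(ch %in% c("G", "P"))
    }, numeric(1))
    data.frame(group = nm, n = length(seqs),
               dg_mean = mean(dg), dg_q25 = unname(quantile(dg, 0.25)),
               dg_q75 = unname(quantile(dg, 0.75)),
               gly_pro_freq = mean(gp))
  })
  do.call(rbind, out)
}
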