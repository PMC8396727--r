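# Per-residue topology alphabet:
#   i  inside (cytoplasmic) loop
#   o  outside (extracytoplasmic) loop
#   M  transmembrane helix
#   B  broken helix (crosses the membrane, discontinuity mid-bilayer)
#   R  reentrant helix (enters and exits on the same side)
#   S  signal peptide (N-terminal, crosses once, excluded from helix counts)

TOPO_CHARS <- c("i", "o", "M", "B", "R", "S")
HELIX_KINDS <- c("tm_helix", "broken_helix", "reentrant_helix")
CROSSING_KINDS <- c("tm_helix", "broken_helix", "signal_peptide")

.kind_for_char <- c(i = "inside_loop", o = "outside_loop", M = "tm_helix",
                    B = "broken_helix", R = "reentrant_helix",
                    S = "signal_peptide")
.char_for_kind <- c(inside_loop = "i", outside_loop = "o", tm_helix = "M",
                    broken_helix = "B", reentrant_helix = "R",
                    signal_peptide = "S")

#' Construct a membrane topology object
#'
#' A `topology` is an ordered, contiguous, 1-based inclusive segmentation of a
#' protein chain into inside/outside loops, transmembrane (TM) helices, broken
#' helices, reentrant helices and an optional N-terminal signal peptide.
#' Loop sides must alternate consistently with the membrane crossings: TM and
#' broken helices (and signal peptides) flip the side, reentrant helices
#' return to their entry side.
#'
#' @param segments data.frame with columns `kind`, `start`, `end`,
#'   `orientation` (`in_to_out`/`out_to_in`/`none`), `reentrant_side`
#'   (`in_in`/`out_out`/`none`) and `break_pos` (NA except for broken helices).
#' @param chain_length total residue count covered by the segments.
#' @param source one of `"predicted"`, `"consensus"`, `"template"`, `"final"`.
#' @param validate run the structural validator (default TRUE).
#' @return an object of class `topology`.
#' @export
topology <- function(segments, chain_length = max(segments$end),
                     source = "predicted", validate = TRUE) {
  stopifnot(is.data.frame(segments))
  needed <- c("kind", "start", "end", "orientation", "reentrant_side",
              "break_pos")
  for (col in setdiff(needed, names(segments))) {
    segments[[col]] <- switch(col,
      orientation = "none", reentrant_side = "none", break_pos = NA_integer_,
      stop("segments missing column: ", col))
  }
  t <- structure(
    list(chain_length = as.integer(chain_length),
         segments = segments[, needed],
         source = match.arg(source,
                            c("predicted", "consensus", "template", "final"))),
    class = "topology")
  if (validate) validate_topology(t)
  t
}

#' Validate a topology object
#'
#' Checks contiguity, coverage, side alternation and segment-level invariants.
#' Throws a condition of class `topology_inconsistency` naming the offending
#' segment when a check fails.
#'
#' @param t a `topology`.
#' @return `t`, invisibly.
#' @export
validate_topology <- function(t) {
  seg <- t$segments
  fail <- function(msg, idx = NA_integer_) {
    stop(structure(class = c("topology_inconsistency", "error", "condition"),
                   list(message = sprintf("%s [segment %s]", msg, idx),
                        call = sys.call(-1), segment = idx)))
  }
  if (nrow(seg) == 0L) fail("topology has no segments")
  if (seg$start[1] != 1L) fail("first segment must start at residue 1", 1L)
  if (seg$end[nrow(seg)] != t$chain_length)
    fail("last segment must end at chain_length", nrow(seg))
  if (any(seg$start > seg$end)) fail("segment with start > end",
                                     which(seg$start > seg$end)[1])
  if (nrow(seg) > 1L && any(seg$start[-1] != seg$end[-nrow(seg)] + 1L))
    fail("segments not contiguous",
         which(seg$start[-1] != seg$end[-nrow(seg)] + 1L)[1] + 1L)
  loopish <- seg$kind %in% c("inside_loop", "outside_loop")
  if (any(loopish[-1] & loopish[-length(loopish)]))
    fail("adjacent loop segments must be merged",
         which(loopish[-1] & loopish[-length(loopish)])[1] + 1L)
  helixish <- !loopish
  if (any(helixish[-1] & helixish[-length(helixish)]))
    fail("two helices without an intervening loop",
         which(helixish[-1] & helixish[-length(helixish)])[1] + 1L)
  # broken helix bookkeeping
  bh <- which(seg$kind == "broken_helix" & !is.na(seg$break_pos))
  for (i in bh) {
    if (seg$break_pos[i] <= seg$start[i] || seg$break_pos[i] >= seg$end[i])
      fail("break_pos must lie strictly inside the broken helix", i)
  }
  # side alternation: walk from the N-terminal side
  side <- .first_side(seg)
  for (i in seq_len(nrow(seg))) {
    k <- seg$kind[i]
    if (k == "inside_loop" && side != "in")
      fail("inside loop on the outside face (side alternation violated)", i)
    if (k == "outside_loop" && side != "out")
      fail("outside loop on the inside face (side alternation violated)", i)
    if (k %in% CROSSING_KINDS) {
      expect_or <- if (side == "in") "in_to_out" else "out_to_in"
      if (!is.na(seg$orientation[i]) && seg$orientation[i] != "none" &&
          seg$orientation[i] != expect_or)
        fail(sprintf("crossing helix orientation %s inconsistent with side %s",
                     seg$orientation[i], side), i)
      side <- if (side == "in") "out" else "in"
    }
    if (k == "reentrant_helix") {
      expect_rs <- if (side == "in") "in_in" else "out_out"
      if (!is.na(seg$reentrant_side[i]) && seg$reentrant_side[i] != "none" &&
          seg$reentrant_side[i] != expect_rs)
        fail("reentrant helix does not return to its entry side", i)
    }
  }
  invisible(t)
}

.first_side <- function(seg) {
  # N-terminal side: side of the first loop, walked back over any preceding
  # crossings (signal peptide before the first loop flips once).
  first_loop <- match(TRUE, seg$kind %in% c("inside_loop", "outside_loop"))
  if (is.na(first_loop)) stop("topology contains no loop segment")
  side <- if (seg$kind[first_loop] == "inside_loop") "in" else "out"
  if (first_loop > 1L) {
    ncross <- sum(seg$kind[seq_len(first_loop - 1L)] %in% CROSSING_KINDS)
    if (ncross %% 2L == 1L) side <- if (side == "in") "out" else "in"
  }
  side
}

#' Parse a per-residue topology string
#'
#' Accepts TOPCONS-style per-residue annotation over the alphabet
#' `{i, o, M, B, R, S}` and reconstructs the segment structure, validating
#' loop-side alternation (a TM or broken helix flips the side, a reentrant
#' helix returns to its entry side). Helix runs shorter than 5 residues are
#' rejected; TM runs shorter than 12 residues trigger a warning.
#'
#' @param s per-residue topology string.
#' @param source source tag for the resulting topology.
#' @param min_helix minimum accepted helix run length (default 5).
#' @return a `topology`.
#' @export
parse_topology_string <- function(s, source = "predicted", min_helix = 5L) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), TOPO_CHARS)
  if (length(bad))
    stop("invalid topology characters: ", paste(bad, collapse = ", "))
  r <- rle(chars)
  n <- length(r$values)
  start <- cumsum(c(1L, r$lengths[-n]))
  end <- cumsum(r$lengths)
  kind <- unname(.kind_for_char[r$values])
  if (kind[1] %in% HELIX_KINDS || kind[n] %in% HELIX_KINDS)
    stop(structure(class = c("topology_inconsistency", "error", "condition"),
                   list(message = "helix runs must be flanked by loop runs",
                        call = sys.call())))
  short <- kind %in% HELIX_KINDS & r$lengths < min_helix
  if (any(short))
    stop(sprintf("helix run of %d residues at %d..%d below minimum of %d",
                 r$lengths[which(short)[1]], start[which(short)[1]],
                 end[which(short)[1]], min_helix))
  if (any(kind == "tm_helix" & r$lengths < 12L))
    warning("TM helix run shorter than 12 residues")
  seg <- data.frame(kind = kind, start = start, end = end,
                    orientation = "none", reentrant_side = "none",
                    break_pos = NA_integer_, stringsAsFactors = FALSE)
  # derive orientations from the walked side; validate_topology re-checks
  side <- .first_side(seg)
  for (i in seq_len(n)) {
    k <- seg$kind[i]
    if (k %in% CROSSING_KINDS) {
      seg$orientation[i] <- if (side == "in") "in_to_out" else "out_to_in"
      side <- if (side == "in") "out" else "in"
    } else if (k == "reentrant_helix") {
      seg$reentrant_side[i] <- if (side == "in") "in_in" else "out_out"
    }
  }
  seg$break_pos[seg$kind == "broken_helix"] <-
    as.integer((seg$start + seg$end) %/% 2L)[seg$kind == "broken_helix"]
  topology(seg, chain_length = length(chars), source = source)
}

#' Serialize a topology back to its per-residue string
#'
#' Inverse of [parse_topology_string()]: `serialize_topology(parse_topology_string(s))`
#' is the identity on valid strings.
#'
#' @param t a `topology`.
#' @return a single string over `{i, o, M, B, R, S}`.
#' @export
serialize_topology <- function(t) {
  seg <- t$segments
  paste(rep(unname(.char_for_kind[seg$kind]), seg$end - seg$start + 1L),
        collapse = "")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d residues, %d segments, source=%s\n",
              x$chain_length, nrow(x$segments), x$source))
  lab <- tryCatch(format(topology_label(x)), error = function(e) NA_character_)
  if (!is.na(lab)) cat("  label:", lab, "\n")
  print(x$segments, ...)
  invisible(x)
}

#' Helix table of a topology
#'
#' @param t a `topology`.
#' @param include_signal include signal peptides (default FALSE).
#' @return data.frame of helix segments with a `helix_index` column numbering
#'   helices N- to C-terminally (signal peptides never counted).
#' @export
helices <- function(t, include_signal = FALSE) {
  seg <- t$segments
  keep <- seg$kind %in% HELIX_KINDS
  h <- seg[keep, , drop = FALSE]
  h$helix_index <- seq_len(nrow(h))
  h$segment_index <- which(keep)
  if (include_signal) {
    sp <- seg[seg$kind == "signal_peptide", , drop = FALSE]
    if (nrow(sp)) {
      sp$helix_index <- NA_integer_
      sp$segment_index <- which(seg$kind == "signal_peptide")
      h <- rbind(sp, h)
    }
  }
  rownames(h) <- NULL
  h
}

# ---- topology label algebra -------------------------------------------------

#' Topology label of a chain
#'
#' All membrane helices — transmembrane plus the non-canonical broken (BH) or
#' reentrant (RH) helices — are counted, and the orientation is assigned from
#' the side of the N-terminus. Serializes as `"<n>H[-<m>BH|-<m>RH]-Nin|Nout"`,
#' e.g. `"10H-2BH-Nin"`. Chains mixing broken and reentrant helices are not
#' supported (no known family does).
#'
#' @param t a `topology`.
#' @return a `topology_label` with fields `n_canonical`, `n_noncanonical`,
#'   `noncanonical_kind` (`"BH"`, `"RH"` or `"none"`) and `n_term_side`
#'   (`"Nin"`/`"Nout"`).
#' @export
topology_label <- function(t) {
  seg <- t$segments
  n_tm <- sum(seg$kind == "tm_helix")
  n_bh <- sum(seg$kind == "broken_helix")
  n_rh <- sum(seg$kind == "reentrant_helix")
  if (n_tm + n_bh + n_rh == 0L)
    stop("topology contains no membrane helices; no label defined")
  if (n_bh > 0L && n_rh > 0L)
    stop(structure(
      class = c("unsupported_mixture", "error", "condition"),
      list(message = "chain mixes broken and reentrant helices; unsupported",
           call = sys.call())))
  side <- .first_side(seg)
  new_topology_label(
    n_canonical = n_tm,
    n_noncanonical = n_bh + n_rh,
    noncanonical_kind = if (n_bh > 0L) "BH" else if (n_rh > 0L) "RH" else "none",
    n_term_side = if (side == "in") "Nin" else "Nout")
}

new_topology_label <- function(n_canonical, n_noncanonical, noncanonical_kind,
                               n_term_side) {
  structure(list(n_canonical = as.integer(n_canonical),
                 n_noncanonical = as.integer(n_noncanonical),
                 noncanonical_kind = noncanonical_kind,
                 n_term_side = n_term_side),
            class = "topology_label")
}

#' Parse a serialized topology label
#'
#' Accepts the canonical plain-text form `"<n>H[-<m>BH|-<m>RH]-Nin|Nout"`
#' (subscript markup such as `N_in_` is normalised away).
#'
#' @param s label string, e.g. `"8H-2BH-Nin"`.
#' @return a `topology_label`.
#' @export
parse_topology_label <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  x <- gsub("[_ ]", "", s)
  m <- regmatches(x, regexec("^([0-9]+)H(?:-([0-9]+)(BH|RH))?-N(in|out)$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse topology label: ", s)
  new_topology_label(
    n_canonical = as.integer(m[2]),
    n_noncanonical = if (nzchar(m[3])) as.integer(m[3]) else 0L,
    noncanonical_kind = if (nzchar(m[4])) m[4] else "none",
    n_term_side = paste0("N", m[5]))
}

#' @export
format.topology_label <- function(x, ...) {
  core <- paste0(x$n_canonical, "H")
  if (x$n_noncanonical > 0L)
    core <- paste0(core, "-", x$n_noncanonical, x$noncanonical_kind)
  paste0(core, "-", x$n_term_side)
}

#' @export
print.topology_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.topology_label <- function(x, ...) format(x)

#' Total helix count of a label
#'
#' Canonical plus non-canonical helices, the number a label like
#' `"8H-2BH-Nin"` summarises (here 10).
#'
#' @param label a `topology_label` or label string.
#' @return integer count.
#' @export
total_helix_count <- function(label) {
  if (is.character(label)) label <- parse_topology_label(label)
  label$n_canonical + label$n_noncanonical
}

#' Number of membrane crossings
#'
#' TM and broken helices cross the membrane; reentrant helices do not and are
#' excluded. Signal peptides are not counted.
#'
#' @param t a `topology`.
#' @return integer count.
#' @export
membrane_crossing_count <- function(t) {
  sum(t$segments$kind %in% c("tm_helix", "broken_helix"))
}

# ---- repeat / subdomain annotation ------------------------------------------

#' Repeat and subdomain annotation
#'
#' CPA/AT-like transporters are built from two inverted internal repeat units,
#' each contributing a scaffold and a core subdomain. The annotation records
#' the residue span of the N- and C-terminal repeat and a scaffold/core tag
#' per membrane helix.
#'
#' @param n_repeat integer length-2 vector `(start, end)` of the N repeat.
#' @param c_repeat integer length-2 vector `(start, end)` of the C repeat.
#' @param helix_tags character vector, one of `"scaffold"`/`"core"` per helix
#'   (indexed as in [helices()]).
#' @param helix_repeat optional character vector `"N"`/`"C"` per helix; when
#'   omitted it is derived from the repeat spans at use time.
#' @return a `repeat_annotation`.
#' @export
repeat_annotation <- function(n_repeat, c_repeat, helix_tags,
                              helix_repeat = NULL) {
  stopifnot(length(n_repeat) == 2L, length(c_repeat) == 2L,
            n_repeat[1] <= n_repeat[2], c_repeat[1] <= c_repeat[2],
            n_repeat[2] < c_repeat[1],
            all(helix_tags %in% c("scaffold", "core")))
  if (!is.null(helix_repeat))
    stopifnot(length(helix_repeat) == length(helix_tags),
              all(helix_repeat %in% c("N", "C")))
  structure(list(n_repeat = as.integer(n_repeat),
                 c_repeat = as.integer(c_repeat),
                 helix_tags = helix_tags,
                 helix_repeat = helix_repeat),
            class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat(sprintf("<repeat_annotation> N %d..%d, C %d..%d\n",
              x$n_repeat[1], x$n_repeat[2], x$c_repeat[1], x$c_repeat[2]))
  cat("  helix tags:", paste(x$helix_tags, collapse = " "), "\n")
  invisible(x)
}

#' Repeat membership of each helix
#'
#' @param t a `topology`.
#' @param ann a `repeat_annotation`.
#' @return character vector per helix: `"N"`, `"C"` or `"linker"` (outside
#'   both repeats), taken from `ann$helix_repeat` when present, else by the
#'   repeat span containing the helix midpoint.
#' @export
helix_repeat_membership <- function(t, ann) {
  h <- helices(t)
  if (!is.null(ann$helix_repeat)) {
    if (length(ann$helix_repeat) != nrow(h))
      stop("annotation lists ", length(ann$helix_repeat),
           " helix repeat entries for a topology with ", nrow(h),
           " helices")
    return(ann$helix_repeat)
  }
  mid <- (h$start + h$end) %/% 2L
  ifelse(mid >= ann$n_repeat[1] & mid <= ann$n_repeat[2], "N",
         ifelse(mid >= ann$c_repeat[1] & mid <= ann$c_repeat[2], "C",
                "linker"))
}

#' Split a topology into its two repeat units
#'
#' Cuts the chain at the repeat boundaries, which must fall in loop segments,
#' and returns the two sub-topologies in absolute chain coordinates. For an
#' inverted repeat pair the two units start on opposite sides of the membrane.
#'
#' @param t a `topology`.
#' @param ann a `repeat_annotation` whose spans lie inside loop segments.
#' @return list of two `topology` objects with attributes `range` giving the
#'   absolute residue span each covers.
#' @export
split_repeats <- function(t, ann) {
  lapply(list(ann$n_repeat, ann$c_repeat), function(span) {
    subset_topology(t, span[1], span[2])
  })
}

#' Extract a sub-topology over a residue range
#'
#' Both boundaries must fall inside loop segments (cutting through a helix is
#' a boundary error). Segment coordinates are rebased to 1 and the original
#' absolute span is kept in the `range` attribute.
#'
#' @param t a `topology`.
#' @param from,to 1-based inclusive residue bounds.
#' @return a `topology` covering `to - from + 1` residues.
#' @export
subset_topology <- function(t, from, to) {
  stopifnot(from >= 1L, to <= t$chain_length, from <= to)
  seg <- t$segments
  for (p in c(from, to)) {
    i <- which(seg$start <= p & seg$end >= p)
    if (!(seg$kind[i] %in% c("inside_loop", "outside_loop")))
      stop(structure(
        class = c("boundary_error", "error", "condition"),
        list(message = sprintf(
          "repeat boundary at residue %d falls inside a %s (%d..%d)",
          p, seg$kind[i], seg$start[i], seg$end[i]), call = sys.call())))
  }
  keep <- seg$end >= from & seg$start <= to
  sub <- seg[keep, , drop = FALSE]
  sub$start <- pmax(sub$start, from) - from + 1L
  sub$end <- pmin(sub$end, to) - from + 1L
  sub$break_pos <- ifelse(is.na(sub$break_pos), NA_integer_,
                          sub$break_pos - from + 1L)
  out <- topology(sub, chain_length = to - from + 1L, source = t$source)
  attr(out, "range") <- c(from, to)
  out
}

# ---- side repair ------------------------------------------------------------

#' Re-propagate loop sides from the N-terminus
#'
#' Keeps helix runs (M/B/R/S) fixed and rewrites every loop character by
#' walking from the given N-terminal side: TM, broken and signal runs flip the
#' side, reentrant runs keep it. This is the orientation-correction primitive
#' used after inserting or deleting helices.
#'
#' @param s per-residue topology string (possibly with inconsistent sides).
#' @param n_term_side `"in"` or `"out"`; default takes the first character's
#'   side (first loop run) of `s`.
#' @return a valid per-residue topology string.
#' @export
repair_topology_sides <- function(s, n_term_side = NULL) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  loop_runs <- which(r$values %in% c("i", "o"))
  if (length(loop_runs) == 0L) stop("no loop runs to anchor side repair")
  if (is.null(n_term_side)) {
    first <- r$values[loop_runs[1]]
    n_term_side <- if (first == "i") "in" else "out"
    # crossings before the first loop flip the anchor back to the N-terminus
    pre <- r$values[seq_len(loop_runs[1] - 1L)]
    if (sum(pre %in% c("M", "B", "S")) %% 2L == 1L)
      n_term_side <- if (n_term_side == "in") "out" else "in"
  }
  side <- n_term_side
  for (j in seq_along(r$values)) {
    v <- r$values[j]
    if (v %in% c("i", "o")) {
      r$values[j] <- if (side == "in") "i" else "o"
    } else if (v %in% c("M", "B", "S")) {
      side <- if (side == "in") "out" else "in"
    }
  }
  paste(inverse.rle(r), collapse = "")
}

#' Flip every side of a topology
#'
#' Inside loops become outside loops and vice versa; helix runs are kept.
#' Useful for orientation (Nin vs Nout) comparisons and KR-bias antisymmetry
#' checks.
#'
#' @param t a `topology` or per-residue string.
#' @return same type as the input.
#' @export
flip_topology_sides <- function(t) {
  if (is.character(t)) return(chartr("io", "oi", t))
  parse_topology_string(chartr("io", "oi", serialize_topology(t)),
                        source = t$source)
}

#' Swap the non-canonical helix type of a topology model
#'
#' Rewrites broken helices as reentrant or vice versa, then re-propagates the
#' loop sides from the N-terminus (a broken helix crosses, a reentrant does
#' not, so all downstream sides change). Used to build the two alternative
#' topology models compared by KR-bias.
#'
#' @param t a `topology`.
#' @return a `topology` with the opposite non-canonical type.
#' @export
alternative_type_model <- function(t) {
  s <- serialize_topology(t)
  lab <- topology_label(t)
  if (lab$noncanonical_kind == "none")
    stop("topology has no non-canonical helices to swap")
  s2 <- if (lab$noncanonical_kind == "BH") chartr("B", "R", s) else
    chartr("R", "B", s)
  side <- if (lab$n_term_side == "Nin") "in" else "out"
  parse_topology_string(repair_topology_sides(s2, side), source = t$source)
}
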