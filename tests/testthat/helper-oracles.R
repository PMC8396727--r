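# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: naive enumeration, direct position-set arithmetic, and a
# hand-rolled newick reader.

# --- helix alignment classification: direct per-column enumeration ----------
oracle_classify <- function(aln, q_topo, t_topo, min_overlap = 5) {
  qc <- strsplit(aln$q_aln, "")[[1]]
  tc <- strsplit(aln$t_aln, "")[[1]]
  q_pos <- cumsum(qc != "-"); q_pos[qc == "-"] <- NA
  t_pos <- cumsum(tc != "-"); t_pos[tc == "-"] <- NA
  t_chars <- strsplit(serialize_topology(t_topo), "")[[1]]
  q_chars <- strsplit(serialize_topology(q_topo), "")[[1]]
  # enumerate template helices naively from the char string
  runs <- rle(t_chars)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  helix_rows <- which(runs$values %in% c("M", "B", "R"))
  q_runs <- rle(q_chars)
  q_ends <- cumsum(q_runs$lengths); q_starts <- q_ends - q_runs$lengths + 1
  q_helix <- which(q_runs$values %in% c("M", "B", "R"))
  out <- character(length(helix_rows))
  for (hi in seq_along(helix_rows)) {
    span <- starts[helix_rows[hi]]:ends[helix_rows[hi]]
    cols <- which(!is.na(t_pos) & t_pos %in% span)
    best <- 0
    for (qi in q_helix) {
      qspan <- q_starts[qi]:q_ends[qi]
      ov <- sum(!is.na(q_pos[cols]) & q_pos[cols] %in% qspan)
      best <- max(best, ov)
    }
    if (best >= min_overlap) { out[hi] <- "aligned"; next }
    votes <- c(gap = 0, inside_loop = 0, outside_loop = 0,
               signal_peptide = 0)
    for (cc in cols) {
      p <- q_pos[cc]
      if (is.na(p)) votes["gap"] <- votes["gap"] + 1
      else if (q_chars[p] == "i")
        votes["inside_loop"] <- votes["inside_loop"] + 1
      else if (q_chars[p] == "o")
        votes["outside_loop"] <- votes["outside_loop"] + 1
      else if (q_chars[p] == "S")
        votes["signal_peptide"] <- votes["signal_peptide"] + 1
    }
    out[hi] <- names(votes)[which.max(votes)]
  }
  out
}

# --- KR windows: brute-force per-position membership -------------------------
oracle_kr_counts <- function(seq, topo_string, depth = 10, extent = 25) {
  chars <- strsplit(topo_string, "")[[1]]
  runs <- rle(chars)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  inside <- integer(); outside <- integer()
  mark <- function(side, pos) {
    if (side == "i") inside <<- c(inside, pos) else
      outside <<- c(outside, pos)
  }
  helix <- which(runs$values %in% c("M", "B", "R"))
  if (length(helix)) {
    h1 <- helix[1]
    if (h1 > 1) {
      tail_start <- starts[h1 - 1]
      side <- runs$values[h1 - 1]
      pos <- tail_start:min(tail_start + extent - 1, ends[h1 - 1])
      pos <- c(pos, starts[h1]:min(starts[h1] + depth - 1, ends[h1]))
      mark(side, pos)
    }
    for (j in helix) {
      if (j == length(runs$values)) next
      side <- runs$values[j + 1]
      if (!(side %in% c("i", "o"))) next
      d <- min(depth, runs$lengths[j])
      pos <- (ends[j] - d + 1):ends[j]
      nxt_helix_start <- if (any(helix > j))
        starts[min(helix[helix > j])] else nchar(topo_string) + 1
      pos <- c(pos, (ends[j] + 1):min(ends[j] + extent, nxt_helix_start - 1))
      mark(side, pos)
    }
  }
  sc <- strsplit(seq, "")[[1]]
  c(inside = sum(sc[unique(inside)] %in% c("K", "R")),
    outside = sum(sc[unique(outside)] %in% c("K", "R")))
}

# --- greedy clustering reference --------------------------------------------
oracle_identity_matrix <- function(seqs, aligned = TRUE) {
  n <- length(seqs)
  m <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- strsplit(seqs[[i]], "")[[1]]; b <- strsplit(seqs[[j]], "")[[1]]
    matches <- sum(a == b & a != "-")
    m[i, j] <- matches / min(sum(a != "-"), sum(b != "-"))
  }
  m
}

oracle_greedy_cluster_count <- function(seqs, threshold) {
  m <- oracle_identity_matrix(seqs)
  ung <- nchar(gsub("-", "", seqs))
  ord <- order(-ung, names(seqs))
  centroids <- character()
  for (id in names(seqs)[ord]) {
    hit <- FALSE
    for (cen in centroids) {
      if (m[cen, id] >= threshold) { hit <- TRUE; break }
    }
    if (!hit) centroids <- c(centroids, id)
  }
  length(centroids)
}

# --- bidirectional dedup reference ------------------------------------------
oracle_dedupe <- function(hits) {
  key <- apply(cbind(pmin(hits$query, hits$hit),
                     pmax(hits$query, hits$hit)), 1, paste, collapse = "|")
  res <- tapply(hits$e_value, key, min)
  setNames(as.numeric(res), names(res))
}

# --- plain-text newick leaf order -------------------------------------------
oracle_newick_leaves <- function(text) {
  text <- gsub(":[0-9.eE+-]+", "", text)
  text <- gsub("[();]", ",", text)
  parts <- strsplit(text, ",")[[1]]
  parts[nzchar(parts)]
}
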