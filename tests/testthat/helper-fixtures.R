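# Builders for topologies and alignments used across the suite.

# per-residue string for n TM helices, optional non-canonical kinds vector
# (entries "M", "B" or "R" per helix), starting side "i" or "o"
topo_string <- function(kinds, start_side = "i", helix_len = 21,
                        loop_len = 12, tail_len = 8) {
  side <- start_side
  out <- strrep(side, tail_len)
  for (k in kinds) {
    len <- if (k == "R") 14 else helix_len
    out <- paste0(out, strrep(k, len))
    if (k %in% c("M", "B")) side <- if (side == "i") "o" else "i"
    out <- paste0(out, strrep(side, loop_len))
  }
  sub(paste0(strrep(side, loop_len), "$"), strrep(side, tail_len), out)
}

# random valid topology string (all-M, or M with two B or two R)
random_topo_string <- function(n_helix = sample(2:12, 1),
                               noncanonical = sample(c("none", "B", "R"), 1),
                               start_side = sample(c("i", "o"), 1)) {
  kinds <- rep("M", n_helix)
  if (noncanonical != "none" && n_helix >= 4) {
    pos <- sort(sample(seq_len(n_helix), 2))
    kinds[pos] <- noncanonical
  }
  topo_string(kinds, start_side,
              helix_len = sample(15:25, 1), loop_len = sample(6:20, 1),
              tail_len = sample(5:20, 1))
}

# pairwise alignment where query and template are the given ungapped
# sequences aligned with optional leading template-only prefix
identity_alignment <- function(q_seq, t_seq_prefix = "", e_value = 1e-10) {
  pairwise_alignment("q", "t",
                     q_aln = paste0(strrep("-", nchar(t_seq_prefix)), q_seq),
                     t_aln = paste0(t_seq_prefix, q_seq),
                     e_value = e_value)
}

random_residues <- function(n) {
  paste(sample(c("A", "L", "S", "K", "R", "G", "D", "T", "V", "F"), n,
               replace = TRUE), collapse = "")
}
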