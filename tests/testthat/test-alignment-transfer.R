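test_that("template helices aligned over >=5 residues classify as aligned", {
  q <- topo_string(c("M", "M"))
  t <- topo_string(c("M", "M"))
  aln <- identity_alignment(random_residues(nchar(q)))
  qt <- parse_topology_string(q); tt <- parse_topology_string(t)
  rec <- classify_helices(aln, qt, tt)
  expect_identical(rec$class, c("aligned", "aligned"))
  expect_true(all(rec$overlap_residues >= 5))
})

test_that("below-threshold overlap falls back to the majority query state", {
  # template: one 18-residue helix; query: 4 columns in a helix, 14 in an
  # inside loop
  q_topo <- parse_topology_string(
    paste0(strrep("o", 4), strrep("M", 14), strrep("i", 30)))
  t_topo <- parse_topology_string(
    paste0(strrep("i", 14), strrep("M", 18), strrep("o", 16)))
  q_seq <- random_residues(48); t_seq <- random_residues(48)
  aln <- pairwise_alignment("q", "t", q_seq, t_seq, e_value = 1e-5)
  rec <- classify_helices(aln, q_topo, t_topo)
  # template helix covers query positions 15..32: 4 helix + 14 inside loop
  expect_identical(rec$class, "inside_loop")
  # a template helix opposite an all-gap region classifies as gap
  aln2 <- pairwise_alignment("q", "t",
                             paste0(strrep("-", 48), q_seq),
                             paste0(t_seq, strrep("-", 48)),
                             e_value = 1e-5)
  rec2 <- classify_helices(aln2, q_topo, t_topo)
  expect_identical(rec2$class, "gap")
})

test_that("classification equals the per-column enumeration oracle", {
  set.seed(77)
  for (trial in 1:60) {
    q <- random_topo_string(n_helix = sample(2:4, 1))
    t <- random_topo_string(n_helix = sample(2:4, 1))
    qs <- random_residues(nchar(q)); ts <- random_residues(nchar(t))
    # random alignment: pad each side with gaps at a random offset
    off_q <- sample(0:30, 1); off_t <- sample(0:30, 1)
    width <- max(off_q + nchar(q), off_t + nchar(t))
    aln <- pairwise_alignment(
      "q", "t",
      paste0(strrep("-", off_q), qs, strrep("-", width - off_q - nchar(q))),
      paste0(strrep("-", off_t), ts, strrep("-", width - off_t - nchar(t))),
      e_value = 1e-4)
    qt <- parse_topology_string(q)
    tt <- parse_topology_string(t)
    got <- classify_helices(aln, qt, tt)$class
    expect_identical(got, oracle_classify(aln, qt, tt))
  }
})

test_that("the transporter type follows the lowest E-value hit", {
  hits <- data.frame(template_type = c("broken", "reentrant"),
                     e_value = c(2.4e-48, 3.3e-13))
  expect_identical(choose_transporter_type(hits), "broken")
  hits2 <- data.frame(template_type = c("reentrant", "broken"),
                      e_value = c(1.8e-42, 0.9))
  expect_identical(choose_transporter_type(hits2), "reentrant")
  single <- data.frame(template_type = "reentrant", e_value = 1e-3)
  expect_identical(choose_transporter_type(single), "reentrant")
  tie <- data.frame(template_type = c("broken", "reentrant"),
                    e_value = c(1e-10, 1e-10))
  err <- tryCatch(choose_transporter_type(tie), error = identity)
  expect_s3_class(err, "ambiguous_type")
})

test_that("missing reentrant helices are regained from the template", {
  set.seed(19)
  spec <- family_spec("10H-2RH-Nout", n_sequences = 6,
                      p_miss_noncanonical = 1, seed = 3)
  fam <- generate_family(spec)
  rep_id <- names(fam$msa)[1]
  tmpl <- make_structure_template(fam, representative = rep_id)
  initial <- parse_topology_string(fam$predicted[[rep_id]])
  expect_identical(format(topology_label(initial)), "10H-Nout")
  rec <- classify_helices(tmpl$alignment, initial, tmpl$topology)
  expect_equal(sum(rec$class %in% c("inside_loop", "outside_loop")), 2)
  final <- infer_final_topology(initial, tmpl$topology, rec,
                                tmpl$alignment)
  expect_identical(format(topology_label(final)), "10H-2RH-Nout")
  # idempotence: re-classifying against the final topology adds nothing
  rec2 <- classify_helices(tmpl$alignment, final, tmpl$topology)
  expect_equal(sum(rec2$class %in% c("inside_loop", "outside_loop")), 0)
  final2 <- infer_final_topology(final, tmpl$topology, rec2,
                                 tmpl$alignment)
  expect_identical(serialize_topology(final2), serialize_topology(final))
  # the noncanonical kind matches the chosen transporter type
  expect_identical(topology_label(final)$noncanonical_kind, "RH")
  expect_identical(tmpl$type, "reentrant")
})

test_that("inserting a crossing helix flips all downstream loop sides", {
  set.seed(29)
  spec <- family_spec("8H-2BH-Nin", n_sequences = 6,
                      p_miss_noncanonical = 1, seed = 5)
  fam <- generate_family(spec)
  rep_id <- names(fam$msa)[1]
  tmpl <- make_structure_template(fam, representative = rep_id)
  initial <- parse_topology_string(fam$predicted[[rep_id]])
  rec <- classify_helices(tmpl$alignment, initial, tmpl$topology)
  final <- infer_final_topology(initial, tmpl$topology, rec,
                                tmpl$alignment)
  expect_identical(format(topology_label(final)), "8H-2BH-Nin")
  expect_identical(serialize_topology(final), fam$truth[[rep_id]])
  # brute-force side propagation over the final string
  chars <- strsplit(serialize_topology(final), "")[[1]]
  side <- "i"
  ok <- TRUE
  for (ch in chars) {
    if (ch %in% c("i", "o")) ok <- ok && (ch == side)
    if (ch %in% c("M", "B", "S")) side <- if (side == "i") "o" else "i"
  }
  expect_true(ok)
})

test_that("subdomain transfer is isomorphic for a 1:1 helix map", {
  set.seed(37)
  spec <- family_spec("10H-2RH-Nout", n_sequences = 6, seed = 11)
  fam <- generate_family(spec)
  rep_id <- names(fam$msa)[1]
  truth <- parse_topology_string(fam$truth[[rep_id]])
  aln <- identity_alignment(degap(fam$msa[[rep_id]]))
  rec <- classify_helices(aln, truth, truth)
  ann <- transfer_subdomains(fam$annotation, truth, rec, truth)
  expect_identical(ann$helix_tags, fam$annotation$helix_tags)
  expect_identical(ann$helix_repeat, fam$annotation$helix_repeat)
  expect_false(attr(ann, "shuffled"))
  expect_false(any(attr(ann, "extrapolated")))
})

test_that("an extra query helix is tagged by extrapolation from its neighbour", {
  set.seed(43)
  spec <- family_spec("10H-2RH-Nout", n_sequences = 6, seed = 13)
  fam <- generate_family(spec)
  rep_id <- names(fam$msa)[1]
  # query gains an N-terminal scaffold helix relative to the template:
  # swap roles of make_structure_template output (template = plain truth)
  tmpl <- make_structure_template(fam, representative = rep_id,
                                  n_extra_scaffold = 1)
  q_topology <- tmpl$topology           # 11 helices, the extra one first
  t_topology <- parse_topology_string(fam$truth[[rep_id]])
  t_ann <- fam$annotation
  q_seq <- random_residues(q_topology$chain_length)
  prefix <- q_topology$chain_length - t_topology$chain_length
  aln <- pairwise_alignment("q", "t",
                            q_aln = q_seq,
                            t_aln = paste0(strrep("-", prefix),
                                           random_residues(
                                             t_topology$chain_length)),
                            e_value = 1e-20)
  rec <- classify_helices(aln, q_topology, t_topology)
  ann <- transfer_subdomains(t_ann, t_topology, rec, q_topology)
  expect_identical(ann$helix_tags[1], "scaffold")
  expect_true(attr(ann, "extrapolated")[1])
  expect_false(any(attr(ann, "extrapolated")[-1]))
})

test_that("repeat shuffling is flagged when template repeats come C-first", {
  # template family whose N repeat sits C-terminally (shuffled relative to
  # the query): a straight 1:1 alignment then tags the query's N-terminal
  # helices as C-repeat, which must raise the shuffle flag
  q <- topo_string(c("M", "M", "M", "M"), helix_len = 20, loop_len = 12,
                   tail_len = 10)
  qt <- parse_topology_string(q)
  tt <- parse_topology_string(q)
  h <- helices(tt)
  mid <- (h$end[2] + h$start[3]) %/% 2
  t_ann <- repeat_annotation(c(1L, mid), c(mid + 1L, tt$chain_length),
                             helix_tags = rep(c("scaffold", "core"), 2),
                             helix_repeat = c("C", "C", "N", "N"))
  aln <- identity_alignment(random_residues(qt$chain_length))
  rec <- classify_helices(aln, qt, tt)
  ann <- transfer_subdomains(t_ann, tt, rec, qt)
  expect_true(attr(ann, "shuffled"))
  expect_identical(ann$helix_repeat, c("C", "C", "N", "N"))
})

test_that("repeat similarity takes the minimum N-vs-C E-value", {
  hits <- data.frame(query_role = c("N", "N", "N"),
                     hit_role = c("C", "C", "N"),
                     e_value = c(1e-8, 1e-3, 1e-30))
  expect_equal(repeat_similarity(hits), 1e-8)
  none <- data.frame(query_role = "N", hit_role = "N", e_value = 1e-4)
  expect_true(is.na(repeat_similarity(none)))
  expect_true(is.na(repeat_similarity(none[0, ])))
})

test_that("recent repeat duplication leaves higher N/C identity than ancient", {
  set.seed(61)
  half <- random_residues(150)
  mutate <- function(s, nmut) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), nmut)
    ch[idx] <- sample(c("A", "L", "S", "K", "G"), nmut, replace = TRUE)
    paste(ch, collapse = "")
  }
  recent_c <- mutate(half, 15)
  ancient_c <- mutate(half, 110)
  expect_gt(pairwise_identity(half, recent_c),
            pairwise_identity(half, ancient_c))
})
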