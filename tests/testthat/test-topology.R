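test_that("per-residue strings parse into the expected segments", {
  t <- parse_topology_string(
    "iiiMMMMMMMMMMMMMMMMMoooMMMMMMMMMMMMMMMMMiii")
  expect_equal(sum(t$segments$kind == "tm_helix"), 2L)
  expect_equal(t$segments$kind[c(1, 3, 5)],
               c("inside_loop", "outside_loop", "inside_loop"))
  expect_equal(topology_label(t)$n_term_side, "Nin")

  t2 <- parse_topology_string("ooRRRRRRRRRRoo")
  expect_equal(t2$segments$kind[2], "reentrant_helix")
  expect_equal(t2$segments$reentrant_side[2], "out_out")
  expect_equal(topology_label(t2)$n_term_side, "Nout")
})

test_that("side-alternation violations are rejected with the offending segment", {
  seg <- data.frame(kind = c("inside_loop", "tm_helix", "inside_loop"),
                    start = c(1L, 3L, 15L), end = c(2L, 14L, 20L),
                    orientation = c("none", "in_to_out", "none"),
                    reentrant_side = "none", break_pos = NA_integer_)
  err <- tryCatch(topology(seg), error = identity)
  expect_s3_class(err, "topology_inconsistency")
  expect_match(conditionMessage(err), "segment 3")
})

test_that("parse and serialize are mutually inverse on random topologies", {
  set.seed(11)
  for (k in 1:60) {
    s <- random_topo_string()
    t <- parse_topology_string(s)
    expect_identical(serialize_topology(t), s)
  }
})

test_that("topology labels count all helices and take the N-terminal side", {
  t <- parse_topology_string(topo_string(c("M", "M", "M", "M", "B", "M",
                                           "M", "M", "M", "M", "B", "M"),
                                         start_side = "i"))
  expect_identical(format(topology_label(t)), "10H-2BH-Nin")
  t3 <- parse_topology_string(topo_string(c("M", "M", "M"),
                                          start_side = "o"))
  expect_identical(format(topology_label(t3)), "3H-Nout")
  # loops only: no label
  expect_error(topology_label(parse_topology_string("iiiii")),
               "no membrane helices")
  # mixing broken and reentrant in one chain is unsupported
  mixed <- parse_topology_string(topo_string(c("M", "B", "M", "R", "M")))
  err <- tryCatch(topology_label(mixed), error = identity)
  expect_s3_class(err, "unsupported_mixture")
})

test_that("label strings round-trip and the helix algebra matches", {
  expect_equal(total_helix_count("8H-2BH-Nin"), 10)
  expect_equal(total_helix_count("11H-2RH-Nin"), 13)
  expect_equal(total_helix_count("3H-Nout"), 3)
  expect_identical(format(parse_topology_label("10H-2BH-N_in_")),
                   "10H-2BH-Nin")
})

test_that("membrane crossings exclude reentrant helices", {
  tb <- parse_topology_string(topo_string(c("M", "M", "M", "M", "B", "M",
                                            "M", "M", "M", "M", "B", "M")))
  expect_equal(membrane_crossing_count(tb), 12)
  tr <- parse_topology_string(topo_string(c("M", "M", "M", "M", "M", "R",
                                            "M", "M", "M", "M", "M", "M",
                                            "R")))
  expect_equal(membrane_crossing_count(tr), 11)
  expect_equal(membrane_crossing_count(parse_topology_string("iiiiii")), 0)
})

test_that("total helix count exceeds crossings by exactly the reentrant count", {
  set.seed(23)
  for (k in 1:40) {
    s <- random_topo_string()
    t <- parse_topology_string(s)
    n_rh <- sum(t$segments$kind == "reentrant_helix")
    expect_equal(total_helix_count(topology_label(t)) -
                   membrane_crossing_count(t), n_rh)
  }
})

test_that("every curated family label round-trips byte-identically", {
  tab <- read.delim(system.file("extdata", "cpa_at_family_labels.tsv",
                                package = "cpatopo"))
  for (lab in tab$label)
    expect_identical(format(parse_topology_label(lab)), lab)
  totals <- vapply(tab$label, total_helix_count, numeric(1))
  expect_true(all(totals >= 3 & totals <= 14))
})

test_that("repeat splitting cuts in loops and preserves the pieces", {
  s <- topo_string(rep("M", 10), start_side = "i",
                   helix_len = 20, loop_len = 12, tail_len = 10)
  t <- parse_topology_string(s)
  h <- helices(t)
  mid <- (h$end[5] + h$start[6]) %/% 2
  ann <- repeat_annotation(n_repeat = c(5L, mid),
                           c_repeat = c(mid + 1L, t$chain_length - 4L),
                           helix_tags = rep(c("scaffold", "core"), 5))
  units <- split_repeats(t, ann)
  expect_equal(nrow(helices(units[[1]])), 5)
  expect_equal(nrow(helices(units[[2]])), 5)
  # boundary inside helix 6 is a boundary error
  bad <- repeat_annotation(n_repeat = c(5L, h$start[6] + 2L),
                           c_repeat = c(h$start[6] + 3L, t$chain_length - 4L),
                           helix_tags = rep(c("scaffold", "core"), 5))
  err <- tryCatch(split_repeats(t, bad), error = identity)
  expect_s3_class(err, "boundary_error")
})

test_that("inverted repeat units start on opposite membrane sides", {
  # an even number of crossings before the C repeat flips the entry side
  for (start_side in c("i", "o")) {
    s <- topo_string(rep("M", 10), start_side = start_side,
                     helix_len = 20, loop_len = 12, tail_len = 10)
    t <- parse_topology_string(s)
    h <- helices(t)
    mid <- (h$end[5] + h$start[6]) %/% 2
    ann <- repeat_annotation(n_repeat = c(1L, mid),
                             c_repeat = c(mid + 1L, t$chain_length),
                             helix_tags = rep(c("scaffold", "core"), 5))
    units <- split_repeats(t, ann)
    sides <- vapply(units,
                    function(u) topology_label(u)$n_term_side, character(1))
    expect_false(sides[1] == sides[2])
  }
})

test_that("swapping the non-canonical type re-propagates downstream sides", {
  t <- parse_topology_string(topo_string(c("M", "M", "B", "M", "M", "B")))
  alt <- alternative_type_model(t)
  expect_equal(topology_label(alt)$noncanonical_kind, "RH")
  # a reentrant does not cross: downstream crossing parity changes
  expect_equal(membrane_crossing_count(alt),
               membrane_crossing_count(t) - 2)
  expect_identical(format(topology_label(alternative_type_model(alt))),
                   format(topology_label(t)))
})

test_that("signal peptides are parsed but never counted as helices", {
  s <- paste0(strrep("S", 15), topo_string(c("M", "M"), start_side = "o"))
  t <- parse_topology_string(s)
  expect_equal(sum(t$segments$kind == "signal_peptide"), 1)
  expect_equal(total_helix_count(topology_label(t)), 2)
  expect_identical(serialize_topology(t), s)
})
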