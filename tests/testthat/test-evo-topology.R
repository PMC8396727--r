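test_that("topology projection places characters at non-gap columns", {
  expect_identical(project_topology("AC-GT", "iiMM"), "ii-MM")
  expect_identical(project_topology("--A--C--", "io"), "--i--o--")
  expect_error(project_topology("AC-GT", "iiMMM"), "projection error")
})

test_that("projection and degapping are mutually inverse on random pairs", {
  set.seed(7)
  for (k in 1:50) {
    n <- sample(10:60, 1)
    topo <- paste(sample(c("i", "o", "M"), n, replace = TRUE), collapse = "")
    row <- strsplit(random_residues(n), "")[[1]]
    gaps <- sort(sample(seq_len(n + 10), sample(0:10, 1)))
    for (g in gaps) row <- append(row, "-", after = min(g, length(row)))
    row <- paste(row, collapse = "")
    expect_identical(degap(project_topology(row, topo)), topo)
  }
})

make_mta <- function(topos, tree = NULL, seqs = NULL) {
  ids <- names(topos)
  if (is.null(seqs))
    seqs <- setNames(vapply(topos, function(s) {
      ch <- strsplit(s, "")[[1]]
      res <- ch != "-"
      ch[res] <- strsplit(random_residues(sum(res)), "")[[1]]
      paste(ch, collapse = "")
    }, character(1)), ids)
  multiple_topology_alignment(seqs, topos, tree = tree)
}

test_that("tree reordering follows the branching order, content untouched", {
  topos <- setNames(rep(topo_string(c("M", "M")), 3), c("C", "A", "B"))
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  mta <- make_mta(topos, tree)
  out <- reorder_by_tree(mta)
  expect_identical(out$row_order, c("A", "B", "C"))
  expect_identical(out$topo_rows, mta$topo_rows)
  expect_identical(out$seq_rows, mta$seq_rows)
})

test_that("caterpillar leaf order matches an independent newick walk", {
  nwk <- "(((((((a:1,b:1):1,c:1):1,d:1):1,e:1):1,f:1):1,g:1):1,h:1);"
  tree <- ape::read.tree(text = nwk)
  topos <- setNames(rep(topo_string(c("M", "M")), 8), letters[1:8])
  out <- reorder_by_tree(make_mta(topos, tree))
  expect_identical(out$row_order, oracle_newick_leaves(nwk))
})

test_that("leaf/row mismatches are reported with the symmetric difference", {
  topos <- setNames(rep(topo_string(c("M", "M")), 2), c("A", "B"))
  tree <- ape::read.tree(text = "((A:1,X:1):1,B:1);")
  expect_error(make_mta(topos, tree), "X")
})

two_clade_mta <- function(n_a = 6, n_b = 5, label_a = c("M", "M", "M"),
                          label_b = c("M", "M", "M", "M"), seed = 1) {
  set.seed(seed)
  sa <- topo_string(label_a); sb <- topo_string(label_b)
  wa <- nchar(sa); wb <- nchar(sb)
  ids_a <- sprintf("a%02d", 1:n_a); ids_b <- sprintf("b%02d", 1:n_b)
  topos <- c(setNames(rep(paste0(sa, strrep("-", wb)), n_a), ids_a),
             setNames(rep(paste0(strrep("-", wa), sb), n_b), ids_b))
  na <- paste0("(", paste(sprintf("%s:1", ids_a), collapse = ","), ")")
  nb <- paste0("(", paste(sprintf("%s:1", ids_b), collapse = ","), ")")
  tree <- ape::read.tree(text = paste0("(", na, ":1,", nb, ":1);"))
  make_mta(topos, tree)
}

test_that("two clean clades with distinct labels split into two groups", {
  mta <- two_clade_mta()
  part <- detect_topology_groups(mta)
  expect_length(part$groups, 2)
  expect_length(part$deviants, 0)
  labs <- sort(vapply(part$groups, `[[`, character(1), "label"))
  expect_identical(labs, c("3H-Nin", "4H-Nin"))
})

test_that("a uniform family is a single group; minorities become deviants", {
  sa <- topo_string(c("M", "M", "M"))
  topos <- setNames(rep(sa, 6), sprintf("u%d", 1:6))
  tree <- ape::read.tree(
    text = paste0("(", paste(sprintf("u%d:1", 1:6), collapse = ","), ");"))
  part <- detect_topology_groups(make_mta(topos, tree))
  expect_length(part$groups, 1)
  # 9 of 10 share a label at fraction 0.75: one group, one deviant
  sb <- topo_string(c("M", "M"))
  sb <- paste0(sb, strrep("-", nchar(sa) - nchar(sb)))
  topos2 <- setNames(c(rep(sa, 9), sb), sprintf("v%02d", 1:10))
  tree2 <- ape::read.tree(
    text = paste0("(", paste(sprintf("v%02d:1", 1:10), collapse = ","), ");"))
  part2 <- detect_topology_groups(make_mta(topos2, tree2))
  expect_length(part2$groups, 1)
  expect_identical(part2$deviants, "v10")
})

test_that("grouping without a tree degrades to label equality with a warning", {
  mta <- two_clade_mta()
  mta$tree <- NULL
  expect_warning(part <- detect_topology_groups(mta), "degraded")
  expect_length(part$groups, 2)
})

test_that("consensus of identical rows is the row itself", {
  s <- topo_string(c("M", "M", "B", "M"))
  topos <- setNames(rep(s, 20), sprintf("c%02d", 1:20))
  mta <- make_mta(topos)
  cons <- consensus_topology(mta)
  expect_identical(serialize_topology(cons), s)
  expect_identical(cons$source, "consensus")
})

test_that("consensus recovers the generating topology under per-column noise", {
  set.seed(101)
  truth <- topo_string(c("M", "M", "R", "M", "M", "R", "M"))
  hits <- 0
  for (trial in 1:20) {
    topos <- setNames(vapply(1:20, function(i)
      corrupt_topology_string(truth, 0.3), character(1)),
      sprintf("n%02d", 1:20))
    mta <- make_mta(topos)
    got <- tryCatch(serialize_topology(consensus_topology(mta)),
                    error = function(e) NA_character_)
    if (identical(got, truth)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("consensus recovery does not improve with more corruption", {
  set.seed(55)
  truth <- topo_string(c("M", "M", "B", "M", "M"))
  rate_hits <- vapply(c(0, 0.15, 0.3), function(rate) {
    hits <- 0
    for (trial in 1:15) {
      topos <- setNames(vapply(1:20, function(i)
        corrupt_topology_string(truth, rate), character(1)),
        sprintf("m%02d", 1:20))
      got <- tryCatch(
        serialize_topology(consensus_topology(make_mta(topos))),
        error = function(e) NA_character_)
      if (identical(got, truth)) hits <- hits + 1
    }
    hits
  }, numeric(1))
  expect_true(all(diff(rate_hits) <= 0))
  expect_equal(rate_hits[1], 15)
})

test_that("the representative breaks per-column ties", {
  s1 <- paste0(strrep("i", 6), strrep("M", 15), strrep("o", 6))
  s2 <- chartr("io", "oi", s1)
  mta <- make_mta(setNames(c(s1, s2), c("r1", "r2")))
  cons <- consensus_topology(mta, representative = "r1")
  expect_identical(serialize_topology(cons), s1)
})
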