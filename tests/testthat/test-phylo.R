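test_that("p-distances and the Dayhoff correction follow their closed forms", {
  rows <- sequence_set(c("a", "b"), c(strrep("A", 40), strrep("A", 40)),
                       gapped = TRUE)
  expect_equal(distance_from_alignment(rows, "p")["a", "b"], 0)
  expect_equal(distance_from_alignment(rows, "dayhoff")["a", "b"], 0)

  # p = 0.1 over 500 columns -> -ln(0.898)
  a <- strrep("A", 500)
  b <- paste0(strrep("C", 50), strrep("A", 450))
  rows <- sequence_set(c("a", "b"), c(a, b), gapped = TRUE)
  expect_equal(distance_from_alignment(rows, "p")["a", "b"], 0.1)
  expect_equal(distance_from_alignment(rows, "dayhoff")["a", "b"],
               -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)

  # random gapped pair: p agrees with a direct column count
  withr::local_seed(3)
  for (k in 1:10) {
    ca <- sample(c("A", "C", "G", "-"), 60, replace = TRUE)
    cb <- sample(c("A", "C", "G", "-"), 60, replace = TRUE)
    shared <- ca != "-" & cb != "-"
    if (!any(shared)) next
    rows <- sequence_set(c("a", "b"),
                         c(paste(ca, collapse = ""), paste(cb, collapse = "")),
                         gapped = TRUE)
    expect_equal(distance_from_alignment(rows, "p")["a", "b"],
                 sum(ca[shared] != cb[shared]) / sum(shared))
  }
})

test_that("distance errors name the offending pair and advise the p model", {
  rows <- sequence_set(c("left", "right"), c("AC--", "--GT"), gapped = TRUE)
  expect_error(distance_from_alignment(rows, "p"), "left.*right")

  rows <- sequence_set(c("a", "b"), c(strrep("A", 20), strrep("C", 20)),
                       gapped = TRUE)
  expect_error(distance_from_alignment(rows, "dayhoff"), "model = \"p\"")
  expect_equal(distance_from_alignment(rows, "p")["a", "b"], 1)
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(d)
  lens <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[["a"]], (3 + 5 - 6) / 2)
  expect_equal(lens[["b"]], (3 + 6 - 5) / 2)
  expect_equal(lens[["c"]], (5 + 6 - 3) / 2)
})

test_that("NJ reconstructs additive matrices exactly up to 8 taxa", {
  for (s in 1:6) {
    n <- sample(4:8, 1)
    ref <- random_additive_matrix(n, seed = s)
    tree <- neighbor_joining(ref$d)
    back <- ape::cophenetic.phylo(tree)
    back <- back[rownames(ref$d), colnames(ref$d)]
    expect_equal(back, ref$d, tolerance = 1e-9)
    # independent implementation agrees on the topology
    alt <- ape::nj(ref$d)
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(alt)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate NJ inputs are handled", {
  d <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree <- neighbor_joining(d)
  expect_equal(sort(tree$tip.label), c("a", "b"))
  expect_equal(tree$edge.length, c(0, 0))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), "symmetric")

  # non-additive input can imply negative branches: clamped, logged
  d <- matrix(c(0, 1, 1,
                1, 0, 5,
                1, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tree <- neighbor_joining(d) # closed form gives a branch of -1.5
  expect_true(all(tree$edge.length >= 0))
  expect_gt(attr(tree, "clamped"), 0)
})

test_that("Newick serialization round-trips topology, lengths and supports", {
  expect_match(write_newick(read_newick("(a:1,b:1);")), "a:1")
  expect_error(read_newick("(a:1,b:1"), "malformed")

  for (s in 1:5) {
    ref <- random_additive_matrix(6, seed = 100 + s)
    tree <- neighbor_joining(ref$d)
    tree$node.label <- c("", as.character(sample(0:100, tree$Nnode - 1)))
    back <- read_newick(write_newick(tree))
    expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(ape::cophenetic.phylo(back)[tree$tip.label, tree$tip.label]),
                 sort(ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]),
                 tolerance = 1e-6)
    expect_setequal(back$node.label, tree$node.label)
  }
})

test_that("bootstrap supports are deterministic and permutation-invariant", {
  fam <- generate_family(family_config(n_tdc = 4, n_tydc = 4, mu = 0.05,
                                       length = 300,
                                       tdc_anchors = c(20, 50, 90, 150),
                                       tydc_anchors = c(30, 65, 110, 170)),
                         seed = 12)
  aln <- as_alignment(fam$sequences)
  t1 <- bootstrap_tree(aln, "p", n_reps = 40, seed = 5)
  t2 <- bootstrap_tree(aln, "p", n_reps = 40, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))

  tdc_ids <- aln$id[aln$class_label == "TDC"]
  s1 <- bipartition_support(t1, tdc_ids)

  perm <- aln[c(3, 8, 1, 5, 2, 7, 4, 6), , drop = FALSE]
  t3 <- bootstrap_tree(perm, "p", n_reps = 40, seed = 5)
  s3 <- bipartition_support(t3, tdc_ids)
  expect_identical(s1, s3)
})

test_that("identical sequences give a degenerate star-like tree", {
  aln <- sequence_set(paste0("s", 1:5), rep(strrep("ACDEF", 10), 5),
                      gapped = TRUE)
  tree <- neighbor_joining(distance_from_alignment(aln, "p"))
  expect_true(all(tree$edge.length == 0))
})

test_that("bootstrap supports live on internal node labels in [0, 100]", {
  fam <- generate_family(family_config(n_tdc = 3, n_tydc = 3, mu = 0.05,
                                       length = 300,
                                       tdc_anchors = c(20, 50, 90, 150),
                                       tydc_anchors = c(30, 65, 110, 170)),
                         seed = 19)
  tree <- bootstrap_tree(as_alignment(fam$sequences), "dayhoff",
                         n_reps = 25, seed = 2)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(length(sup) >= 1)
  expect_true(all(sup >= 0 & sup <= 100))
  rt <- read_newick(write_newick(tree))
  expect_setequal(rt$node.label, tree$node.label)
})
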