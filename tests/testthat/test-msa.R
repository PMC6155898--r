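test_that("pairwise alignment scores match matrix lookups on gapless cases", {
  expect_equal(align_pair("HKW", "HKW")$score, 24) # 8 + 5 + 11
  al <- align_pair("SPHKW", "NAHKW")
  expect_false(grepl("-", al$a))
  expect_false(grepl("-", al$b))
  expect_equal(al$score, 1 + (-1) + 24) # s(S,N) + s(P,A) + HKW diagonal
  expect_equal(align_pair("A", "A")$score, 4)
  expect_error(align_pair("", "A"), "empty")
})

test_that("pairwise alignment attains the brute-force affine-gap optimum", {
  withr::local_seed(21)
  sch <- scoring_scheme(gap_open = 4, gap_extend = 1)
  submat <- sch$matrix
  for (k in 1:12) {
    a <- random_protein(sample(2:6, 1), alphabet = c("A", "C", "D", "W"))
    b <- random_protein(sample(2:6, 1), alphabet = c("A", "C", "D", "W"))
    mine <- align_pair(a, b, sch)
    expect_equal(mine$score, brute_force_score(a, b, submat, 4, 1),
                 info = paste(a, b))
    # degapping recovers the inputs
    expect_identical(degap(mine$a), a)
    expect_identical(degap(mine$b), b)
    expect_equal(nchar(mine$a), nchar(mine$b))
  }
})

test_that("pairwise scores agree with an independent aligner", {
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  withr::local_seed(42)
  for (k in 1:8) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = e$BLOSUM62, gapOpening = 10, gapExtension = 1)
    expect_equal(align_pair(a, b)$score, Biostrings::score(ref))
  }
})

test_that("guide tree pairs the obvious clusters first", {
  withr::local_seed(5)
  s <- random_protein(60)
  far <- random_protein(60)
  x <- sequence_set(c("a", "b", "c"), c(s, s, far))
  ht <- guide_tree(x)
  expect_equal(sort(ht$merge[1, ]), c(-2L, -1L)) # a and b join first

  expect_error(guide_tree(sequence_set("a", s)), "at least 2")

  # two records: a single cherry
  ht2 <- guide_tree(sequence_set(c("a", "b"), c(s, far)))
  expect_equal(nrow(ht2$merge), 1L)
})

test_that("progressive alignment satisfies its structural invariants", {
  withr::local_seed(31)
  s <- random_protein(40)
  x <- sequence_set(c("a", "b", "c"), c(s, s, s))
  aln <- progressive_align(x)
  expect_equal(alignment_width(aln), 40L)
  expect_false(any(grepl("-", aln$residues, fixed = TRUE)))

  # random unequal-length set: degapping invariant, width bounds, no
  # all-gap column
  lens <- c(25, 31, 28, 40)
  x <- sequence_set(paste0("s", 1:4),
                    vapply(lens, random_protein, character(1)))
  aln <- progressive_align(x)
  w <- alignment_width(aln)
  expect_true(w >= max(lens) && w <= sum(lens))
  expect_identical(degap(aln$residues), x$residues)
  expect_identical(aln$id, x$id)
  m <- do.call(rbind, strsplit(aln$residues, ""))
  expect_true(all(colSums(m != "-") > 0))
})

test_that("two-sequence progressive alignment equals the pairwise optimum", {
  withr::local_seed(8)
  a <- random_protein(35)
  b <- paste0(substr(a, 1, 15), substr(a, 22, 35)) # deletion variant
  aln <- progressive_align(sequence_set(c("a", "b"), c(a, b)))
  pw <- align_pair(a, b)
  expect_identical(aln$residues, c(pw$a, pw$b))
})

test_that("noise-free families align with motifs at one shared offset", {
  fam <- generate_family(family_config(n_tdc = 3, n_tydc = 3, mu = 0,
                                       length = 200,
                                       tdc_anchors = c(20, 50, 90, 150),
                                       tydc_anchors = c(30, 65, 110, 170)),
                         seed = 2)
  aln <- progressive_align(fam$sequences)
  # equal-length ungapped inputs from one backbone: alignment is gapless,
  # so every class motif sits at its planted column in every row
  expect_equal(alignment_width(aln), 200L)
  sigs <- load_signatures()
  for (k in seq_along(sigs)) {
    for (r in which(aln$class_label == "TDC")) {
      h <- scan_motif(aln$residues[r], sigs[[k]]$tdc)
      expect_true(fam$truth$motif_starts$TDC[k] %in% h$start)
    }
  }
})

test_that("scoring scheme validates its invariants", {
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "exceed")
  expect_error(scoring_scheme(gap_open = -1), "positive")
  m <- matrix(1, 20, 20, dimnames = list(AA20_T, AA20_T))
  m[1, 2] <- 5 # asymmetric
  expect_error(scoring_scheme(m), "symmetric")
})
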