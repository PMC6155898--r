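toy_alignment <- function() {
  sequence_set(
    c("a1", "a2", "b1", "b2"),
    c("THWLSP", "TNWMSP", "THWQSP", "THWQSP"),
    class_label = c("TDC", "TDC", "TYDC", "TYDC"),
    gapped = TRUE
  )
}

test_that("column profiles report per-class frequencies and gap fractions", {
  aln <- sequence_set(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    c("LA-", "LC-", "MA-", "QAW", "QAW", "QAW"),
    class_label = rep(c("TDC", "TYDC"), each = 3), gapped = TRUE
  )
  pr <- column_profiles(labeled_alignment(aln))
  expect_equal(pr$classes, c("TDC", "TYDC"))
  expect_equal(unname(pr$TDC$freq["L", 1]), 2 / 3)
  expect_equal(unname(pr$TDC$freq["M", 1]), 1 / 3)
  expect_equal(unname(pr$TYDC$freq["Q", 1]), 1)
  expect_equal(sum(pr$TDC$freq[, 2]), 1)
  # all-gap column in one class
  expect_equal(pr$TDC$gap_fraction[3], 1)
  expect_equal(pr$TYDC$gap_fraction[3], 0)
  expect_error(column_profiles(sequence_set("a", "AC")), "two classes")
})

test_that("profiles on a planted family match the generator's emissions", {
  fam <- generate_family(family_config(n_tdc = 10, n_tydc = 10, mu = 0),
                         seed = 6)
  la <- labeled_alignment(as_alignment(fam$sequences))
  pr <- column_profiles(la)
  m <- do.call(rbind, strsplit(fam$sequences$residues, ""))
  for (cl in c("TDC", "TYDC")) {
    sub <- m[fam$sequences$class_label == cl, , drop = FALSE]
    for (j in sample(ncol(sub), 25)) {
      emp <- table(factor(sub[, j], levels = rownames(pr[[cl]]$freq)))
      expect_equal(pr[[cl]]$freq[, j], as.numeric(emp) / nrow(sub),
                   ignore_attr = TRUE)
    }
  }
})

test_that("diagnostic columns on the toy alignment are exactly the Q column", {
  la <- labeled_alignment(toy_alignment())
  expect_equal(find_diagnostic_columns(la), 4L)

  # identical consensus in both classes: nothing is diagnostic
  same <- sequence_set(paste0("s", 1:4), rep("THWQSP", 4),
                       class_label = rep(c("TDC", "TYDC"), each = 2),
                       gapped = TRUE)
  expect_equal(length(find_diagnostic_columns(labeled_alignment(same))), 0L)
})

test_that("motif extraction reproduces the toy signature pair", {
  la <- labeled_alignment(toy_alignment())
  pairs <- extract_motif_pairs(la)
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]$span, c(1L, 6L))
  expect_equal(pairs[[1]]$patterns[["TDC"]], "T[H/N]W[L/M]SP")
  expect_equal(pairs[[1]]$patterns[["TYDC"]], "THWQSP")
  expect_equal(pairs[[1]]$diagnostic_offsets, 4L)
  expect_equal(unname(pairs[[1]]$positions), c(1L, 1L))

  # no diagnostic columns -> no motifs
  same <- sequence_set(paste0("s", 1:4), rep("THWQSPAA", 4),
                       class_label = rep(c("TDC", "TYDC"), each = 2),
                       gapped = TRUE)
  expect_length(extract_motif_pairs(labeled_alignment(same)), 0L)
})

test_that("planted blocks on non-conserved backbones are recovered as pairs", {
  pb <- planted_block_alignment(n_per_class = 8, seed = 3)
  pairs <- extract_motif_pairs(pb$alignment)
  expect_length(pairs, 4L)
  spans <- t(vapply(pairs, `[[`, integer(2), "span"))
  expect_equal(unname(spans), unname(pb$spans), ignore_attr = TRUE)
  dc <- find_diagnostic_columns(pb$alignment)
  # every diagnostic column reported inside a motif is globally diagnostic
  expect_true(all(unlist(lapply(pairs, `[[`, "diagnostic_columns")) %in% dc))
  # and discovered pairs feed straight back into classification
  sigs <- discovered_to_signatures(pairs)
  fam <- generate_family(family_config(n_tdc = 3, n_tydc = 3, mu = 0),
                         seed = 30)
  expect_identical(classify_set(fam$sequences, sigs)$label,
                   fam$sequences$class_label)
})

test_that("class-label swaps move patterns but not geometry", {
  pb <- planted_block_alignment(n_per_class = 5, seed = 9)
  la <- pb$alignment
  swapped <- la
  swapped$class_label <- ifelse(la$class_label == "TDC", "TYDC", "TDC")
  swapped <- labeled_alignment(swapped)
  p1 <- extract_motif_pairs(la)
  p2 <- extract_motif_pairs(swapped)
  expect_equal(lapply(p1, `[[`, "span"), lapply(p2, `[[`, "span"))
  expect_equal(lapply(p1, `[[`, "diagnostic_columns"),
               lapply(p2, `[[`, "diagnostic_columns"))
  for (k in seq_along(p1)) {
    expect_identical(p1[[k]]$patterns[["TDC"]], p2[[k]]$patterns[["TYDC"]])
    expect_identical(p1[[k]]$patterns[["TYDC"]], p2[[k]]$patterns[["TDC"]])
  }
  expect_identical(find_diagnostic_columns(la),
                   find_diagnostic_columns(swapped))
})

test_that("column-to-reference mapping counts non-gap prefix residues", {
  aln <- sequence_set(c("r1", "r2"), c("AD-C", "ADDC"),
                      class_label = c("TDC", "TYDC"), gapped = TRUE)
  expect_equal(column_to_reference_position(aln, "r1", 4), 3L)
  expect_equal(column_to_reference_position(aln, "r1", 1), 1L)
  expect_error(column_to_reference_position(aln, "r1", 3), "gap at column")
  expect_error(column_to_reference_position(aln, "zz", 1), "no row")

  # brute-force prefix-count oracle on random gapped rows
  withr::local_seed(44)
  for (k in 1:10) {
    chars <- sample(c(AA20_T, "-", "-"), 30, replace = TRUE)
    if (all(chars == "-")) next
    aln <- sequence_set(c("x", "y"),
                        c(paste(chars, collapse = ""), strrep("A", 30)),
                        class_label = c("TDC", "TYDC"), gapped = TRUE)
    col <- sample(which(chars != "-"), 1)
    expect_equal(column_to_reference_position(aln, "x", col),
                 sum(chars[1:col] != "-"))
  }
})
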