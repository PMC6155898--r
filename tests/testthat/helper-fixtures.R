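# Shared helpers: tiny independent oracles and constructed fixtures.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA20_T) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force affine-gap global alignment score by exhaustive recursion.
# A gap of length L costs open + L * ext (charged per gap column, with the
# opening surcharge on the first column of each run). Only viable for
# sequences of length <= ~7.
brute_force_score <- function(a, b, submat, open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) { # gap in b
      pen <- ext + if (last == "gb") 0 else open
      best <- max(best, -pen + rec(i + 1, j, "gb"))
    }
    if (j <= length(cb)) { # gap in a
      pen <- ext + if (last == "ga") 0 else open
      best <- max(best, -pen + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

# Alignment with class-specific motif blocks planted at fixed columns on
# per-row random (non-conserved) backbones. Uses the three packaged pairs
# that carry diagnostic offsets plus one constructed pair (the packaged
# third pair has no class-disjoint column, so a block built from it would
# rightly be dropped by extraction). Returns the labeled alignment plus the
# planted spans.
planted_block_alignment <- function(n_per_class = 6, width = 120, seed = 1) {
  withr::local_seed(seed)
  pk <- load_signatures()
  sigs <- list(pk[[1]], pk[[2]],
               signature_pair(parse_motif("GDERH"), parse_motif("GAKWH")),
               pk[[4]])
  lens <- vapply(sigs, function(p) length(p$tdc$sets), integer(1))
  anchors <- c(10, 30, 60, 90)
  rows <- list()
  labels <- character()
  for (cl in c("TDC", "TYDC")) {
    side <- if (cl == "TDC") "tdc" else "tydc"
    for (r in seq_len(n_per_class)) {
      chars <- sample(AA20_T, width, replace = TRUE)
      for (k in seq_along(sigs)) {
        sets <- sigs[[k]][[side]]$sets
        for (o in seq_along(sets)) {
          s <- sets[[o]]
          chars[anchors[k] + o - 1] <- if (length(s) == 1) s else sample(s, 1)
        }
      }
      rows[[length(rows) + 1]] <- paste(chars, collapse = "")
      labels <- c(labels, cl)
    }
  }
  aln <- sequence_set(sprintf("r%02d", seq_along(rows)), unlist(rows),
                      class_label = labels, gapped = TRUE)
  list(alignment = labeled_alignment(as_alignment(aln)),
       spans = cbind(start = anchors, end = anchors + lens - 1))
}

# Random additive distance matrix: path-length distances of a random
# unrooted binary tree with positive branch lengths, plus the tree.
random_additive_matrix <- function(n_taxa, seed) {
  withr::local_seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tree, d = d)
}
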