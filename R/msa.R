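#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties. A gap of length L costs
#' `gap_open + L * gap_extend`. Defaults (BLOSUM62, 10/1) are the standard
#' protein choices and are adequate for decarboxylase families of ~500
#' residues with high within-class identity.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`), or a symmetric numeric
#'   matrix with residue dimnames.
#' @param gap_open,gap_extend Positive gap penalties, `gap_extend <= gap_open`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  if (is.character(matrix)) {
    name <- matrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  } else {
    name <- "custom"
  }
  matrix <- matrix[AA20, AA20]
  if (!isSymmetric(unname(matrix))) stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  structure(list(name = name, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

seq_to_int <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  match(chars, c(AA20, "X", GAP))
}

# Extended 22-symbol scoring table: 20 residues, X, gap. X scores the
# matrix minimum against everything (conservative); gap rows/cols score 0
# (gap handling is the DP's job, and in profiles existing gaps are free).
scheme_table <- function(s) {
  full <- matrix(0, 22L, 22L)
  full[1:20, 1:20] <- s$matrix
  full[21L, 1:21] <- min(s$matrix)
  full[1:21, 21L] <- min(s$matrix)
  full
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gap penalties (Gotoh). Deterministic
#' traceback: match/mismatch preferred over a gap in `a` over a gap in `b`.
#'
#' @param a,b Ungapped residue strings (or single-row `seq_set`s).
#' @param scheme A [scoring_scheme()].
#' @return List with `a`, `b` (gapped strings of equal length) and `score`.
#' @export
align_pair <- function(a, b, scheme = scoring_scheme()) {
  if (is.data.frame(a)) a <- a$residues
  if (is.data.frame(b)) b <- b$residues
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  ia <- seq_to_int(a)
  ib <- seq_to_int(b)
  tab <- scheme_table(scheme)
  S <- tab[ia, ib, drop = FALSE]
  res <- gotoh_core(S, scheme$gap_open, scheme$gap_extend)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  list(
    a = paste(ifelse(res$a == 0L, GAP, ca[pmax(res$a, 1L)]), collapse = ""),
    b = paste(ifelse(res$b == 0L, GAP, cb[pmax(res$b, 1L)]), collapse = ""),
    score = res$score
  )
}

#' UPGMA guide tree for progressive alignment
#'
#' Distances are `1 - identity/100` from optimal pairwise alignments of
#' every sequence pair. Returns the merge order used by
#' [progressive_align()]; ties are resolved by `stats::hclust`'s
#' deterministic ordering.
#'
#' @param x A `seq_set` with at least 2 sequences.
#' @param scheme A [scoring_scheme()].
#' @return An `hclust` object (average linkage) with sequence ids as labels.
#' @export
guide_tree <- function(x, scheme = scoring_scheme()) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 sequences to build a guide tree")
  d <- matrix(0, n, n, dimnames = list(x$id, x$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_pair(x$residues[i], x$residues[j], scheme)
      d[i, j] <- d[j, i] <- 1 - percent_identity(al$a, al$b) / 100
    }
  }
  hclust(as.dist(d), method = "average")
}

# Profile: 22 x W count matrix (rows: AA20, X, gap) over the rows of a
# gapped character matrix.
profile_counts <- function(mat) {
  W <- ncol(mat)
  out <- matrix(0, 22L, W)
  idx <- match(mat, c(AA20, "X", GAP))
  dim(idx) <- dim(mat)
  for (j in seq_len(W)) {
    tb <- tabulate(idx[, j], nbins = 22L)
    out[, j] <- tb
  }
  out
}

# Merge two gapped character matrices along a gotoh_core path.
merge_by_path <- function(ma, mb, pa, pb) {
  W <- length(pa)
  out <- matrix(GAP, nrow(ma) + nrow(mb), W)
  ka <- which(pa > 0L)
  kb <- which(pb > 0L)
  out[seq_len(nrow(ma)), ka] <- ma[, pa[ka], drop = FALSE]
  out[nrow(ma) + seq_len(nrow(mb)), kb] <- mb[, pb[kb], drop = FALSE]
  out
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile progressive alignment along the UPGMA guide tree.
#' The score for pairing two profile columns is the mean pairwise
#' substitution score over their residue frequencies (gap entries
#' contribute zero), and new gaps pay the scheme's affine penalties. For
#' two sequences the result is exactly the optimal pairwise alignment.
#'
#' @param x A `seq_set` with at least 2 ungapped sequences.
#' @param scheme A [scoring_scheme()].
#' @return A gapped `seq_set` of class `c("aa_alignment", "seq_set",
#'   "data.frame")`, rows in input order; degapping any row recovers its
#'   input sequence.
#' @export
progressive_align <- function(x, scheme = scoring_scheme()) {
  ht <- guide_tree(x, scheme)
  tab <- scheme_table(scheme)
  rows_of <- list()   # cluster -> original row indices
  mats <- list()      # cluster -> gapped char matrix
  as_mat <- function(k) {
    matrix(strsplit(x$residues[k], "", fixed = TRUE)[[1L]], nrow = 1L)
  }
  n <- nrow(x)
  singles <- vector("list", n)
  for (k in seq_len(n)) singles[[k]] <- list(rows = k, mat = as_mat(k))
  clusters <- vector("list", nrow(ht$merge))
  fetch <- function(ref) {
    if (ref < 0L) singles[[-ref]] else clusters[[ref]]
  }
  for (s in seq_len(nrow(ht$merge))) {
    a <- fetch(ht$merge[s, 1L])
    b <- fetch(ht$merge[s, 2L])
    pa <- profile_counts(a$mat)
    pb <- profile_counts(b$mat)
    fa <- pa / nrow(a$mat)
    fb <- pb / nrow(b$mat)
    S <- t(fa) %*% tab %*% fb
    path <- gotoh_core(S, scheme$gap_open, scheme$gap_extend)
    merged <- merge_by_path(a$mat, b$mat, path$a, path$b)
    clusters[[s]] <- list(rows = c(a$rows, b$rows), mat = merged)
  }
  final <- clusters[[nrow(ht$merge)]]
  ord <- order(final$rows)
  gapped <- apply(final$mat[ord, , drop = FALSE], 1L, paste, collapse = "")
  out <- sequence_set(x$id, gapped, description = x$description,
                      class_label = x$class_label, gapped = TRUE)
  class(out) <- c("aa_alignment", class(out))
  out
}

#' Alignment width (number of columns)
#'
#' @param aln A gapped `seq_set`.
#' @return Integer column count.
#' @export
alignment_width <- function(aln) {
  w <- unique(nchar(aln$residues))
  if (length(w) != 1L) stop("rows have unequal lengths; not an alignment")
  w
}

#' Coerce a gapped sequence set to an alignment
#'
#' Validates equal row lengths and absence of all-gap columns.
#'
#' @param x A `seq_set` whose residues may contain `-`.
#' @return `x` with class `aa_alignment` prepended.
#' @export
as_alignment <- function(x) {
  alignment_width(x)
  m <- alignment_matrix(x)
  if (any(colSums(m != GAP) == 0L)) stop("alignment contains an all-gap column")
  if (!inherits(x, "aa_alignment")) class(x) <- c("aa_alignment", class(x))
  x
}

# Character matrix view of an alignment (rows = sequences).
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
}

#' Remove gaps from a residue string
#'
#' @param x Gapped residue string(s).
#' @return String(s) with `-` removed.
#' @export
degap <- function(x) gsub(GAP, "", x, fixed = TRUE)
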