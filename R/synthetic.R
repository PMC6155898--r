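#' Configuration for the synthetic family generator
#'
#' Describes two protein families of equal length sharing one random
#' backbone. Each class carries its four signature-motif variants at fixed
#' anchor positions (defaults: the reference anchors of the packaged
#' signature set — TDC at 92, 103, 167, 318; TYDC at 137, 148, 217, 369 in
#' a 500-residue chain). Outside its own motif windows every site of a
#' record is substituted independently with probability `mu` (uniform over
#' the other 19 residues); motif windows are noise-free, their variability
#' coming only from sampling each degenerate position uniformly from its
#' allowed set.
#'
#' @param n_tdc,n_tydc Records per class (>= 2 each).
#' @param length Sequence length in residues (default 500).
#' @param mu Per-site substitution probability outside motifs (default
#'   0.05).
#' @param sigs A `signature_set` supplying the motif variants.
#' @param tdc_anchors,tydc_anchors 1-based motif start positions per class;
#'   defaults taken from the signature set's reference positions.
#' @return Object of class `family_config`.
#' @export
family_config <- function(n_tdc = 7L, n_tydc = 7L, length = 500L, mu = 0.05,
                          sigs = load_signatures(),
                          tdc_anchors = NULL, tydc_anchors = NULL) {
  if (n_tdc < 2L || n_tydc < 2L) stop("need at least 2 records per class")
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  if (is.null(tdc_anchors)) {
    tdc_anchors <- vapply(sigs, function(p) p$tdc$position, integer(1))
  }
  if (is.null(tydc_anchors)) {
    tydc_anchors <- vapply(sigs, function(p) p$tydc$position, integer(1))
  }
  lens <- vapply(sigs, function(p) motif_length(p$tdc), integer(1))
  check_layout <- function(anchors, who) {
    if (any(is.na(anchors))) stop(who, " anchors contain NA")
    if (any(anchors < 1L) || any(anchors + lens - 1L > length)) {
      stop(who, " motifs do not fit within length ", length)
    }
    iv <- cbind(anchors, anchors + lens - 1L)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
      stop(who, " motif placements overlap")
    }
  }
  check_layout(tdc_anchors, "TDC")
  check_layout(tydc_anchors, "TYDC")
  structure(list(n_tdc = as.integer(n_tdc), n_tydc = as.integer(n_tydc),
                 length = as.integer(length), mu = mu, sigs = sigs,
                 tdc_anchors = as.integer(tdc_anchors),
                 tydc_anchors = as.integer(tydc_anchors)),
            class = "family_config")
}

# Columns covered by a class's motif windows.
motif_windows <- function(anchors, lens) {
  unlist(lapply(seq_along(anchors), function(k) {
    anchors[k]:(anchors[k] + lens[k] - 1L)
  }))
}

#' Generate a labeled synthetic TDC/TYDC family with ground truth
#'
#' One shared random backbone; per record, class-specific motif variants
#' written at the class anchors (each degenerate position drawn uniformly
#' from its allowed set) and independent substitution noise at rate `mu`
#' elsewhere. Deterministic given `seed`.
#'
#' The ground truth's `diagnostic_columns` are the columns where the two
#' class "ancestors" have disjoint residue sets: at a motif column the
#' class's set is the motif's allowed set, elsewhere it is the backbone
#' singleton. Since the backbone is shared, only motif columns can be
#' diagnostic, and a motif column is diagnostic exactly when the backbone
#' residue of the other class falls outside the motif's allowed set (or the
#' two classes' windows overlap with disjoint sets).
#'
#' @param cfg A [family_config()].
#' @param seed Integer seed.
#' @return List with `sequences` (a `seq_set`, TDC records first) and
#'   `truth` (list: `backbone`, `classes`, `motif_starts` per class,
#'   `diagnostic_columns`).
#' @export
generate_family <- function(cfg = family_config(), seed = 1L) {
  withr::local_seed(seed)
  L <- cfg$length
  backbone <- sample(AA20, L, replace = TRUE)
  lens <- vapply(cfg$sigs, function(p) motif_length(p$tdc), integer(1))
  layout <- list(
    TDC = list(anchors = cfg$tdc_anchors,
               motifs = lapply(cfg$sigs, `[[`, "tdc")),
    TYDC = list(anchors = cfg$tydc_anchors,
                motifs = lapply(cfg$sigs, `[[`, "tydc"))
  )
  n_per <- c(TDC = cfg$n_tdc, TYDC = cfg$n_tydc)
  ids <- character()
  seqs <- character()
  labels <- character()
  for (cl in c("TDC", "TYDC")) {
    anchors <- layout[[cl]]$anchors
    motifs <- layout[[cl]]$motifs
    windows <- motif_windows(anchors, lens)
    free <- setdiff(seq_len(L), windows)
    for (r in seq_len(n_per[[cl]])) {
      chars <- backbone
      if (cfg$mu > 0) {
        hit <- free[stats::runif(length(free)) < cfg$mu]
        for (pos in hit) {
          chars[pos] <- sample(setdiff(AA20, chars[pos]), 1L)
        }
      }
      for (k in seq_along(motifs)) {
        sets <- motifs[[k]]$sets
        for (o in seq_along(sets)) {
          s <- sets[[o]]
          chars[anchors[k] + o - 1L] <-
            if (length(s) == 1L) s else sample(s, 1L)
        }
      }
      ids <- c(ids, sprintf("%s_%02d", tolower(cl), r))
      seqs <- c(seqs, paste(chars, collapse = ""))
      labels <- c(labels, cl)
    }
  }
  # ancestor residue sets per class per column -> planted diagnostic columns
  sets_of <- function(cl) {
    sets <- as.list(backbone)
    anchors <- layout[[cl]]$anchors
    motifs <- layout[[cl]]$motifs
    for (k in seq_along(motifs)) {
      for (o in seq_along(motifs[[k]]$sets)) {
        sets[[anchors[k] + o - 1L]] <- motifs[[k]]$sets[[o]]
      }
    }
    sets
  }
  sa <- sets_of("TDC")
  sb <- sets_of("TYDC")
  diagnostic <- which(vapply(seq_len(L), function(j) {
    length(intersect(sa[[j]], sb[[j]])) == 0L
  }, logical(1)))
  truth <- list(
    backbone = paste(backbone, collapse = ""),
    classes = setNames(labels, ids),
    motif_starts = list(TDC = setNames(cfg$tdc_anchors,
                                       vapply(cfg$sigs, `[[`, character(1), "name")),
                        TYDC = setNames(cfg$tydc_anchors,
                                        vapply(cfg$sigs, `[[`, character(1), "name"))),
    diagnostic_columns = diagnostic
  )
  list(sequences = sequence_set(ids, seqs, class_label = labels),
       truth = truth)
}

#' Generate the near-identical TDC-planted pair
#'
#' Two length-500 sequences carrying the full TDC signature layout,
#' identical except for a single substitution at position 463 — the
#' situation of two orthologous decarboxylases from sibling species whose
#' percent identity is 99.80. Position 463 lies outside every motif
#' window, so both records classify as TDC.
#'
#' @param seed Integer seed.
#' @return A `seq_set` of 2 records (`citrus_a`, `citrus_b`).
#' @export
generate_citrus_like_pair <- function(seed = 1L) {
  fam <- generate_family(family_config(n_tdc = 2L, n_tydc = 2L, mu = 0),
                         seed = seed)
  base <- fam$sequences$residues[1L]
  withr::local_seed(seed + 1L)
  pos <- 463L
  old <- substr(base, pos, pos)
  repl <- sample(setdiff(AA20, old), 1L)
  other <- paste0(substr(base, 1L, pos - 1L), repl,
                  substr(base, pos + 1L, nchar(base)))
  sequence_set(c("citrus_a", "citrus_b"), c(base, other),
               description = c("synthetic clementine-like pTDC",
                               "synthetic sweet-orange-like pTDC"),
               class_label = "UNKNOWN")
}
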