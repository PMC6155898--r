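#' Label-checked alignment for motif discovery
#'
#' Validates that a gapped `seq_set` carries exactly two class labels with
#' at least two rows each.
#'
#' @param aln A gapped `seq_set` with `class_label` set per row.
#' @return `aln` with class `labeled_alignment` prepended.
#' @export
labeled_alignment <- function(aln) {
  alignment_width(aln)
  cls <- unique(aln$class_label)
  if (length(cls) != 2L) {
    stop("need exactly two classes; got: ", paste(cls, collapse = ", "))
  }
  if (any(table(aln$class_label) < 2L)) {
    stop("each class needs at least 2 rows")
  }
  if (!inherits(aln, "labeled_alignment")) {
    class(aln) <- c("labeled_alignment", class(aln))
  }
  aln
}

#' Discovery configuration
#'
#' A column is "conserved" within a class when its gap fraction is at most
#' `max_gap_fraction` and the smallest residue set covering at least
#' `1 - coverage` of the class's non-gap members has at most `max_set_size`
#' residues. The defaults (`max_set_size = 3`, `coverage = 0`) demand that
#' every member be covered, mirroring motifs conserved in all members of a
#' class with at most three printed alternatives per position.
#'
#' @param max_set_size Maximum allowed-set cardinality for conservation.
#' @param coverage Fraction of class members a set may fail to cover
#'   (`0 <= coverage < 0.5`).
#' @param max_gap_fraction Maximum per-class gap fraction of a conserved
#'   column.
#' @param merge_gap Maximum run of non-conserved columns bridged inside one
#'   motif.
#' @param min_length Minimum motif length in columns.
#' @return Object of class `discovery_config`.
#' @export
discovery_config <- function(max_set_size = 3L, coverage = 0,
                             max_gap_fraction = 0.1, merge_gap = 1L,
                             min_length = 4L) {
  if (coverage < 0 || coverage >= 0.5) stop("coverage must be in [0, 0.5)")
  if (max_set_size < 1L) stop("max_set_size must be >= 1")
  structure(list(max_set_size = as.integer(max_set_size), coverage = coverage,
                 max_gap_fraction = max_gap_fraction,
                 merge_gap = as.integer(merge_gap),
                 min_length = as.integer(min_length)),
            class = "discovery_config")
}

#' Per-column, per-class residue profiles
#'
#' @param la A [labeled_alignment()].
#' @return List with `classes` (the two labels) and, per class, `freq` (a
#'   residues x columns matrix of frequencies over non-gap members; columns
#'   that are all-gap in the class are zero) and `gap_fraction` (per
#'   column).
#' @export
column_profiles <- function(la) {
  la <- labeled_alignment(la)
  m <- alignment_matrix(la)
  classes <- sort(unique(la$class_label))
  out <- list(classes = classes)
  for (cl in classes) {
    sub <- m[la$class_label == cl, , drop = FALSE]
    W <- ncol(sub)
    freq <- matrix(0, length(AA_ALPHABET), W,
                   dimnames = list(AA_ALPHABET, NULL))
    gapf <- numeric(W)
    for (j in seq_len(W)) {
      col <- sub[, j]
      gapf[j] <- mean(col == GAP)
      res <- col[col != GAP]
      if (length(res)) {
        tb <- table(factor(res, levels = AA_ALPHABET))
        freq[, j] <- as.numeric(tb) / length(res)
      }
    }
    out[[cl]] <- list(freq = freq, gap_fraction = gapf)
  }
  out
}

# Minimal covering residue set of one class column, or NULL if the column
# is not conserved under cfg. X cannot be part of an allowed set, so with
# coverage = 0 any X in the column disqualifies it.
conserved_set <- function(col, cfg) {
  gapf <- mean(col == GAP)
  if (gapf > cfg$max_gap_fraction) return(NULL)
  res <- col[col != GAP]
  if (!length(res)) return(NULL)
  counts <- sort(table(res[res != "X"]), decreasing = TRUE)
  if (!length(counts)) return(NULL)
  need <- ceiling((1 - cfg$coverage) * length(res))
  covered <- cumsum(counts)
  k <- match(TRUE, covered >= need)
  if (is.na(k) || k > cfg$max_set_size) return(NULL)
  sort(names(counts)[seq_len(k)])
}

# Per-column conserved sets for both classes: list of two lists (NULL where
# not conserved), named by class.
conserved_columns <- function(la, cfg) {
  la <- labeled_alignment(la)
  m <- alignment_matrix(la)
  classes <- sort(unique(la$class_label))
  lapply(setNames(classes, classes), function(cl) {
    sub <- m[la$class_label == cl, , drop = FALSE]
    lapply(seq_len(ncol(sub)), function(j) conserved_set(sub[, j], cfg))
  })
}

#' Columns that discriminate the two classes
#'
#' A column is diagnostic when both classes are conserved there (see
#' [discovery_config()]) and their covering residue sets are disjoint.
#'
#' @param la A [labeled_alignment()].
#' @param cfg A [discovery_config()].
#' @return Ordered integer vector of 1-based column indices.
#' @export
find_diagnostic_columns <- function(la, cfg = discovery_config()) {
  cons <- conserved_columns(la, cfg)
  a <- cons[[1L]]
  b <- cons[[2L]]
  which(vapply(seq_along(a), function(j) {
    !is.null(a[[j]]) && !is.null(b[[j]]) &&
      length(intersect(a[[j]], b[[j]])) == 0L
  }, logical(1)))
}

#' Extract discriminative motif pairs from a labeled alignment
#'
#' Finds maximal runs of columns conserved in both classes (bridging at
#' most `merge_gap` non-conserved columns), keeps runs of at least
#' `min_length` columns containing at least one diagnostic column, and
#' renders each class's pattern in the bracketed-alternatives dialect.
#' Bridged (non-conserved) columns are rendered as the class's full
#' residue set at that column.
#'
#' @param la A [labeled_alignment()].
#' @param cfg A [discovery_config()].
#' @param reference_rows Optional named character vector mapping each class
#'   to the row id whose ungapped numbering anchors the reported positions;
#'   defaults to the first row of each class. `NA` is reported when the
#'   reference row has a gap at the motif start.
#' @return List of `discovered_motif_pair` objects: `span` (first, last
#'   column), `patterns` (named by class), `diagnostic_columns` (alignment
#'   indices), `diagnostic_offsets` (1-based within the motif),
#'   `positions` (reference positions per class).
#' @export
extract_motif_pairs <- function(la, cfg = discovery_config(),
                                reference_rows = NULL) {
  la <- labeled_alignment(la)
  cons <- conserved_columns(la, cfg)
  classes <- names(cons)
  W <- length(cons[[1L]])
  both <- vapply(seq_len(W), function(j) {
    !is.null(cons[[1L]][[j]]) && !is.null(cons[[2L]][[j]])
  }, logical(1))
  diag_cols <- find_diagnostic_columns(la, cfg)
  if (is.null(reference_rows)) {
    reference_rows <- vapply(classes, function(cl) {
      la$id[la$class_label == cl][1L]
    }, character(1))
  }
  # maximal runs of conserved columns, then merge across short breaks
  runs <- rle(both)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blocks <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (!nrow(blocks)) return(list())
  merged <- blocks[1L, , drop = FALSE]
  if (nrow(blocks) > 1L) {
    for (k in 2L:nrow(blocks)) {
      gap_len <- blocks$start[k] - merged$end[nrow(merged)] - 1L
      if (gap_len <= cfg$merge_gap) {
        merged$end[nrow(merged)] <- blocks$end[k]
      } else {
        merged <- rbind(merged, blocks[k, , drop = FALSE])
      }
    }
  }
  m <- alignment_matrix(la)
  out <- list()
  for (k in seq_len(nrow(merged))) {
    span <- c(merged$start[k], merged$end[k])
    cols <- span[1L]:span[2L]
    dg <- intersect(cols, diag_cols)
    if (length(cols) < cfg$min_length || !length(dg)) next
    patterns <- setNames(character(length(classes)), classes)
    for (cl in classes) {
      sets <- lapply(cols, function(j) {
        s <- cons[[cl]][[j]]
        if (is.null(s)) {
          sub <- m[la$class_label == cl, j]
          s <- sort(unique(sub[sub != GAP & sub != "X"]))
        }
        s
      })
      patterns[cl] <- paste(vapply(sets, function(s) {
        if (length(s) == 1L) s else paste0("[", paste(s, collapse = "/"), "]")
      }, character(1)), collapse = "")
    }
    positions <- vapply(classes, function(cl) {
      rid <- reference_rows[[cl]]
      row <- la$residues[la$id == rid]
      if (substr(row, span[1L], span[1L]) == GAP) {
        NA_integer_
      } else {
        column_to_reference_position(la, rid, span[1L])
      }
    }, integer(1))
    out[[length(out) + 1L]] <- structure(
      list(span = span, patterns = patterns, diagnostic_columns = dg,
           diagnostic_offsets = dg - span[1L] + 1L, positions = positions),
      class = "discovered_motif_pair"
    )
  }
  out
}

#' Map an alignment column to a reference row's ungapped position
#'
#' @param aln A gapped `seq_set`.
#' @param row_id Id of the reference row.
#' @param column 1-based alignment column; must not be a gap in that row.
#' @return 1-based position in the ungapped reference sequence.
#' @export
column_to_reference_position <- function(aln, row_id, column) {
  row <- aln$residues[aln$id == row_id]
  if (!length(row)) stop("no row with id '", row_id, "'")
  if (column < 1L || column > nchar(row)) stop("column out of range")
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  if (chars[column] == GAP) {
    stop("row '", row_id, "' has a gap at column ", column)
  }
  sum(chars[seq_len(column)] != GAP)
}

#' Convert discovered motif pairs to a loadable signature set
#'
#' Maps the `TDC`/`TYDC` patterns of discovered pairs into the same
#' structure as the packaged signature fixture so they can drive
#' [classify_sequence()] directly.
#'
#' @param pairs Result of [extract_motif_pairs()] on a TDC/TYDC-labeled
#'   alignment.
#' @return A `signature_set`.
#' @export
discovered_to_signatures <- function(pairs) {
  out <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    if (!all(c("TDC", "TYDC") %in% names(p$patterns))) {
      stop("discovered pair ", k, " is not labeled TDC/TYDC")
    }
    signature_pair(
      parse_motif(p$patterns[["TDC"]], position = p$positions[["TDC"]]),
      parse_motif(p$patterns[["TYDC"]], position = p$positions[["TYDC"]]),
      name = paste0("discovered_", k)
    )
  })
  structure(out, class = "signature_set")
}
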