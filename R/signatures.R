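#' Parse a degenerate motif pattern
#'
#' Patterns use the bracketed-alternatives dialect of the signature table:
#' a single residue per position, or a slash-separated set in square
#' brackets, e.g. `"T[H/N]W[L/M]SP"`.
#'
#' @param pattern Pattern string.
#' @param name Optional motif name.
#' @param position Optional 1-based reference anchor position (metadata
#'   only; never used for matching).
#' @param annotation Optional hypothetical binding role.
#' @return An object of class `deg_motif`: a list with `name`, `sets`
#'   (ordered list of allowed-residue character vectors), `position`,
#'   `annotation`.
#' @export
parse_motif <- function(pattern, name = pattern, position = NA_integer_,
                        annotation = NA_character_) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sets <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "]") { close <- j; break }
        if (chars[j] == "[") break
        j <- j + 1L
      }
      if (is.na(close)) {
        stop("unbalanced '[' at offset ", i, " in pattern '", pattern, "'")
      }
      inner <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      alts <- strsplit(inner, "/", fixed = TRUE)[[1L]]
      n_expected <- nchar(gsub("[^/]", "", inner)) + 1L
      if (!length(alts) || length(alts) != n_expected || any(!nzchar(alts))) {
        stop("empty alternative at offset ", i, " in pattern '", pattern, "'")
      }
      if (any(nchar(alts) != 1L) || any(!alts %in% AA20)) {
        stop("illegal residue in alternatives at offset ", i,
             " in pattern '", pattern, "'")
      }
      sets[[length(sets) + 1L]] <- alts
      i <- close + 1L
    } else if (ch == "]") {
      stop("unbalanced ']' at offset ", i, " in pattern '", pattern, "'")
    } else {
      if (!ch %in% AA20) {
        stop("illegal residue '", ch, "' at offset ", i,
             " in pattern '", pattern, "'")
      }
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    }
  }
  if (length(sets) < 3L) {
    stop("motif '", pattern, "' is shorter than 3 positions")
  }
  structure(
    list(name = name, sets = sets, position = position,
         annotation = annotation),
    class = "deg_motif"
  )
}

#' Render a degenerate motif back to its pattern string
#'
#' Inverse of [parse_motif()] on canonical patterns (alternatives in the
#' stored order).
#'
#' @param motif A `deg_motif`.
#' @return Pattern string.
#' @export
motif_to_string <- function(motif) {
  paste(vapply(motif$sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = "/"), "]")
  }, character(1)), collapse = "")
}

#' @export
print.deg_motif <- function(x, ...) {
  cat("<deg_motif> ", motif_to_string(x),
      if (!is.na(x$position)) paste0(" (", x$position, ")"), "\n", sep = "")
  invisible(x)
}

motif_length <- function(motif) length(motif$sets)

#' Construct a TDC/TYDC signature pair
#'
#' @param tdc_motif,tydc_motif `deg_motif` objects of equal length.
#' @param name Pair name.
#' @param binding Hypothetical binding role annotation.
#' @return An object of class `signature_pair` with the diagnostic
#'   offsets precomputed by [diagnostic_positions()].
#' @export
signature_pair <- function(tdc_motif, tydc_motif, name = tdc_motif$name,
                           binding = NA_character_) {
  if (motif_length(tdc_motif) != motif_length(tydc_motif)) {
    stop("motifs in a signature pair must have equal length")
  }
  p <- structure(
    list(name = name, tdc = tdc_motif, tydc = tydc_motif, binding = binding),
    class = "signature_pair"
  )
  p$diagnostic <- diagnostic_positions(p)
  p
}

#' Diagnostic offsets of a signature pair
#'
#' Offsets (1-based, within the motif) where the TDC and TYDC
#' allowed-residue sets are disjoint, so a residue there can only belong
#' to one class. Positions where the sets overlap (e.g. `[H/N]` vs `H`)
#' are not diagnostic.
#'
#' @param pair A `signature_pair`, or a list with `tdc` and `tydc` motifs.
#' @return Sorted integer vector of offsets (possibly empty).
#' @export
diagnostic_positions <- function(pair) {
  a <- pair$tdc$sets
  b <- pair$tydc$sets
  if (length(a) != length(b)) {
    stop("motifs have different lengths (", length(a), " vs ", length(b), ")")
  }
  which(vapply(seq_along(a),
               function(i) length(intersect(a[[i]], b[[i]])) == 0L,
               logical(1)))
}

#' Load the packaged signature set
#'
#' The four signature pairs that discriminate plant TDC from TYDC: the
#' substrate-region motifs anchored at TDC positions 92, 103 and 167 (TYDC
#' 137, 148 and 217) and the PLP-region motif SPHKW/NAHKW at 318/369.
#' Diagnostic offsets are recomputed from the patterns; the packaged
#' `diagnostic_hint` field only records which residues the source table
#' highlighted, and a disagreement indicates a corrupted fixture.
#'
#' @param path Optional path to a signature JSON file in the packaged
#'   schema (fields `name`, `tdc_pattern`, `tydc_pattern`, `tdc_position`,
#'   `tydc_position`, `binding`, optional `diagnostic_hint`).
#' @return An object of class `signature_set`: a list of `signature_pair`s.
#' @export
load_signatures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "signature_motifs.json",
                        package = "tdcsig", mustWork = TRUE)
  }
  rows <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  pairs <- lapply(rows, function(r) {
    p <- signature_pair(
      parse_motif(r$tdc_pattern, name = paste0(r$name, "_tdc"),
                  position = r$tdc_position, annotation = r$binding),
      parse_motif(r$tydc_pattern, name = paste0(r$name, "_tydc"),
                  position = r$tydc_position, annotation = r$binding),
      name = r$name, binding = r$binding
    )
    p$diagnostic_hint <- as.integer(unlist(r$diagnostic_hint))
    p
  })
  structure(pairs, class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> with", length(x), "pairs\n")
  for (p in x) {
    cat(sprintf("  %-22s %s | %s  diagnostic: %s\n", p$name,
                motif_to_string(p$tdc), motif_to_string(p$tydc),
                if (length(p$diagnostic)) {
                  paste(p$diagnostic, collapse = ",")
                } else "none"))
  }
  invisible(x)
}

#' Scan a sequence for matches to a degenerate motif
#'
#' Slides the motif over every ungapped window of the sequence. Residues
#' at offsets in `diagnostic_strict` must belong to the allowed set
#' exactly; remaining offsets may mismatch at up to `max_mismatch`
#' positions. `X` in the sequence never satisfies an allowed set.
#'
#' @param residues Residue string (or a single-row `seq_set`).
#' @param motif A `deg_motif`.
#' @param max_mismatch Mismatch tolerance at non-strict offsets.
#' @param diagnostic_strict Integer offsets (within the motif) that must
#'   match exactly.
#' @return A data frame with columns `start`, `matched`, `n_mismatch`,
#'   `mismatch_offsets` (list column), sorted by `(n_mismatch, start)`.
#'   Empty (no error) when the sequence is shorter than the motif.
#' @export
scan_motif <- function(residues, motif, max_mismatch = 0L,
                       diagnostic_strict = integer()) {
  if (is.data.frame(residues)) {
    stopifnot(nrow(residues) == 1L)
    residues <- residues$residues
  }
  m <- motif_length(motif)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  empty <- data.frame(start = integer(), matched = character(),
                      n_mismatch = integer(), stringsAsFactors = FALSE)
  empty$mismatch_offsets <- list()
  if (n < m) return(empty)
  n_win <- n - m + 1L
  # mism[w, j] : window w mismatches motif offset j
  mism <- matrix(FALSE, nrow = n_win, ncol = m)
  for (j in seq_len(m)) {
    mism[, j] <- !chars[seq_len(n_win) + j - 1L] %in% motif$sets[[j]]
  }
  strict_ok <- if (length(diagnostic_strict)) {
    rowSums(mism[, diagnostic_strict, drop = FALSE]) == 0L
  } else rep(TRUE, n_win)
  soft <- setdiff(seq_len(m), diagnostic_strict)
  n_mm <- rowSums(mism[, soft, drop = FALSE])
  keep <- which(strict_ok & n_mm <= max_mismatch)
  if (!length(keep)) return(empty)
  out <- data.frame(
    start = keep,
    matched = substring(residues, keep, keep + m - 1L),
    n_mismatch = as.integer(n_mm[keep]),
    stringsAsFactors = FALSE
  )
  out$mismatch_offsets <- lapply(keep, function(w) soft[mism[w, soft]])
  ord <- order(out$n_mismatch, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
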