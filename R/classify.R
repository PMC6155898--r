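#' Classification configuration
#'
#' Controls the vote-based TDC/TYDC decision. Each signature pair casts at
#' most one vote: the class whose motif variant attains the strictly better
#' (fewer-mismatch) best match in the query wins the pair; ties and double
#' misses cast no vote. A label is called when the winning class has at
#' least `min_votes` votes and leads by at least `margin`; a query matching
#' nothing is `UNCLASSIFIED`, anything else is `AMBIGUOUS`.
#'
#' The default `min_votes = 3` of 4 reflects that one signature pair has no
#' diagnostic (class-disjoint) position, so demanding all four pairs would
#' be fragile, while the PLP-region SP/NA doublet and the two substrate
#' motifs carry the decision.
#'
#' @param max_mismatch Mismatch tolerance at non-diagnostic offsets
#'   (default 1).
#' @param strict_diagnostic Require exact matches at diagnostic offsets
#'   (default TRUE).
#' @param min_votes Minimum winning-class votes to call a label (default 3).
#' @param margin Minimum vote difference (default 1).
#' @return Object of class `classification_config`.
#' @export
classification_config <- function(max_mismatch = 1L, strict_diagnostic = TRUE,
                                  min_votes = 3L, margin = 1L) {
  if (min_votes > 4L) stop("min_votes cannot exceed the 4 signature pairs")
  if (margin < 0L) stop("margin must be >= 0")
  structure(list(max_mismatch = as.integer(max_mismatch),
                 strict_diagnostic = isTRUE(strict_diagnostic),
                 min_votes = as.integer(min_votes),
                 margin = as.integer(margin)),
            class = "classification_config")
}

# Best match of one motif variant in a sequence under the config.
best_match <- function(residues, motif, diagnostic, cfg) {
  strict <- if (cfg$strict_diagnostic) diagnostic else integer()
  hits <- scan_motif(residues, motif, max_mismatch = cfg$max_mismatch,
                     diagnostic_strict = strict)
  if (!nrow(hits)) return(NULL)
  hits[1L, , drop = FALSE]
}

#' Classify one sequence from signature evidence
#'
#' @param residues Ungapped residue string (or single-row `seq_set`).
#' @param sigs A `signature_set` (default: the packaged one).
#' @param cfg A [classification_config()].
#' @return List of class `classification_result`: `label`, `votes_tdc`,
#'   `votes_tydc`, and `evidence` (per-pair best matches; NULL where a
#'   variant found no match).
#' @export
classify_sequence <- function(residues, sigs = load_signatures(),
                              cfg = classification_config()) {
  if (is.data.frame(residues)) {
    stopifnot(nrow(residues) == 1L)
    residues <- residues$residues
  }
  votes <- c(TDC = 0L, TYDC = 0L)
  evidence <- vector("list", length(sigs))
  names(evidence) <- vapply(sigs, `[[`, character(1), "name")
  for (k in seq_along(sigs)) {
    pair <- sigs[[k]]
    bt <- best_match(residues, pair$tdc, pair$diagnostic, cfg)
    by <- best_match(residues, pair$tydc, pair$diagnostic, cfg)
    mt <- if (is.null(bt)) Inf else bt$n_mismatch
    my <- if (is.null(by)) Inf else by$n_mismatch
    if (mt < my) votes["TDC"] <- votes["TDC"] + 1L
    if (my < mt) votes["TYDC"] <- votes["TYDC"] + 1L
    evidence[[k]] <- list(tdc = bt, tydc = by)
  }
  total <- sum(votes)
  label <- if (total == 0L) {
    "UNCLASSIFIED"
  } else {
    win <- names(votes)[which.max(votes)]
    lead <- abs(votes[["TDC"]] - votes[["TYDC"]])
    if (max(votes) >= cfg$min_votes && lead >= cfg$margin) win else "AMBIGUOUS"
  }
  structure(list(label = label, votes_tdc = votes[["TDC"]],
                 votes_tydc = votes[["TYDC"]], evidence = evidence),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>", x$label,
      sprintf("(TDC %d : %d TYDC)\n", x$votes_tdc, x$votes_tydc))
  invisible(x)
}

#' Classify every sequence in a set
#'
#' @param x A `seq_set` of ungapped sequences.
#' @param sigs A `signature_set`.
#' @param cfg A [classification_config()].
#' @return Data frame with one row per record: `id`, `label`, `votes_tdc`,
#'   `votes_tydc`, and per-pair `<pair>_start` / `<pair>_mismatch` columns
#'   for the winning variant (NA when no variant matched). The summary
#'   counts per label are attached as the `summary` attribute.
#' @export
classify_set <- function(x, sigs = load_signatures(),
                         cfg = classification_config()) {
  pair_names <- vapply(sigs, `[[`, character(1), "name")
  if (nrow(x) == 0L) {
    out <- data.frame(id = character(), label = character(),
                      votes_tdc = integer(), votes_tydc = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- table(factor(character(), levels = c(
      "TDC", "TYDC", "AMBIGUOUS", "UNCLASSIFIED")))
    return(out)
  }
  rows <- lapply(seq_len(nrow(x)), function(k) {
    res <- classify_sequence(x$residues[k], sigs, cfg)
    row <- data.frame(id = x$id[k], label = res$label,
                      votes_tdc = res$votes_tdc, votes_tydc = res$votes_tydc,
                      stringsAsFactors = FALSE)
    for (p in pair_names) {
      ev <- res$evidence[[p]]
      best <- NULL
      for (side in list(ev$tdc, ev$tydc)) {
        if (!is.null(side) &&
            (is.null(best) || side$n_mismatch < best$n_mismatch)) {
          best <- side
        }
      }
      row[[paste0(p, "_start")]] <- if (is.null(best)) NA_integer_ else best$start
      row[[paste0(p, "_mismatch")]] <-
        if (is.null(best)) NA_integer_ else best$n_mismatch
    }
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "summary") <- table(factor(out$label, levels = c(
    "TDC", "TYDC", "AMBIGUOUS", "UNCLASSIFIED")))
  out
}

#' Swap the TDC/TYDC sides of every signature pair
#'
#' Utility for symmetry checks: relabeling the two motif sets of every
#' pair must swap TDC/TYDC calls on any input.
#'
#' @param sigs A `signature_set`.
#' @return A `signature_set` with sides exchanged.
#' @export
swap_signatures <- function(sigs) {
  out <- lapply(sigs, function(p) {
    signature_pair(p$tydc, p$tdc, name = p$name, binding = p$binding)
  })
  structure(out, class = "signature_set")
}
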