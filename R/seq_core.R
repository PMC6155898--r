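#' Construct a sequence set
#'
#' A sequence set is the package's basic container for labeled protein
#' sequences: a data frame with columns `id`, `description`, `residues`
#' and `class_label` (one of `"TDC"`, `"TYDC"`, `"UNKNOWN"`). Residues are
#' uppercase amino acids over the 20-letter alphabet plus the ambiguity
#' code `X`; aligned sets may additionally contain the gap character `-`.
#'
#' @param id Character vector of unique identifiers.
#' @param residues Character vector of residue strings (same length as `id`).
#' @param description Optional free-text descriptions.
#' @param class_label Class labels, recycled; one of `TDC`, `TYDC`, `UNKNOWN`.
#' @param gapped Logical; allow the gap character `-` in `residues`.
#' @return A data frame of class `seq_set`.
#' @export
sequence_set <- function(id, residues, description = "",
                         class_label = "UNKNOWN", gapped = FALSE) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues)) {
    stop("'id' and 'residues' must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  class_label <- rep_len(as.character(class_label), length(id))
  bad <- setdiff(unique(class_label), c("TDC", "TYDC", "UNKNOWN"))
  if (length(bad)) stop("unknown class label: ", bad[1L])
  for (k in seq_along(residues)) {
    validate_residues(residues[k], id[k], gapped = gapped)
  }
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    residues = residues,
    class_label = class_label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_set", "data.frame")
  out
}

validate_residues <- function(x, id, gapped = FALSE) {
  if (!nzchar(x)) stop("sequence '", id, "' is empty")
  ok <- AA_ALPHABET
  if (gapped) ok <- c(ok, GAP)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop("illegal residue '", chars[bad[1L]], "' in sequence '", id,
         "' at position ", bad[1L])
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Class labels are recovered from a `class=` token in the description
#' (the convention used by [write_fasta()] and the synthetic generator);
#' records without one are labeled `UNKNOWN`.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param gapped Logical; accept gap characters (aligned FASTA).
#' @return A `seq_set` (empty for an empty file).
#' @export
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (!length(meaningful)) {
    return(sequence_set(character(), character()))
  }
  first <- meaningful[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA in '", path, "': line ", first,
         " contains sequence data before any '>' header")
  }
  # parsed directly: residues must be validated verbatim, with the record
  # and position of any illegal character reported
  is_header <- startsWith(lines, ">")
  rec <- cumsum(is_header)
  headers <- trimws(sub("^>", "", lines[is_header]))
  seqs <- vapply(seq_along(headers), function(k) {
    body <- lines[!is_header & rec == k]
    toupper(gsub("[ \t]", "", paste(body, collapse = "")))
  }, character(1))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  cls <- rep("UNKNOWN", length(headers))
  has <- grepl("class=(TDC|TYDC|UNKNOWN)", desc)
  cls[has] <- sub("^.*class=(TDC|TYDC|UNKNOWN).*$", "\\1", desc[has])
  sequence_set(ids, seqs, description = desc,
               class_label = cls, gapped = gapped)
}

#' Write a sequence set to FASTA
#'
#' The class label is appended to the header as a `class=` token unless it
#' is already present in the description, so that [read_fasta()] recovers it.
#'
#' @param x A `seq_set` (gapped or ungapped).
#' @param path Output file path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(x))) {
    desc <- x$description[k]
    if (!grepl("class=", desc)) {
      desc <- trimws(paste(desc, paste0("class=", x$class_label[k])))
    }
    writeLines(paste0(">", trimws(paste(x$id[k], desc))), con)
    s <- x$residues[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Percent identity between two equal-length (possibly gapped) strings
#'
#' Identity is the number of columns with identical non-gap residues over
#' the number of columns where at least one string has a residue; columns
#' that are gaps in both strings are excluded from the denominator. The
#' ambiguity code `X` never counts as a match. The result is reported to
#' two decimals, the precision at which near-identical isoforms are
#' conventionally compared (e.g. 99.80 for one substitution in 500).
#'
#' @param a,b Residue strings of equal length.
#' @return Percentage in `[0, 100]`, rounded to 2 decimals.
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  scored <- !(ca == GAP & cb == GAP)
  if (!any(scored)) stop("no scored columns: both sequences are all gaps")
  ident <- scored & ca == cb & ca != GAP & ca != "X"
  round(100 * sum(ident) / sum(scored), 2)
}

#' Load the packaged TDC/TYDC accession catalog
#'
#' The catalog lists the 42 plant aromatic L-amino-acid decarboxylase
#' accessions used as the labeled reference panel: 14 TDC sequences from
#' 10 species and 28 TYDC sequences from 13 species, with database
#' accession strings verbatim.
#'
#' @return A data frame with columns `species`, `accession`, `class`.
#' @export
load_catalog <- function() {
  path <- system.file("extdata", "decarboxylase_catalog.tsv",
                      package = "tdcsig", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Residue count encoded by an ORF span
#'
#' Number of amino acids encoded by an open reading frame spanning
#' transcript nucleotides `start_nt` to `end_nt` inclusive, where the last
#' codon is a stop codon (not translated). The canonical example is the
#' Catharanthus roseus TDC transcript: nt 70 to 1572 encode 500 residues.
#'
#' @param start_nt,end_nt 1-based first and last nucleotide of the ORF.
#' @return Integer number of encoded residues.
#' @export
orf_protein_length <- function(start_nt, end_nt) {
  len <- end_nt - start_nt + 1L
  if (len < 6L || len %% 3L != 0L) {
    stop("ORF span of ", len, " nt is not a whole number of codons (>= 2)")
  }
  as.integer(len / 3L - 1L)
}
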