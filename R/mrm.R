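# Monoisotopic atomic masses (Da). The proton constant already carries the
# electron adjustment for [M+H]+ ions; permanently charged cations subtract
# the electron mass explicitly.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  D = 2.0141017780,
  N = 14.0030740052,
  O = 15.9949146221
)
PROTON_MASS <- 1.00727646
ELECTRON_MASS <- 0.00054857990907

#' Parse a molecular formula
#'
#' Supported elements: C, H, D (deuterium), N, O. Counts must be positive
#' integers; a bare symbol means count 1. No normalization is applied.
#'
#' @param s Formula string, e.g. `"C10H12N2"`, `"NH3"`.
#' @param charge Integer charge (0 or +1).
#' @return Object of class `mol_formula`: named integer vector of counts
#'   with a `charge` attribute.
#' @export
parse_formula <- function(s, charge = 0L) {
  if (!grepl("^([CHDNO][0-9]*)+$", s)) {
    stop("cannot parse formula '", s, "': unknown element or stray character")
  }
  m <- gregexpr("[CHDNO][0-9]*", s)[[1L]]
  parts <- regmatches(s, list(m))[[1L]]
  counts <- integer(0)
  for (p in parts) {
    el <- substr(p, 1L, 1L)
    cnt <- if (nchar(p) > 1L) as.integer(substr(p, 2L, nchar(p))) else 1L
    if (cnt == 0L) stop("zero count for element ", el, " in '", s, "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + cnt
  }
  mol_formula(counts, charge)
}

mol_formula <- function(counts, charge = 0L) {
  counts <- counts[counts > 0L]
  if (!length(counts)) stop("formula must contain at least one atom")
  if (!charge %in% c(0L, 1L)) stop("only charges 0 and +1 are supported")
  full <- setNames(integer(5L), names(ATOMIC_MASS))
  full[names(counts)] <- as.integer(counts)
  structure(full, charge = as.integer(charge), class = "mol_formula")
}

#' @export
print.mol_formula <- function(x, ...) {
  nz <- x[x > 0L]
  cat(paste0(names(nz), ifelse(nz > 1L, nz, "")), sep = "")
  if (attr(x, "charge") == 1L) cat("+")
  cat("\n")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of atomic monoisotopic masses (neutral mass; the charge attribute is
#' ignored here — use [formula_mz()] for ions).
#'
#' @param f A `mol_formula` or formula string.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(unclass(f) * ATOMIC_MASS[names(f)])
}

#' m/z of a (possibly charged) formula
#'
#' For a +1 species the electron mass is subtracted; for neutral formulas
#' this is just the monoisotopic mass.
#'
#' @param f A `mol_formula`.
#' @return m/z in Da per unit charge.
#' @export
formula_mz <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  monoisotopic_mass(f) - attr(f, "charge") * ELECTRON_MASS
}

#' Analyte specification for the tryptamine methylation series
#'
#' @param n_methyl Number of N-methyl groups, 0-3.
#' @param labeled_d5 Logical: indole-ring d5 labeling (five ring hydrogens
#'   replaced by deuterium, mass shift ~5.0314 Da).
#' @return Object of class `analyte_spec`.
#' @export
analyte_spec <- function(n_methyl = 0L, labeled_d5 = FALSE) {
  n_methyl <- as.integer(n_methyl)
  if (!n_methyl %in% 0:3) stop("n_methyl must be 0, 1, 2 or 3")
  structure(list(n_methyl = n_methyl, labeled_d5 = isTRUE(labeled_d5)),
            class = "analyte_spec")
}

ANALYTE_NAMES <- c("tryptamine", "N-methyltryptamine",
                   "N,N-dimethyltryptamine", "N,N,N-trimethyltryptamine")

analyte_name <- function(a) {
  paste0(if (a$labeled_d5) "[d5]", ANALYTE_NAMES[a$n_methyl + 1L])
}

#' Ion formula of a series analyte
#'
#' Tryptamine (C10H12N2) and its mono- and di-methyl derivatives ionize as
#' `[M+H]+`; the N,N,N-trimethyl derivative is a quaternary ammonium cation
#' (C13H19N2+) detected at its own m/z with no added proton. d5 labeling
#' replaces five indole-ring hydrogens with deuterium.
#'
#' @param a An [analyte_spec()].
#' @return A `mol_formula` with charge +1.
#' @export
analyte_formula <- function(a) {
  stopifnot(inherits(a, "analyte_spec"))
  n_c <- 10L + a$n_methyl
  # neutral H count 12 + 2 per methyl for n<=2; quaternary cation C13H19N2+
  n_h <- if (a$n_methyl <= 2L) 12L + 2L * a$n_methyl + 1L else 19L
  n_d <- 0L
  if (a$labeled_d5) {
    n_h <- n_h - 5L
    n_d <- 5L
  }
  counts <- c(C = n_c, H = n_h, N = 2L)
  if (n_d > 0L) counts["D"] <- n_d
  mol_formula(counts, charge = 1L)
}

NEUTRAL_LOSSES <- c("NH3", "CH5N", "C2H7N", "C3H9N")
NEUTRAL_LOSS_NAMES <- c("ammonia", "methylamine", "dimethylamine",
                        "trimethylamine")

# Truncate (floor) to `digits` decimals; the instrument transition list is
# printed with floored values, e.g. exact 203.154 -> 203.1 and 208.186 ->
# 208.1, which rounding would misreport as 203.2/208.2.
truncate_mz <- function(x, digits) floor(x * 10^digits) / 10^digits

#' MRM precursor m/z of a series analyte
#'
#' Exact ion m/z truncated (floored, not rounded) to one decimal, the
#' convention of the instrument transition list.
#'
#' @param a An [analyte_spec()].
#' @return Precursor m/z, one decimal.
#' @export
precursor_mz <- function(a) {
  truncate_mz(formula_mz(analyte_formula(a)), 1L)
}

#' MRM product ion of a series analyte
#'
#' The product is the (possibly d5-labeled) protonated vinylindole ion
#' formed by neutral loss of the amine: ammonia for tryptamine,
#' methylamine, dimethylamine or trimethylamine for the N-methylated
#' analytes. The m/z is truncated to an integer (144 unlabeled, 149
#' labeled for every series member).
#'
#' @param a An [analyte_spec()].
#' @return List with `mz` (integer-truncated), `neutral_loss` (name),
#'   `loss_formula` and `exact_mz`.
#' @export
product_mz <- function(a) {
  stopifnot(inherits(a, "analyte_spec"))
  loss <- NEUTRAL_LOSSES[a$n_methyl + 1L]
  exact <- formula_mz(analyte_formula(a)) - monoisotopic_mass(loss)
  list(mz = truncate_mz(exact, 0L),
       neutral_loss = NEUTRAL_LOSS_NAMES[a$n_methyl + 1L],
       loss_formula = loss,
       exact_mz = exact)
}

#' m/z of the protonated neutral-loss amine
#'
#' Diagnostic low-mass fragment: the protonated amine lost by the analyte,
#' e.g. protonated trimethylamine at m/z 60 for the N,N,N-trimethyl
#' species. Truncated to an integer.
#'
#' @param a An [analyte_spec()].
#' @return Integer-truncated m/z.
#' @export
protonated_loss_mz <- function(a) {
  stopifnot(inherits(a, "analyte_spec"))
  loss <- NEUTRAL_LOSSES[a$n_methyl + 1L]
  truncate_mz(monoisotopic_mass(loss) + PROTON_MASS, 0L)
}

#' Full MRM transition table for the tryptamine methylation series
#'
#' All eight (n_methyl, labeling) combinations in the monitored order:
#' unlabeled tryptamine through N,N,N-trimethyltryptamine, then their d5
#' analogues. Precursors are floored to one decimal and products to
#' integers.
#'
#' @return Data frame with columns `analyte`, `n_methyl`, `labeled_d5`,
#'   `precursor_mz`, `product_mz`, `neutral_loss`.
#' @export
transition_table <- function() {
  specs <- list()
  for (lab in c(FALSE, TRUE)) {
    for (n in 0:3) specs[[length(specs) + 1L]] <- analyte_spec(n, lab)
  }
  do.call(rbind, lapply(specs, function(a) {
    pr <- product_mz(a)
    data.frame(
      analyte = analyte_name(a),
      n_methyl = a$n_methyl,
      labeled_d5 = a$labeled_d5,
      precursor_mz = precursor_mz(a),
      product_mz = pr$mz,
      neutral_loss = pr$neutral_loss,
      stringsAsFactors = FALSE
    )
  }))
}
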