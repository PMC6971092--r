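# Reference tables: hydropathy scales, residue masses, pKa sets and the
# Swiss-Prot average amino-acid composition. The same tables are shipped as
# plain TSV under inst/extdata/ so users can inspect or substitute them.

.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# average (not monoisotopic) residue masses, g/mol
.AVG_RESIDUE_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.WATER_MASS <- 18.0153

# UniProtKB/Swiss-Prot release statistics, average composition (%)
.SWISSPROT_COMPOSITION <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37,
  Q = 3.93, E = 6.75, G = 7.07, H = 2.27, I = 5.96,
  L = 9.66, K = 5.84, M = 2.42, F = 3.86, P = 4.70,
  S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

.PKA_SETS <- list(
  lehninger = c(nterm = 9.69, cterm = 2.34, D = 3.65, E = 4.25, C = 8.33,
                Y = 10.07, H = 6.00, K = 10.53, R = 12.48),
  emboss    = c(nterm = 8.6, cterm = 3.6, D = 3.9, E = 4.1, C = 8.5,
                Y = 10.1, H = 6.5, K = 10.8, R = 12.5)
)

#' Hydrophobicity scale lookup
#'
#' Returns a named numeric vector mapping each of the 20 canonical residues to
#' a dimensionless hydropathy value. The default (and only built-in) scale is
#' Kyte-Doolittle; a path to a two-column TSV (`residue`, `value`) is also
#' accepted for custom scales.
#'
#' @param name scale name (`"kyte_doolittle"`) or path to a TSV file.
#' @return named numeric vector over the 20 canonical residues.
#' @export
#' @examples
#' hydrophobicity_scale()[["I"]]  # 4.5
hydrophobicity_scale <- function(name = "kyte_doolittle") {
  if (identical(name, "kyte_doolittle")) return(.KYTE_DOOLITTLE)
  if (file.exists(name)) {
    tab <- utils::read.delim(name, comment.char = "#", stringsAsFactors = FALSE)
    vals <- stats::setNames(as.numeric(tab[[2]]), tab[[1]])
    if (!all(CANONICAL_AA %in% names(vals))) {
      validation_error("hydrophobicity scale file misses canonical residues")
    }
    return(vals[CANONICAL_AA])
  }
  validation_error("unknown hydrophobicity scale: ", name)
}

#' Per-residue hydrophobicity value
#'
#' @param residue single canonical residue letter.
#' @param scale named numeric vector from [hydrophobicity_scale()].
#' @return dimensionless hydropathy value.
#' @export
kd_value <- function(residue, scale = hydrophobicity_scale()) {
  if (!residue %in% names(scale)) {
    validation_error("no hydrophobicity value for residue '", residue, "'")
  }
  unname(scale[[residue]])
}

#' Amino-acid background composition
#'
#' The Swiss-Prot average composition used to draw random background
#' peptides, normalized to sum to 1. A TSV path (`residue`, `frequency`)
#' may be given for custom compositions.
#'
#' @param name `"swissprot"` or a TSV path.
#' @return named numeric vector of relative frequencies (sums to 1).
#' @export
aa_composition <- function(name = "swissprot") {
  if (identical(name, "swissprot")) {
    comp <- .SWISSPROT_COMPOSITION
  } else if (file.exists(name)) {
    tab <- utils::read.delim(name, comment.char = "#", stringsAsFactors = FALSE)
    comp <- stats::setNames(as.numeric(tab[[2]]), tab[[1]])
  } else {
    validation_error("unknown composition: ", name)
  }
  check_composition(comp)
  comp / sum(comp)
}

check_composition <- function(comp) {
  if (!all(CANONICAL_AA %in% names(comp))) {
    validation_error("composition must cover the 20 canonical residues")
  }
  if (any(comp <= 0)) validation_error("composition frequencies must be positive")
  invisible(comp)
}

#' pKa set lookup
#'
#' @param name `"lehninger"` (default) or `"emboss"`.
#' @return named numeric vector with entries `nterm`, `cterm` and the
#'   ionizable side chains D, E, C, Y, H, K, R.
#' @export
pka_set <- function(name = "lehninger") {
  if (!name %in% names(.PKA_SETS)) {
    abort("unknown pKa set: ", name, class = "amphipept_config_error")
  }
  .PKA_SETS[[name]]
}
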