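# riBAQ label-free quantification and peptide-level abundance mapping.
# iBAQ divides a protein's summed MS1 intensity by its number of theoretical
# tryptic peptides of length 6-30; normalizing iBAQ to sum to 1 per sample
# (riBAQ) approximates the relative molar distribution of proteins.

#' Compute riBAQ from protein intensities
#'
#' @param intensities data.frame with columns `protein_id` and either
#'   `intensity` (summed MS1; iBAQ computed here) or `ribaq` (precomputed;
#'   renormalized pass-through).
#' @param sequences named character vector: protein id -> sequence. Required
#'   when computing from intensities.
#' @param rule a [cleavage_rule()] for the theoretical-peptide denominator.
#' @param min_len,max_len theoretical-peptide length window (default 6-30).
#' @return data.frame `protein_id`, `ibaq`, `ribaq`; riBAQ sums to 1.
#' @export
compute_ribaq <- function(intensities, sequences = NULL,
                          rule = cleavage_rule(), min_len = 6L, max_len = 30L) {
  if ("ribaq" %in% names(intensities)) {
    v <- intensities$ribaq
    if (any(v < 0)) validation_error("riBAQ values must be >= 0")
    out <- data.frame(protein_id = intensities$protein_id, ibaq = NA_real_,
                      ribaq = v / sum(v), stringsAsFactors = FALSE)
    return(out)
  }
  if (!"intensity" %in% names(intensities)) {
    validation_error("intensity table needs an 'intensity' or 'ribaq' column")
  }
  if (any(intensities$intensity < 0)) {
    validation_error("intensities must be >= 0")
  }
  missing <- setdiff(intensities$protein_id, names(sequences))
  if (length(missing) > 0L) {
    validation_error("no sequence for protein(s): ", paste(missing, collapse = ", "))
  }
  counts <- vapply(sequences[intensities$protein_id],
                   theoretical_peptide_count, integer(1),
                   rule = rule, min_len = min_len, max_len = max_len)
  zero <- counts == 0L
  if (any(zero)) {
    warning(sum(zero), " protein(s) with zero theoretical peptides excluded: ",
            paste(intensities$protein_id[zero], collapse = ", "))
  }
  keep <- intensities[!zero, , drop = FALSE]
  ibaq <- keep$intensity / counts[!zero]
  data.frame(protein_id = keep$protein_id, ibaq = ibaq,
             ribaq = ibaq / sum(ibaq), stringsAsFactors = FALSE)
}

#' Best ungapped identity of a peptide within a protein
#'
#' Maximum over all ungapped windows of (identical positions / peptide
#' length). Returns 0 when the peptide is longer than the protein.
#'
#' @param peptide,protein canonical sequences.
#' @return fraction in \[0, 1\].
#' @export
window_identity <- function(peptide, protein) {
  np <- nchar(peptide); nq <- nchar(protein)
  if (np > nq) return(0)
  a <- residues(peptide); b <- residues(protein)
  best <- 0L
  for (off in 0:(nq - np)) {
    m <- sum(a == b[(off + 1L):(off + np)])
    if (m > best) best <- m
    if (best == np) break
  }
  best / np
}

#' Peptide-level abundance in a protein mixture
#'
#' Sums riBAQ over proteins carrying the peptide at 100% identity (exact
#' tier) and over proteins with window identity strictly greater than
#' `homolog_threshold` (homolog tier; includes the exact tier).
#'
#' @param peptide peptide sequence.
#' @param proteins data.frame with `id`, `sequence`.
#' @param abundances table from [compute_ribaq()].
#' @param homolog_threshold identity cut-off (default 0.90, strictly
#'   greater passes).
#' @return list: `exact_match_ribaq`, `homolog_ribaq`, `exact_proteins`,
#'   `homolog_proteins`.
#' @export
peptide_abundance <- function(peptide, proteins, abundances,
                              homolog_threshold = 0.90) {
  idx <- match(abundances$protein_id, proteins$id)
  if (anyNA(idx)) {
    warning("protein(s) in abundance table absent from proteome, excluded: ",
            paste(abundances$protein_id[is.na(idx)], collapse = ", "))
  }
  keep <- !is.na(idx)
  ids <- abundances$protein_id[keep]
  ribaq <- abundances$ribaq[keep]
  ident <- vapply(proteins$sequence[idx[keep]], window_identity,
                  numeric(1), peptide = peptide)
  exact <- ident == 1
  homol <- ident > homolog_threshold
  list(exact_match_ribaq = sum(ribaq[exact]),
       homolog_ribaq = sum(ribaq[homol]),
       exact_proteins = ids[exact],
       homolog_proteins = ids[homol])
}
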