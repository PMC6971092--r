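#' @keywords internal
"_PACKAGE"

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

abort <- function(..., class = "amphipept_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

validation_error <- function(...) abort(..., class = "amphipept_validation_error")
io_error <- function(...) abort(..., class = "amphipept_io_error")

is_canonical <- function(sequence) {
  !grepl(paste0("[^", paste(CANONICAL_AA, collapse = ""), "]"), sequence)
}

check_canonical <- function(sequence, what = "sequence") {
  bad <- unique(setdiff(strsplit(sequence, "")[[1]], CANONICAL_AA))
  if (length(bad) > 0L) {
    validation_error(what, " contains non-canonical residue(s): ",
                     paste(bad, collapse = ", "))
  }
  invisible(sequence)
}

#' Split a sequence into single-letter residues
#' @noRd
residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# Deterministic 32-bit sub-seed derived from a master seed and a label,
# so independent stages (background lengths, fixture replicates) do not
# share RNG streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
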