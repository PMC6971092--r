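# Sequence input/output, signal-peptide maturation, exhaustive candidate
# enumeration and similarity clustering of predicted peptides.

#' Read protein sequences from FASTA
#'
#' One record per entry; the header token before the first whitespace becomes
#' the id, the remainder is kept as description. Sequences are uppercased.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `description`, `sequence`,
#'   `signal_end` (NA until set).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) io_error("cannot read FASTA file: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) io_error("failed to parse FASTA '", path,
                                              "': ", conditionMessage(e)))
  if (length(aa) == 0L) {
    warning("FASTA file '", path, "' contains no sequences")
    return(data.frame(id = character(), description = character(),
                      sequence = character(), signal_end = integer(),
                      stringsAsFactors = FALSE))
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    validation_error("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  data.frame(id = ids, description = desc,
             sequence = toupper(as.character(aa)),
             signal_end = NA_integer_, stringsAsFactors = FALSE)
}

#' Write protein or peptide sequences to FASTA
#'
#' @param ids,sequences character vectors of equal length.
#' @param path output file.
#' @export
write_fasta <- function(ids, sequences, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(sequences, ids))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Attach signal-peptide annotations to protein records
#'
#' @param proteins data.frame from [read_fasta()].
#' @param path two-column delimited file (id, signal_end), `#` comments allowed.
#' @return proteins with `signal_end` filled where annotated.
#' @export
read_signal_annotations <- function(proteins, path) {
  if (!file.exists(path)) io_error("cannot read signal annotation file: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           header = TRUE)
  idx <- match(proteins$id, tab[[1]])
  proteins$signal_end <- ifelse(is.na(idx), proteins$signal_end,
                                as.integer(tab[[2]][idx]))
  proteins
}

#' Remove an annotated signal peptide
#'
#' Drops residues `1..signal_end` and clears the annotation. Records without
#' a `signal_end` are returned unchanged; a signal covering the whole
#' sequence is an error (the mature sequence may not be empty).
#'
#' @param record one-row data.frame with `sequence` and `signal_end`.
#' @return the matured record.
#' @export
#' @examples
#' rec <- data.frame(id = "p", sequence = "MKKLLAGIKGII", signal_end = 4L)
#' mature_sequence(rec)$sequence  # "LAGIKGII"
mature_sequence <- function(record) {
  se <- record$signal_end
  if (is.null(se) || all(is.na(se))) return(record)
  for (i in seq_len(nrow(record))) {
    if (is.na(se[i])) next
    len <- nchar(record$sequence[i])
    if (se[i] >= len) {
      validation_error("signal_end (", se[i], ") leaves no mature sequence for '",
                       record$id[i], "' (length ", len, ")")
    }
    record$sequence[i] <- substring(record$sequence[i], se[i] + 1L, len)
    record$signal_end[i] <- NA_integer_
  }
  record
}

#' Enumerate all candidate peptides of a protein
#'
#' Every contiguous subsequence with `min_len <= w <= max_len` appears exactly
#' once. Coordinates are 1-based inclusive on the mature sequence. Candidates
#' overlapping non-canonical residues (B, J, O, U, X, Z) are skipped with a
#' warning, because hydrophobicity values are undefined for them.
#'
#' @param record one-row protein data.frame (`id`, `sequence`).
#' @param min_len,max_len length bounds (default 7 and 30).
#' @return data.frame with `parent_id`, `start`, `end`, `length`, `sequence`.
#' @export
enumerate_peptides <- function(record, min_len = 7L, max_len = 30L) {
  if (min_len > max_len) validation_error("min_len must be <= max_len")
  seqs <- record$sequence
  out <- vector("list", length(seqs))
  for (r in seq_along(seqs)) {
    s <- seqs[r]
    L <- nchar(s)
    lens <- seq.int(min_len, min(max_len, L))
    lens <- lens[lens <= L]
    if (L < min_len || length(lens) == 0L) {
      out[[r]] <- NULL
      next
    }
    starts <- unlist(lapply(lens, function(w) seq_len(L - w + 1L)))
    widths <- rep(lens, times = L - lens + 1L)
    cand <- data.frame(parent_id = record$id[r], start = starts,
                       end = starts + widths - 1L, length = widths,
                       stringsAsFactors = FALSE)
    cand$sequence <- substring(s, cand$start, cand$end)
    if (!is_canonical(s)) {
      bad_pos <- which(!residues(s) %in% CANONICAL_AA)
      keep <- !vapply(seq_len(nrow(cand)), function(i) {
        any(bad_pos >= cand$start[i] & bad_pos <= cand$end[i])
      }, logical(1))
      warning(sum(!keep), " candidate(s) of '", record$id[r],
              "' skipped: overlap non-canonical residues")
      cand <- cand[keep, , drop = FALSE]
    }
    out[[r]] <- cand
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(parent_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Pairwise peptide similarity (ungapped)
#'
#' Fraction of identical aligned positions in the best ungapped sliding
#' alignment of the shorter sequence onto the longer, divided by the shorter
#' length. An embedded peptide therefore scores 1.
#'
#' @param p,q peptide sequences.
#' @return similarity in \[0, 1\].
#' @export
peptide_similarity <- function(p, q) {
  if (nchar(p) > nchar(q)) { tmp <- p; p <- q; q <- tmp }
  a <- residues(p); b <- residues(q)
  np <- length(a); nq <- length(b)
  best <- 0L
  for (off in 0:(nq - np)) {
    m <- sum(a == b[(off + 1L):(off + np)])
    if (m > best) best <- m
  }
  best / np
}

#' Cluster predicted peptides by sequence similarity
#'
#' Single-linkage clustering under `similarity > threshold`. The cluster
#' representative is the highest-scoring member; ties broken by greater
#' length, then lexicographically smallest sequence.
#'
#' @param peptides data.frame with at least `sequence`; an optional `z`
#'   column supplies the score used to pick representatives.
#' @param similarity_threshold default 0.70 (strictly greater passes).
#' @return `peptides` with added `cluster` (integer id) and
#'   `representative` (logical).
#' @export
cluster_peptides <- function(peptides, similarity_threshold = 0.70) {
  n <- nrow(peptides)
  if (n == 0L) {
    peptides$cluster <- integer(0)
    peptides$representative <- logical(0)
    return(peptides)
  }
  # single linkage over unique sequences (identical sequences are trivially
  # linked); sorting unique sequences groups near-identical windows so most
  # expensive alignments are skipped once their components merge
  useq <- sort(unique(peptides$sequence))
  m <- length(useq)
  ints <- lapply(useq, utf8ToInt)
  lens <- nchar(useq)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # all-pairs best ungapped match counts, computed per length pair as
  # position-wise outer equalities (C-level) instead of per-pair loops
  bylen <- split(seq_len(m), lens)
  ws <- as.integer(names(bylen))
  intmat <- function(ix, w) matrix(unlist(ints[ix], use.names = FALSE),
                                   nrow = length(ix), ncol = w, byrow = TRUE)
  for (ai in seq_along(ws)) {
    for (bi in ai:length(ws)) {
      w1 <- ws[ai]; w2 <- ws[bi]
      I <- bylen[[ai]]; J <- bylen[[bi]]
      A <- intmat(I, w1); B <- intmat(J, w2)
      best <- matrix(0L, length(I), length(J))
      for (off in 0:(w2 - w1)) {
        acc <- matrix(0L, length(I), length(J))
        for (p in seq_len(w1)) {
          acc <- acc + outer(A[, p], B[, off + p], "==")
        }
        best <- pmax(best, acc)
      }
      hit <- best > similarity_threshold * w1
      if (w1 == w2) hit[lower.tri(hit, diag = TRUE)] <- FALSE
      idx <- which(hit, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        ri <- find(I[idx[r, 1L]]); rj <- find(J[idx[r, 2L]])
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  # stable ids independent of input order: label clusters by their
  # lexicographically smallest member sequence
  key <- vapply(split(seq_len(m), roots),
                function(ix) min(useq[ix]), character(1))
  ord <- order(key)
  relab <- stats::setNames(seq_along(ord), names(key)[ord])
  uclust <- unname(relab[as.character(roots)])
  peptides$cluster <- uclust[match(peptides$sequence, useq)]
  score <- if ("z" %in% names(peptides)) peptides$z else rep(0, n)
  peptides$representative <- FALSE
  for (cl in unique(peptides$cluster)) {
    ix <- which(peptides$cluster == cl)
    o <- ix[order(-score[ix], -nchar(peptides$sequence[ix]),
                  peptides$sequence[ix])]
    peptides$representative[o[1L]] <- TRUE
  }
  peptides
}
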