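# Keil-style protease digestion and release-feasibility analysis. The
# default trypsin rule cleaves C-terminally of K/R (P1), never before
# proline (blocked P1'), and only slowly before acidic residues (slow P1',
# D/E) — the partial-cleavage mechanism the feasibility analysis exploits.

#' Define a protease cleavage rule
#'
#' @param name protease name.
#' @param p1 residues recognized at P1 (cleave after, for C-side proteases)
#'   or at P1' (cleave before) when `direction = "N"`.
#' @param blocked P1' residues that block cleavage entirely.
#' @param slow P1' residues where cleavage is slow/optional; must be
#'   disjoint from `blocked`.
#' @param direction `"C"` (cleave after P1, e.g. trypsin) or `"N"`
#'   (cleave before the recognized residue, e.g. Asp-N).
#' @return list of class `cleavage_rule`.
#' @export
cleavage_rule <- function(name = "trypsin", p1 = c("K", "R"),
                          blocked = "P", slow = c("D", "E"),
                          direction = c("C", "N")) {
  direction <- match.arg(direction)
  if (length(intersect(blocked, slow)) > 0L) {
    validation_error("blocked and slow P1' sets must be disjoint")
  }
  structure(list(name = name, p1 = p1, blocked = blocked, slow = slow,
                 direction = direction), class = "cleavage_rule")
}

#' Asp-N endopeptidase rule (cleaves N-terminally of D)
#' @export
aspn_rule <- function() {
  cleavage_rule("aspn", p1 = "D", blocked = character(0),
                slow = character(0), direction = "N")
}

# cut positions: cut after residue i (i in 1..L-1)
cut_sites <- function(res, rule, skip_slow_sites = FALSE) {
  L <- length(res)
  if (L < 2L) return(integer(0))
  i <- seq_len(L - 1L)
  if (rule$direction == "C") {
    ok <- res[i] %in% rule$p1 & !(res[i + 1L] %in% rule$blocked)
    if (skip_slow_sites) ok <- ok & !(res[i + 1L] %in% rule$slow)
  } else {
    ok <- res[i + 1L] %in% rule$p1 & !(res[i] %in% rule$blocked)
    if (skip_slow_sites) ok <- ok & !(res[i] %in% rule$slow)
  }
  i[ok]
}

#' Digest a sequence with a cleavage rule
#'
#' Cleaves after each P1 residue unless the following residue is blocked;
#' with `skip_slow_sites = TRUE`, sites whose P1' residue is in the slow set
#' are additionally left uncut. Fragments always tile the parent exactly.
#'
#' @param sequence canonical protein sequence.
#' @param rule a [cleavage_rule()].
#' @param skip_slow_sites skip slow P1' sites (default FALSE = full digest).
#' @return data.frame with `start`, `end` (1-based inclusive), `sequence`,
#'   `skipped_slow_sites` (comma-separated positions inside the fragment).
#' @export
digest <- function(sequence, rule = cleavage_rule(),
                   skip_slow_sites = FALSE) {
  check_canonical(sequence)
  res <- residues(sequence)
  cuts <- cut_sites(res, rule, skip_slow_sites)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(res))
  skipped <- if (skip_slow_sites) {
    setdiff(cut_sites(res, rule, FALSE), cuts)
  } else integer(0)
  frag_skips <- vapply(seq_along(starts), function(j) {
    inside <- skipped[skipped >= starts[j] & skipped < ends[j]]
    paste(inside, collapse = ",")
  }, character(1))
  data.frame(start = starts, end = ends,
             sequence = substring(sequence, starts, ends),
             skipped_slow_sites = frag_skips, stringsAsFactors = FALSE)
}

#' Number of theoretical peptides in a length window
#'
#' Count of fully cleaved fragments (no slow-site skipping, no missed
#' cleavages) whose length falls within `[min_len, max_len]` — the iBAQ
#' denominator.
#'
#' @param sequence canonical protein sequence.
#' @param rule a [cleavage_rule()].
#' @param min_len,max_len length window (default 6-30).
#' @return integer count.
#' @export
theoretical_peptide_count <- function(sequence, rule = cleavage_rule(),
                                      min_len = 6L, max_len = 30L) {
  fr <- digest(sequence, rule, skip_slow_sites = FALSE)
  len <- fr$end - fr$start + 1L
  sum(len >= min_len & len <= max_len)
}

#' Feasibility of releasing a target peptide by digestion
#'
#' Digests the parent under both slow-site regimes and, per regime, selects
#' the fragment with maximal overlap with the target span. Reports N/C
#' truncations (target residues lost), N/C elongations (extra fragment
#' residues), and the number of fast (non-slow, non-blocked) cleavage sites
#' strictly inside the target. Verdict (from the slow-site-skipping digest):
#' `"feasible"` if a fragment equals the target exactly,
#' `"feasible_with_modification"` if the best fragment covers at least
#' `min_coverage` of the target, else `"infeasible"`. An internal fast site
#' always rules out the intact verdict.
#'
#' @param target_start,target_end 1-based inclusive span on the parent.
#' @param parent_sequence parent protein sequence.
#' @param target_sequence optional; validated against the span if given.
#' @param rule a [cleavage_rule()].
#' @param min_coverage fraction of the target a fragment must cover to be
#'   called releasable with modification (default 0.75).
#' @return list of class `release_report`.
#' @export
release_feasibility <- function(target_start, target_end, parent_sequence,
                                target_sequence = NULL,
                                rule = cleavage_rule(), min_coverage = 0.75) {
  L <- nchar(parent_sequence)
  if (target_start < 1L || target_end > L || target_start > target_end) {
    validation_error("target span outside parent sequence")
  }
  span_seq <- substring(parent_sequence, target_start, target_end)
  if (!is.null(target_sequence) && !identical(span_seq, target_sequence)) {
    validation_error("target sequence does not match parent at ",
                     target_start, "-", target_end)
  }
  res <- residues(parent_sequence)
  fast <- cut_sites(res, rule, skip_slow_sites = TRUE)
  internal_fast <- fast[fast >= target_start & fast < target_end]
  best_fragment <- function(skip) {
    fr <- digest(parent_sequence, rule, skip_slow_sites = skip)
    ov <- pmax(0L, pmin(fr$end, target_end) - pmax(fr$start, target_start) + 1L)
    fr[which.max(ov), , drop = FALSE]
  }
  tlen <- target_end - target_start + 1L
  report_for <- function(frag) {
    list(fragment = frag,
         n_term_truncation = max(0L, frag$start - target_start),
         c_term_truncation = max(0L, target_end - frag$end),
         n_term_elongation = max(0L, target_start - frag$start),
         c_term_elongation = max(0L, frag$end - target_end),
         coverage = (pmin(frag$end, target_end) -
                       pmax(frag$start, target_start) + 1L) / tlen)
  }
  full <- report_for(best_fragment(FALSE))
  slow <- report_for(best_fragment(TRUE))
  verdict <- if (slow$coverage == 1 && slow$n_term_elongation == 0L &&
                 slow$c_term_elongation == 0L) {
    "feasible"
  } else if (slow$coverage >= min_coverage) {
    "feasible_with_modification"
  } else {
    "infeasible"
  }
  structure(list(target_start = target_start, target_end = target_end,
                 target_sequence = span_seq,
                 internal_fast_sites = length(internal_fast),
                 full_digest = full, slow_skipping_digest = slow,
                 verdict = verdict, rule = rule$name), class = "release_report")
}

#' @export
print.release_report <- function(x, ...) {
  cat(sprintf("Release feasibility (%s) for %d-%d %s\n", x$rule,
              x$target_start, x$target_end, x$target_sequence))
  cat(sprintf("  internal fast sites: %d\n", x$internal_fast_sites))
  s <- x$slow_skipping_digest
  cat(sprintf("  best fragment (slow sites skipped): %d-%d %s\n",
              s$fragment$start, s$fragment$end, s$fragment$sequence))
  cat(sprintf("  truncation N/C: %d/%d  elongation N/C: %d/%d  coverage: %.2f\n",
              s$n_term_truncation, s$c_term_truncation,
              s$n_term_elongation, s$c_term_elongation, s$coverage))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
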