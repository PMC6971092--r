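# Secondary-structure gating and assembly of the final ranked predictions.
# Helical and strand scores are zeroed when the peptide's average predicted
# probability of the corresponding conformation falls below a threshold
# (default 0.3, strictly below fails); the axial score is never gated
# because the two-block mechanism works in any conformation.

#' Load per-residue secondary-structure probability profiles
#'
#' Generic delimited format: columns `id`, `position`, `p_helix`, `p_strand`,
#' `p_coil` (tab- or comma-delimited, header required, `#` comments allowed).
#' Positions must be contiguous from 1 per protein and probabilities in
#' \[0, 1\]; no sum constraint is imposed, since predictor outputs may not
#' normalize exactly.
#'
#' @param path profile file.
#' @return data.frame keyed by (`id`, `position`).
#' @export
load_ss_profiles <- function(path) {
  if (!file.exists(path)) io_error("cannot read profile file: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("id", "position", "p_helix", "p_strand", "p_coil")
  if (!all(need %in% names(tab))) {
    validation_error("profile file must have columns: ", paste(need, collapse = ", "))
  }
  for (col in c("p_helix", "p_strand", "p_coil")) {
    bad <- which(tab[[col]] < 0 | tab[[col]] > 1)
    if (length(bad) > 0L) {
      validation_error("probability out of [0,1] in column ", col,
                       " at data line ", bad[1])
    }
  }
  for (pid in unique(tab$id)) {
    pos <- sort(tab$position[tab$id == pid])
    if (!identical(as.integer(pos), seq_len(length(pos)))) {
      validation_error("positions of '", pid, "' are not contiguous from 1")
    }
  }
  tab[order(tab$id, tab$position), , drop = FALSE]
}

#' Average conformation probability over a residue span
#'
#' Unbiased arithmetic mean of the per-residue probability of the given
#' state over `start..end`.
#'
#' @param profiles table from [load_ss_profiles()].
#' @param id protein id.
#' @param start,end 1-based inclusive span.
#' @param state `"helix"` or `"strand"`.
#' @return probability in \[0, 1\].
#' @export
avg_probability <- function(profiles, id, start, end, state = c("helix", "strand")) {
  state <- match.arg(state)
  sub <- profiles[profiles$id == id, , drop = FALSE]
  if (nrow(sub) == 0L) validation_error("no profile for protein '", id, "'")
  if (start < 1L || end > nrow(sub) || start > end) {
    validation_error("span ", start, "-", end, " outside profile of '", id,
                     "' (length ", nrow(sub), ")")
  }
  col <- if (state == "helix") "p_helix" else "p_strand"
  mean(sub[[col]][sub$position >= start & sub$position <= end])
}

#' Apply the structure gate to a score
#'
#' Helical/strand scores with average probability strictly below the
#' threshold are set to 0; a probability exactly at the threshold passes.
#' Axial scores are returned unchanged regardless of `avg_prob`.
#'
#' @param z score value (any scale; gating is 0-or-unchanged).
#' @param score_type `"alpha"`, `"beta"` or `"gamma"`.
#' @param avg_prob average conformation probability (may be NA for gamma).
#' @param threshold default 0.3.
#' @return gated score.
#' @export
gate <- function(z, score_type, avg_prob, threshold = 0.3) {
  gated <- score_type %in% c("alpha", "beta") &
    (is.na(avg_prob) | avg_prob < threshold)
  ifelse(gated, 0, z)
}

#' Predict emulsifier peptides in a set of proteins
#'
#' Full prediction pass: enumerate candidates, compute the three raw scores,
#' z-normalize per length and type, gate helical/strand scores on average
#' structure probability, keep scores above the z threshold, cluster the
#' hits by sequence similarity and annotate physicochemical properties. A
#' peptide passing several score types appears once per passing type;
#' `best_type` marks its maximal-z type.
#'
#' @param proteins protein data.frame (mature sequences).
#' @param background model table from [build_background()].
#' @param profiles optional table from [load_ss_profiles()]. Proteins
#'   without a profile have their helical/strand scores gated to 0 with a
#'   warning (set `missing_profile = "error"` to make this fatal).
#' @param min_len,max_len candidate length bounds.
#' @param z_threshold final score cut-off (strictly greater passes).
#' @param gate_threshold structure-probability gate.
#' @param similarity_threshold clustering threshold.
#' @param scale hydrophobicity scale vector.
#' @param missing_profile `"gate"` (default) or `"error"`.
#' @return data.frame of hits sorted by z descending: candidate fields,
#'   `score_type`, `raw`, `split_k`, `avg_structure_prob`, `gated`, `z`,
#'   `best_type`, `cluster`, `representative`, `mw`, `pI`, `net_charge`.
#' @export
predict_peptides <- function(proteins, background, profiles = NULL,
                             min_len = 7L, max_len = 30L, z_threshold = 2,
                             gate_threshold = 0.3,
                             similarity_threshold = 0.70,
                             scale = hydrophobicity_scale(),
                             missing_profile = c("gate", "error")) {
  missing_profile <- match.arg(missing_profile)
  empty <- data.frame(parent_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      sequence = character(), score_type = character(),
                      raw = numeric(), split_k = integer(),
                      avg_structure_prob = numeric(), gated = logical(),
                      z = numeric(), best_type = character(),
                      cluster = integer(), representative = logical(),
                      mw = numeric(), pI = numeric(), net_charge = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L) return(empty)
  cand <- enumerate_peptides(proteins, min_len, max_len)
  if (nrow(cand) == 0L) return(empty)
  scored <- score_candidates(cand, scale)
  scored$z <- z_normalize(scored$raw, scored$score_type, scored$length,
                          background)
  # average structure probability for helical/strand rows
  scored$avg_structure_prob <- NA_real_
  ab <- scored$score_type %in% c("alpha", "beta")
  if (any(ab)) {
    have_profile <- if (is.null(profiles)) character(0) else unique(profiles$id)
    missing <- setdiff(unique(scored$parent_id[ab]), have_profile)
    if (length(missing) > 0L) {
      if (missing_profile == "error") {
        validation_error("no structure profile for: ",
                         paste(missing, collapse = ", "))
      }
      warning("no structure profile for ", length(missing),
              " protein(s); their helical/strand scores are gated to 0")
    }
    ix <- which(ab & scored$parent_id %in% have_profile)
    if (length(ix) > 0L) {
      # cumulative sums per protein/state make span means O(1)
      for (pid in unique(scored$parent_id[ix])) {
        sub <- profiles[profiles$id == pid, , drop = FALSE]
        sub <- sub[order(sub$position), , drop = FALSE]
        csh <- cumsum(sub$p_helix); css <- cumsum(sub$p_strand)
        for (st in c("alpha", "beta")) {
          jx <- which(scored$parent_id == pid & scored$score_type == st)
          if (length(jx) == 0L) next
          cs <- c(0, if (st == "alpha") csh else css)
          s <- scored$start[jx]; e <- scored$end[jx]
          if (any(e + 1L > length(cs))) {
            validation_error("profile of '", pid, "' shorter than its sequence")
          }
          tot <- cs[e + 1L] - cs[s]
          scored$avg_structure_prob[jx] <- tot / (e - s + 1L)
        }
      }
    }
  }
  scored$gated <- scored$score_type %in% c("alpha", "beta") &
    (is.na(scored$avg_structure_prob) |
       scored$avg_structure_prob < gate_threshold)
  scored$z <- gate(scored$z, scored$score_type, scored$avg_structure_prob,
                   gate_threshold)
  hits <- scored[scored$z > z_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  # best type per unique peptide occurrence
  occ <- paste(hits$parent_id, hits$start, hits$end)
  hits$best_type <- vapply(occ, function(k) {
    sub <- hits[occ == k, ]
    sub$score_type[which.max(sub$z)]
  }, character(1))
  hits <- cluster_peptides(hits, similarity_threshold)
  hits <- annotate_properties(hits)
  hits <- hits[order(-hits$z, hits$parent_id, hits$start, hits$score_type), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
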