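# Pipeline orchestration and a small subcommand-style CLI.

#' Default run configuration
#'
#' Defaults reproduce the published analysis parameters: candidate lengths
#' 7-30, z threshold 2, structure gate 0.3, clustering similarity 0.70,
#' homolog identity 0.90, background n = 40000 from Swiss-Prot composition,
#' iBAQ theoretical-peptide window 6-30.
#'
#' @param ... overrides for any field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(min_len = 7L, max_len = 30L, z_threshold = 2,
              gate_threshold = 0.3, similarity_threshold = 0.70,
              homolog_threshold = 0.90, background_n = 40000L, seed = 1L,
              scale = "kyte_doolittle", composition = "swissprot",
              ibaq_min_len = 6L, ibaq_max_len = 30L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    abort("unknown config key(s): ", paste(unknown, collapse = ", "),
          class = "amphipept_config_error")
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

provenance_lines <- function(cfg) {
  c(sprintf("# amphipept %s", as.character(utils::packageVersion("amphipept"))),
    sprintf("# config: %s", paste(sprintf("%s=%s", names(cfg),
                                          vapply(cfg, function(x)
                                            paste(format(x), collapse = ","),
                                            character(1))), collapse = " ")))
}

write_report <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Maturation, enumeration, scoring, background normalization, structure
#' gating, thresholding, clustering and annotation; release feasibility for
#' every hit; riBAQ abundance mapping when an intensity table is supplied.
#'
#' @param proteins protein data.frame (see [read_fasta()]); signal peptides
#'   are stripped if `signal_end` annotations are present.
#' @param profiles optional structure-probability table.
#' @param intensities optional intensity table (`protein_id`,
#'   `intensity` or `ribaq`).
#' @param background optional prebuilt background (built from `config`
#'   when NULL).
#' @param config a [run_config()].
#' @param outdir optional directory for tab-delimited reports.
#' @return list: `predictions`, `release`, `abundance` (NULL if no
#'   intensities), `background`, `config`.
#' @export
run_pipeline <- function(proteins, profiles = NULL, intensities = NULL,
                         background = NULL, config = run_config(),
                         outdir = NULL) {
  cfg <- config
  proteins <- mature_sequence(proteins)
  scale <- hydrophobicity_scale(cfg$scale)
  comp <- aa_composition(cfg$composition)
  if (is.null(background)) {
    background <- build_background(cfg$min_len:cfg$max_len,
                                   n = cfg$background_n, composition = comp,
                                   seed = cfg$seed,
                                   composition_name = cfg$composition)
  }
  predictions <- predict_peptides(proteins, background, profiles,
                                  min_len = cfg$min_len,
                                  max_len = cfg$max_len,
                                  z_threshold = cfg$z_threshold,
                                  gate_threshold = cfg$gate_threshold,
                                  similarity_threshold = cfg$similarity_threshold,
                                  scale = scale)
  release <- NULL
  if (nrow(predictions) > 0L) {
    rel <- lapply(seq_len(nrow(predictions)), function(i) {
      p <- predictions[i, ]
      parent <- proteins$sequence[proteins$id == p$parent_id]
      r <- release_feasibility(p$start, p$end, parent,
                               target_sequence = p$sequence)
      s <- r$slow_skipping_digest
      data.frame(parent_id = p$parent_id, start = p$start, end = p$end,
                 sequence = p$sequence, score_type = p$score_type,
                 internal_fast_sites = r$internal_fast_sites,
                 fragment_start = s$fragment$start,
                 fragment_end = s$fragment$end,
                 n_term_truncation = s$n_term_truncation,
                 c_term_truncation = s$c_term_truncation,
                 n_term_elongation = s$n_term_elongation,
                 c_term_elongation = s$c_term_elongation,
                 coverage = s$coverage, verdict = r$verdict,
                 stringsAsFactors = FALSE)
    })
    release <- do.call(rbind, rel)
  }
  abundance <- NULL
  if (!is.null(intensities)) {
    seqs <- stats::setNames(proteins$sequence, proteins$id)
    ribaq <- compute_ribaq(intensities, seqs,
                           min_len = cfg$ibaq_min_len,
                           max_len = cfg$ibaq_max_len)
    if (nrow(predictions) > 0L) {
      uniq <- unique(predictions$sequence)
      ab <- lapply(uniq, function(p) {
        pa <- peptide_abundance(p, proteins, ribaq,
                                homolog_threshold = cfg$homolog_threshold)
        data.frame(peptide = p, exact_match_ribaq = pa$exact_match_ribaq,
                   homolog_ribaq = pa$homolog_ribaq,
                   stringsAsFactors = FALSE)
      })
      abundance <- list(ribaq = ribaq, peptides = do.call(rbind, ab))
    } else {
      abundance <- list(ribaq = ribaq, peptides = NULL)
    }
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_report(predictions, file.path(outdir, "predictions.tsv"), cfg)
    if (!is.null(release)) {
      write_report(release, file.path(outdir, "release.tsv"), cfg)
    }
    if (!is.null(abundance)) {
      write_report(abundance$ribaq, file.path(outdir, "ribaq.tsv"), cfg)
      if (!is.null(abundance$peptides)) {
        write_report(abundance$peptides,
                     file.path(outdir, "peptide_abundance.tsv"), cfg)
      }
    }
    write_background(background, file.path(outdir, "background.tsv"))
  }
  list(predictions = predictions, release = release, abundance = abundance,
       background = background, config = cfg)
}

#' Command-line entry point
#'
#' Subcommands: `fixtures` (write a synthetic fixture directory),
#' `background` (build and save background models), `predict` (run the
#' pipeline on FASTA + optional profiles/intensities). Exit codes: 0
#' success, 1 validation error, 2 I/O error.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
amphipept_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: amphipept <subcommand> [options]",
    "  fixtures   --out DIR [--seed N] [--n-proteins N] [--mode permissive|realistic|absent]",
    "  background --out FILE [--seed N] [--n N] [--min-len N] [--max-len N]",
    "  predict    --fasta FILE --out DIR [--profiles FILE] [--intensities FILE]",
    "             [--background FILE] [--seed N] [--z-threshold X] [--signal FILE]",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    args[i[1] + 1L]
  }
  status <- tryCatch({
    if (length(args) == 0L) { message(usage); return(invisible(1L)) }
    sub <- args[1]
    if (sub == "fixtures") {
      out <- opt("--out"); if (is.null(out)) io_error("--out required")
      spec <- fixture_spec(seed = as.integer(opt("--seed", "1")),
                           n_proteins = as.integer(opt("--n-proteins", "3")),
                           profile_mode = opt("--mode", "permissive"))
      write_fixture(spec, out)
      message("fixture written to ", out)
    } else if (sub == "background") {
      out <- opt("--out"); if (is.null(out)) io_error("--out required")
      bg <- build_background(as.integer(opt("--min-len", "7")):
                               as.integer(opt("--max-len", "30")),
                             n = as.integer(opt("--n", "40000")),
                             seed = as.integer(opt("--seed", "1")))
      write_background(bg, out)
      message("background models written to ", out)
    } else if (sub == "predict") {
      fa <- opt("--fasta"); out <- opt("--out")
      if (is.null(fa) || is.null(out)) io_error("--fasta and --out required")
      proteins <- read_fasta(fa)
      sig <- opt("--signal")
      if (!is.null(sig)) proteins <- read_signal_annotations(proteins, sig)
      profiles <- if (!is.null(opt("--profiles"))) {
        load_ss_profiles(opt("--profiles"))
      }
      intensities <- if (!is.null(opt("--intensities"))) {
        utils::read.delim(opt("--intensities"), comment.char = "#",
                          stringsAsFactors = FALSE)
      }
      background <- if (!is.null(opt("--background"))) {
        read_background(opt("--background"))
      }
      cfg <- run_config(seed = as.integer(opt("--seed", "1")),
                        z_threshold = as.numeric(opt("--z-threshold", "2")))
      res <- run_pipeline(proteins, profiles, intensities, background,
                          cfg, outdir = out)
      message(nrow(res$predictions), " predictions written to ", out)
    } else {
      message(usage)
      return(invisible(1L))
    }
    0L
  },
  amphipept_io_error = function(e) { message("I/O error: ", conditionMessage(e)); 2L },
  amphipept_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 1L },
  amphipept_config_error = function(e) { message("config error: ", conditionMessage(e)); 1L })
  invisible(status)
}
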