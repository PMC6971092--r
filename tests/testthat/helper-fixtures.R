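# shared helpers: published peptide table, tiny FASTA writer, cached
# background models (built once per test run)

published_table <- function() {
  path <- system.file("extdata", "published_predictions.tsv",
                      package = "amphipept")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

tmp_fasta <- function(ids, seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

protein_df <- function(ids, seqs, signal_end = NA_integer_) {
  data.frame(id = ids, description = "", sequence = seqs,
             signal_end = signal_end, stringsAsFactors = FALSE)
}

# one full-scale background per test run (1-2 s to build)
.bg_cache <- new.env(parent = emptyenv())
cached_background <- function() {
  if (is.null(.bg_cache$bg)) {
    .bg_cache$bg <- build_background(7:30, n = 40000L, seed = 20260909L)
  }
  .bg_cache$bg
}

# independent scalar oracles used by the score tests
oracle_alpha <- function(sequence, scale = hydrophobicity_scale()) {
  v <- scale[strsplit(sequence, "")[[1]]]
  x <- 0; y <- 0
  for (n in seq_along(v)) {
    x <- x + v[[n]] * cos(n * 5 * pi / 9)
    y <- y + v[[n]] * sin(n * 5 * pi / 9)
  }
  sqrt(x^2 + y^2)
}

oracle_gamma <- function(sequence, scale = hydrophobicity_scale()) {
  v <- unname(scale[strsplit(sequence, "")[[1]]])
  w <- length(v)
  best_r <- -Inf; best <- -Inf; bestk <- NA_integer_
  for (k in 1:(w - 1)) {
    # same 1e-6 tie convention as the implementation: mathematically tied
    # splits break to the smallest k independent of summation order
    d <- abs(sum(v[1:k]) - sum(v[(k + 1):w]))
    dr <- round(d, 6)
    if (dr > best_r) { best_r <- dr; best <- d; bestk <- k }
  }
  list(value = best, split_k = bestk)
}
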