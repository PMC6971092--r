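test_that("read_fasta parses headers, normalizes case, rejects duplicates", {
  path <- tmp_fasta(c("p1 patatin-like", "p2"),
                    c("MKKLLAGIKG", "gikgiipaiilefleqqlqe"))
  recs <- read_fasta(path)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$description[1], "patatin-like")
  expect_equal(nchar(recs$sequence), c(10L, 20L))
  expect_equal(recs$sequence[2], "GIKGIIPAIILEFLEQQLQE")

  dup <- tmp_fasta(c("p1", "p1"), c("AAAAAAA", "CCCCCCC"))
  expect_error(read_fasta(dup), "duplicate", class = "amphipept_validation_error")
  expect_error(read_fasta("no/such/file.fa"), class = "amphipept_io_error")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_warning(recs <- read_fasta(empty), "no sequences")
  expect_equal(nrow(recs), 0L)
})

test_that("mature_sequence strips annotated signal peptides", {
  rec <- protein_df("p", "MKKLLAGIKGII", signal_end = 4L)
  out <- mature_sequence(rec)
  expect_equal(out$sequence, "LAGIKGII")
  expect_true(is.na(out$signal_end))

  unannotated <- protein_df("p", "MKKLLAGIKGII")
  expect_identical(mature_sequence(unannotated), unannotated)

  whole <- protein_df("p", "MKKLLAGIKGII", signal_end = 12L)
  expect_error(mature_sequence(whole), "mature",
               class = "amphipept_validation_error")
})

test_that("enumeration matches the closed form and is duplicate-free", {
  expect_equal(nrow(enumerate_peptides(protein_df("p", strrep("A", 6)))), 0L)
  one <- enumerate_peptides(protein_df("p", strrep("A", 7)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$sequence, strrep("A", 7))
  expect_equal(nrow(enumerate_peptides(protein_df("p", strrep("A", 30)))), 300L)

  set.seed(11)
  for (L in c(1:10, sample(11:100, 12))) {
    s <- paste(sample(c("A", "G", "K", "V"), L, TRUE), collapse = "")
    cand <- enumerate_peptides(protein_df("p", s))
    lens <- seq.int(7, min(30, L))
    closed <- if (L < 7) 0L else sum(L - lens + 1L)
    expect_equal(nrow(cand), closed, info = paste("L =", L))
    expect_false(any(duplicated(cand[, c("parent_id", "start", "end")])))
    if (nrow(cand) > 0L) {
      expect_equal(cand$sequence, substring(s, cand$start, cand$end))
      expect_equal(cand$length, cand$end - cand$start + 1L)
    }
  }
})

test_that("candidates overlapping non-canonical residues are skipped", {
  rec <- protein_df("p", paste0(strrep("A", 10), "X", strrep("G", 10)))
  expect_warning(cand <- enumerate_peptides(rec), "non-canonical")
  expect_false(any(grepl("X", cand$sequence)))
  expect_true(nrow(cand) > 0L)
})

test_that("peptide similarity handles embedding and disjoint sequences", {
  expect_equal(peptide_similarity("AAAAAAA", "AAAAAAA"), 1)
  expect_equal(peptide_similarity("AAAAAAA", "RRRRRRR"), 0)
  # embedded peptide scores 1 regardless of argument order
  expect_equal(peptide_similarity("DSPETYEEALKRFAKLLSD",
                                  "KKPVSKDSPETYEEALKRFAKLLSDRKKL"), 1)
})

test_that("clustering is single-linkage, order-invariant, with deterministic representatives", {
  peps <- data.frame(
    sequence = c("DSPETYEEALKRFAKLLSD",             # embedded in the next
                 "KKPVSKDSPETYEEALKRFAKLLSDRKKL",
                 "AAAAAAA", "RRRRRRR"),
    z = c(3.0, 2.2, 2.1, 2.5), stringsAsFactors = FALSE)
  out <- cluster_peptides(peps)
  expect_equal(out$cluster[1], out$cluster[2])
  expect_equal(length(unique(out$cluster)), 3L)
  # representative of the embedded pair: higher z wins
  rep1 <- out$sequence[out$representative & out$cluster == out$cluster[1]]
  expect_equal(rep1, "DSPETYEEALKRFAKLLSD")

  set.seed(4)
  for (i in 1:5) {
    perm <- sample(nrow(peps))
    out2 <- cluster_peptides(peps[perm, , drop = FALSE])
    part1 <- split(out$sequence, out$cluster)
    part2 <- split(out2$sequence, out2$cluster)
    norm <- function(p) unname(lapply(p, sort)[order(vapply(lapply(p, sort), `[`, "", 1))])
    expect_equal(norm(part1), norm(part2))
  }

  ident <- cluster_peptides(data.frame(sequence = c("LNIQFNI", "LNIQFNI"),
                                       stringsAsFactors = FALSE))
  expect_equal(length(unique(ident$cluster)), 1L)
})

test_that("FASTA round-trip preserves candidate export", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c("p|1-7", "p|2-8"), c("GIKGIIP", "IKGIIPA"), path)
  back <- read_fasta(path)
  expect_equal(back$id, c("p|1-7", "p|2-8"))
  expect_equal(back$sequence, c("GIKGIIP", "IKGIIPA"))
})
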