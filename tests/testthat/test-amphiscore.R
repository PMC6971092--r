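test_that("single-residue scores equal the absolute hydropathy", {
  expect_equal(alpha_raw("I")$value, 4.5)
  expect_equal(beta_raw("L")$value, 3.8)
})

test_that("helical score matches the geometric closed form and the summation oracle", {
  # homopolymer: norm = |K| * |sin(w*theta/2) / sin(theta/2)|
  theta <- 100 * pi / 180
  closed <- 0.4 * abs(sin(7 * theta / 2) / sin(theta / 2))
  expect_equal(alpha_raw("GGGGGGG")$value, closed, tolerance = 1e-9)
  expect_equal(alpha_raw("EALKRFAKLLSD")$value,
               oracle_alpha("EALKRFAKLLSD"), tolerance = 1e-9)
  expect_error(alpha_raw("AXA"), class = "amphipept_validation_error")
})

test_that("strand score equals the alternating sum", {
  expect_equal(beta_raw("VVVVVVVV")$value, 0, tolerance = 1e-9)
  expect_equal(beta_raw("VNVNVNVN")$value, 30.8, tolerance = 1e-9)
  # reversal symmetry for even length
  expect_equal(beta_raw("NVNVNVNV")$value, beta_raw("VNVNVNVN")$value,
               tolerance = 1e-9)
})

test_that("axial score handles homopolymers and published examples", {
  hom <- gamma_raw("LLLLLLL")
  expect_equal(hom$value, 19.0, tolerance = 1e-9)
  expect_equal(hom$split_k, 1L)   # tie with k = 6 broken to the smallest k

  g39 <- gamma_raw("HQNGKRRLALV")
  expect_equal(g39$split_k, 7L)
  expect_equal(g39$value, 37.1, tolerance = 1e-9)

  g1 <- gamma_raw("GIKGIIPAIILEFLEGQLQEVDNNKDAR")
  expect_equal(g1$split_k, 14L)
  expect_equal(g1$value, 51.9, tolerance = 1e-9)

  expect_equal(gamma_raw("FDVIGGTSTGGLLTAMITTPNENNRP")$split_k, 17L)
  expect_error(gamma_raw("A"), class = "amphipept_validation_error")
})

test_that("published divide positions reproduce for all 17 axial peptides", {
  tab <- published_table()
  gam <- tab[tab$score_type == "gamma", ]
  ks <- vapply(gam$sequence, function(s) gamma_raw(s)$split_k, integer(1))
  expect_equal(unname(ks), gam$separation)
  # and the independent brute-force oracle agrees
  oks <- vapply(gam$sequence, function(s) oracle_gamma(s)$split_k, integer(1))
  expect_equal(unname(oks), gam$separation)
})

test_that("axial score equals brute force on random peptides", {
  set.seed(31)
  aas <- names(hydrophobicity_scale())
  for (i in 1:300) {
    s <- paste(sample(aas, sample(7:30, 1), TRUE), collapse = "")
    got <- gamma_raw(s)
    want <- oracle_gamma(s)
    expect_identical(got$split_k, want$split_k)
    expect_equal(got$value, want$value, tolerance = 1e-12)
  }
})

test_that("scores are norms: scaling the hydropathy scale scales scores", {
  set.seed(32)
  aas <- names(hydrophobicity_scale())
  for (cfac in c(2, -1.5, 0.3)) {
    scaled <- hydrophobicity_scale() * cfac
    for (i in 1:10) {
      s <- paste(sample(aas, 12, TRUE), collapse = "")
      expect_equal(alpha_raw(s, scaled)$value,
                   abs(cfac) * alpha_raw(s)$value, tolerance = 1e-9)
      expect_equal(beta_raw(s, scaled)$value,
                   abs(cfac) * beta_raw(s)$value, tolerance = 1e-9)
      expect_equal(gamma_raw(s, scaled)$value,
                   abs(cfac) * gamma_raw(s)$value, tolerance = 1e-9)
    }
  }
})

test_that("index origin is pinned at 1", {
  # with origin 1 the first residue of a helical peptide sits at 100 degrees,
  # so a single-residue score contributes at angle theta, not 0: the two-residue
  # peptide "IG" must differ from "GI" (origin-sensitive phase)
  v <- hydrophobicity_scale()
  th <- 5 * pi / 9
  expect_equal(alpha_raw("IG")$value,
               sqrt((v[["I"]] * cos(th) + v[["G"]] * cos(2 * th))^2 +
                    (v[["I"]] * sin(th) + v[["G"]] * sin(2 * th))^2),
               tolerance = 1e-12)
  # beta with origin 1: odd positions carry negative sign
  expect_equal(beta_raw("IG")$value, abs(-v[["I"]] + v[["G"]]), tolerance = 1e-12)
})

test_that("batch scoring agrees with per-peptide scoring", {
  set.seed(33)
  aas <- names(hydrophobicity_scale())
  seqs <- vapply(1:40, function(i)
    paste(sample(aas, sample(7:30, 1), TRUE), collapse = ""), character(1))
  cand <- data.frame(parent_id = "p", start = 1L, end = nchar(seqs),
                     length = nchar(seqs), sequence = seqs,
                     stringsAsFactors = FALSE)
  long <- score_candidates(cand)
  expect_equal(nrow(long), 3L * nrow(cand))
  for (i in sample(nrow(long), 30)) {
    row <- long[i, ]
    ref <- score_all(row$sequence)[[row$score_type]]
    expect_equal(row$raw, ref$value, tolerance = 1e-12)
    if (row$score_type == "gamma") expect_identical(row$split_k, ref$split_k)
  }
  expect_true(all(long$raw >= 0))
})
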