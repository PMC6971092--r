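write_profile <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("profile loading validates range and contiguity", {
  ok <- data.frame(id = "p", position = 1:10, p_helix = 0.5,
                   p_strand = 0.2, p_coil = 0.3)
  prof <- load_ss_profiles(write_profile(ok))
  expect_equal(nrow(prof), 10L)

  bad <- ok; bad$p_helix[3] <- 1.2
  expect_error(load_ss_profiles(write_profile(bad)), "line",
               class = "amphipept_validation_error")

  gap <- ok[-5, ]
  expect_error(load_ss_profiles(write_profile(gap)), "contiguous",
               class = "amphipept_validation_error")

  # comma-delimited dialect accepted
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(ok, path, sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(load_ss_profiles(path)), 10L)
})

test_that("average probability is the arithmetic mean over the span", {
  prof <- data.frame(id = "p", position = 1:10,
                     p_helix = c(0.2, 0.4, rep(0.5, 8)),
                     p_strand = 0.1, p_coil = 0.4)
  expect_equal(avg_probability(prof, "p", 1, 2, "helix"), 0.3)
  expect_equal(avg_probability(prof, "p", 1, 10, "helix"),
               mean(prof$p_helix))
  expect_equal(avg_probability(prof, "p", 3, 10, "strand"), 0.1)
  expect_error(avg_probability(prof, "p", 5, 11, "helix"),
               class = "amphipept_validation_error")
  expect_error(avg_probability(prof, "q", 1, 2, "helix"),
               class = "amphipept_validation_error")
})

test_that("gate semantics: strictly below fails, boundary passes, axial exempt", {
  expect_equal(gate(3.1, "alpha", 0.29), 0)
  expect_equal(gate(3.1, "alpha", 0.30), 3.1)
  expect_equal(gate(3.1, "gamma", 0.0), 3.1)
  expect_equal(gate(3.1, "beta", NA), 0)
  # idempotence
  expect_equal(gate(gate(3.1, "alpha", 0.29), "alpha", 0.29), 0)
  expect_equal(gate(gate(3.1, "beta", 0.9), "beta", 0.9), 3.1)
})

test_that("prediction recovers a planted alternating segment as top strand hit", {
  spec <- fixture_spec(seed = 42, n_proteins = 3, profile_mode = "permissive")
  fx <- make_proteins(spec)
  aux <- make_profiles_and_abundances(spec, fx)
  bg <- cached_background()
  pred <- predict_peptides(fx$proteins, bg, aux$profiles)
  expect_true(nrow(pred) > 0L)
  beta_truth <- fx$truth[fx$truth$type == "beta", ]
  top_beta <- pred[pred$score_type == "beta", ][1, ]
  expect_equal(top_beta$parent_id, beta_truth$protein_id)
  expect_true(top_beta$start <= beta_truth$end &&
              top_beta$end >= beta_truth$start)
  # ranked by z descending, all above threshold, annotated
  expect_true(all(diff(pred$z) <= 1e-12))
  expect_true(all(pred$z > 2))
  expect_true(all(c("mw", "pI", "net_charge", "cluster") %in% names(pred)))
})

test_that("permissive profiles equal ungated predictions; missing profiles gate to 0", {
  spec <- fixture_spec(seed = 8, n_proteins = 3, profile_mode = "permissive")
  fx <- make_proteins(spec)
  aux <- make_profiles_and_abundances(spec, fx)
  bg <- cached_background()
  gated <- predict_peptides(fx$proteins, bg, aux$profiles)
  ungated <- predict_peptides(fx$proteins, bg, aux$profiles, gate_threshold = 0)
  expect_equal(gated$z, ungated$z)
  expect_equal(gated$sequence, ungated$sequence)

  expect_warning(noprof <- predict_peptides(fx$proteins, bg, profiles = NULL),
                 "gated")
  expect_true(all(noprof$score_type == "gamma"))
  expect_error(predict_peptides(fx$proteins, bg, profiles = NULL,
                                missing_profile = "error"),
               class = "amphipept_validation_error")
})

test_that("raising the z threshold never adds hits", {
  spec <- fixture_spec(seed = 13, profile_mode = "permissive")
  fx <- make_proteins(spec)
  aux <- make_profiles_and_abundances(spec, fx)
  bg <- cached_background()
  lo <- predict_peptides(fx$proteins, bg, aux$profiles, z_threshold = 2)
  hi <- predict_peptides(fx$proteins, bg, aux$profiles, z_threshold = 4)
  expect_true(nrow(hi) <= nrow(lo))
  key <- function(d) paste(d$parent_id, d$start, d$end, d$score_type)
  expect_true(all(key(hi) %in% key(lo)))
  inf <- predict_peptides(fx$proteins, bg, aux$profiles, z_threshold = Inf)
  expect_equal(nrow(inf), 0L)
  empty <- predict_peptides(fx$proteins[0, ], bg)
  expect_equal(nrow(empty), 0L)
})

test_that("realistic profiles gate off-motif helical hits but keep the planted one", {
  spec <- fixture_spec(seed = 77, n_proteins = 3, profile_mode = "realistic")
  fx <- make_proteins(spec)
  aux <- make_profiles_and_abundances(spec, fx)
  bg <- cached_background()
  pred <- predict_peptides(fx$proteins, bg, aux$profiles)
  alpha_truth <- fx$truth[fx$truth$type == "alpha", ]
  ah <- pred[pred$score_type == "alpha", ]
  expect_true(nrow(ah) > 0L)
  # every surviving helical hit overlaps the high-probability planted span
  expect_true(all(ah$parent_id == alpha_truth$protein_id &
                  ah$start <= alpha_truth$end & ah$end >= alpha_truth$start))
})
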