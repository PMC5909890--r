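test_that("expected m/z follows the single-protonation adduct rule", {
  expect_equal(expected_mz(272.235, "NEG"), 271.227724, tolerance = 1e-6)
  expect_equal(expected_mz(543.3325, "POS"), 544.339776, tolerance = 1e-6)
  expect_equal(expected_mz(1.007276, "NEG"), 0)
  expect_error(expected_mz(300, "NEUTRAL"), "unknown ESI mode")
  expect_error(expected_mz(0.5, "NEG"), "proton")
  # vector masses with a scalar mode recycle correctly
  expect_equal(expected_mz(c(272.235, 284.272), "NEG"),
               c(272.235, 284.272) - 1.007276)
})

test_that("all six published (m/z, mode) pairs annotate at 0.01 Da", {
  lib <- builtin_panel_library()
  printed <- data.frame(
    feature_id = lib$records$name,
    mz = c(271.2266, 283.2629, 498.2936, 722.513, 762.5081, 544.3411),
    esi_mode = lib$records$expected_mode,
    stringsAsFactors = FALSE
  )
  res <- match_features(printed, lib, threshold = 0.01)
  expect_equal(res$n_annotated, 6)
  expect_equal(nrow(res$flagged), 0)
  expect_identical(res$primary$compound_name[
    match(printed$feature_id, res$primary$feature_id)], printed$feature_id)
  expect_true(all(abs(res$primary$mass_error) <= 0.0041))
  expect_true(all(grepl("_(N|P)$", res$primary$label)))
})

test_that("out-of-threshold features are dropped, near-duplicates flagged", {
  lib <- builtin_panel_library()
  far <- data.frame(feature_id = "f", mz = 271.25, esi_mode = "NEG")
  expect_equal(match_features(far, lib, 0.01)$n_annotated, 0)

  two <- data.frame(feature_id = c("f1", "f2"),
                    mz = c(271.2277, 271.2330), esi_mode = "NEG")
  res <- match_features(two, lib, 0.01)
  expect_equal(res$primary$feature_id, "f1")
  expect_equal(res$primary$mass_error, 0, tolerance = 1e-4)
  expect_equal(res$flagged$feature_id, "f2")
  expect_equal(res$flagged$rank, "secondary")

  expect_error(match_features(two, lib, -0.01), "positive")
  empty_lib <- compound_library(data.frame(name = "x",
                                           monoisotopic_mass = 100,
                                           is_drug_or_nonhuman = TRUE))
  expect_error(match_features(two, empty_lib, 0.01), "empty")
})

test_that("greedy matching equals the sequential minimum-error oracle", {
  lib <- default_library()
  for (seed in 1:8) {
    set.seed(seed)
    rec <- lib$records[sample(which(!lib$records$is_drug_or_nonhuman), 20), ]
    sub <- compound_library(rec)
    # features scattered near (and sometimes between) expected masses
    base <- expected_mz(rec$monoisotopic_mass[sample(20, 15, replace = TRUE)],
                        "NEG")
    feats <- data.frame(
      feature_id = sprintf("f%02d", 1:15),
      mz = pmin(pmax(base + rnorm(15, 0, 0.012), 50), 1200),
      esi_mode = "NEG", stringsAsFactors = FALSE
    )
    got <- match_features(feats, sub, threshold = 0.02)$primary
    want <- bf_match(feats, sub, threshold = 0.02)
    expect_equal(got$feature_id, want$feature_id)
    expect_equal(got$compound_name, want$compound_name)
    expect_equal(got$mass_error, want$mass_error, tolerance = 1e-12)
  }
})

test_that("matches respect the threshold, exclusivity and monotonicity", {
  lib <- default_library()
  set.seed(99)
  feats <- data.frame(
    feature_id = sprintf("f%03d", 1:300),
    mz = runif(300, 50, 1200),
    esi_mode = sample(c("NEG", "POS"), 300, replace = TRUE),
    stringsAsFactors = FALSE
  )
  for (thr in c(0.005, 0.02, 0.05)) {
    res <- match_features(feats, lib, thr)
    all_matches <- rbind(res$primary, res$flagged)
    expect_true(all(abs(all_matches$mass_error) <= thr))
    expect_false(any(duplicated(res$primary$feature_id)))
    expect_false(any(duplicated(paste(res$primary$compound_name,
                                      res$primary$esi_mode))))
    expect_lte(res$n_annotated, res$n_input_features)
  }
  # candidate sets grow with the threshold
  small <- match_features(feats, lib, 0.01)
  large <- match_features(feats, lib, 0.05)
  key <- function(r) paste(rbind(r$primary, r$flagged)$feature_id,
                           rbind(r$primary, r$flagged)$compound_name)
  expect_true(all(key(small) %in% key(large)))
})

test_that("annotate_table reduces to primary features and is idempotent", {
  lib <- builtin_panel_library()
  set.seed(5)
  n_noise <- 90
  lib_mz <- expected_mz(lib$records$monoisotopic_mass,
                        lib$records$expected_mode)
  noise_mz <- numeric(0)
  while (length(noise_mz) < n_noise) {
    cand <- runif(n_noise, 50, 1200)
    ok <- vapply(cand, function(m) all(abs(m - c(lib_mz,
      expected_mz(lib$records$monoisotopic_mass, "POS"),
      expected_mz(lib$records$monoisotopic_mass, "NEG"))) >= 0.05),
      logical(1))
    noise_mz <- c(noise_mz, cand[ok])
  }
  noise_mz <- noise_mz[seq_len(n_noise)]
  feats <- data.frame(
    feature_id = sprintf("f%03d", seq_len(6 + n_noise)),
    mz = c(lib_mz, noise_mz),
    esi_mode = c(lib$records$expected_mode,
                 rep(c("NEG", "POS"), length.out = n_noise)),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = c("a", "b", "c", "d"),
                        group = c("case", "case", "control", "control"))
  tab <- feature_table(samples, feats,
                       matrix(rexp(4 * nrow(feats)), 4))
  ann <- annotate_table(tab, lib, 0.01)
  expect_equal(ncol(ann$abundances), 6)
  expect_setequal(ann$features$feature_id, marker_labels)
  expect_identical(ann$features$annotation,
                   sub("_(N|P)$", "", ann$features$feature_id))

  # idempotence: an annotated table re-annotates to itself
  again <- annotate_table(ann, lib, 0.01)
  expect_identical(again$features$feature_id, ann$features$feature_id)
  expect_equal(again$abundances, ann$abundances)

  # nothing in threshold -> empty table and a warning
  off <- tab
  off$features$mz <- off$features$mz + 0.5
  expect_warning(none <- annotate_table(off, lib, 0.001), "no features")
  expect_equal(ncol(none$abundances), 0)
})

test_that("intersect_common keeps order, handles identity and disjoint sets", {
  other <- tiny_table(4, 6)
  other$features$feature_id <- c("A_N", "B_P", "C_N", "D_N", "E_P", "F_N")
  colnames(other$abundances) <- other$features$feature_id
  panel <- panel_definition(c("X_P", "C_N", "A_N", "Y_N", "E_P", "Z_P",
                              "B_P", "W_N", "D_N", "F_N"), method = "test")
  expect_message(common <- intersect_common(panel, other), "dropping 4")
  expect_equal(common$labels, c("C_N", "A_N", "E_P", "B_P", "D_N", "F_N"))

  same <- panel_definition(other$features$feature_id)
  expect_equal(intersect_common(same, other)$labels, same$labels)

  disjoint <- panel_definition(c("nope_N", "nada_P"))
  expect_warning(expect_message(empty <- intersect_common(disjoint, other)),
                 "no panel labels")
  expect_length(empty$labels, 0)
})
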