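test_that("blank-ratio rule removes background and keeps blank-absent features", {
  samples <- make_samples(n_per_group = 1L, n_blank = 1L)
  # rows: ratio 9 (removed), blank-absent (kept), ratio 10 (kept, not <10)
  areas <- rbind(c(9e5, 9e5, 1e5),
                 c(5e5, 5e5, 0),
                 c(1e6, 1e6, 1e5))
  feats <- make_features(c(300, 400, 500), c(5, 6, 7), areas, samples)
  res <- blank_ratio_filter(feats, samples, threshold = 10)
  expect_equal(res$removed, "F001")
  expect_equal(res$kept$feature_id, c("F002", "F003"))
  no_blank <- make_samples(n_per_group = 1L, n_blank = 0L)
  expect_error(
    blank_ratio_filter(make_features(300, 5, matrix(1, 1, nrow(no_blank)),
                                     no_blank), no_blank),
    "no blank samples")
})

test_that("intensity cutoff is strictly greater-than", {
  samples <- make_samples(n_per_group = 1L, n_blank = 1L)
  areas <- rbind(c(1000001, 1, 0), c(1000000, 1, 0), c(1, 1000001, 0))
  feats <- make_features(c(300, 400, 500), c(5, 6, 7), areas, samples)
  res <- intensity_filter(feats, samples, min_area = 1e6)
  expect_equal(res$kept$feature_id, c("F001", "F003"))
  expect_equal(res$removed, "F002")
  # every curated compound's maximum area clears the cutoff
  expect_true(all(load_table1()$max_area > 1e6))
})

test_that("Kendrick window is inclusive and suspect hits can rescue", {
  samples <- make_samples(n_per_group = 1L, n_blank = 1L)
  mz_at_kmd <- function(kmd, nominal = 400) (nominal + kmd) * CF2_EXACT / 50
  mz <- c(498.9321,                 # PFOS-like, kmd ~ -0.036
          mz_at_kmd(-0.25),         # exactly on the lower bound
          mz_at_kmd(0.30))          # hydrogen-rich decoy
  feats <- make_features(mz, c(18, 5, 6), matrix(1, 3, nrow(samples)), samples)
  hard <- kmd_filter(feats, mode = "hard")
  expect_equal(hard$kept$feature_id, c("F001", "F002"))
  expect_equal(hard$removed, "F003")
  rescued <- kmd_filter(feats, mode = "or_with_suspect",
                        suspect_hits = "F003")
  expect_equal(nrow(rescued$kept), 3L)
})

test_that("exclusion lists merge within tolerance and match features", {
  # two blank injections observe the same contaminant 5 ppm / 0.05 min apart
  bl <- data.frame(mz = c(400.0000, 400.0016, 600.0), rt = c(5.0, 5.05, 8))
  ex <- build_exclusion_list(bl, mz_tol_ppm = 5, rt_tol_min = 0.2)
  expect_equal(nrow(ex), 2L)
  expect_equal(ex$n_merged, c(2L, 1L))
  expect_equal(ex$mz[1], 400.0008)
  # disjoint features stay separate
  far <- data.frame(mz = c(400.000, 400.008), rt = c(5, 5))
  expect_equal(nrow(build_exclusion_list(far, mz_tol_ppm = 5)), 2L)
  expect_warning(empty <- build_exclusion_list(data.frame(mz = numeric(0),
                                                          rt = numeric(0))),
                 "empty")
  expect_equal(nrow(empty), 0L)

  samples <- make_samples(n_per_group = 1L, n_blank = 1L)
  feats <- make_features(c(400.0010, 500), c(5.02, 9),
                         matrix(1, 2, nrow(samples)), samples)
  res <- exclusion_filter(feats, ex)
  expect_equal(res$removed, "F001")
})

test_that("the funnel telescopes and partitions the input", {
  set.seed(101)
  samples <- make_samples(n_per_group = 3L, n_injections = 2L, n_blank = 2L)
  feats <- random_instance(120L, samples)
  res <- run_cascade(feats, samples, filter_config())
  f <- res$funnel
  expect_equal(f$n_in, f$n_out + f$n_removed)
  expect_equal(f$n_out[-nrow(f)], f$n_in[-1])
  all_removed <- unlist(res$removed, use.names = FALSE)
  expect_false(any(duplicated(all_removed)))
  expect_setequal(c(all_removed, res$candidates$feature_id),
                  feats$feature_id)
  # provenance records every stage passed
  if (nrow(res$candidates))
    expect_true(all(grepl("blank_ratio;intensity;kmd_window",
                          res$candidates$provenance)))
  # empty input gives an all-zero funnel
  empty <- run_cascade(feats[0, ], samples, filter_config())
  expect_equal(nrow(empty$candidates), 0L)
  expect_true(all(empty$funnel$n_in == 0L))
})

test_that("cascade equals brute-force rule reapplication on random instances", {
  set.seed(202)
  samples <- make_samples(n_per_group = 3L, n_injections = 2L,
                          n_blank = 2L, n_qc = 1L)
  sus <- table1_suspects()[1:10, ]
  for (rep in 1:25) {
    feats <- random_instance(sample(20:200, 1), samples)
    cfg <- filter_config(
      min_area = sample(c(1e5, 1e6), 1),
      kmd_mode = sample(c("hard", "or_with_suspect"), 1))
    res <- run_cascade(feats, samples, cfg, suspects = sus)
    oracle <- brute_force_cascade(feats, samples, cfg, suspects = sus)
    expect_setequal(res$candidates$feature_id, oracle$kept)
  }
})

test_that("relaxing any threshold never removes a previously kept feature", {
  set.seed(303)
  samples <- make_samples(n_per_group = 3L, n_injections = 2L, n_blank = 2L)
  feats <- random_instance(150L, samples)
  base_cfg <- filter_config()
  base <- run_cascade(feats, samples, base_cfg)$candidates$feature_id
  relaxed <- list(
    filter_config(min_area = 1e5),
    filter_config(kmd_window = c(-0.4, 0.3)),
    filter_config(blank_ratio_threshold = 5),
    filter_config(require_ms2 = FALSE))
  for (cfg in relaxed) {
    kept <- run_cascade(feats, samples, cfg)$candidates$feature_id
    expect_true(all(base %in% kept))
  }
})

test_that("replicate collapse averages injections per biological sample", {
  samples <- make_samples(n_per_group = 2L, n_injections = 2L, n_blank = 1L)
  areas <- matrix(seq_len(9), nrow = 1)
  feats <- make_features(300, 5, areas, samples)
  coll <- collapse_replicates(feats, samples)
  expect_equal(nrow(coll$samples), 5L)  # 4 biological units + blank
  expect_equal(coll$features[["liver_A01"]], mean(c(1, 2)))
  cmax <- collapse_replicates(feats, samples, collapse = "max")
  expect_equal(cmax$features[["liver_A01"]], 2)
})

test_that("filter configuration reads from YAML and rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("blank_ratio_threshold: 8", "min_area: 2000000",
               "kmd_window: [-0.3, 0.2]", "kmd_mode: hard"), f)
  cfg <- read_filter_config(f)
  expect_equal(cfg$blank_ratio_threshold, 8)
  expect_equal(cfg$min_area, 2e6)
  expect_equal(cfg$kmd_window, c(-0.3, 0.2))
  expect_equal(cfg$kmd_mode, "hard")
  writeLines("not_a_threshold: 1", f)
  expect_error(read_filter_config(f), "unknown filter config key")
})
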