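spec <- function(mz, int, id = "q") {
  pk <- cbind(mz = mz, intensity = int)
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  list(ms2_id = id, precursor_mz = max(mz) + 50, collision_energy = "10,70",
       peaks = pk)
}

test_that("suspect matching ranks by ppm distance within tolerance", {
  sus <- table1_suspects()
  hits <- match_suspects(498.9321, sus, tol_ppm = 5)
  # the two same-formula sulfonate isomers tie on ppm and lead the ranking,
  # ordered lexicographically
  expect_true("Perfluoro-n-octanesulfonate" %in% hits$name[1:2])
  expect_equal(hits$name[1], "Perfluoro-6-methylheptanesulfonate")
  expect_equal(round(hits$delta_ppm[1], 2), 3.77)
  exact <- match_suspects(formula_mz("C7HF13O2"), sus, tol_ppm = 5)
  expect_equal(exact$delta_ppm[1], 0)
  off <- match_suspects(formula_mz("C7HF13O2") * (1 + 10e-6), sus, tol_ppm = 5)
  expect_equal(nrow(off), 0L)
  expect_warning(none <- match_suspects(500, sus[0, ]), "empty suspect")
  expect_equal(nrow(none), 0L)
})

test_that("CF2 chains are detected with the RT gate", {
  mz <- vapply(c("C5HF9O2", "C6HF11O2", "C7HF13O2"), formula_mz, 0)
  f <- data.frame(feature_id = c("a", "b", "c"), mz = mz, rt = c(9, 13, 15))
  s <- detect_series(f)
  expect_equal(unique(s$series_id), "S001")
  expect_equal(s$feature_id, c("a", "b", "c"))
  expect_equal(diff(s$mz), rep(CF2_EXACT, 2), tolerance = 1e-9)
  # shuffled RTs break the chain when monotonicity is required
  f2 <- f; f2$rt <- c(15, 9, 13)
  expect_equal(nrow(detect_series(f2)), 0L)
  expect_equal(nrow(detect_series(f2, require_rt_increase = FALSE)), 3L)
  # gaps of 2 and 3 units still chain
  mzg <- formula_mz("C5HF9O2") + c(0, 2, 5) * CF2_EXACT
  fg <- data.frame(feature_id = c("x", "y", "z"), mz = mzg, rt = c(1, 2, 3))
  expect_equal(nrow(detect_series(fg)), 3L)
})

test_that("non-homologous m/z sets yield no series (brute-force check)", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    mz <- stats::runif(n, 150, 900)
    f <- data.frame(feature_id = sprintf("f%02d", 1:n), mz = mz,
                    rt = stats::runif(n, 1, 14))
    # brute force: any pair with a gap within 5 ppm of 1..3 CF2 units?
    gaps <- abs(outer(mz, mz, `-`))
    linked <- FALSE
    for (k in 1:3)
      linked <- linked || any(abs(gaps - k * CF2_EXACT) <=
                                5e-6 * max(mz) & gaps > 0)
    if (!linked)
      expect_equal(nrow(detect_series(f, require_rt_increase = FALSE)), 0L)
  }
})

test_that("series detection agrees with exhaustive chain construction", {
  # arithmetic CF2 chains of any length >= 3 come back as one series
  set.seed(9)
  for (k in 3:7) {
    start <- stats::runif(1, 200, 400)
    f <- data.frame(feature_id = sprintf("m%d", 1:k),
                    mz = start + (0:(k - 1)) * CF2_EXACT,
                    rt = sort(stats::runif(k, 1, 14)))
    s <- detect_series(f)
    expect_equal(nrow(s), k)
    expect_equal(length(unique(s$series_id)), 1L)
  }
})

test_that("spectral cosine matches a hand-evaluated oracle", {
  a <- spec(c(100, 200, 300), c(10, 20, 30))
  expect_equal(spectral_similarity(a, a), 100)
  b <- spec(c(150, 250), c(5, 5))
  expect_equal(spectral_similarity(a, b), 0)
  # one of three peaks intensity-perturbed x2: cosine of (10,20,30) vs
  # (10,20,60) = (100+400+1800)/(sqrt(1400)*sqrt(4100))
  pert <- spec(c(100, 200, 300), c(10, 20, 60))
  hand <- 100 * (10 * 10 + 20 * 20 + 30 * 60) /
    (sqrt(10^2 + 20^2 + 30^2) * sqrt(10^2 + 20^2 + 60^2))
  expect_equal(spectral_similarity(a, pert), hand, tolerance = 1e-9)
  expect_equal(spectral_similarity(pert, a), hand, tolerance = 1e-9)
  expect_error(spectral_similarity(a, list(peaks = NULL)), "empty")
})

test_that("diagnostic-fragment scoring counts each ion once", {
  ms2 <- spec(c(118.232, 168.145, 500.1), c(50, 40, 10))
  cs <- class_fragment_score(ms2, c(118.232, 168.145, 218.784))
  expect_equal(cs$fraction, 2 / 3)
  expect_equal(cs$n_matched, 2L)
  expect_equal(class_fragment_score(ms2, c(700, 800))$fraction, 0)
  expect_equal(class_fragment_score(ms2, c(118.232))$fraction, 1)
  expect_error(class_fragment_score(ms2, numeric(0)), "non-empty")
})

test_that("branched isomers are flagged by earlier elution than the standard", {
  # two same-formula sulfonate features; the standard elutes at 18.26
  f <- data.frame(feature_id = c("f49", "f51"), rt = c(17.91, 18.26))
  tags <- flag_branched_isomer(f, standard_rt = 18.26)
  expect_equal(tags$isomer_tag, c("branched-candidate", "linear/confirmed"))
  # single feature: nothing to contrast
  expect_true(all(is.na(flag_branched_isomer(f[1, ], 18.26)$isomer_tag)))
  f3 <- data.frame(feature_id = c("a", "b", "c"), rt = c(16.5, 17.2, 18.26))
  tags3 <- flag_branched_isomer(f3, standard_rt = 18.26)
  expect_equal(tags3$isomer_tag,
               c("branched-candidate", "branched-candidate",
                 "linear/confirmed"))
})

test_that("confidence decision list follows the evidence hierarchy", {
  expect_equal(assign_confidence(standard_match = TRUE,
                                 n_diagnostic_matched = 2L,
                                 masslist_hit = TRUE,
                                 has_ms2 = TRUE)$confidence_level, 1L)
  expect_equal(assign_confidence(spectral_score = 85, has_ms2 = TRUE,
                                 masslist_hit = TRUE)$confidence_level, 2L)
  # "higher than 60%" is strict: 60.0 fails the spectral gate
  at60 <- assign_confidence(spectral_score = 60, has_ms2 = TRUE,
                            masslist_hit = TRUE, n_diagnostic_matched = 1L)
  expect_equal(at60$confidence_level, 3L)
  just_above <- assign_confidence(spectral_score = 60.01, has_ms2 = TRUE)
  expect_equal(just_above$confidence_level, 2L)
  at60_nolist <- assign_confidence(spectral_score = 60, has_ms2 = TRUE,
                                   formula_unambiguous = TRUE)
  expect_equal(at60_nolist$confidence_level, 4L)
  expect_equal(assign_confidence(masslist_hit = TRUE,
                                 series_member = TRUE)$confidence_level, 3L)
  expect_equal(assign_confidence(formula_unambiguous = TRUE)$confidence_level,
               4L)
  expect_equal(assign_confidence()$confidence_level, 5L)
  expect_error(assign_confidence(spectral_score = 70, has_ms2 = FALSE),
               "inconsistent")
})

test_that("adding evidence never worsens the confidence level", {
  set.seed(13)
  for (i in 1:200) {
    ev <- list(standard_match = sample(c(TRUE, FALSE), 1),
               spectral_score = sample(c(NA, stats::runif(1, 0, 100)), 1),
               masslist_hit = sample(c(TRUE, FALSE), 1),
               n_diagnostic_matched = sample(0:3, 1),
               series_member = sample(c(TRUE, FALSE), 1),
               formula_unambiguous = sample(c(TRUE, FALSE), 1))
    ev$has_ms2 <- !is.na(ev$spectral_score) || sample(c(TRUE, FALSE), 1)
    base <- do.call(assign_confidence, ev)$confidence_level
    up <- ev
    up$standard_match <- TRUE
    up$n_diagnostic_matched <- max(1L, ev$n_diagnostic_matched)
    expect_lte(do.call(assign_confidence, up)$confidence_level, base)
    up2 <- ev
    up2$spectral_score <- 99
    up2$has_ms2 <- TRUE
    expect_lte(do.call(assign_confidence, up2)$confidence_level, base)
  }
})

test_that("evidence reconstructed from the curated table reproduces its levels", {
  tb <- load_table1()
  # minimal evidence consistent with each printed level: standards for the
  # seven level-1 rows; library spectral matches for level 2; mass-list +
  # diagnostic ions for level 3
  got <- vapply(seq_len(nrow(tb)), function(i) {
    cl <- tb$confidence_level[i]
    ev <- switch(as.character(cl),
      "1" = list(standard_match = TRUE, n_diagnostic_matched = 2L,
                 masslist_hit = TRUE, has_ms2 = TRUE),
      "2" = list(spectral_score = 75, masslist_hit = TRUE, has_ms2 = TRUE,
                 n_diagnostic_matched = 1L),
      "3" = list(masslist_hit = TRUE, n_diagnostic_matched = 1L,
                 has_ms2 = TRUE))
    do.call(assign_confidence, ev)$confidence_level
  }, 0L)
  expect_equal(got, tb$confidence_level)
  expect_equal(sum(got == 1L), 7L)
})
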