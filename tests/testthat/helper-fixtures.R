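# Shared builders for small in-memory designs and an independent brute-force
# re-implementation of the prioritization rules (the oracle the cascade is
# checked against).

make_samples <- function(n_per_group = 3L, n_injections = 1L,
                         n_blank = 1L, n_qc = 0L) {
  rows <- list()
  for (g in c("liver", "muscle"))
    for (a in seq_len(n_per_group))
      for (j in seq_len(n_injections))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_A%02d_%d", g, a, j), group = g,
          animal_id = sprintf("A%02d", a), injection_replicate = j)
  for (b in seq_len(n_blank))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("blank_B%d_1", b), group = "blank",
      animal_id = NA_character_, injection_replicate = 1L)
  for (q in seq_len(n_qc))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("qc_Q%d_1", q), group = "qc",
      animal_id = NA_character_, injection_replicate = 1L)
  do.call(rbind, rows)
}

# features with explicit per-sample areas; `areas` is a matrix with one row
# per feature, columns matching samples$sample_id
make_features <- function(mz, rt, areas, samples, ms2_id = NA_character_) {
  df <- data.frame(feature_id = sprintf("F%03d", seq_along(mz)),
                   mz = mz, rt = rt,
                   ms2_id = rep_len(ms2_id, length(mz)))
  areas <- matrix(areas, nrow = length(mz))
  colnames(areas) <- samples$sample_id
  cbind(df, as.data.frame(areas, check.names = FALSE))
}

small_config <- function(seed) {
  scenario_config(n_per_group = 5L, n_true_pfas = 60L,
                  n_blank_contaminants = 10L, n_background_features = 150L,
                  seed = seed)
}

# ---- independent brute-force reapplication of the cascade rules ----------
# Deliberately written feature-by-feature from the rule definitions, with no
# code shared with run_cascade().
brute_force_cascade <- function(features, samples, config,
                                suspects = NULL, exclusion_list = NULL) {
  # collapse technical replicates per biological unit by mean
  unit <- ifelse(is.na(samples$animal_id), samples$group,
                 paste(samples$group, samples$animal_id, sep = "_"))
  units <- unique(unit)
  collapsed <- sapply(units, function(u) {
    cols <- samples$sample_id[unit == u]
    rowMeans(as.matrix(features[, cols, drop = FALSE]))
  })
  collapsed <- matrix(collapsed, nrow = nrow(features),
                      dimnames = list(features$feature_id, units))
  grp <- samples$group[!duplicated(unit)]
  kept <- character(0)
  removed_at <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    a <- collapsed[i, ]
    blank_max <- if (any(grp == "blank")) max(a[grp == "blank"]) else 0
    real_max <- max(a[grp != "blank"])
    excl_hit <- FALSE
    if (!is.null(exclusion_list) && nrow(exclusion_list) > 0L)
      excl_hit <- any(
        abs(f$mz - exclusion_list$mz) / exclusion_list$mz * 1e6 <=
          config$mz_tol_ppm &
        abs(f$rt - exclusion_list$rt) <= config$rt_tol_min)
    km <- f$mz * 50 / CF2_EXACT
    kmd <- km - round(km)
    suspect_hit <- !is.null(suspects) &&
      any(abs((f$mz - suspects$theoretical_mz) /
                suspects$theoretical_mz * 1e6) <= config$mz_tol_ppm)
    stage <- if (excl_hit) "exclusion_list"
      else if (blank_max > 0 &&
               real_max < config$blank_ratio_threshold * blank_max) "blank_ratio"
      else if (real_max <= config$min_area) "intensity"
      else if (!(kmd >= config$kmd_window[1] & kmd <= config$kmd_window[2]) &&
               !(config$kmd_mode == "or_with_suspect" && suspect_hit)) "kmd_window"
      else if (config$require_ms2 && is.na(f$ms2_id)) "ms2_available"
      else ""
    removed_at[i] <- stage
    if (stage == "") kept <- c(kept, f$feature_id)
  }
  list(kept = kept, removed_at = removed_at)
}

# random small instance for oracle-equivalence checks
random_instance <- function(n_features, samples) {
  n_s <- nrow(samples)
  mz <- stats::runif(n_features, 150, 900)
  # a third of the features get exact in-window Kendrick defects
  inwin <- seq_len(n_features) %% 3 == 0
  km <- sample(150:900, n_features, replace = TRUE) +
    stats::runif(n_features, -0.25, 0.15)
  mz[inwin] <- (km * CF2_EXACT / 50)[inwin]
  areas <- matrix(exp(stats::runif(n_features * n_s, log(1e4), log(1e7))),
                  nrow = n_features)
  # some features absent from blanks, some low, some without MS2
  blank_cols <- which(samples$group == "blank")
  areas[stats::runif(n_features) < 0.5, blank_cols] <- 0
  ms2 <- ifelse(stats::runif(n_features) < 0.6, "MS2_X", NA_character_)
  make_features(mz, stats::runif(n_features, 0.5, 14.5), areas, samples,
                ms2_id = ms2)
}
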