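#' Configuration of a synthetic LC-HRMS screening scenario
#'
#' Describes a synthetic study emulating a two-tissue wildlife biomonitoring
#' design: `n_per_group` animals sampled in liver and muscle, each extract
#' injected `n_injections` times, procedural blanks run twice, pooled QCs,
#' planted true PFAS features (at the theoretical [M-H]- m/z of the curated
#' compound formulas plus ppm-scale mass error), blank contaminants at
#' sample-to-blank ratios strictly below 10, hydrogen-rich background
#' features with positive Kendrick mass defects, and planted tissue effects
#' (fold changes and tissue-exclusive compounds).
#'
#' @param n_per_group Animals per tissue group (default 18).
#' @param n_injections Technical injections per sample (default 2).
#' @param n_true_pfas Number of curated compounds planted (default 60).
#' @param n_blank_contaminants Blank contaminant features (default 50).
#' @param n_background_features Background features (default 2000).
#' @param mass_error_sd Mass error sd in ppm (default 1.5).
#' @param rt_jitter_sd RT jitter sd in minutes (default 0.05).
#' @param area_cv Biological coefficient of variation of areas (default 0.30).
#' @param replicate_cv Technical-injection CV (default 0.10).
#' @param loading_sd Log-sd of per-sample loading factors (default 0.2).
#' @param n_up_liver,n_up_muscle Planted differential compounds (20 / 12).
#' @param fold_range Fold-change range for planted effects (default 2-8).
#' @param n_exclusive_liver,n_exclusive_muscle Tissue-exclusive compounds
#'   (3 / 4).
#' @param n_qc Pooled QC samples (default 2).
#' @param seed Mandatory RNG seed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_per_group = 18L, n_injections = 2L,
                            n_true_pfas = 60L, n_blank_contaminants = 50L,
                            n_background_features = 2000L,
                            mass_error_sd = 1.5, rt_jitter_sd = 0.05,
                            area_cv = 0.30, replicate_cv = 0.10,
                            loading_sd = 0.2,
                            n_up_liver = 20L, n_up_muscle = 12L,
                            fold_range = c(2, 8),
                            n_exclusive_liver = 3L, n_exclusive_muscle = 4L,
                            n_qc = 2L, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric seed is mandatory for reproducibility")
  if (n_up_liver + n_up_muscle + n_exclusive_liver + n_exclusive_muscle >
      n_true_pfas)
    stop("more differential/exclusive compounds than planted true PFAS")
  stopifnot(n_per_group >= 2L, n_injections >= 1L, n_true_pfas >= 1L,
            n_true_pfas <= 60L, all(fold_range > 1), mass_error_sd > 0)
  structure(as.list(environment()), class = "scenario_config")
}

rlnorm_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  # meanlog chosen so that the arithmetic mean equals `mean`
  mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic screening scenario
#'
#' Produces, deterministically for a given seed, all inputs of the pipeline
#' plus a ground-truth manifest: the sample design, a wide feature table
#' (per-injection areas, integer-rounded), MS2 spectra for every true PFAS
#' (containing the compound's curated diagnostic ions plus Poisson-count
#' noise peaks) and a minority of background features, the suspect list
#' derived from the curated table (authentic-standard RTs on the
#' confidence-level-1 compounds), and a clean spectral library per suspect.
#'
#' Planted homologous series in the manifest are the CF2 chains present
#' among the generated true-PFAS features (computed with the same chain rule
#' as [detect_series()], on true features only), so series recovery can be
#' scored against the whole feature set.
#'
#' @param config A [scenario_config()].
#' @return List with `samples`, `features`, `spectra`, `suspects`,
#'   `spectral_library`, `manifest`, `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  tb <- load_table1()[seq_len(config$n_true_pfas), ]

  ## ---- design -------------------------------------------------------
  animals <- sprintf("A%02d", seq_len(config$n_per_group))
  design <- expand.grid(injection = seq_len(config$n_injections),
                        animal = animals, group = c("liver", "muscle"),
                        stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_%d", design$group, design$animal,
                        design$injection),
    group = design$group, animal_id = design$animal,
    injection_replicate = design$injection, stringsAsFactors = FALSE)
  blanks <- data.frame(
    sample_id = sprintf("blank_B1_%d", seq_len(2L)),
    group = "blank", animal_id = NA_character_,
    injection_replicate = seq_len(2L), stringsAsFactors = FALSE)
  qcs <- do.call(rbind, lapply(seq_len(config$n_qc), function(q)
    data.frame(sample_id = sprintf("qc_Q%d_%d", q, seq_len(config$n_injections)),
               group = "qc", animal_id = NA_character_,
               injection_replicate = seq_len(config$n_injections),
               stringsAsFactors = FALSE)))
  samples <- validate_sample_table(rbind(samples, blanks, qcs))
  tissue <- samples[samples$group %in% c("liver", "muscle"), ]
  bio_units <- unique(paste(tissue$group, tissue$animal_id, sep = "_"))
  n_bio <- length(bio_units)
  bio_group <- sub("_.*", "", bio_units)
  loading <- stats::rlnorm(n_bio, 0, config$loading_sd)
  names(loading) <- bio_units

  ## ---- planted effect assignment ------------------------------------
  codes <- tb$code
  pool <- sample(codes)
  n_eff <- c(config$n_up_liver, config$n_up_muscle,
             config$n_exclusive_liver, config$n_exclusive_muscle)
  up_liver <- pool[seq_len(n_eff[1])]
  up_muscle <- pool[n_eff[1] + seq_len(n_eff[2])]
  excl_liver <- pool[n_eff[1] + n_eff[2] + seq_len(n_eff[3])]
  excl_muscle <- pool[sum(n_eff[1:3]) + seq_len(n_eff[4])]
  fold <- stats::setNames(rep(1, length(codes)), codes)
  fold[as.character(up_liver)] <-
    stats::runif(n_eff[1], config$fold_range[1], config$fold_range[2])
  fold[as.character(up_muscle)] <-
    stats::runif(n_eff[2], config$fold_range[1], config$fold_range[2])

  ## ---- true PFAS features -------------------------------------------
  theo <- suppressWarnings(vapply(tb$formula, formula_mz, 0))
  mz_true <- theo * (1 + stats::rnorm(length(theo), 0,
                                      config$mass_error_sd) * 1e-6)
  rt_true <- pmax(0.1, tb$rt + stats::rnorm(length(theo), 0,
                                            config$rt_jitter_sd))
  base_true <- exp(stats::runif(length(theo), log(3e6), log(1e8)))
  true_ids <- sprintf("TRUE%03d", tb$code)

  ## per-biological-sample expected level, then injection noise
  area_block <- function(base, effect_liver, effect_muscle, excl) {
    bio <- base * loading *
      ifelse(bio_group == "liver", effect_liver, effect_muscle) *
      rlnorm_cv(n_bio, 1, config$area_cv)
    if (!is.na(excl))
      bio[bio_group != excl] <- 0
    inj <- matrix(0, nrow = 1, ncol = nrow(tissue))
    unit <- paste(tissue$group, tissue$animal_id, sep = "_")
    inj[1, ] <- bio[unit] * rlnorm_cv(nrow(tissue), 1, config$replicate_cv)
    qc_val <- mean(bio)
    qn <- sum(samples$group == "qc")
    c(inj[1, ], rep(0, 2L),                      # blanks: absent
      qc_val * rlnorm_cv(qn, 1, config$replicate_cv))
  }
  col_order <- c(tissue$sample_id, blanks$sample_id,
                 samples$sample_id[samples$group == "qc"])
  true_areas <- t(vapply(seq_along(true_ids), function(i) {
    code <- tb$code[i]
    excl <- if (code %in% excl_liver) "liver"
      else if (code %in% excl_muscle) "muscle" else NA_character_
    f <- fold[as.character(code)]
    el <- if (code %in% up_liver) f else 1
    em <- if (code %in% up_muscle) f else 1
    # fold is applied to the affected tissue; the other stays at baseline
    area_block(base_true[i], el, em, excl)
  }, numeric(length(col_order))))

  ## ---- blank contaminants -------------------------------------------
  nc <- config$n_blank_contaminants
  cont_ids <- sprintf("CONT%03d", seq_len(nc))
  mz_cont <- stats::runif(nc, 200, 900)
  rt_cont <- stats::runif(nc, 0.5, 14.5)
  base_cont <- exp(stats::runif(nc, log(1e6), log(1e7)))
  cont_areas <- t(vapply(seq_len(nc), function(i) {
    # per-sample ratio to blank drawn strictly below 10; bounded injection
    # noise keeps max(sample)/max(blank) < 10 deterministically
    r <- stats::runif(n_bio, 0.5, 8)
    unit <- paste(tissue$group, tissue$animal_id, sep = "_")
    bio <- stats::setNames(base_cont[i] * r, bio_units)
    inj <- bio[unit] * stats::runif(nrow(tissue), 0.9, 1.1)
    blank_inj <- base_cont[i] * stats::runif(2L, 0.9, 1.1)
    qc_val <- mean(bio) * stats::runif(sum(samples$group == "qc"), 0.9, 1.1)
    c(inj, blank_inj, qc_val)
  }, numeric(length(col_order))))

  ## ---- hydrogen-rich background -------------------------------------
  nb <- config$n_background_features
  bg_ids <- sprintf("BG%04d", seq_len(nb))
  km_nominal <- sample(200:900, nb, replace = TRUE)
  kmd_bg <- stats::runif(nb, 0.16, 0.45)
  mz_bg <- (km_nominal + kmd_bg) * CF2_EXACT / 50
  rt_bg <- stats::runif(nb, 0.5, 14.5)
  base_bg <- exp(stats::runif(nb, log(1e4), log(2e6)))
  unit <- paste(tissue$group, tissue$animal_id, sep = "_")
  bg_areas <- t(vapply(seq_len(nb), function(i) {
    bio <- stats::setNames(
      base_bg[i] * loading * rlnorm_cv(n_bio, 1, config$area_cv), bio_units)
    inj <- bio[unit] * rlnorm_cv(nrow(tissue), 1, config$replicate_cv)
    qc_val <- mean(bio) * rlnorm_cv(sum(samples$group == "qc"), 1,
                                    config$replicate_cv)
    c(inj, rep(0, 2L), qc_val)
  }, numeric(length(col_order))))

  ## ---- MS2 spectra ---------------------------------------------------
  spectra <- list()
  canon_intensity <- vector("list", length(true_ids))
  ms2_true <- sprintf("MS2_%s", true_ids)
  for (i in seq_along(true_ids)) {
    frags <- parse_fragment_list(tb$diagnostic_ions[i])
    canon_intensity[[i]] <- stats::runif(length(frags), 30, 100)
    n_noise <- stats::rpois(1, 3)
    noise_mz <- stats::runif(n_noise, 50, max(mz_true[i] - 1, 60))
    pk <- rbind(cbind(frags, canon_intensity[[i]] *
                        stats::runif(length(frags), 0.8, 1.2)),
                cbind(noise_mz, stats::runif(n_noise, 1, 10)))
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    colnames(pk) <- c("mz", "intensity")
    spectra[[ms2_true[i]]] <- list(ms2_id = ms2_true[i],
                                   precursor_mz = mz_true[i],
                                   collision_energy = "10,70",
                                   peaks = pk)
  }
  # a minority of background features carry uninformative MS2
  bg_with_ms2 <- stats::runif(nb) < 0.10
  ms2_bg <- ifelse(bg_with_ms2, sprintf("MS2_%s", bg_ids), NA_character_)
  for (i in which(bg_with_ms2)) {
    npk <- 2L + stats::rpois(1, 3)
    pk <- cbind(sort(stats::runif(npk, 50, mz_bg[i] - 1)),
                stats::runif(npk, 1, 100))
    colnames(pk) <- c("mz", "intensity")
    spectra[[ms2_bg[i]]] <- list(ms2_id = ms2_bg[i], precursor_mz = mz_bg[i],
                                 collision_energy = "10,70", peaks = pk)
  }

  ## ---- suspect list and spectral library ----------------------------
  suspects <- table1_suspects(tb)
  spectral_library <- list()
  for (i in seq_along(true_ids)) {
    frags <- parse_fragment_list(tb$diagnostic_ions[i])
    pk <- cbind(frags, canon_intensity[[i]])[order(frags), , drop = FALSE]
    colnames(pk) <- c("mz", "intensity")
    # library spectra are keyed (TITLE) by suspect name so annotation and
    # the export/import round trip agree
    spectral_library[[tb$iupac_name[i]]] <-
      list(ms2_id = tb$iupac_name[i], precursor_mz = theo[i],
           collision_energy = "10,70", peaks = pk)
  }

  ## ---- assemble ------------------------------------------------------
  areas <- rbind(true_areas, cont_areas, bg_areas)
  areas <- round(areas)
  colnames(areas) <- col_order
  features <- data.frame(
    feature_id = c(true_ids, cont_ids, bg_ids),
    mz = round(c(mz_true, mz_cont, mz_bg), 6),
    rt = round(c(rt_true, rt_cont, rt_bg), 3),
    ms2_id = c(ms2_true, rep(NA_character_, nc), ms2_bg),
    stringsAsFactors = FALSE)
  features <- cbind(features, as.data.frame(areas, check.names = FALSE))
  features <- validate_feature_table(features, samples)

  ## planted series among the generated true features
  true_feats <- features[seq_along(true_ids), c("feature_id", "mz", "rt")]
  planted <- detect_series(true_feats)
  series_of <- stats::setNames(planted$series_id, planted$feature_id)

  tissue_effect <- rep("none", length(codes))
  tissue_effect[codes %in% up_liver] <- "up_liver"
  tissue_effect[codes %in% up_muscle] <- "up_muscle"
  exclusive_to <- rep(NA_character_, length(codes))
  exclusive_to[codes %in% excl_liver] <- "liver"
  exclusive_to[codes %in% excl_muscle] <- "muscle"
  manifest <- data.frame(
    feature_id = features$feature_id,
    origin = c(rep("true_pfas", length(true_ids)),
               rep("blank_contaminant", nc), rep("background", nb)),
    code = c(tb$code, rep(NA_integer_, nc + nb)),
    formula = c(tb$formula, rep(NA_character_, nc + nb)),
    series_id = c(unname(series_of[true_ids]), rep(NA_character_, nc + nb)),
    tissue_effect = c(tissue_effect, rep("none", nc + nb)),
    fold = c(unname(fold[as.character(codes)]), rep(NA_real_, nc + nb)),
    exclusive_to = c(exclusive_to, rep(NA_character_, nc + nb)),
    standard_evidence = c(tb$confidence_level == 1L, rep(FALSE, nc + nb)),
    stringsAsFactors = FALSE)

  list(samples = samples, features = features, spectra = spectra,
       suspects = suspects, spectral_library = spectral_library,
       manifest = manifest, config = config)
}

#' Export a generated scenario to disk
#'
#' Writes the sample table, feature table, MS2 spectra (MGF), suspect list,
#' spectral library (MGF) and ground-truth manifest in the package's
#' plain-text formats; [import_scenario()] reads them back.
#'
#' @param scenario As returned by [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the six file paths.
#' @export
export_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, "samples.tsv"),
    features = file.path(dir, "features.tsv"),
    spectra = file.path(dir, "spectra.mgf"),
    suspects = file.path(dir, "suspects.tsv"),
    spectral_library = file.path(dir, "spectral_library.mgf"),
    manifest = file.path(dir, "manifest.tsv"))
  write_sample_table(scenario$samples, paths["samples"])
  write_feature_table(scenario$features, paths["features"])
  write_mgf(scenario$spectra, paths["spectra"])
  write_suspect_list(scenario$suspects, paths["suspects"])
  write_mgf(scenario$spectral_library, paths["spectral_library"])
  write_tsv(scenario$manifest, paths["manifest"])
  paths
}

#' @rdname export_scenario
#' @param dir Directory written by [export_scenario()].
#' @export
import_scenario <- function(dir) {
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  list(samples = samples,
       features = read_feature_table(file.path(dir, "features.tsv"), samples),
       spectra = read_mgf(file.path(dir, "spectra.mgf")),
       suspects = read_suspect_list(file.path(dir, "suspects.tsv")),
       spectral_library = read_mgf(file.path(dir, "spectral_library.mgf")),
       manifest = read_tsv(file.path(dir, "manifest.tsv")))
}
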