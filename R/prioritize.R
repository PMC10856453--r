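#' Filter configuration for the prioritization cascade
#'
#' Bundles the thresholds of the feature-reduction cascade. Defaults follow
#' the published workflow: features with a sample-to-blank maximum-area
#' ratio below 10 are treated as background; the minimum-intensity cutoff
#' is 1,000,000 arbitrary area units (strictly greater than); the CF2
#' Kendrick mass-defect window is [-0.25, +0.15] inclusive; and only
#' features with an MS2 spectrum proceed to identification.
#'
#' `kmd_mode = "or_with_suspect"` (default) retains out-of-window features
#' that carry a suspect-list hit -- several curated hydrogen-rich PFAS fall
#' outside the literal window -- while `"hard"` applies the window strictly.
#'
#' @param blank_ratio_threshold Sample/blank max-area ratio below which a
#'   feature is removed (dimensionless, > 0).
#' @param min_area Minimum maximum peak area across non-blank samples
#'   (arbitrary units; strict inequality).
#' @param kmd_window Numeric length-2, inclusive KMD bounds.
#' @param require_ms2 Drop features without an MS2 spectrum?
#' @param mz_tol_ppm,rt_tol_min Tolerances for exclusion-list matching.
#' @param kmd_mode `"hard"` or `"or_with_suspect"`.
#' @param replicate_collapse How technical injection replicates are combined
#'   per biological sample before filtering: `"mean"` (default) or `"max"`.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(blank_ratio_threshold = 10,
                          min_area = 1e6,
                          kmd_window = c(-0.25, 0.15),
                          require_ms2 = TRUE,
                          mz_tol_ppm = 5,
                          rt_tol_min = 0.2,
                          kmd_mode = c("or_with_suspect", "hard"),
                          replicate_collapse = c("mean", "max")) {
  kmd_mode <- match.arg(kmd_mode)
  replicate_collapse <- match.arg(replicate_collapse)
  stopifnot(blank_ratio_threshold > 0, min_area > 0,
            length(kmd_window) == 2L, kmd_window[1] < kmd_window[2],
            mz_tol_ppm > 0, rt_tol_min > 0)
  structure(list(blank_ratio_threshold = blank_ratio_threshold,
                 min_area = min_area, kmd_window = kmd_window,
                 require_ms2 = isTRUE(require_ms2),
                 mz_tol_ppm = mz_tol_ppm, rt_tol_min = rt_tol_min,
                 kmd_mode = kmd_mode,
                 replicate_collapse = replicate_collapse),
            class = "filter_config")
}

#' Read a filter configuration from a YAML file
#'
#' Keys are the [filter_config()] argument names; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return `filter_config` object.
#' @export
read_filter_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(filter_config)))
  if (length(unknown))
    stop("unknown filter config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("blank_ratio_threshold", "min_area", "kmd_window",
              "mz_tol_ppm", "rt_tol_min"))
    if (!is.null(vals[[k]])) vals[[k]] <- as.numeric(vals[[k]])
  do.call(filter_config, vals)
}

#' Average technical injection replicates
#'
#' Collapses the per-injection area columns of a feature table to one column
#' per biological unit (animal + tissue for real samples; the group label
#' for blanks and QCs), combining replicates by mean (default) or max.
#'
#' @param features Feature table (wide).
#' @param samples Sample table.
#' @param collapse `"mean"` or `"max"`.
#' @return List with collapsed `features` and `samples` tables; collapsed
#'   sample ids are the biological unit labels.
#' @export
collapse_replicates <- function(features, samples,
                                collapse = c("mean", "max")) {
  collapse <- match.arg(collapse)
  unit <- ifelse(is.na(samples$animal_id),
                 samples$group,
                 paste(samples$group, samples$animal_id, sep = "_"))
  fun <- if (collapse == "mean") rowMeans else
    function(m) apply(m, 1L, max)
  meta <- features[, c("feature_id", "mz", "rt", "ms2_id")]
  blocks <- lapply(unique(unit), function(u) {
    cols <- samples$sample_id[unit == u]
    fun(as.matrix(features[, cols, drop = FALSE]))
  })
  collapsed <- do.call(cbind, blocks)
  colnames(collapsed) <- unique(unit)
  new_samples <- data.frame(
    sample_id = unique(unit),
    group = samples$group[!duplicated(unit)],
    animal_id = samples$animal_id[!duplicated(unit)],
    injection_replicate = 1L,
    stringsAsFactors = FALSE
  )
  list(features = cbind(meta, as.data.frame(collapsed, check.names = FALSE)),
       samples = new_samples)
}

#' Build an exclusion list from procedural-blank features
#'
#' Merges the features observed across repeated procedural-blank injections
#' into a deduplicated list of (m/z, RT) entries: entries within both the
#' m/z tolerance (ppm) and the RT tolerance (minutes) of each other are
#' merged to their means. Sorted by m/z.
#'
#' @param blank_features Data frame with `mz` and `rt` columns (features
#'   observed in blank injections).
#' @param mz_tol_ppm,rt_tol_min Merge tolerances.
#' @return Data frame with columns `mz`, `rt`, `n_merged`.
#' @export
build_exclusion_list <- function(blank_features, mz_tol_ppm = 5,
                                 rt_tol_min = 0.2) {
  if (nrow(blank_features) == 0L) {
    warning("no blank features supplied; exclusion list is empty")
    return(data.frame(mz = numeric(0), rt = numeric(0), n_merged = integer(0)))
  }
  df <- blank_features[order(blank_features$mz), c("mz", "rt")]
  groups <- integer(nrow(df))
  g <- 0L
  for (i in seq_len(nrow(df))) {
    assigned <- FALSE
    if (i > 1L) {
      for (j in which(groups[seq_len(i - 1L)] > 0L)) {
        gj <- groups[j]
        ref_mz <- mean(df$mz[groups == gj])
        ref_rt <- mean(df$rt[groups == gj])
        if (abs(df$mz[i] - ref_mz) / ref_mz * 1e6 <= mz_tol_ppm &&
            abs(df$rt[i] - ref_rt) <= rt_tol_min) {
          groups[i] <- gj
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) {
      g <- g + 1L
      groups[i] <- g
    }
  }
  out <- do.call(rbind, lapply(seq_len(g), function(k) {
    data.frame(mz = mean(df$mz[groups == k]),
               rt = mean(df$rt[groups == k]),
               n_merged = sum(groups == k))
  }))
  out[order(out$mz), ]
}

#' Remove features matching an exclusion list
#'
#' @param features Feature table.
#' @param exclusion_list As from [build_exclusion_list()]; `NULL` keeps all.
#' @param mz_tol_ppm,rt_tol_min Match tolerances.
#' @return List with `kept` (feature table) and `removed` (feature ids).
#' @export
exclusion_filter <- function(features, exclusion_list,
                             mz_tol_ppm = 5, rt_tol_min = 0.2) {
  if (is.null(exclusion_list) || nrow(exclusion_list) == 0L)
    return(list(kept = features, removed = character(0)))
  hit <- vapply(seq_len(nrow(features)), function(i) {
    any(abs(features$mz[i] - exclusion_list$mz) /
          exclusion_list$mz * 1e6 <= mz_tol_ppm &
        abs(features$rt[i] - exclusion_list$rt) <= rt_tol_min)
  }, TRUE)
  list(kept = features[!hit, , drop = FALSE],
       removed = features$feature_id[hit])
}

#' Blank-ratio background filter
#'
#' A feature is removed when its maximum area over real (non-blank) samples
#' is less than `threshold` times its maximum area over the procedural
#' blanks; features entirely absent from the blanks (blank maximum 0) are
#' always kept.
#'
#' @param features Feature table.
#' @param samples Sample table (must contain blank samples).
#' @param threshold Ratio threshold (default 10).
#' @return List with `kept` and `removed`.
#' @export
blank_ratio_filter <- function(features, samples, threshold = 10) {
  if (!any(samples$group == "blank"))
    stop("no blank samples in the design; drop this stage explicitly ",
         "instead of running it without blanks")
  blank_max <- apply(area_matrix(features, samples, "blank"), 1L, max)
  real_max <- apply(area_matrix(features, samples,
                                setdiff(SAMPLE_GROUPS, "blank")), 1L, max)
  removed <- blank_max > 0 & real_max < threshold * blank_max
  list(kept = features[!removed, , drop = FALSE],
       removed = features$feature_id[removed])
}

#' Minimum-intensity filter
#'
#' Keeps features whose maximum area across non-blank samples is strictly
#' greater than `min_area`.
#'
#' @inheritParams blank_ratio_filter
#' @param min_area Cutoff in arbitrary area units (default 1e6).
#' @return List with `kept` and `removed`.
#' @export
intensity_filter <- function(features, samples, min_area = 1e6) {
  real_max <- apply(area_matrix(features, samples,
                                setdiff(SAMPLE_GROUPS, "blank")), 1L, max)
  keep <- real_max > min_area
  list(kept = features[keep, , drop = FALSE],
       removed = features$feature_id[!keep])
}

#' Kendrick mass-defect window filter
#'
#' Keeps features whose CF2 Kendrick mass defect lies inside the window
#' (inclusive bounds). In `"or_with_suspect"` mode, out-of-window features
#' whose ids appear in `suspect_hits` are retained as well.
#'
#' @inheritParams blank_ratio_filter
#' @param window Inclusive KMD bounds (default `c(-0.25, 0.15)`).
#' @param mode `"hard"` or `"or_with_suspect"`.
#' @param suspect_hits Character vector of feature ids with a suspect-list
#'   hit (used only in `"or_with_suspect"` mode).
#' @return List with `kept` and `removed`.
#' @export
kmd_filter <- function(features, window = c(-0.25, 0.15),
                       mode = c("hard", "or_with_suspect"),
                       suspect_hits = character(0)) {
  mode <- match.arg(mode)
  kmd <- kendrick(features$mz)$kmd
  inside <- kmd >= window[1] & kmd <= window[2]
  if (mode == "or_with_suspect")
    inside <- inside | features$feature_id %in% suspect_hits
  list(kept = features[inside, , drop = FALSE],
       removed = features$feature_id[!inside])
}

#' MS2 availability filter
#'
#' @inheritParams blank_ratio_filter
#' @return List with `kept` and `removed`.
#' @export
ms2_filter <- function(features) {
  keep <- !is.na(features$ms2_id)
  list(kept = features[keep, , drop = FALSE],
       removed = features$feature_id[!keep])
}

#' Run the full prioritization cascade
#'
#' Applies, in order: optional exclusion-list matching, blank-ratio
#' background removal, the minimum-intensity cutoff, the Kendrick
#' mass-defect window, and (optionally) the MS2-availability gate.
#' Technical injection replicates are collapsed per biological sample
#' first. Every stage's removals are recorded in a telescoping funnel
#' report, and surviving features carry the ordered list of stages they
#' passed in their `provenance` column.
#'
#' @param features Feature table (per-injection, wide).
#' @param samples Sample table.
#' @param config A [filter_config()].
#' @param suspects Optional suspect list; used to compute suspect hits for
#'   `kmd_mode = "or_with_suspect"`.
#' @param exclusion_list Optional exclusion list ([build_exclusion_list()]);
#'   `NULL` skips that stage.
#' @return List with `candidates` (feature table with `provenance`),
#'   `funnel` (data frame: stage, n_in, n_out, n_removed), `removed`
#'   (named list of removed feature ids per stage), and the collapsed
#'   `samples` table used downstream.
#' @export
run_cascade <- function(features, samples, config = filter_config(),
                        suspects = NULL, exclusion_list = NULL) {
  stopifnot(inherits(config, "filter_config"))
  coll <- collapse_replicates(features, samples, config$replicate_collapse)
  feats <- coll$features
  smp <- coll$samples

  suspect_hits <- character(0)
  if (!is.null(suspects) && nrow(feats) > 0L) {
    hit <- vapply(feats$mz, function(m)
      any(abs(ppm_error(m, suspects$theoretical_mz)) <= config$mz_tol_ppm),
      TRUE)
    suspect_hits <- feats$feature_id[hit]
  }

  stages <- list()
  stages[["exclusion_list"]] <- function(f)
    exclusion_filter(f, exclusion_list, config$mz_tol_ppm, config$rt_tol_min)
  stages[["blank_ratio"]] <- function(f)
    blank_ratio_filter(f, smp, config$blank_ratio_threshold)
  stages[["intensity"]] <- function(f)
    intensity_filter(f, smp, config$min_area)
  stages[["kmd_window"]] <- function(f)
    kmd_filter(f, config$kmd_window, config$kmd_mode, suspect_hits)
  if (config$require_ms2)
    stages[["ms2_available"]] <- function(f) ms2_filter(f)

  funnel <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), n_removed = integer(0))
  removed <- list()
  current <- feats
  current$provenance <- rep("", nrow(current))
  for (nm in names(stages)) {
    n_in <- nrow(current)
    res <- stages[[nm]](current)
    res$kept$provenance <- ifelse(
      nzchar(res$kept$provenance),
      paste(res$kept$provenance, nm, sep = ";"), nm)
    funnel <- rbind(funnel, data.frame(
      stage = nm, n_in = n_in, n_out = nrow(res$kept),
      n_removed = length(res$removed)))
    removed[[nm]] <- res$removed
    current <- res$kept
  }
  list(candidates = current, funnel = funnel, removed = removed,
       samples = smp)
}

#' Format a funnel report as log lines
#'
#' @param funnel Funnel data frame from [run_cascade()].
#' @return Character vector, one line per stage.
#' @export
format_funnel <- function(funnel) {
  sprintf("stage %-16s in=%6d  removed=%6d  out=%6d",
          funnel$stage, funnel$n_in, funnel$n_removed, funnel$n_out)
}
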