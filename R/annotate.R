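#' Match a feature m/z against a suspect library
#'
#' @param mz Observed [M-H]- m/z (single value).
#' @param suspects Suspect list (see [read_suspect_list()]).
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @return Data frame of matching suspects with a `delta_ppm` column, sorted
#'   by absolute delta (ties broken by name); zero rows when nothing matches.
#' @export
match_suspects <- function(mz, suspects, tol_ppm = 5) {
  if (is.null(suspects) || nrow(suspects) == 0L) {
    warning("empty suspect library")
    return(data.frame(name = character(0), formula = character(0),
                      delta_ppm = numeric(0)))
  }
  delta <- ppm_error(mz, suspects$theoretical_mz)
  hits <- suspects[abs(delta) <= tol_ppm, , drop = FALSE]
  hits$delta_ppm <- delta[abs(delta) <= tol_ppm]
  hits[order(abs(hits$delta_ppm), hits$name), , drop = FALSE]
}

#' Detect CF2 homologous series
#'
#' Finds chains of features whose consecutive m/z gaps equal an integer
#' number (1..`max_step`) of CF2 units within `tol_ppm`, optionally
#' requiring retention time to increase strictly with m/z (homologues elute
#' later with longer chains). Chains are grown greedily from the lowest
#' unassigned m/z, always extending to the smallest admissible next m/z, so
#' the result is deterministic; each feature belongs to at most one series.
#'
#' @param features Data frame with `feature_id`, `mz`, `rt`.
#' @param spacing Exact repeat-unit mass (default [CF2_EXACT]).
#' @param tol_ppm Gap tolerance, in ppm of the heavier member.
#' @param min_members Minimum chain length to report (default 3).
#' @param max_step Maximum number of repeat units per gap (default 3).
#' @param require_rt_increase Require strictly increasing RT along the chain?
#' @return Data frame with one row per series member: `series_id`,
#'   `feature_id`, `mz`, `rt`, `position`; zero rows if none found.
#' @export
detect_series <- function(features, spacing = CF2_EXACT, tol_ppm = 5,
                          min_members = 3L, max_step = 3L,
                          require_rt_increase = TRUE) {
  ord <- order(features$mz, features$feature_id)
  f <- features[ord, c("feature_id", "mz", "rt")]
  n <- nrow(f)
  assigned <- rep(FALSE, n)
  out <- list()
  sid <- 0L
  for (i in seq_len(n)) {
    if (assigned[i]) next
    chain <- i
    repeat {
      cur <- chain[length(chain)]
      nxt <- NA_integer_
      for (j in seq_len(n)) {
        if (assigned[j] || j %in% chain || f$mz[j] <= f$mz[cur]) next
        gap <- f$mz[j] - f$mz[cur]
        k <- round(gap / spacing)
        if (k < 1L || k > max_step) next
        if (abs(gap - k * spacing) > tol_ppm * 1e-6 * f$mz[j]) next
        if (require_rt_increase && f$rt[j] <= f$rt[cur]) next
        if (is.na(nxt) || f$mz[j] < f$mz[nxt]) nxt <- j
      }
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
    }
    if (length(chain) >= min_members) {
      sid <- sid + 1L
      assigned[chain] <- TRUE
      out[[sid]] <- data.frame(
        series_id = sprintf("S%03d", sid),
        feature_id = f$feature_id[chain],
        mz = f$mz[chain], rt = f$rt[chain],
        position = seq_along(chain))
    }
  }
  if (!length(out))
    return(data.frame(series_id = character(0), feature_id = character(0),
                      mz = numeric(0), rt = numeric(0), position = integer(0)))
  do.call(rbind, out)
}

match_tol <- function(tol_ppm, mz) pmax(tol_ppm * 1e-6 * mz, 0.01)

#' Spectral cosine similarity (0-100)
#'
#' Greedy best-match peak pairing within the fragment tolerance, then the
#' cosine of the intensity vectors over the union of matched and unmatched
#' peaks, scaled to 0-100. Symmetric; 100 for identical spectra, 0 for
#' disjoint fragment sets. A local stand-in for online spectral-library
#' match scores.
#'
#' @param query,library_spectrum Spectra as returned by [read_mgf()] (lists
#'   with a `peaks` matrix).
#' @param frag_tol_ppm Pairing tolerance; the effective tolerance is
#'   `max(frag_tol_ppm ppm, 0.01 Th)` to accommodate fragment m/z printed at
#'   2-3 decimals.
#' @return Score in [0, 100].
#' @export
spectral_similarity <- function(query, library_spectrum, frag_tol_ppm = 10) {
  qp <- query$peaks
  lp <- library_spectrum$peaks
  if (is.null(qp) || nrow(qp) == 0L || is.null(lp) || nrow(lp) == 0L)
    stop("cannot score an empty spectrum")
  # candidate pairs within tolerance, greedily matched by closeness in m/z
  cand <- which(outer(qp[, 1], lp[, 1], function(a, b)
    abs(a - b) <= match_tol(frag_tol_ppm, pmax(a, b))), arr.ind = TRUE)
  qi <- numeric(0); li <- numeric(0)
  used_q <- rep(FALSE, nrow(qp)); used_l <- rep(FALSE, nrow(lp))
  if (nrow(cand)) {
    d <- abs(qp[cand[, 1], 1] - lp[cand[, 2], 1])
    for (k in order(d)) {
      a <- cand[k, 1]; b <- cand[k, 2]
      if (used_q[a] || used_l[b]) next
      used_q[a] <- TRUE; used_l[b] <- TRUE
      qi <- c(qi, qp[a, 2]); li <- c(li, lp[b, 2])
    }
  }
  qv <- c(qi, qp[!used_q, 2], rep(0, sum(!used_l)))
  lv <- c(li, rep(0, sum(!used_q)), lp[!used_l, 2])
  denom <- sqrt(sum(qv^2)) * sqrt(sum(lv^2))
  if (denom == 0) return(0)
  100 * sum(qv * lv) / denom
}

#' Diagnostic-fragment (compound class) score
#'
#' Fraction of a compound-class diagnostic fragment list found in an MS2
#' spectrum; each diagnostic ion counts at most once.
#'
#' @param ms2 Spectrum (list with `peaks`).
#' @param class_fragments Numeric vector of diagnostic fragment m/z (Th).
#' @param frag_tol_ppm Match tolerance; effective tolerance
#'   `max(frag_tol_ppm ppm, 0.01 Th)`.
#' @return List with `fraction` (matched / listed) and `n_matched`.
#' @export
class_fragment_score <- function(ms2, class_fragments, frag_tol_ppm = 10) {
  if (!length(class_fragments)) stop("class_fragments must be non-empty")
  peaks <- ms2$peaks[, 1]
  matched <- vapply(class_fragments, function(fr)
    any(abs(peaks - fr) <= match_tol(frag_tol_ppm, fr)), TRUE)
  list(fraction = mean(matched), n_matched = sum(matched))
}

#' Flag branched-chain isomer candidates among same-formula features
#'
#' When several features match the same molecular formula, the one whose RT
#' matches an authentic standard (within `rt_tol_min`) is tagged as the
#' confirmed (typically linear) isomer; any same-formula feature eluting
#' earlier is tagged as a branched-chain candidate, reflecting the earlier
#' elution of branched perfluoroalkyl isomers.
#'
#' @param features Data frame with `feature_id`, `rt` (all sharing one
#'   formula).
#' @param standard_rt Authentic-standard RT (minutes) or NA.
#' @param rt_tol_min RT match tolerance (default 0.1 min).
#' @return Data frame `feature_id`, `isomer_tag` (`"linear/confirmed"`,
#'   `"branched-candidate"`, or NA); zero tags when only one feature.
#' @export
flag_branched_isomer <- function(features, standard_rt = NA_real_,
                                 rt_tol_min = 0.1) {
  tags <- rep(NA_character_, nrow(features))
  if (nrow(features) >= 2L && !is.na(standard_rt)) {
    is_std <- abs(features$rt - standard_rt) <= rt_tol_min
    tags[is_std] <- "linear/confirmed"
    tags[!is_std & features$rt < standard_rt] <- "branched-candidate"
  }
  data.frame(feature_id = features$feature_id, isomer_tag = tags)
}

#' Assign a Schymanski-style identification confidence level
#'
#' Ordered decision list over the per-feature evidence record:
#' \itemize{
#'   \item CL 1 -- authentic-standard RT match plus supporting fragment or
#'     spectral evidence (score > `spectral_threshold` or >= 1 diagnostic
#'     fragment matched).
#'   \item CL 2 -- library spectral match score strictly greater than
#'     `spectral_threshold` (the "higher than 60%" gate).
#'   \item CL 3 -- suspect mass-list hit together with at least one
#'     diagnostic fragment or homologous-series membership.
#'   \item CL 4 -- an unambiguous molecular formula only.
#'   \item CL 5 -- everything else.
#' }
#'
#' @param standard_match Logical: RT matches an authentic standard.
#' @param spectral_score Numeric 0-100 or NA (requires `has_ms2`).
#' @param masslist_hit Logical: feature matches a suspect mass list.
#' @param n_diagnostic_matched Integer count of matched diagnostic ions.
#' @param series_member Logical: member of a detected homologous series.
#' @param formula_unambiguous Logical: a single formula explains the ion.
#' @param has_ms2 Logical: an MS2 spectrum exists for the feature.
#' @param spectral_threshold Spectral-score gate (default 60, strict `>`).
#' @return List with `confidence_level` (integer 1-5) and `rationale`
#'   (character vector of fired clauses).
#' @export
assign_confidence <- function(standard_match = FALSE,
                              spectral_score = NA_real_,
                              masslist_hit = FALSE,
                              n_diagnostic_matched = 0L,
                              series_member = FALSE,
                              formula_unambiguous = FALSE,
                              has_ms2 = FALSE,
                              spectral_threshold = 60) {
  if (!is.na(spectral_score) && !has_ms2)
    stop("inconsistent evidence: spectral score without an MS2 spectrum")
  if (!is.na(spectral_score) && (spectral_score < 0 || spectral_score > 100))
    stop("spectral_score must be in [0, 100]")
  spec_ok <- !is.na(spectral_score) && spectral_score > spectral_threshold
  rationale <- character(0)
  if (standard_match && (spec_ok || n_diagnostic_matched >= 1L)) {
    level <- 1L
    rationale <- c("authentic standard RT match",
                   if (spec_ok) "spectral score above threshold",
                   if (n_diagnostic_matched >= 1L) "diagnostic fragment(s) matched")
  } else if (spec_ok) {
    level <- 2L
    rationale <- "spectral score above threshold"
  } else if (masslist_hit && (n_diagnostic_matched >= 1L || series_member)) {
    level <- 3L
    rationale <- c("suspect mass-list hit",
                   if (n_diagnostic_matched >= 1L) "diagnostic fragment(s) matched",
                   if (series_member) "homologous series member")
  } else if (formula_unambiguous) {
    level <- 4L
    rationale <- "unambiguous molecular formula"
  } else {
    level <- 5L
    rationale <- "exact mass only"
  }
  list(confidence_level = level, rationale = rationale)
}

#' Annotate prioritized candidates against a suspect library
#'
#' For each candidate feature: finds the best suspect match within
#' `tol_ppm`, scores its MS2 spectrum against the suspect's diagnostic
#' fragment list and (when available) a library spectrum, checks the RT
#' against the suspect's authentic-standard RT, joins homologous-series
#' membership from [detect_series()], and assigns a confidence level via
#' [assign_confidence()]. Features sharing the formula of a
#' standard-confirmed suspect get branched-isomer tags.
#'
#' @param candidates Feature table (prioritized candidates).
#' @param suspects Suspect list.
#' @param spectra Named list of MS2 spectra (names = `ms2_id`).
#' @param spectral_library Optional named list of library spectra, keyed by
#'   suspect name.
#' @param tol_ppm Precursor match tolerance (default 5 ppm).
#' @param frag_tol_ppm Fragment match tolerance (default 10 ppm, floored at
#'   0.01 Th).
#' @param rt_tol_min Standard RT tolerance (default 0.1 min).
#' @param spectral_threshold Confidence gate for spectral scores.
#' @return Data frame with one row per candidate: suspect name/formula/
#'   class/source, `delta_ppm`, `spectral_score`, `class_score`,
#'   `n_diagnostic_matched`, `series_id`, `standard_match`, `isomer_tag`,
#'   `confidence_level`, `rationale`.
#' @export
annotate_candidates <- function(candidates, suspects, spectra = list(),
                                spectral_library = list(), tol_ppm = 5,
                                frag_tol_ppm = 10, rt_tol_min = 0.1,
                                spectral_threshold = 60) {
  series <- detect_series(candidates)
  series_of <- stats::setNames(series$series_id, series$feature_id)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    fid <- candidates$feature_id[i]
    mz <- candidates$mz[i]
    rt <- candidates$rt[i]
    ms2 <- if (!is.na(candidates$ms2_id[i]))
      spectra[[candidates$ms2_id[i]]] else NULL
    hits <- suppressWarnings(match_suspects(mz, suspects, tol_ppm))
    # evaluate the evidence for every in-tolerance suspect and keep the
    # strongest candidate: precursor mass alone cannot separate isomers,
    # but standard RT, library spectra and diagnostic ions can
    best <- NULL
    for (h in seq_len(max(nrow(hits), 1L))) {
      top <- if (nrow(hits)) hits[h, ] else NULL
      spectral_score <- NA_real_
      class_score <- NA_real_
      n_diag <- 0L
      standard_match <- FALSE
      if (!is.null(top)) {
        frags <- parse_fragment_list(top$diagnostic_fragments)
        if (!is.null(ms2) && length(frags)) {
          cs <- class_fragment_score(ms2, frags, frag_tol_ppm)
          class_score <- cs$fraction
          n_diag <- cs$n_matched
        }
        lib <- spectral_library[[top$name]]
        if (!is.null(ms2) && !is.null(lib))
          spectral_score <- spectral_similarity(ms2, lib, frag_tol_ppm)
        standard_match <- !is.na(top$standard_rt) &&
          abs(rt - top$standard_rt) <= rt_tol_min
      }
      conf <- assign_confidence(
        standard_match = standard_match,
        spectral_score = spectral_score,
        masslist_hit = !is.null(top),
        n_diagnostic_matched = n_diag,
        series_member = fid %in% names(series_of),
        formula_unambiguous = !is.null(top),
        has_ms2 = !is.null(ms2),
        spectral_threshold = spectral_threshold)
      cand <- list(top = top, spectral_score = spectral_score,
                   class_score = class_score, n_diag = n_diag,
                   standard_match = standard_match, conf = conf)
      if (is.null(best) ||
          conf$confidence_level < best$conf$confidence_level ||
          (conf$confidence_level == best$conf$confidence_level &&
           !is.na(spectral_score) &&
           (is.na(best$spectral_score) ||
            spectral_score > best$spectral_score)))
        best <- cand
    }
    top <- best$top
    spectral_score <- best$spectral_score
    class_score <- best$class_score
    n_diag <- best$n_diag
    standard_match <- best$standard_match
    conf <- best$conf
    data.frame(
      feature_id = fid, mz = mz, rt = rt,
      suspect_name = if (is.null(top)) NA_character_ else top$name,
      suspect_formula = if (is.null(top)) NA_character_ else top$formula,
      suspect_class = if (is.null(top)) NA_character_ else top$class,
      source_list = if (is.null(top)) NA_character_ else top$source_list,
      delta_ppm = if (is.null(top)) NA_real_ else top$delta_ppm,
      spectral_score = spectral_score,
      class_score = class_score,
      n_diagnostic_matched = n_diag,
      series_id = if (fid %in% names(series_of)) series_of[[fid]] else NA_character_,
      standard_match = standard_match,
      confidence_level = conf$confidence_level,
      rationale = paste(conf$rationale, collapse = "; "),
      stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann$isomer_tag <- NA_character_
  # branched-isomer reasoning among features assigned the same formula
  for (fml in unique(stats::na.omit(ann$suspect_formula))) {
    idx <- which(ann$suspect_formula == fml)
    if (length(idx) < 2L) next
    std_rt <- suspects$standard_rt[suspects$formula == fml]
    std_rt <- std_rt[!is.na(std_rt)]
    tags <- flag_branched_isomer(
      data.frame(feature_id = ann$feature_id[idx], rt = ann$rt[idx]),
      standard_rt = if (length(std_rt)) std_rt[1] else NA_real_,
      rt_tol_min = rt_tol_min)
    ann$isomer_tag[idx] <- tags$isomer_tag
  }
  ann
}
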