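#' Run the full non-targeted screening pipeline
#'
#' Chains prioritization (blank subtraction, intensity, Kendrick window,
#' MS2 gate), suspect annotation with confidence levels, and the
#' liver-versus-muscle differential analysis, and assembles a run report
#' whose counts are consistent with the stage outputs. All stages are
#' deterministic given the inputs and configuration.
#'
#' @param features Wide per-injection feature table.
#' @param samples Sample table.
#' @param spectra Named list of MS2 spectra.
#' @param suspects Suspect list.
#' @param spectral_library Named list of library spectra (by suspect name).
#' @param config [filter_config()].
#' @param exclusion_list Optional exclusion list for the first stage.
#' @param skip_diff Skip the differential analysis?
#' @param p_thr,lfc_thr Volcano thresholds (defaults 0.05 and 1).
#' @param out_dir Optional directory; when given, every stage writes its
#'   table there (funnel, candidates, annotations, differential results,
#'   PCA scores, clustering exports) plus a YAML run report.
#' @return List of class `pfas_run`: `funnel`, `candidates`, `annotations`,
#'   `diff` (NULL when skipped), `pca`, `clustering`, `report`.
#' @export
run_pipeline <- function(features, samples, spectra = list(),
                         suspects = NULL, spectral_library = list(),
                         config = filter_config(), exclusion_list = NULL,
                         skip_diff = FALSE, p_thr = 0.05, lfc_thr = 1,
                         out_dir = NULL) {
  casc <- run_cascade(features, samples, config, suspects, exclusion_list)
  ann <- annotate_candidates(casc$candidates, suspects, spectra,
                             spectral_library, tol_ppm = config$mz_tol_ppm)

  diff <- NULL; pca <- NULL; clust <- NULL
  if (!skip_diff && nrow(casc$candidates) > 0L) {
    ab <- abundance_matrix(casc$candidates, casc$samples)
    norm <- normalize_abundance(ab$matrix)
    diff <- volcano(norm, ab$groups, p_thr = p_thr, lfc_thr = lfc_thr)
    pca <- pca_samples(norm)
    sig <- diff$compound[diff$volcano_class != "ns"]
    if (length(sig) >= 2L)
      clust <- hclust_heatmap(norm[sig, , drop = FALSE])
  }

  report <- list(
    config = unclass(config),
    funnel = casc$funnel,
    n_candidates = nrow(casc$candidates),
    confidence_counts = as.list(table(factor(ann$confidence_level,
                                             levels = 1:5))),
    differential = if (is.null(diff)) NULL else list(
      up_liver = sum(diff$volcano_class == "up_liver"),
      up_muscle = sum(diff$volcano_class == "up_muscle"),
      ns = sum(diff$volcano_class == "ns"),
      exclusive_liver = sum(diff$exclusive_to == "liver", na.rm = TRUE),
      exclusive_muscle = sum(diff$exclusive_to == "muscle", na.rm = TRUE)),
    package_version = as.character(utils::packageVersion("pfasnta")))

  out <- structure(list(funnel = casc$funnel, candidates = casc$candidates,
                        samples = casc$samples, annotations = ann,
                        diff = diff, pca = pca, clustering = clust,
                        report = report),
                   class = "pfas_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write all pipeline artifacts to a directory
#'
#' @param run A `pfas_run` object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(run$funnel, file.path(dir, "funnel.tsv"))
  write_feature_table(run$candidates, file.path(dir, "candidates.tsv"))
  write_tsv(run$annotations, file.path(dir, "annotations.tsv"))
  if (!is.null(run$diff))
    write_tsv(run$diff, file.path(dir, "differential.tsv"))
  if (!is.null(run$pca)) {
    sc <- data.frame(sample_id = rownames(run$pca$scores), run$pca$scores)
    write_tsv(sc, file.path(dir, "pca_scores.tsv"))
  }
  if (!is.null(run$clustering)) {
    write_tsv(data.frame(compound = rownames(run$clustering$ordered),
                         run$clustering$ordered, check.names = FALSE),
              file.path(dir, "heatmap_matrix.tsv"))
    write_tree_newick(run$clustering$compound_hclust,
                      file.path(dir, "compound_tree.nwk"))
    write_tree_newick(run$clustering$sample_hclust,
                      file.path(dir, "sample_tree.nwk"))
  }
  yaml::write_yaml(run$report, file.path(dir, "run_report.yaml"))
  invisible(dir)
}

#' @export
print.pfas_run <- function(x, ...) {
  cat("Non-targeted PFAS screening run\n")
  cat(paste0("  ", format_funnel(x$funnel), "\n"), sep = "")
  cat(sprintf("  candidates: %d\n", nrow(x$candidates)))
  cl <- table(factor(x$annotations$confidence_level, levels = 1:5))
  cat("  confidence levels:",
      paste(sprintf("CL%s=%d", names(cl), as.integer(cl)), collapse = " "),
      "\n")
  if (!is.null(x$diff)) {
    d <- x$report$differential
    cat(sprintf("  differential: up_liver=%d up_muscle=%d ns=%d (exclusive: %d liver, %d muscle)\n",
                d$up_liver, d$up_muscle, d$ns,
                d$exclusive_liver, d$exclusive_muscle))
  }
  invisible(x)
}
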