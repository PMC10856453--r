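#' Load the curated 60-compound PFAS identification table
#'
#' The package ships the curated identification table from a roe deer
#' (liver and muscle) non-targeted PFAS biomonitoring study: 60 compounds
#' with IUPAC name, molecular formula, observed [M-H]- m/z (4 decimals),
#' printed mass error (ppm), diagnostic DDA fragment ions, retention time
#' (minutes), maximum peak area and Schymanski confidence level (1-3 in
#' this dataset; 7 compounds confirmed by authentic standards at level 1).
#' It is the validation anchor for the mass arithmetic and the source of
#' formulas for the synthetic scenario generator.
#'
#' @return Data frame with 60 rows and columns `code`, `iupac_name`,
#'   `formula`, `printed_mz`, `printed_ppm`, `diagnostic_ions`, `rt`,
#'   `max_area`, `confidence_level`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_roedeer_pfas.tsv",
                      package = "pfasnta", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  problems <- character(0)
  if (nrow(df) != 60L)
    problems <- c(problems, sprintf("expected 60 rows, found %d", nrow(df)))
  if (!identical(sort(df$code), 1:60))
    problems <- c(problems, "codes are not exactly 1..60")
  if (!all(df$confidence_level %in% 1:5))
    problems <- c(problems, "confidence levels outside 1..5")
  bad_formula <- df$code[vapply(df$formula, function(f)
    inherits(try(parse_formula(f), silent = TRUE), "try-error"), TRUE)]
  if (length(bad_formula))
    problems <- c(problems, paste("unparseable formula in row(s):",
                                  paste(bad_formula, collapse = ", ")))
  if (length(problems))
    stop("curated table fixture failed validation:\n  ",
         paste(problems, collapse = "\n  "))
  df[order(df$code), ]
}

#' Recompute mass errors and Kendrick defects for the curated table
#'
#' For each curated row, recomputes the theoretical [M-H]- m/z from the
#' formula, the signed ppm error against the printed observed m/z, the
#' difference to the printed ppm error, and the CF2 Kendrick mass defect.
#' Rows whose recomputed error differs from the printed one by more than
#' `tol_ppm` are flagged as discrepant (three rows are expected to flag:
#' one known outlier whose printed error does not recompute under any
#' standard convention, and one row whose printed m/z matches a chloride
#' adduct instead of [M-H]-). Discrepancies are reported, never raised.
#'
#' @param rows Curated table as returned by [load_table1()].
#' @param tol_ppm Agreement threshold in ppm (default 0.5; the printed
#'   observed m/z is rounded to 4 decimals, which alone bounds agreement to
#'   roughly +/- 0.15 ppm in this mass range).
#' @return List with `per_row` (data frame: code, formula, printed and
#'   recomputed values, `delta_ppm`, `kmd`, `agrees`) and `summary`
#'   (n rows, n within 0.25 / within tol / discrepant, discrepant codes).
#' @export
validate_table1 <- function(rows = load_table1(), tol_ppm = 0.5) {
  theo <- suppressWarnings(vapply(rows$formula, formula_mz, 0))
  recomputed_ppm <- ppm_error(rows$printed_mz, theo)
  delta <- recomputed_ppm - rows$printed_ppm
  kmd <- kendrick(rows$printed_mz)$kmd
  per_row <- data.frame(
    code = rows$code,
    formula = rows$formula,
    printed_mz = rows$printed_mz,
    theoretical_mz = theo,
    printed_ppm = rows$printed_ppm,
    recomputed_ppm = recomputed_ppm,
    delta_ppm = delta,
    kmd = kmd,
    agrees = abs(delta) <= tol_ppm,
    row.names = NULL
  )
  list(
    per_row = per_row,
    summary = list(
      n = nrow(per_row),
      n_within_025 = sum(abs(delta) <= 0.25),
      n_within_tol = sum(per_row$agrees),
      discrepant_codes = per_row$code[!per_row$agrees]
    )
  )
}

#' Build a suspect list from the curated table
#'
#' Turns the curated identification table into a suspect library usable by
#' [match_suspects()]: one entry per compound, with its diagnostic fragments,
#' and the curated RT as authentic-standard RT for confidence-level-1
#' compounds (the seven confirmed against standards).
#'
#' @param rows Curated table (default [load_table1()]).
#' @return Suspect list data frame (see [read_suspect_list()]).
#' @export
table1_suspects <- function(rows = load_table1()) {
  validate_suspect_list(data.frame(
    name = rows$iupac_name,
    formula = rows$formula,
    class = ifelse(grepl("sulfonate|sulphonyl|sulfonamide", rows$iupac_name,
                         ignore.case = TRUE), "PFSA",
                   ifelse(grepl("acid", rows$iupac_name, ignore.case = TRUE),
                          "PFCA", "other")),
    diagnostic_fragments = rows$diagnostic_ions,
    standard_rt = ifelse(rows$confidence_level == 1L, rows$rt, NA_real_),
    source_list = "curated_roedeer",
    stringsAsFactors = FALSE
  ))
}
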