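#' @title Readers and writers for the pipeline's plain-text formats
#' @description
#' All exchange formats are tab-separated text with a `"."` decimal point.
#' A feature table is wide: one row per aligned LC-HRMS feature with columns
#' `feature_id`, `mz`, `rt`, optional `ms2_id`, and one peak-area column per
#' sample (column name = `sample_id`). The sample table describes the study
#' design: `sample_id`, `group` (liver/muscle/blank/qc), `animal_id`
#' (empty for blanks and QCs) and `injection_replicate`.
#' @name pfasnta-io
NULL

SAMPLE_GROUPS <- c("liver", "muscle", "blank", "qc")

write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# written by pfasnta %s",
                     as.character(utils::packageVersion("pfasnta"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read / write a sample (study design) table
#'
#' @param path File path.
#' @return Data frame with columns `sample_id`, `group`, `animal_id`,
#'   `injection_replicate`.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv(path)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param samples Sample table data frame.
#' @export
write_sample_table <- function(samples, path) {
  write_tsv(validate_sample_table(samples), path)
}

#' Validate a sample table against the design schema
#'
#' @param samples Sample table data frame.
#' @return The validated (column-ordered) table; errors on violations.
#' @export
validate_sample_table <- function(samples) {
  need <- c("sample_id", "group", "animal_id", "injection_replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(samples$group), SAMPLE_GROUPS)
  if (length(bad))
    stop("unknown sample group(s): ", paste(bad, collapse = ", "))
  samples$animal_id <- as.character(samples$animal_id)
  samples$animal_id[samples$animal_id == "" | is.na(samples$animal_id)] <- NA_character_
  if (any(!is.na(samples$animal_id[samples$group %in% c("blank", "qc")])))
    stop("blank/qc samples must have empty animal_id")
  samples$injection_replicate <- as.integer(samples$injection_replicate)
  if (any(is.na(samples$injection_replicate)) ||
      any(samples$injection_replicate < 1L))
    stop("injection_replicate must be an integer >= 1")
  samples[, need]
}

#' Read / write a wide feature table
#'
#' Columns `feature_id`, `mz`, `rt`, optional `ms2_id`, then one area column
#' per sample in `sample_table`. Unknown area columns are an error; samples
#' missing from the file get zero areas with a warning.
#'
#' @param path File path.
#' @param sample_table Validated sample table (see [read_sample_table()]).
#' @return Feature data frame; area columns coerced to numeric, `ms2_id`
#'   present (NA where absent).
#' @export
read_feature_table <- function(path, sample_table) {
  sample_table <- validate_sample_table(sample_table)
  df <- read_tsv(path)
  validate_feature_table(df, sample_table)
}

#' @rdname read_feature_table
#' @param features Feature table data frame.
#' @export
write_feature_table <- function(features, path) {
  write_tsv(features, path)
}

#' Validate a wide feature table against a sample table
#'
#' @inheritParams read_feature_table
#' @param features Feature table data frame.
#' @return The validated table (areas numeric, `ms2_id` normalized, columns
#'   ordered); errors on schema violations.
#' @export
validate_feature_table <- function(features, sample_table) {
  need <- c("feature_id", "mz", "rt")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  features$mz <- as.numeric(features$mz)
  features$rt <- as.numeric(features$rt)
  if (any(is.na(features$mz)) || any(features$mz <= 0))
    stop("non-numeric or non-positive m/z in feature table")
  if (any(is.na(features$rt)) || any(features$rt < 0))
    stop("non-numeric or negative RT in feature table")
  if (!"ms2_id" %in% names(features)) features$ms2_id <- NA_character_
  features$ms2_id <- as.character(features$ms2_id)
  features$ms2_id[features$ms2_id == ""] <- NA_character_
  meta <- c("feature_id", "mz", "rt", "ms2_id",
            intersect("provenance", names(features)))
  area_cols <- setdiff(names(features), meta)
  unknown <- setdiff(area_cols, sample_table$sample_id)
  if (length(unknown))
    stop("area column(s) not in sample table: ", paste(unknown, collapse = ", "))
  absent <- setdiff(sample_table$sample_id, area_cols)
  if (length(absent)) {
    warning(sprintf("%d sample(s) missing from feature table; areas set to 0",
                    length(absent)))
    for (s in absent) features[[s]] <- 0
  }
  for (s in sample_table$sample_id) {
    features[[s]] <- as.numeric(features[[s]])
    features[[s]][is.na(features[[s]])] <- 0
    if (any(features[[s]] < 0)) stop("negative peak area in sample ", s)
  }
  features[, c(meta, sample_table$sample_id)]
}

area_matrix <- function(features, sample_table, groups = NULL) {
  ids <- sample_table$sample_id
  if (!is.null(groups)) ids <- ids[sample_table$group %in% groups]
  m <- as.matrix(features[, ids, drop = FALSE])
  rownames(m) <- features$feature_id
  m
}

#' Read an MGF file of MS2 spectra
#'
#' Parses standard `BEGIN IONS`/`END IONS` blocks. `TITLE` carries the
#' spectrum id used for feature linkage, `PEPMASS` the precursor m/z.
#'
#' @param path MGF file path.
#' @return Named list of spectra; each spectrum is a list with `ms2_id`,
#'   `precursor_mz`, `collision_energy` (string tag, may be NA) and `peaks`,
#'   a two-column matrix (`mz`, `intensity`) sorted by m/z.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("unterminated BEGIN IONS block in ", path)
  spectra <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    hdr <- block[kv]
    keys <- toupper(sub("=.*", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    if (!"PEPMASS" %in% keys) stop("MGF block without PEPMASS in ", path)
    title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else
      sprintf("spectrum_%d", i)
    prec <- as.numeric(strsplit(vals[keys == "PEPMASS"][1], "[ \t]+")[[1]][1])
    ce <- if ("COLLISION_ENERGY" %in% keys)
      vals[keys == "COLLISION_ENERGY"][1] else NA_character_
    pk <- block[!kv]
    if (!length(pk)) stop("MGF block '", title, "' has no peaks")
    mat <- do.call(rbind, lapply(strsplit(pk, "[ \t]+"), function(x)
      as.numeric(x[1:2])))
    if (any(is.na(mat))) stop("non-numeric peak line in MGF block '", title, "'")
    if (any(mat[, 2] < 0)) stop("negative intensity in MGF block '", title, "'")
    mat <- mat[order(mat[, 1]), , drop = FALSE]
    colnames(mat) <- c("mz", "intensity")
    spectra[[i]] <- list(ms2_id = title, precursor_mz = prec,
                         collision_energy = ce, peaks = mat)
  }
  names(spectra) <- vapply(spectra, `[[`, "", "ms2_id")
  spectra
}

#' @rdname read_mgf
#' @param spectra List of spectra as returned by [read_mgf()].
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", sp$ms2_id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$collision_energy))
      writeLines(sprintf("COLLISION_ENERGY=%s", sp$collision_energy), con)
    writeLines(sprintf("%.6f %.4f", sp$peaks[, 1], sp$peaks[, 2]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read / write a suspect list
#'
#' Tab-separated with columns `name`, `formula`, `class`,
#' `diagnostic_fragments` (";"-separated m/z values, may be empty),
#' `standard_rt` (minutes; empty when no authentic standard is available)
#' and `source_list`. The neutral monoisotopic mass and theoretical
#' [M-H]- m/z are recomputed from the formula on read.
#'
#' @param path File path.
#' @return Data frame with the columns above plus `neutral_mass` and
#'   `theoretical_mz`.
#' @export
read_suspect_list <- function(path) {
  df <- read_tsv(path)
  validate_suspect_list(df)
}

#' @rdname read_suspect_list
#' @param suspects Suspect list data frame.
#' @export
write_suspect_list <- function(suspects, path) {
  keep <- c("name", "formula", "class", "diagnostic_fragments",
            "standard_rt", "source_list")
  write_tsv(suspects[, intersect(keep, names(suspects))], path)
}

validate_suspect_list <- function(df) {
  need <- c("name", "formula")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("suspect list missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(df)
  if (!"class" %in% names(df)) df$class <- rep(NA_character_, n)
  if (!"diagnostic_fragments" %in% names(df)) df$diagnostic_fragments <- rep("", n)
  if (!"standard_rt" %in% names(df)) df$standard_rt <- rep(NA_real_, n)
  if (!"source_list" %in% names(df)) df$source_list <- rep("user", n)
  df$standard_rt <- suppressWarnings(as.numeric(df$standard_rt))
  df$diagnostic_fragments <- as.character(df$diagnostic_fragments)
  df$diagnostic_fragments[is.na(df$diagnostic_fragments)] <- ""
  df$neutral_mass <- vapply(df$formula, monoisotopic_mass, 0)
  df$theoretical_mz <- suppressWarnings(
    vapply(df$formula, formula_mz, 0))
  df
}

#' Parse a ";"-separated fragment m/z list
#'
#' @param x Single string of ";"-separated m/z values (may be empty).
#' @return Numeric vector (length 0 for empty input).
#' @export
parse_fragment_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}
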