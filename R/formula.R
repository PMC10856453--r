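#' Monoisotopic mass table
#'
#' Exact monoisotopic masses (Da) of the elements supported by the formula
#' parser, on the IUPAC scale (12C = 12 exactly), plus the proton mass used
#' for deprotonated-adduct arithmetic.
#'
#' @format Named numeric vector of element masses in Da.
#' @export
MONOISOTOPIC_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  F  = 18.9984032,
  P  = 30.97376151,
  S  = 31.97207069,
  Cl = 34.96885271
)

#' @rdname MONOISOTOPIC_MASS
#' @export
PROTON_MASS <- 1.00727646

#' Exact monoisotopic mass of one CF2 repeat unit (Da)
#'
#' The repeat unit of perfluoroalkyl homologous series; default exact base of
#' the Kendrick rescaling.
#' @export
CF2_EXACT <- 2 * 18.9984032 + 12.0  # 49.9968064

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula (e.g. `"C8HF17O3S"`) into a named
#' integer vector of element counts. Underscores and surrounding whitespace,
#' as found in typeset tables (`"C_8_HF_17_O_3_S"`), are stripped before
#' parsing. Only elements present in [MONOISOTOPIC_MASS] are accepted.
#'
#' @param text Formula string.
#' @return Named integer vector of counts, one entry per element present,
#'   all counts >= 1, in order of first appearance.
#' @examples
#' parse_formula("C8HF17O3S")
#' parse_formula("C_5_HF_11_")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  clean <- gsub("[_[:space:]]", "", text)
  if (!nzchar(clean)) stop("empty formula")
  toks <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean)[[1]]
  matched <- regmatches(clean, list(toks))[[1]]
  if (sum(attr(toks, "match.length")) != nchar(clean)) {
    # locate first character not covered by any token
    covered <- rep(FALSE, nchar(clean))
    for (i in seq_along(toks))
      covered[toks[i] + seq_len(attr(toks, "match.length")[i]) - 1L] <- TRUE
    pos <- which(!covered)[1]
    stop(sprintf("malformed formula '%s': unparseable at position %d ('%s')",
                 text, pos, substr(clean, pos, pos)))
  }
  el <- sub("[0-9]*$", "", matched)
  n  <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", matched)))
  n[is.na(n)] <- 1L
  bad <- setdiff(unique(el), names(MONOISOTOPIC_MASS))
  if (length(bad))
    stop(sprintf("unsupported element symbol(s) in '%s': %s",
                 text, paste(bad, collapse = ", ")))
  if (any(n == 0L)) {
    pos <- which(n == 0L)[1]
    stop(sprintf("zero count for element '%s' in formula '%s'", el[pos], text))
  }
  counts <- tapply(n, factor(el, levels = unique(el)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Canonical Hill-order formula string
#'
#' Writes an element-count vector back as a formula string in Hill order
#' (C first, then H, then all other elements alphabetically); counts of 1
#' are omitted. `parse_formula(formula_string(x))` is the identity.
#'
#' @param comp Named integer vector as returned by [parse_formula()].
#' @return Single formula string.
#' @export
formula_string <- function(comp) {
  comp <- validate_composition(comp)
  els <- names(comp)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  paste0(ord, ifelse(comp[ord] > 1L, comp[ord], ""), collapse = "")
}

validate_composition <- function(comp) {
  if (is.null(names(comp)) || length(comp) == 0L)
    stop("composition must be a non-empty named vector")
  bad <- setdiff(names(comp), names(MONOISOTOPIC_MASS))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(comp < 1L) || any(comp != round(comp)))
    stop("element counts must be positive integers")
  storage.mode(comp) <- "integer"
  comp
}

#' Neutral monoisotopic mass of a composition or formula
#'
#' @param comp Named integer vector of element counts, or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C8HF17O3S")
#' @export
monoisotopic_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- validate_composition(comp)
  sum(MONOISOTOPIC_MASS[names(comp)] * comp)
}

#' m/z of an adduct ion
#'
#' Computes the expected m/z of a neutral compound under a given adduct.
#' Only the deprotonated ion `"[M-H]-"` observed in negative-mode
#' electrospray is supported: m/z = M - proton mass (the electron is
#' retained by the anion).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct tag; only `"[M-H]-"`.
#' @return m/z in Th.
#' @export
adduct_mz <- function(neutral_mass, adduct = "[M-H]-") {
  if (!identical(adduct, "[M-H]-"))
    stop(sprintf("unsupported adduct '%s': only \"[M-H]-\" is implemented", adduct))
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0))
    stop("neutral_mass must be positive")
  neutral_mass - PROTON_MASS
}

#' Theoretical [M-H]- m/z of a formula
#'
#' Convenience wrapper: parse, sum masses, subtract the proton. Compositions
#' with no hydrogen still yield a value (some curated entries print an
#' [M-H]- m/z for H-free formulas) but raise a warning.
#'
#' @param formula Formula string or composition vector.
#' @return m/z in Th.
#' @export
formula_mz <- function(formula) {
  comp <- if (is.character(formula)) parse_formula(formula) else
    validate_composition(formula)
  if (!"H" %in% names(comp))
    warning(sprintf("formula '%s' has no hydrogen; [M-H]- m/z is nominal",
                    formula_string(comp)))
  adduct_mz(monoisotopic_mass(comp))
}

#' Signed mass error in ppm
#'
#' @param observed_mz Observed m/z (Th).
#' @param theoretical_mz Theoretical m/z (Th, > 0).
#' @return Signed error in ppm: (observed - theoretical) / theoretical * 1e6.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical_mz must be positive")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Kendrick mass and mass defect
#'
#' Rescales an m/z so that the chosen repeat unit (CF2 by default) has
#' integer mass: KM = mz * base_nominal / base_exact. The Kendrick mass
#' defect is KMD = KM - round(KM), which lies in (-0.5, 0.5] and is shared
#' by all members of a homologous series differing only in repeat-unit
#' count. Fluorine-rich ions have slightly negative KMD under this
#' convention, which is why PFAS prioritization uses an asymmetric window
#' around zero.
#'
#' @param mz m/z values (Th, > 0); vectorized.
#' @param base_nominal Nominal (integer) mass of the repeat unit; 50 for CF2.
#' @param base_exact Exact mass of the repeat unit; defaults to [CF2_EXACT].
#' @return Data frame with columns `kendrick_mass` and `kmd`.
#' @examples
#' kendrick(498.9321)
#' @export
kendrick <- function(mz, base_nominal = 50L, base_exact = CF2_EXACT) {
  if (any(mz <= 0) || base_exact <= 0 || base_nominal <= 0)
    stop("mz and Kendrick base must be positive")
  km <- mz * base_nominal / base_exact
  data.frame(kendrick_mass = km, kmd = km - round(km))
}
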