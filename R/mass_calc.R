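# Peptide mass bookkeeping: residue mass tables, precursor delta mass, and
# tryptic specificity checks. Monoisotopic masses are the default because
# delta-mass QC on an ion trap is judged against the monoisotopic peptide mass.

.MONOISOTOPIC <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AVERAGE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.AMINO_ACIDS <- names(.MONOISOTOPIC)

#' Residue mass table
#'
#' Assemble the residue masses, water and proton constants, and named
#' modification masses used for all peptide mass arithmetic. Monoisotopic
#' masses are the default; an average-mass table is available for synthetic
#' realism at low resolving power. Individual residue masses can be
#' overridden from a two-column (residue, mass) TSV.
#'
#' @param type `"monoisotopic"` (default) or `"average"`.
#' @param override_file Optional path to a headerless TSV with columns
#'   residue and mass (Da) overriding individual residues.
#' @return An object of class `residue_mass_table`: a list with elements
#'   `residues` (named numeric, 20 standard residues), `water`, `proton`,
#'   and `modifications` (named numeric, includes `phospho`).
#' @examples
#' tab <- residue_mass_table()
#' tab$residues[["G"]]
#' @export
residue_mass_table <- function(type = c("monoisotopic", "average"),
                               override_file = NULL) {
  type <- match.arg(type)
  residues <- if (type == "monoisotopic") .MONOISOTOPIC else .AVERAGE
  water <- if (type == "monoisotopic") 18.010565 else 18.01528
  if (!is.null(override_file)) {
    ov <- utils::read.table(override_file, sep = "\t",
                            col.names = c("residue", "mass"),
                            colClasses = c("character", "numeric"))
    bad <- setdiff(ov$residue, names(residues))
    if (length(bad) > 0)
      stop("unknown residue(s) in override file: ", paste(bad, collapse = ", "))
    residues[ov$residue] <- ov$mass
  }
  if (any(residues <= 0)) stop("all residue masses must be positive")
  structure(
    list(residues = residues,
         water = water,
         proton = 1.007276,
         modifications = c(phospho = 79.96633, oxidation = 15.994915)),
    class = "residue_mass_table"
  )
}

#' @export
print.residue_mass_table <- function(x, ...) {
  cat("Residue mass table (", length(x$residues), " residues)\n", sep = "")
  cat("  water ", x$water, " Da, proton ", x$proton, " Da\n", sep = "")
  cat("  modifications:",
      paste(names(x$modifications), format(x$modifications), sep = "="),
      "\n")
  invisible(x)
}

#' Theoretical peptide mass
#'
#' Neutral (uncharged) peptide mass: the sum of residue masses plus one
#' water, plus any fixed added modification mass.
#'
#' @param peptide Character vector of uppercase peptide sequences.
#' @param mod_mass Added modification mass in Da (scalar or vector,
#'   recycled); must be non-negative.
#' @param table A [residue_mass_table()].
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("G")            # 75.03203
#' peptide_mass("AK", mod_mass = residue_mass_table()$modifications[["phospho"]])
#' @export
peptide_mass <- function(peptide, mod_mass = 0, table = residue_mass_table()) {
  if (any(mod_mass < 0)) stop("mod_mass must be >= 0")
  if (length(peptide) == 0) return(numeric(0))
  masses <- table$residues
  out <- vapply(peptide, function(p) {
    if (is.na(p) || nchar(p) == 0) stop("empty peptide")
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    unknown <- which(!aa %in% names(masses))
    if (length(unknown) > 0)
      stop(sprintf("unknown residue '%s' at position %d of '%s'",
                   aa[unknown[1]], unknown[1], p))
    sum(masses[aa])
  }, numeric(1), USE.NAMES = FALSE)
  out + table$water + mod_mass
}

#' Precursor delta mass
#'
#' Observed neutral mass minus theoretical mass:
#' `(precursor_mz * charge - charge * proton) - theoretical_mass`. On a
#' linear ion trap its distribution is approximately Gaussian within
#' +/- 2 Da and serves as an identification quality control.
#'
#' @param precursor_mz Observed precursor m/z (Th).
#' @param charge Precursor charge (integer >= 1).
#' @param theoretical_mass Theoretical neutral peptide mass (Da).
#' @param table A [residue_mass_table()] supplying the proton mass.
#' @return Numeric vector of delta masses in Da.
#' @export
delta_mass <- function(precursor_mz, charge, theoretical_mass,
                       table = residue_mass_table()) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (precursor_mz * charge - charge * table$proton) - theoretical_mass
}

#' Tryptic specificity and missed-cleavage count
#'
#' A peptide is fully tryptic when its N-terminus follows a K/R cleavage (or
#' the protein N-terminus, flank `'-'`) and its C-terminal residue is K/R
#' (or it ends at the protein C-terminus). Missed cleavages count internal
#' K/R sites. With `proline_rule = TRUE` (default) K/R followed by proline
#' is not a cleavage site, for both the terminus checks and the
#' missed-cleavage count.
#'
#' @param peptide Character vector of peptide sequences.
#' @param prev_aa,next_aa Flanking residues; `'-'` marks protein termini.
#' @param proline_rule Suppress cleavage at KP/RP junctions (default TRUE).
#' @return A data.frame with columns `is_fully_tryptic` (logical) and
#'   `missed_cleavages` (integer).
#' @examples
#' tryptic_status("AKAAR", "K", "A")  # fully tryptic, 1 missed cleavage
#' @export
tryptic_status <- function(peptide, prev_aa, next_aa, proline_rule = TRUE) {
  if (length(peptide) == 0)
    return(data.frame(is_fully_tryptic = logical(0),
                      missed_cleavages = integer(0)))
  if (any(is.na(peptide) | nchar(peptide) == 0)) stop("empty peptide")
  n <- nchar(peptide)
  first <- substr(peptide, 1L, 1L)
  last <- substr(peptide, n, n)
  nterm_ok <- prev_aa == "-" | prev_aa %in% c("K", "R")
  cterm_ok <- next_aa == "-" | last %in% c("K", "R")
  if (proline_rule) {
    nterm_ok <- prev_aa == "-" |
      (prev_aa %in% c("K", "R") & first != "P")
    cterm_ok <- next_aa == "-" |
      (last %in% c("K", "R") & next_aa != "P")
  }
  missed <- mapply(function(p, len) {
    if (len < 2L) return(0L)
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    internal <- aa[-len] %in% c("K", "R")
    if (proline_rule) internal <- internal & aa[-1L] != "P"
    sum(internal)
  }, peptide, n, USE.NAMES = FALSE)
  data.frame(is_fully_tryptic = nterm_ok & cterm_ok,
             missed_cleavages = as.integer(missed))
}
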