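# Readers and writers for the fixed dialects: tab-separated, UTF-8, '.'
# decimal, one header row. Lines starting with '#' are metadata headers and
# are skipped on read.

.PSM_REQUIRED <- c("spectrum_id", "precursor_mz", "charge", "intensity",
                   "peptide", "prev_aa", "next_aa", "accession",
                   "gene_symbol", "p_value", "algorithm", "sample_id",
                   "treatment", "time_h")

.PSM_NUMERIC <- c("precursor_mz", "charge", "intensity", "p_value", "time_h",
                  "mod_mass")

.PEPTIDE_RE <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches, one row per
#' MS/MS-to-peptide correlation. All required columns must be present in the
#' header; rows failing type or invariant checks (charge >= 1, intensity >=
#' 0, p in (0,1], valid peptide alphabet, time in \[0,72\], known treatment
#' and algorithm labels) are rejected individually, counted, and reported
#' with their line numbers -- never silently dropped.
#'
#' @param path Path to a TSV file with header columns `spectrum_id`,
#'   `precursor_mz`, `charge`, `intensity`, `peptide`, `prev_aa`, `next_aa`,
#'   `accession`, `gene_symbol`, `p_value`, `algorithm`, `sample_id`,
#'   `treatment`, `time_h` and optionally `mod_mass`.
#' @return A data.frame of validated PSM records (empty gene symbols kept as
#'   `""`). Rejected rows are attached as attribute `"rejects"`, a
#'   data.frame with columns `line` and `reason`.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, comment.char = "#",
                           na.strings = NULL, quote = "")
  missing_cols <- setdiff(.PSM_REQUIRED, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"mod_mass" %in% names(raw)) raw$mod_mass <- "0"
  raw <- raw[, c(.PSM_REQUIRED, "mod_mass")]
  n <- nrow(raw)
  if (n == 0) {
    out <- .coerce_psm(raw)
    attr(out, "rejects") <- data.frame(line = integer(0),
                                       reason = character(0))
    return(out)
  }
  reason <- character(n)
  num <- lapply(raw[.PSM_NUMERIC], function(x) suppressWarnings(as.numeric(x)))
  for (col in .PSM_NUMERIC) {
    bad <- is.na(num[[col]]) & reason == ""
    reason[bad] <- sprintf("unparseable numeric in '%s'", col)
  }
  ok <- reason == ""
  chk <- function(cond, msg) {
    bad <- ok & !cond
    reason[bad] <<- msg
    ok <<- ok & cond
  }
  chk(num$charge >= 1 & num$charge == floor(num$charge), "charge must be a positive integer")
  chk(num$intensity >= 0, "intensity must be >= 0")
  chk(num$p_value > 0 & num$p_value <= 1, "p_value must be in (0,1]")
  chk(num$time_h >= 0 & num$time_h <= 72, "time_h must be in [0,72]")
  chk(num$mod_mass >= 0, "mod_mass must be >= 0")
  chk(grepl(.PEPTIDE_RE, raw$peptide), "invalid peptide sequence")
  chk(grepl("^([ACDEFGHIKLMNPQRSTVWY]|-)$", raw$prev_aa), "invalid prev_aa")
  chk(grepl("^([ACDEFGHIKLMNPQRSTVWY]|-)$", raw$next_aa), "invalid next_aa")
  chk(raw$treatment %in% c("ICE", "RT"), "treatment must be ICE or RT")
  chk(raw$algorithm %in% c("XTANDEM", "SEQUEST"), "algorithm must be XTANDEM or SEQUEST")
  chk(nchar(raw$spectrum_id) > 0, "empty spectrum_id")
  chk(nchar(raw$accession) > 0, "empty accession")
  rejects <- data.frame(line = which(!ok) + 1L, reason = reason[!ok],
                        stringsAsFactors = FALSE)
  out <- .coerce_psm(raw[ok, , drop = FALSE])
  if (nrow(rejects) > 0)
    message(nrow(rejects), " malformed row(s) rejected from ", path,
            " (first: line ", rejects$line[1], ", ", rejects$reason[1], ")")
  attr(out, "rejects") <- rejects
  out
}

.coerce_psm <- function(raw) {
  out <- data.frame(
    spectrum_id = raw$spectrum_id,
    precursor_mz = as.numeric(raw$precursor_mz),
    charge = as.integer(raw$charge),
    intensity = as.numeric(raw$intensity),
    peptide = raw$peptide,
    prev_aa = raw$prev_aa,
    next_aa = raw$next_aa,
    accession = raw$accession,
    gene_symbol = raw$gene_symbol,
    p_value = as.numeric(raw$p_value),
    algorithm = raw$algorithm,
    sample_id = raw$sample_id,
    treatment = raw$treatment,
    time_h = as.numeric(raw$time_h),
    mod_mass = as.numeric(raw$mod_mass),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a PSM table
#'
#' Writes the fixed tab-separated dialect read by [read_psm_table()].
#' Numeric fields are serialized with 17 significant digits so that a
#' write/read round trip reproduces every record exactly.
#'
#' @param psms A PSM data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms[, intersect(c(.PSM_REQUIRED, "mod_mass"), names(psms)),
              drop = FALSE]
  for (col in intersect(.PSM_NUMERIC, names(out)))
    out[[col]] <- sprintf("%.17g", out[[col]])
  out$charge <- as.character(psms$charge)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein library from FASTA
#'
#' Builds an accession -> (sequence, gene symbol) library. The accession is
#' the first whitespace-delimited token of each FASTA header. Gene symbols
#' come from an optional accession -> symbol map; accessions absent from the
#' map carry an empty symbol (in the human federated library only about 74%
#' of accessions have one).
#'
#' @param path FASTA file of protein sequences.
#' @param symbol_map Optional data.frame (or TSV path) with columns
#'   `accession` and `gene_symbol`.
#' @return A `protein_library`: data.frame with columns `accession`,
#'   `gene_symbol`, `sequence`; attribute `"symbol_fraction"` holds the
#'   fraction of accessions with a defined symbol.
#' @export
read_fasta_library <- function(path, symbol_map = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  accession <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(accession))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0))
    stop("empty sequence for accession(s): ",
         paste(accession[Biostrings::width(seqs) == 0], collapse = ", "))
  if (is.character(symbol_map) && length(symbol_map) == 1)
    symbol_map <- utils::read.delim(symbol_map, colClasses = "character",
                                    comment.char = "#", quote = "")
  gene_symbol <- rep("", length(accession))
  if (!is.null(symbol_map)) {
    idx <- match(accession, symbol_map$accession)
    hit <- !is.na(idx)
    gene_symbol[hit] <- symbol_map$gene_symbol[idx[hit]]
    gene_symbol[is.na(gene_symbol)] <- ""
  }
  protein_library(accession, gene_symbol, as.character(seqs))
}

#' Construct a protein library
#'
#' @param accession Unique accession strings.
#' @param gene_symbol Gene symbols (empty string when undefined).
#' @param sequence Non-empty protein sequences.
#' @param gene_id Optional internal gene identifiers (used by the synthetic
#'   generator so that truth tracking survives empty gene symbols).
#' @return A `protein_library` data.frame.
#' @export
protein_library <- function(accession, gene_symbol, sequence,
                            gene_id = NULL) {
  if (anyDuplicated(accession)) stop("accessions must be unique")
  if (any(nchar(sequence) == 0)) stop("sequences must be non-empty")
  out <- data.frame(accession = accession, gene_symbol = gene_symbol,
                    sequence = sequence, stringsAsFactors = FALSE)
  if (!is.null(gene_id)) out$gene_id <- gene_id
  attr(out, "symbol_fraction") <- mean(gene_symbol != "")
  class(out) <- c("protein_library", "data.frame")
  out
}

#' @export
print.protein_library <- function(x, ...) {
  cat("Protein library: ", nrow(x), " accessions, ",
      length(unique(x$gene_symbol[x$gene_symbol != ""])),
      " distinct gene symbols\n", sep = "")
  cat(sprintf("  symbol coverage: %.1f%%\n",
              100 * attr(x, "symbol_fraction")))
  invisible(x)
}

#' Write a protein library as FASTA (plus symbol map)
#'
#' @param library A `protein_library`.
#' @param path Output FASTA path.
#' @param symbol_map_path Optional path for a TSV accession -> gene_symbol
#'   map (written only when given).
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path, symbol_map_path = NULL) {
  seqs <- Biostrings::AAStringSet(setNames(library$sequence,
                                           library$accession))
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(symbol_map_path))
    utils::write.table(library[, c("accession", "gene_symbol")],
                       symbol_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' @param path TSV with columns `sample_id`, `treatment` (ICE/RT), `time_h`,
#'   `preservation` (ICE, LN2, MINUS80 or RT).
#' @return A validated data.frame.
#' @export
read_sample_manifest <- function(path) {
  m <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                         quote = "")
  need <- c("sample_id", "treatment", "time_h", "preservation")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  m$time_h <- as.numeric(m$time_h)
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  if (!all(m$treatment %in% c("ICE", "RT")))
    stop("treatment must be ICE or RT")
  if (!all(m$preservation %in% c("ICE", "LN2", "MINUS80", "RT")))
    stop("preservation must be one of ICE, LN2, MINUS80, RT")
  m[, need]
}

#' Check that every PSM sample is in the manifest
#'
#' @param psms PSM data.frame.
#' @param manifest Sample manifest.
#' @return TRUE invisibly; errors listing unmatched sample ids otherwise.
#' @export
validate_manifest <- function(psms, manifest) {
  missing_ids <- setdiff(unique(psms$sample_id), manifest$sample_id)
  if (length(missing_ids) > 0)
    stop("sample_id(s) absent from manifest: ",
         paste(missing_ids, collapse = ", "))
  invisible(TRUE)
}

#' Read a category annotation table
#'
#' @param path TSV with columns `term_id`, `description`, `gene` (one gene
#'   per row, long format).
#' @return A data.frame with those three columns.
#' @export
read_annotation_table <- function(path) {
  a <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                         quote = "")
  need <- c("term_id", "description", "gene")
  missing_cols <- setdiff(need, names(a))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  a[, need]
}

#' Write gene summaries
#'
#' Rows are ordered by ascending q-value, ties broken by gene symbol; the
#' per-peptide p-value list is serialized semicolon-separated. Column and
#' row order are deterministic.
#'
#' @param summaries Gene summary data.frame (see [gene_rollup()]).
#' @param path Output TSV path.
#' @param header_lines Optional character vector of metadata lines written
#'   verbatim (prefixed with `# `) before the table.
#' @return `path`, invisibly.
#' @export
write_gene_summaries <- function(summaries, path, header_lines = NULL) {
  ord <- order(summaries$q_value, summaries$gene_symbol)
  s <- summaries[ord, , drop = FALSE]
  out <- data.frame(
    gene_symbol = s$gene_symbol,
    accession = s$accession,
    peptide_count = s$peptide_count,
    n_ice = s$n_ice,
    n_rt = s$n_rt,
    mean_p = sprintf("%.6g", s$mean_p),
    log10_cumulative_p = sprintf("%.6g", s$log10_cumulative_p),
    cumulative_p = sprintf("%.6g", s$cumulative_p),
    q_value = sprintf("%.6g", s$q_value),
    peptide_p_values = vapply(s$peptide_p_values,
                              function(p) paste(sprintf("%.6g", p),
                                                collapse = ";"),
                              character(1)),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
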