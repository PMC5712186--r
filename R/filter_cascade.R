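# The deduplication and filtering cascade from raw MS/MS-to-peptide
# correlations down to distinct gene symbols. Every stage is deterministic:
# ties are broken by lower charge, then lower p-value, then lexicographic
# peptide, then lexicographic accession, in that order.

.CASCADE_STAGES <- c("RAW", "INTENSITY_GE_1000", "BEST_CHARGE",
                     "BEST_PEPTIDE", "RANK1_PEPTIDES", "ACCESSION_GE_K",
                     "GENE_ROLLUP", "DISTINCT_GENES")

#' Cascade stage names
#'
#' The fixed, ordered stage names reported by [run_cascade()].
#' @return Character vector of the eight stage names.
#' @export
cascade_stages <- function() .CASCADE_STAGES

#' Complex key of a correlation
#'
#' A deterministic key over (spectrum_id, charge, peptide, accession)
#' identifying one candidate correlation; equal keys correspond exactly to
#' equal 4-tuples. Used to enforce that no MS/MS spectrum is counted under
#' more than one assignment.
#'
#' @param psms PSM data.frame.
#' @return Character vector of keys, one per row.
#' @export
complex_key <- function(psms) {
  paste(psms$spectrum_id, psms$charge, psms$peptide, psms$accession,
        sep = "\r")
}

#' Precursor intensity filter
#'
#' Keeps correlations whose precursor intensity reaches the threshold. The
#' physical filter is one thousand detector counts; the boundary value is
#' kept by default ("at least one thousand"), with a strict (>) mode
#' available.
#'
#' @param psms PSM data.frame.
#' @param min_counts Intensity threshold in detector counts (default 1000).
#' @param strict If TRUE use a strict `>` comparison instead of `>=`.
#' @return Filtered PSM data.frame.
#' @export
intensity_filter <- function(psms, min_counts = 1000, strict = FALSE) {
  if (min_counts < 0) stop("min_counts must be >= 0")
  keep <- if (strict) psms$intensity > min_counts
          else psms$intensity >= min_counts
  psms[keep, , drop = FALSE]
}

#' Best charge state per spectrum
#'
#' For each spectrum, keeps only the correlations at the single charge state
#' whose best (lowest) p-value is lowest; ties go to the lower charge.
#'
#' @param psms PSM data.frame.
#' @return Filtered PSM data.frame.
#' @export
best_charge_state <- function(psms) {
  if (nrow(psms) == 0) return(psms)
  dt <- data.table::as.data.table(psms)
  best <- dt[, .(best_p = min(p_value)), by = .(spectrum_id, charge)]
  data.table::setorder(best, spectrum_id, best_p, charge)
  sel <- best[, utils::head(.SD, 1L), by = spectrum_id][, .(spectrum_id, charge)]
  out <- dt[sel, on = c("spectrum_id", "charge")]
  .as_psm_df(out, psms)
}

#' Best peptide per spectrum
#'
#' After [best_charge_state()], keeps for each spectrum only the peptide
#' sequence with the lowest p-value (ties: lexicographically smaller
#' peptide), so that no spectrum is assigned to more than one sequence.
#' Rows carrying that peptide in multiple accessions remain; exact
#' duplicates of the (spectrum, charge, peptide, accession) complex key are
#' collapsed to one row.
#'
#' @param psms PSM data.frame (one charge per spectrum).
#' @return Filtered PSM data.frame.
#' @export
best_peptide <- function(psms) {
  if (nrow(psms) == 0) return(psms)
  dt <- data.table::as.data.table(psms)
  best <- dt[, .(best_p = min(p_value)), by = .(spectrum_id, peptide)]
  data.table::setorder(best, spectrum_id, best_p, peptide)
  sel <- best[, utils::head(.SD, 1L), by = spectrum_id][, .(spectrum_id, peptide)]
  out <- dt[sel, on = c("spectrum_id", "peptide")]
  data.table::setorder(out, spectrum_id, p_value, charge, accession)
  out <- unique(out, by = c("spectrum_id", "charge", "peptide", "accession"))
  .as_psm_df(out, psms)
}

#' Collapse shared peptides to RANK1 correlations
#'
#' After [best_peptide()], a spectrum may still correlate to the same
#' peptide in several accessions (isoform redundancy). Each spectrum is
#' assigned to exactly one accession: the candidate accession with the
#' highest total number of correlations in the input (the gene-rollup
#' representative rule); ties go to the lexicographically smaller accession.
#'
#' @param psms PSM data.frame (one peptide per spectrum).
#' @param library Optional `protein_library`; accessions not resolvable in
#'   it trigger a warning (rows are kept with their stated gene symbol).
#' @return PSM data.frame with exactly one row per spectrum.
#' @export
rank1_collapse <- function(psms, library = NULL) {
  if (nrow(psms) == 0) return(psms)
  if (!is.null(library)) {
    unresolved <- setdiff(unique(psms$accession), library$accession)
    if (length(unresolved) > 0)
      warning("accession(s) not in library (rows kept): ",
              paste(utils::head(unresolved, 5), collapse = ", "),
              if (length(unresolved) > 5) ", ..." else "")
  }
  dt <- data.table::as.data.table(psms)
  counts <- dt[, .(n_acc = .N), by = accession]
  dt <- counts[dt, on = "accession"]
  data.table::setorder(dt, spectrum_id, -n_acc, accession)
  out <- dt[, utils::head(.SD, 1L), by = spectrum_id]
  out[, n_acc := NULL]
  .as_psm_df(out, psms)
}

#' Minimum peptide-count filter per accession
#'
#' Keeps correlations whose accession carries at least `k` RANK1
#' correlations. By default "independent peptides" counts correlations
#' (PSMs); a distinct-sequence mode is available.
#'
#' @param psms RANK1 PSM data.frame.
#' @param k Minimum count (default 5; a more permissive screen uses 3).
#' @param count_mode `"correlations"` (default) or `"sequences"`.
#' @return Filtered PSM data.frame.
#' @export
min_peptide_count_filter <- function(psms, k = 5,
                                     count_mode = c("correlations",
                                                    "sequences")) {
  count_mode <- match.arg(count_mode)
  if (k < 1) stop("k must be >= 1")
  if (nrow(psms) == 0) return(psms)
  dt <- data.table::as.data.table(psms)
  cnt <- if (count_mode == "correlations")
    dt[, .(n_acc = .N), by = accession]
  else
    dt[, .(n_acc = data.table::uniqueN(peptide)), by = accession]
  keep <- cnt[n_acc >= k, accession]
  .as_psm_df(dt[accession %in% keep], psms)
}

#' Gene-symbol rollup
#'
#' Collapses accessions to one representative per gene symbol: the accession
#' with the most correlations (ties: lexicographically smaller accession).
#' Records with empty gene symbols are excluded from the rollup and counted
#' separately (attribute `"n_no_symbol"`).
#'
#' @param psms RANK1 PSM data.frame after the minimum-count filter.
#' @return A data.frame with one row per gene symbol: `gene_symbol`,
#'   `accession` (representative), `peptide_count`, `n_ice`, `n_rt`,
#'   `mean_p` and a list column `peptide_p_values`. Attributes:
#'   `"n_no_symbol"` (correlations without a gene symbol) and
#'   `"rollup_correlations"` (correlations on representative accessions).
#' @export
gene_rollup <- function(psms) {
  dt <- data.table::as.data.table(psms)
  n_no_symbol <- sum(dt$gene_symbol == "")
  dt <- dt[gene_symbol != ""]
  if (nrow(dt) == 0) {
    out <- data.frame(gene_symbol = character(0), accession = character(0),
                      peptide_count = integer(0), n_ice = integer(0),
                      n_rt = integer(0), mean_p = numeric(0))
    out$peptide_p_values <- list()
    attr(out, "n_no_symbol") <- n_no_symbol
    attr(out, "rollup_correlations") <- 0L
    return(out)
  }
  acc <- dt[, .(n_acc = .N), by = .(gene_symbol, accession)]
  data.table::setorder(acc, gene_symbol, -n_acc, accession)
  rep_acc <- acc[, utils::head(.SD, 1L), by = gene_symbol]
  kept <- dt[rep_acc[, .(gene_symbol, accession)],
             on = c("gene_symbol", "accession")]
  has_treat <- "treatment" %in% names(kept)
  summ <- kept[, .(
    accession = accession[1L],
    peptide_count = .N,
    n_ice = if (has_treat) sum(treatment == "ICE") else 0L,
    n_rt = if (has_treat) sum(treatment == "RT") else 0L,
    mean_p = mean(p_value),
    peptide_p_values = list(sort(p_value))
  ), by = gene_symbol]
  data.table::setorder(summ, gene_symbol)
  out <- data.table::setDF(summ)
  attr(out, "n_no_symbol") <- n_no_symbol
  attr(out, "rollup_correlations") <- sum(out$peptide_count)
  out
}

#' Run the full filtering cascade
#'
#' Applies, in fixed order: intensity filter, best charge state per
#' spectrum, best peptide per spectrum, RANK1 collapse of shared peptides,
#' minimum correlation count per accession, and gene-symbol rollup; then
#' attaches gene-level cumulative p-values and Benjamini-Hochberg q-values.
#' The report records the number of surviving correlations at every stage
#' (the last stage counts distinct gene symbols).
#'
#' @param psms PSM data.frame.
#' @param min_intensity Intensity threshold (default 1000 counts).
#' @param min_peptides Minimum correlations per accession (default 5).
#' @param strict_intensity Use strict `>` for the intensity filter.
#' @param count_mode Counting mode for the minimum-count filter.
#' @param cumulative_method `"product"` (default) or `"fisher"` for the
#'   gene-level combined p-value.
#' @param library Optional `protein_library` for accession resolution.
#' @return An object of class `cascade_result`: list with `summaries` (gene
#'   summaries including `cumulative_p`, `log10_cumulative_p`, `q_value`),
#'   `report` (a `cascade_report` data.frame of stage counts), `rank1` (the
#'   surviving RANK1 correlations after the minimum-count filter),
#'   `n_no_symbol`, and the configuration used.
#' @export
run_cascade <- function(psms, min_intensity = 1000, min_peptides = 5,
                        strict_intensity = FALSE,
                        count_mode = c("correlations", "sequences"),
                        cumulative_method = c("product", "fisher"),
                        library = NULL) {
  count_mode <- match.arg(count_mode)
  cumulative_method <- match.arg(cumulative_method)
  counts <- integer(length(.CASCADE_STAGES))
  names(counts) <- .CASCADE_STAGES
  counts["RAW"] <- nrow(psms)
  s1 <- intensity_filter(psms, min_intensity, strict = strict_intensity)
  counts["INTENSITY_GE_1000"] <- nrow(s1)
  s2 <- best_charge_state(s1)
  counts["BEST_CHARGE"] <- nrow(s2)
  s3 <- best_peptide(s2)
  counts["BEST_PEPTIDE"] <- nrow(s3)
  s4 <- rank1_collapse(s3, library = library)
  counts["RANK1_PEPTIDES"] <- nrow(s4)
  s5 <- min_peptide_count_filter(s4, k = min_peptides,
                                 count_mode = count_mode)
  counts["ACCESSION_GE_K"] <- nrow(s5)
  summaries <- gene_rollup(s5)
  counts["GENE_ROLLUP"] <- attr(summaries, "rollup_correlations")
  counts["DISTINCT_GENES"] <- nrow(summaries)
  summaries <- .attach_gene_significance(summaries, cumulative_method)
  report <- data.frame(stage = .CASCADE_STAGES, count = unname(counts),
                       stringsAsFactors = FALSE)
  class(report) <- c("cascade_report", "data.frame")
  structure(
    list(summaries = summaries, report = report, rank1 = s5,
         n_no_symbol = attr(summaries, "n_no_symbol"),
         config = list(min_intensity = min_intensity,
                       min_peptides = min_peptides,
                       strict_intensity = strict_intensity,
                       count_mode = count_mode,
                       cumulative_method = cumulative_method)),
    class = "cascade_result"
  )
}

.attach_gene_significance <- function(summaries, method) {
  n_no_symbol <- attr(summaries, "n_no_symbol")
  rollup <- attr(summaries, "rollup_correlations")
  if (nrow(summaries) == 0) {
    summaries$cumulative_p <- numeric(0)
    summaries$log10_cumulative_p <- numeric(0)
    summaries$q_value <- numeric(0)
  } else if (method == "product") {
    log10p <- vapply(summaries$peptide_p_values,
                     function(p) sum(log10(p)), numeric(1))
    summaries$log10_cumulative_p <- log10p
    summaries$cumulative_p <- 10^log10p   # may underflow to 0; documented
    summaries$q_value <- bh_fdr(summaries$cumulative_p)
  } else {
    fp <- vapply(summaries$peptide_p_values,
                 function(p) cumulative_p(p, method = "fisher"), numeric(1))
    summaries$cumulative_p <- fp
    summaries$log10_cumulative_p <- log10(fp)
    summaries$q_value <- bh_fdr(fp)
  }
  attr(summaries, "n_no_symbol") <- n_no_symbol
  attr(summaries, "rollup_correlations") <- rollup
  summaries
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Filtering cascade:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-18s %10d\n", x$stage[i], x$count[i]))
  invisible(x)
}

#' @export
print.cascade_result <- function(x, ...) {
  print(x$report)
  cat(x$n_no_symbol,
      "correlation(s) without a gene symbol excluded from rollup\n")
  invisible(x)
}

.as_psm_df <- function(dt, template) {
  out <- data.table::setDF(dt[, names(template), with = FALSE])
  rownames(out) <- NULL
  out
}
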