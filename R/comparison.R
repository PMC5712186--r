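# Room-temperature versus ice comparison: normalized RT/ICE correlation
# ratios, the fivefold degradation filter, contaminant catalogues, and the
# cross-algorithm consensus rule.

#' Contaminant catalogue
#'
#' Three named gene-symbol sets of known spurious identifications:
#' `random_miscorrelation` (giant proteins hit by random spectra),
#' `source_noise` (correlations from blank-gradient runs), and `dust`
#' (laboratory dust digests: keratins, POTE family, actins, mucins).
#' Keratins are matched by the `KRT` prefix in [flag_contaminants()].
#'
#' @param random_miscorrelation,source_noise,dust Character vectors
#'   overriding the default sets.
#' @return A named list of three character vectors, class
#'   `contaminant_catalog`.
#' @export
contaminant_catalog <- function(
    random_miscorrelation = c("TTN", "NEB", "CCDC168", "SYNE1", "OBSCN",
                              "TROPH", "SYNE2", "MACF1", "AHNAK", "DST",
                              "LRP1", "XIRP2", "MUC16", "FSIP2", "LRP1B",
                              "PLEC"),
    source_noise = c("ZNF503", "VWCE", "API5", "TMEM199", "SYT7", "TPSG1",
                     "USP9X", "DACT3", "SUGP2", "CXorf31", "MYO3A", "KLRC4",
                     "CYCS", "RGP1", "SYN1", "DSPP", "IMMP1L", "CAMK1",
                     "ASPM", "AHNAK", "TTN"),
    dust = c("POTEI", "POTEE", "POTEF", "ACTA2", "ACTB", "ACTG2", "GFAP",
             "POTEM", "MUC5AC")) {
  structure(list(random_miscorrelation = random_miscorrelation,
                 source_noise = source_noise,
                 dust = dust),
            class = "contaminant_catalog")
}

#' RT/ICE correlation ratios per gene symbol
#'
#' For every gene symbol observed in either treatment group, computes the
#' normalized ratio of RANK1 correlation counts in room-temperature samples
#' over ice-preserved samples:
#' `((count_rt + pseudocount) / runs_rt) / ((count_ice + pseudocount) /
#' runs_ice)`. Run counts are the number of LC-ESI-MS/MS runs per group in
#' the manifest; normalization by runs can be disabled when the groups are
#' balanced. The pseudocount keeps genes absent from one group (the
#' RT-specific inventory) finite.
#'
#' @param psms RANK1 PSM data.frame (after the cascade).
#' @param manifest Sample manifest assigning each `sample_id` a treatment.
#' @param pseudocount Added to both counts (default 1).
#' @param normalize_by_runs Divide each count by its group's run number
#'   (default TRUE).
#' @return A data.frame with columns `gene_symbol`, `count_rt`, `count_ice`,
#'   `runs_rt`, `runs_ice`, `ratio`, sorted by descending ratio (ties by
#'   gene symbol).
#' @export
treatment_ratio <- function(psms, manifest, pseudocount = 1,
                            normalize_by_runs = TRUE) {
  validate_manifest(psms, manifest)
  runs_rt <- sum(manifest$treatment == "RT")
  runs_ice <- sum(manifest$treatment == "ICE")
  if (runs_rt == 0 || runs_ice == 0)
    stop("both treatment groups must have at least one run in the manifest")
  treat <- manifest$treatment[match(psms$sample_id, manifest$sample_id)]
  dt <- data.table::data.table(gene_symbol = psms$gene_symbol,
                               treatment = treat)
  dt <- dt[gene_symbol != ""]
  cnt <- dt[, .(count_rt = sum(treatment == "RT"),
                count_ice = sum(treatment == "ICE")), by = gene_symbol]
  div_rt <- if (normalize_by_runs) runs_rt else 1
  div_ice <- if (normalize_by_runs) runs_ice else 1
  cnt[, `:=`(runs_rt = runs_rt, runs_ice = runs_ice)]
  out <- data.table::setDF(cnt)
  out$ratio <- ((out$count_rt + pseudocount) / div_rt) /
    ((out$count_ice + pseudocount) / div_ice)
  out <- out[order(-out$ratio, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes enriched at room temperature
#'
#' Gene symbols whose RT/ICE ratio reaches the fold threshold (boundary
#' inclusive), sorted by descending ratio. A fivefold excess with
#' temperature removes false positives common to both conditions (random
#' mis-correlations, noise, dust), which sit near ratio 1.
#'
#' @param ratios Output of [treatment_ratio()].
#' @param fold Fold threshold (default 5).
#' @return Character vector of gene symbols.
#' @export
rt_enriched <- function(ratios, fold = 5) {
  if (fold <= 0) stop("fold must be > 0")
  keep <- ratios$ratio >= fold
  out <- ratios[keep, , drop = FALSE]
  out$gene_symbol[order(-out$ratio, out$gene_symbol)]
}

#' Flag genes on contaminant lists
#'
#' Tags each gene with the contaminant set(s) containing it. Keratins are
#' matched in the dust set by the `KRT` symbol prefix in addition to the
#' literal dust list.
#'
#' @param genes Character vector of gene symbols.
#' @param catalog A [contaminant_catalog()].
#' @return data.frame with `gene_symbol`, one logical column per set, and
#'   `flagged` (TRUE when any set matches).
#' @export
flag_contaminants <- function(genes, catalog = contaminant_catalog()) {
  out <- data.frame(gene_symbol = genes, stringsAsFactors = FALSE)
  out$random_miscorrelation <- genes %in% catalog$random_miscorrelation
  out$source_noise <- genes %in% catalog$source_noise
  out$dust <- genes %in% catalog$dust | startsWith(genes, "KRT")
  out$flagged <- out$random_miscorrelation | out$source_noise | out$dust
  out
}

#' Cross-algorithm consensus filter
#'
#' Keeps gene symbols identified by SEQUEST with at least `k_sequest`
#' peptides that were also detected by X!TANDEM at least `m_xtandem` times.
#'
#' @param sequest_summaries,xtandem_summaries Gene summary data.frames with
#'   `gene_symbol` and `peptide_count`.
#' @param k_sequest Minimum SEQUEST peptide count (default 5).
#' @param m_xtandem Minimum X!TANDEM peptide count (default 1).
#' @return Sorted character vector of gene symbols passing both rules.
#' @export
consensus_filter <- function(sequest_summaries, xtandem_summaries,
                             k_sequest = 5, m_xtandem = 1) {
  seq_n <- setNames(sequest_summaries$peptide_count,
                    sequest_summaries$gene_symbol)
  xt_n <- setNames(xtandem_summaries$peptide_count,
                   xtandem_summaries$gene_symbol)
  genes <- union(names(seq_n), names(xt_n))
  sc <- ifelse(is.na(seq_n[genes]), 0, seq_n[genes])
  xc <- ifelse(is.na(xt_n[genes]), 0, xt_n[genes])
  sort(genes[sc >= k_sequest & xc >= m_xtandem])
}
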