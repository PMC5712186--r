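# Single entry point wiring the stages: filter cascade -> gene-level
# significance -> RT/ICE comparison -> contaminant flagging -> consensus ->
# optional category enrichment, with deterministic, metadata-headed TSV
# outputs.

#' Pipeline configuration
#'
#' Thresholds and method flags for [run_pipeline()], echoed verbatim into
#' every output file header together with a checksum.
#'
#' @param min_intensity Precursor intensity threshold (counts, default 1000).
#' @param min_peptides Minimum correlations per accession (default 5).
#' @param fold RT/ICE fold threshold (default 5).
#' @param fdr Gene-level FDR threshold for the significant list (default
#'   0.01).
#' @param cumulative_method `"product"` or `"fisher"`.
#' @param pseudocount Ratio pseudocount (default 1).
#' @param normalize_by_runs Normalize ratio counts by run numbers.
#' @param strict_intensity Strict `>` intensity comparison.
#' @param count_mode Counting mode of the minimum-count filter.
#' @param consensus_before_fold Apply the cross-algorithm consensus before
#'   the fold filter (default TRUE).
#' @param seed Seed recorded in output metadata.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_intensity = 1000, min_peptides = 5,
                            fold = 5, fdr = 0.01,
                            cumulative_method = c("product", "fisher"),
                            pseudocount = 1, normalize_by_runs = TRUE,
                            strict_intensity = FALSE,
                            count_mode = c("correlations", "sequences"),
                            consensus_before_fold = TRUE,
                            seed = 1L) {
  if (min_intensity < 0 || min_peptides < 1 || fold <= 0 || fdr <= 0)
    stop("thresholds must be positive")
  structure(list(min_intensity = min_intensity,
                 min_peptides = min_peptides, fold = fold, fdr = fdr,
                 cumulative_method = match.arg(cumulative_method),
                 pseudocount = pseudocount,
                 normalize_by_runs = normalize_by_runs,
                 strict_intensity = strict_intensity,
                 count_mode = match.arg(count_mode),
                 consensus_before_fold = consensus_before_fold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic polynomial checksum of the serialized config (not a
# cryptographic hash; there is no sha dependency)
config_checksum <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(js)))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Applies the filtering cascade to the X!TANDEM table (and, when given,
#' the SEQUEST table), computes gene-level q-values, the RT/ICE ratios and
#' the fold-enriched gene list with contaminant flags, the cross-algorithm
#' consensus, and optional category enrichment, writing every artifact as a
#' TSV whose header records the package version, configuration (verbatim),
#' checksum and seed. Outputs are deterministic: rerunning with the same
#' inputs and configuration reproduces the files byte for byte.
#'
#' @param xtandem X!TANDEM PSM data.frame (or TSV path).
#' @param manifest Sample manifest data.frame (or TSV path).
#' @param sequest Optional SEQUEST PSM data.frame (or TSV path).
#' @param library Optional `protein_library` (or FASTA path).
#' @param annotation Optional [annotation_table()] for enrichment.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite existing outputs (default FALSE: existing files
#'   are an error).
#' @return Invisibly, a list with `cascade` (the `cascade_result`),
#'   `summaries`, `significant` (genes at the FDR threshold), `ratios`,
#'   `enriched` (contaminant-annotated fold-passing genes), `consensus`,
#'   `enrichment`, and `files` (paths written).
#' @export
run_pipeline <- function(xtandem, manifest, sequest = NULL, library = NULL,
                         annotation = NULL, config = pipeline_config(),
                         out_dir, force = FALSE) {
  t0 <- Sys.time()
  if (is.character(xtandem)) xtandem <- read_psm_table(xtandem)
  if (is.character(manifest)) manifest <- read_sample_manifest(manifest)
  if (is.character(sequest)) sequest <- read_psm_table(sequest)
  if (is.character(library)) library <- read_fasta_library(library)
  validate_manifest(xtandem, manifest)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, c(
    cascade = "cascade_report.tsv", summaries = "gene_summaries.tsv",
    significant = "significant_genes.tsv", ratios = "ratios.tsv",
    enriched = "rt_enriched_genes.tsv", consensus = "consensus_genes.tsv",
    enrichment = "enrichment.tsv"))
  names(files) <- c("cascade", "summaries", "significant", "ratios",
                    "enriched", "consensus", "enrichment")
  existing <- files[file.exists(files)]
  if (length(existing) > 0 && !force)
    stop("output file(s) exist (use force = TRUE): ",
         paste(basename(existing), collapse = ", "))
  hdr <- c(paste0("degradomeR ", as.character(utils::packageVersion("degradomeR"))),
           paste0("config: ", jsonlite::toJSON(unclass(config),
                                               auto_unbox = TRUE,
                                               digits = NA)),
           paste0("config_checksum: ", config_checksum(config)),
           paste0("seed: ", config$seed))

  .stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.2fs", name,
                    as.numeric(difftime(Sys.time(), t, units = "secs"))))
    res
  }

  casc <- .stage("cascade", run_cascade(
    xtandem, min_intensity = config$min_intensity,
    min_peptides = config$min_peptides,
    strict_intensity = config$strict_intensity,
    count_mode = config$count_mode,
    cumulative_method = config$cumulative_method, library = library))
  .write_tsv(casc$report, files[["cascade"]], hdr)
  write_gene_summaries(casc$summaries, files[["summaries"]],
                       header_lines = hdr)

  significant <- casc$summaries[casc$summaries$q_value <= config$fdr, ,
                                drop = FALSE]
  write_gene_summaries(significant, files[["significant"]],
                       header_lines = hdr)

  sq_casc <- NULL
  consensus <- NULL
  if (!is.null(sequest)) {
    sq_casc <- .stage("cascade_sequest", run_cascade(
      sequest, min_intensity = config$min_intensity,
      min_peptides = config$min_peptides,
      strict_intensity = config$strict_intensity,
      count_mode = config$count_mode,
      cumulative_method = config$cumulative_method, library = library))
    consensus <- .stage("consensus", consensus_filter(
      sq_casc$summaries, casc$summaries,
      k_sequest = config$min_peptides, m_xtandem = 1))
    .write_tsv(data.frame(gene_symbol = consensus), files[["consensus"]],
               hdr)
  }

  # ratios on the RANK1 correlations of the more sensitive algorithm when
  # both are present (with consensus restriction), X!TANDEM alone otherwise
  ratio_psms <- if (!is.null(sq_casc)) sq_casc$rank1 else casc$rank1
  ratios <- .stage("ratio", treatment_ratio(
    ratio_psms, manifest, pseudocount = config$pseudocount,
    normalize_by_runs = config$normalize_by_runs))
  if (!is.null(consensus) && config$consensus_before_fold)
    ratios <- ratios[ratios$gene_symbol %in% consensus, , drop = FALSE]
  .write_tsv(.fmt_num(ratios, "ratio"), files[["ratios"]], hdr)

  enriched_genes <- rt_enriched(ratios, fold = config$fold)
  if (!is.null(consensus) && !config$consensus_before_fold)
    enriched_genes <- enriched_genes[enriched_genes %in% consensus]
  enriched <- flag_contaminants(enriched_genes)
  .write_tsv(enriched, files[["enriched"]], hdr)

  enr <- NULL
  enrichable <- if (is.null(annotation)) character(0)
                else intersect(enriched_genes, annotation$background)
  if (length(enrichable) > 0) {
    enr <- .stage("enrichment", enrich(enrichable, annotation))
    .write_tsv(.fmt_num(enr, c("p_value", "p_fdr", "p_bonferroni")),
               files[["enrichment"]], hdr)
  }

  message(sprintf("pipeline done in %.2fs",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(cascade = casc, summaries = casc$summaries,
                 significant = significant, ratios = ratios,
                 enriched = enriched, consensus = consensus,
                 sequest_cascade = sq_casc, enrichment = enr,
                 files = files[file.exists(files)]))
}

.fmt_num <- function(df, cols) {
  for (col in intersect(cols, names(df)))
    df[[col]] <- sprintf("%.6g", df[[col]])
  df
}

.write_tsv <- function(df, path, header_lines) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
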