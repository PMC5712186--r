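# Seeded generator for protein libraries, PSM tables and null tables with
# the statistical structure the analysis assumes: isoform redundancy inside
# gene symbols, fully tryptic peptides with missed cleavages, a true/false
# p-value mixture, log-normal intensities, a truncated-Gaussian delta mass,
# an ICE/RT design with gene-specific degradation folds, and contaminant
# injection shared equally by both treatments. Ground truth is exported
# row-for-row.

#' Simulation design
#'
#' All tunable parameters of the generator, with the study's design as
#' defaults: 82 ice-preserved and 88 room-temperature LC-ESI-MS/MS runs,
#' roughly 3,400 spectra per run, 74% gene-symbol coverage of the library,
#' a Beta(0.05, 1) law for true-PSM p-values against Uniform(0,1) for
#' mis-correlations, and a Normal(0, 0.4) delta mass truncated to +/- 2 Da.
#' The seed is mandatory; every source of randomness flows from it.
#'
#' @param seed Integer seed (mandatory, < 2^31 - 10).
#' @param n_genes Number of simulated genes (excluding contaminants).
#' @param isoforms_per_gene Integer range `c(min, max)`; isoform count per
#'   gene is uniform on it.
#' @param protein_length_meanlog,protein_length_sdlog Log-normal law of
#'   protein length (aa).
#' @param n_ice_runs,n_rt_runs Runs per treatment group (defaults 82 / 88).
#' @param psms_per_run Expected spectra per ICE run (room-temperature runs
#'   exceed it through the degradation folds).
#' @param abundance_sdlog Spread (sdlog) of the per-gene log-normal
#'   abundance law.
#' @param degraded_gene_fraction Fraction of genes degraded at room
#'   temperature.
#' @param fold_log10_range Degradation folds are `10^Uniform(range)`
#'   (default 5x to 100x, i.e. up to two orders of magnitude).
#' @param true_p_alpha Alpha of the Beta(alpha, 1) true-PSM p-value law.
#' @param psm_false_rate Fraction of spectra mis-correlated to a random
#'   peptide with a Uniform(0,1) p-value.
#' @param intensity_meanlog Named vector `c(ICE=, RT=)` of log-intensity
#'   means.
#' @param intensity_sdlog Log-intensity spread.
#' @param delta_mass_sd,delta_mass_limit Gaussian delta-mass sd and
#'   truncation limit (Da).
#' @param contaminant_rate Fraction of the per-run spectrum budget injected
#'   as contaminant correlations, split equally across `contaminant_genes`
#'   and across treatments.
#' @param contaminant_genes Gene symbols injected as contaminants; symbols
#'   known as giant proteins receive long sequences.
#' @param shared_peptide_fraction Fraction of tryptic fragments each extra
#'   isoform shares with its gene's base sequence (>= 0.5 keeps isoforms
#'   collapsible).
#' @param symbol_coverage Probability that a gene's accessions carry a
#'   defined gene symbol (default 0.74).
#' @param charge_probs Named probabilities for 2+ and 3+ precursors.
#' @param competing_charge_rate,competing_peptide_rate Rates at which a
#'   spectrum additionally carries a worse-scoring candidate at the other
#'   charge state / for another peptide (exercises the dedup stages).
#' @param phospho_rate Probability that an S/T/Y-containing peptide carries
#'   a phospho modification.
#' @param max_missed Maximum missed cleavages in the digest (default 3).
#' @param algorithm_overlap Fraction of spectra also reported by the second
#'   search algorithm.
#' @param sequest_giant_bias Rate of extra SEQUEST-only mis-correlations to
#'   the giant contaminant proteins.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(seed,
                              n_genes = 500,
                              isoforms_per_gene = c(1L, 3L),
                              protein_length_meanlog = log(400),
                              protein_length_sdlog = 0.5,
                              n_ice_runs = 82L,
                              n_rt_runs = 88L,
                              psms_per_run = 3400,
                              abundance_sdlog = 1.0,
                              degraded_gene_fraction = 0.2,
                              fold_log10_range = c(0.7, 2),
                              true_p_alpha = 0.05,
                              psm_false_rate = 0.05,
                              intensity_meanlog = c(ICE = 9.2, RT = 9.6),
                              intensity_sdlog = 1.0,
                              delta_mass_sd = 0.4,
                              delta_mass_limit = 2,
                              contaminant_rate = 0.05,
                              contaminant_genes = c("TTN", "NEB", "AHNAK",
                                                    "KRT1", "KRT10", "ACTB",
                                                    "POTEE", "MUC5AC"),
                              shared_peptide_fraction = 0.7,
                              symbol_coverage = 0.74,
                              charge_probs = c(`2` = 0.6, `3` = 0.4),
                              competing_charge_rate = 0.10,
                              competing_peptide_rate = 0.10,
                              phospho_rate = 0.05,
                              max_missed = 3L,
                              algorithm_overlap = 0.8,
                              sequest_giant_bias = 0.02) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || seed >= 2^31 - 10) stop("seed must be an integer < 2^31 - 10")
  probs <- c(degraded_gene_fraction, psm_false_rate, contaminant_rate,
             symbol_coverage, shared_peptide_fraction, competing_charge_rate,
             competing_peptide_rate, phospho_rate, algorithm_overlap)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  design <- list(seed = seed, n_genes = n_genes,
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 protein_length_meanlog = protein_length_meanlog,
                 protein_length_sdlog = protein_length_sdlog,
                 n_ice_runs = as.integer(n_ice_runs),
                 n_rt_runs = as.integer(n_rt_runs),
                 psms_per_run = psms_per_run,
                 abundance_sdlog = abundance_sdlog,
                 degraded_gene_fraction = degraded_gene_fraction,
                 fold_log10_range = fold_log10_range,
                 true_p_alpha = true_p_alpha,
                 psm_false_rate = psm_false_rate,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 delta_mass_sd = delta_mass_sd,
                 delta_mass_limit = delta_mass_limit,
                 contaminant_rate = contaminant_rate,
                 contaminant_genes = contaminant_genes,
                 shared_peptide_fraction = shared_peptide_fraction,
                 symbol_coverage = symbol_coverage,
                 charge_probs = charge_probs,
                 competing_charge_rate = competing_charge_rate,
                 competing_peptide_rate = competing_peptide_rate,
                 phospho_rate = phospho_rate,
                 max_missed = as.integer(max_missed),
                 algorithm_overlap = algorithm_overlap,
                 sequest_giant_bias = sequest_giant_bias)
  class(design) <- "simulation_design"
  design
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Simulation design (seed ", x$seed, "): ", x$n_genes, " genes, ",
      x$n_ice_runs, " ICE + ", x$n_rt_runs, " RT runs, ~", x$psms_per_run,
      " spectra/run\n", sep = "")
  cat(sprintf("  %.0f%% of genes degraded at RT (fold 10^U(%.2g, %.2g))\n",
              100 * x$degraded_gene_fraction, x$fold_log10_range[1],
              x$fold_log10_range[2]))
  invisible(x)
}

#' Serialize / restore a simulation design
#'
#' The design is written as JSON next to every generated output so that a
#' simulated data set is fully reproducible from its seed.
#'
#' @param design A `simulation_design`.
#' @param path Output (input) path.
#' @return `path` (for write) or the restored design (for read).
#' @export
write_design <- function(design, path) {
  d <- unclass(design)
  # named numeric vectors must serialize as JSON objects, not arrays
  d$intensity_meanlog <- as.list(d$intensity_meanlog)
  d$charge_probs <- as.list(d$charge_probs)
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$intensity_meanlog <- unlist(raw$intensity_meanlog)
  raw$charge_probs <- unlist(raw$charge_probs)
  do.call(simulation_design, raw)
}

# residue sampling weights: K/R at ~5.5% each gives tryptic peptides of
# realistic mean length; mild proline presence exercises the KP/RP rule
.AA_FREQ <- local({
  f <- setNames(rep(1, 20), .AMINO_ACIDS)
  f[c("K", "R")] <- 1.2
  f["P"] <- 1.0
  f / sum(f)
})

.GIANT_LENGTHS <- c(TTN = 6000, NEB = 3000, SYNE1 = 2500, OBSCN = 2000,
                    AHNAK = 1800, MACF1 = 1600, MUC16 = 1500, PLEC = 1400)

.random_protein <- function(len) {
  paste(sample(.AMINO_ACIDS, len, replace = TRUE, prob = .AA_FREQ),
        collapse = "")
}

# 0-missed-cleavage tryptic fragments of a sequence
.tryptic_fragments <- function(sequence, proline_rule = TRUE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  b <- .cleavage_boundaries(aa, proline_rule)
  substring(sequence, b[-length(b)] + 1L, b[-1L])
}

.cleavage_boundaries <- function(aa, proline_rule = TRUE) {
  n <- length(aa)
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n]
  if (proline_rule && length(sites) > 0)
    sites <- sites[aa[sites + 1L] != "P"]
  c(0L, sites, n)
}

#' Generate a redundant synthetic protein library
#'
#' Builds a library whose accessions group into gene symbols with isoform
#' redundancy: each extra isoform of a gene shares a prefix of the base
#' sequence's tryptic fragments (so isoforms share peptides by
#' construction) and diverges in the remainder. A configurable fraction of
#' genes carries no defined gene symbol, mirroring incomplete symbol
#' annotation in federated libraries. Contaminant genes are appended with a
#' single accession each; known giant proteins get long sequences so that
#' random-assignment nulls accumulate hits on them.
#'
#' @param design A [simulation_design()].
#' @return A `protein_library` with an extra `gene_id` column (internal
#'   gene identity that survives empty symbols).
#' @export
make_library <- function(design) {
  set.seed(design$seed)
  n <- design$n_genes
  has_symbol <- runif(n) < design$symbol_coverage
  gene_id <- sprintf("g%04d", seq_len(n))
  gene_symbol <- ifelse(has_symbol, sprintf("GENE%04d", seq_len(n)), "")
  iso_vals <- design$isoforms_per_gene[1]:design$isoforms_per_gene[2]
  n_iso <- iso_vals[sample.int(length(iso_vals), n, replace = TRUE)]
  lens <- pmax(60L, round(rlnorm(n, design$protein_length_meanlog,
                                 design$protein_length_sdlog)))
  acc <- character(0); sym <- character(0); gid <- character(0)
  seqs <- character(0)
  for (i in seq_len(n)) {
    base <- .random_protein(lens[i])
    frags <- .tryptic_fragments(base)
    iso_seqs <- base
    if (n_iso[i] > 1) {
      n_keep <- max(1L, ceiling(design$shared_peptide_fraction *
                                  length(frags)))
      shared <- paste(frags[seq_len(n_keep)], collapse = "")
      tail_len <- max(20L, lens[i] - nchar(shared))
      for (k in 2:n_iso[i])
        iso_seqs <- c(iso_seqs, paste0(shared, .random_protein(tail_len)))
    }
    acc <- c(acc, sprintf("SYN%04d.%d", i, seq_len(n_iso[i])))
    sym <- c(sym, rep(gene_symbol[i], n_iso[i]))
    gid <- c(gid, rep(gene_id[i], n_iso[i]))
    seqs <- c(seqs, iso_seqs)
  }
  for (cg in design$contaminant_genes) {
    len <- if (cg %in% names(.GIANT_LENGTHS)) .GIANT_LENGTHS[[cg]]
           else pmax(60L, round(rlnorm(1, design$protein_length_meanlog,
                                       design$protein_length_sdlog)))
    acc <- c(acc, paste0(cg, ".1"))
    sym <- c(sym, cg)
    gid <- c(gid, cg)
    seqs <- c(seqs, .random_protein(len))
  }
  protein_library(acc, sym, seqs, gene_id = gid)
}

#' In-silico tryptic digest
#'
#' Enumerates, for every accession, all fully tryptic peptides with 0 to
#' `max_missed` missed cleavages, with flanking residues (`'-'` at protein
#' termini). Cleavage is C-terminal to K/R; with the proline rule, KP/RP
#' junctions are not cut.
#'
#' @param library A `protein_library`.
#' @param max_missed Maximum missed cleavages (default 3).
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @param min_length Minimum peptide length to report (default 1).
#' @return data.frame: `accession`, `gene_symbol`, `peptide`, `prev_aa`,
#'   `next_aa`, `missed_cleavages`, `start`, `end`.
#' @export
in_silico_digest <- function(library, max_missed = 3, proline_rule = TRUE,
                             min_length = 1) {
  if (max_missed < 0) stop("max_missed must be >= 0")
  per_acc <- lapply(seq_len(nrow(library)), function(i) {
    sq <- library$sequence[i]
    aa <- strsplit(sq, "", fixed = TRUE)[[1]]
    n <- length(aa)
    b <- .cleavage_boundaries(aa, proline_rule)
    f <- length(b) - 1L
    starts <- integer(0); ends <- integer(0); missed <- integer(0)
    for (m in 0:min(max_missed, f - 1L)) {
      idx <- seq_len(f - m)
      starts <- c(starts, b[idx] + 1L)
      ends <- c(ends, b[idx + m + 1L])
      missed <- c(missed, rep(m, f - m))
    }
    keep <- (ends - starts + 1L) >= min_length
    starts <- starts[keep]; ends <- ends[keep]; missed <- missed[keep]
    data.table::data.table(
      accession = library$accession[i],
      gene_symbol = library$gene_symbol[i],
      peptide = substring(sq, starts, ends),
      prev_aa = ifelse(starts == 1L, "-", aa[pmax(starts - 1L, 1L)]),
      next_aa = ifelse(ends == n, "-", aa[pmin(ends + 1L, n)]),
      missed_cleavages = missed,
      start = starts, end = ends
    )
  })
  out <- data.table::setDF(data.table::rbindlist(per_acc))
  rownames(out) <- NULL
  out
}

.truncnorm <- function(n, sd, limit) {
  d <- rnorm(n, 0, sd)
  while (any(abs(d) > limit))
    d[abs(d) > limit] <- rnorm(sum(abs(d) > limit), 0, sd)
  d
}

.gene_key <- function(library) {
  if ("gene_id" %in% names(library)) library$gene_id
  else ifelse(library$gene_symbol != "", library$gene_symbol,
              library$accession)
}

#' Simulate paired X!TANDEM / SEQUEST PSM tables with ground truth
#'
#' Draws per-gene, per-treatment correlation counts from Poisson laws whose
#' room-temperature rates are multiplied by gene-specific degradation
#' folds; assigns each spectrum a tryptic peptide of its gene (or a random
#' peptide for mis-correlations), a 2+/3+ charge, a p-value from the
#' true/false mixture, a log-normal intensity, and a precursor m/z
#' reconstructed from the theoretical mass plus a truncated-Gaussian delta.
#' Peptides shared by several accessions emit one row per accession
#' (redundancy for the cascade to collapse), a fraction of spectra carry
#' worse-scoring competing candidates at the other charge or another
#' peptide, and contaminant genes are injected at equal per-run rates in
#' both treatments. The SEQUEST table shares a configurable fraction of
#' spectra with re-drawn scores plus extra mis-correlations to the giant
#' contaminants.
#'
#' @param library A library from [make_library()].
#' @param design The [simulation_design()] used for the library.
#' @return An object of class `synthetic_psm_data`: list with `xtandem` and
#'   `sequest` PSM data.frames, `manifest`, `truth` (list: `genes` with
#'   degraded flag, fold, rates, expected ICE count; `spectra` with
#'   per-spectrum true/false and contaminant labels), and `design`.
#' @export
simulate_psm_tables <- function(library, design) {
  set.seed(design$seed + 1L)
  mass_tab <- residue_mass_table()
  digest <- data.table::as.data.table(
    in_silico_digest(library, design$max_missed, min_length = 6))
  gene_of_acc <- setNames(.gene_key(library), library$accession)
  digest[, gene_id := gene_of_acc[accession]]
  gene_peps <- unique(digest[, .(gene_id, peptide)])
  pep_acc <- unique(digest, by = c("peptide", "accession"))[
    , .(peptide, accession, gene_symbol, prev_aa, next_aa)]

  manifest <- .make_manifest(design)

  genes <- data.table::data.table(
    gene_id = intersect(unique(gene_of_acc), unique(gene_peps$gene_id)))
  sym_of_gene <- library$gene_symbol[match(genes$gene_id, .gene_key(library))]
  genes[, gene_symbol := sym_of_gene]
  genes[, contaminant := gene_symbol %in% design$contaminant_genes]
  n_real <- sum(!genes$contaminant)
  n_cont <- sum(genes$contaminant)
  alpha <- rlnorm(n_real, 0, design$abundance_sdlog)
  w <- numeric(nrow(genes))
  w[!genes$contaminant] <- design$psms_per_run *
    (1 - design$contaminant_rate) * alpha / sum(alpha)
  if (n_cont > 0)
    w[genes$contaminant] <- design$psms_per_run * design$contaminant_rate /
      n_cont
  genes[, rate_per_run := w]
  genes[, degraded := !contaminant &
          runif(.N) < design$degraded_gene_fraction]
  genes[, fold := ifelse(degraded,
                         10^runif(.N, design$fold_log10_range[1],
                                  design$fold_log10_range[2]), 1)]
  genes[, expected_ice := design$n_ice_runs * rate_per_run]
  genes[, expected_rt := design$n_rt_runs * rate_per_run * fold]
  count_ice <- rpois(nrow(genes), genes$expected_ice)
  count_rt <- rpois(nrow(genes), genes$expected_rt)

  spec <- data.table::data.table(
    gene_id = c(rep(genes$gene_id, count_ice),
                rep(genes$gene_id, count_rt)),
    treatment = c(rep("ICE", sum(count_ice)), rep("RT", sum(count_rt)))
  )
  if (nrow(spec) == 0) stop("design produced zero spectra")
  spec[, contaminant := gene_id %in% genes$gene_id[genes$contaminant]]
  ice_runs <- manifest$sample_id[manifest$treatment == "ICE"]
  rt_runs <- manifest$sample_id[manifest$treatment == "RT"]
  spec[treatment == "ICE",
       sample_id := sample(ice_runs, .N, replace = TRUE)]
  spec[treatment == "RT",
       sample_id := sample(rt_runs, .N, replace = TRUE)]
  spec[, time_h := manifest$time_h[match(sample_id, manifest$sample_id)]]
  spec[, is_false := !contaminant & runif(.N) < design$psm_false_rate]

  # peptide assignment: uniform over the gene's peptide universe for true
  # spectra, uniform over the whole universe for mis-correlations
  gp_index <- split(seq_len(nrow(gene_peps)), gene_peps$gene_id)
  spec[, pep_row := 0L]
  spec[is_false == FALSE,
       pep_row := {
         rows <- gp_index[[gene_id[1]]]
         rows[sample.int(length(rows), .N, replace = TRUE)]
       }, by = gene_id]
  n_false <- sum(spec$is_false)
  if (n_false > 0)
    spec[is_false == TRUE,
         pep_row := sample.int(nrow(gene_peps), n_false, replace = TRUE)]
  spec[, peptide := gene_peps$peptide[pep_row]]
  spec[, charge := sample(as.integer(names(design$charge_probs)), .N,
                          replace = TRUE, prob = design$charge_probs)]
  spec[, is_true := !is_false & !contaminant]
  spec[, p_value := ifelse(is_true,
                           rbeta(.N, design$true_p_alpha, 1),
                           runif(.N))]
  spec[p_value == 0, p_value := .Machine$double.xmin]
  spec[, intensity := round(rlnorm(
    .N, design$intensity_meanlog[treatment], design$intensity_sdlog))]
  spec[, delta := .truncnorm(.N, design$delta_mass_sd,
                             design$delta_mass_limit)]
  spec[, mod_mass := ifelse(grepl("[STY]", peptide) &
                              runif(.N) < design$phospho_rate,
                            mass_tab$modifications[["phospho"]], 0)]
  upep <- unique(spec$peptide)
  umass <- peptide_mass(upep, table = mass_tab)
  spec[, mass := umass[match(peptide, upep)]]
  spec[, precursor_mz := (mass + mod_mass + delta +
                            charge * mass_tab$proton) / charge]
  data.table::setorder(spec, sample_id, gene_id, peptide)
  spec[, spectrum_id := paste0(sample_id, ".S",
                               formatC(seq_len(.N), width = 6, flag = "0")),
       by = sample_id]

  xt_rows <- .expand_rows(spec, pep_acc, design, mass_tab, "XTANDEM")

  # SEQUEST: overlapping spectra, re-drawn scores, extra giant hits
  keep <- runif(nrow(spec)) < design$algorithm_overlap
  sq_spec <- spec[keep]
  if (nrow(sq_spec) > 0)
    sq_spec[, p_value := pmin(1, pmax(.Machine$double.xmin,
                                      p_value^exp(rnorm(.N, 0, 0.3))))]
  giant_acc <- library$accession[library$gene_symbol %in%
                                   design$contaminant_genes]
  n_extra <- rpois(1, nrow(spec) * design$sequest_giant_bias)
  if (n_extra > 0 && length(giant_acc) > 0) {
    gd <- digest[accession %in% giant_acc]
    pick <- gd[sample.int(nrow(gd), n_extra, replace = TRUE)]
    runs <- manifest$sample_id
    extra <- data.table::data.table(
      gene_id = pick$gene_id, treatment = NA_character_,
      contaminant = TRUE,
      sample_id = sample(runs, n_extra, replace = TRUE),
      is_false = TRUE, pep_row = 0L, peptide = pick$peptide,
      charge = sample(as.integer(names(design$charge_probs)), n_extra,
                      replace = TRUE, prob = design$charge_probs),
      is_true = FALSE, p_value = runif(n_extra)
    )
    extra[, treatment := manifest$treatment[match(sample_id,
                                                  manifest$sample_id)]]
    extra[, time_h := manifest$time_h[match(sample_id,
                                            manifest$sample_id)]]
    extra[, intensity := round(rlnorm(
      .N, design$intensity_meanlog[treatment], design$intensity_sdlog))]
    extra[, delta := .truncnorm(.N, design$delta_mass_sd,
                                design$delta_mass_limit)]
    extra[, mod_mass := 0]
    uem <- peptide_mass(unique(extra$peptide), table = mass_tab)
    extra[, mass := uem[match(peptide, unique(extra$peptide))]]
    extra[, precursor_mz := (mass + mod_mass + delta +
                               charge * mass_tab$proton) / charge]
    extra[, spectrum_id := paste0(sample_id, ".X",
                                  formatC(seq_len(.N), width = 6,
                                          flag = "0"))]
    sq_spec <- data.table::rbindlist(list(sq_spec, extra),
                                     use.names = TRUE, fill = TRUE)
  }
  sq_rows <- .expand_rows(sq_spec, pep_acc, design, mass_tab, "SEQUEST",
                          competing = FALSE)

  truth_genes <- data.table::setDF(genes)
  truth_spec <- data.table::setDF(
    spec[, .(spectrum_id, gene_id, treatment, sample_id, is_true, is_false,
             contaminant)])
  structure(
    list(xtandem = xt_rows, sequest = sq_rows, manifest = manifest,
         truth = list(genes = truth_genes, spectra = truth_spec),
         design = design),
    class = "synthetic_psm_data"
  )
}

#' @export
print.synthetic_psm_data <- function(x, ...) {
  cat("Synthetic PSM data (seed ", x$design$seed, "):\n", sep = "")
  cat("  X!TANDEM rows:", nrow(x$xtandem),
      " SEQUEST rows:", nrow(x$sequest), "\n")
  cat("  runs:", nrow(x$manifest), " genes:", nrow(x$truth$genes),
      " (", sum(x$truth$genes$degraded), "degraded,",
      sum(x$truth$genes$contaminant), "contaminant )\n")
  invisible(x)
}

# expand spectra to correlation rows (one per accession sharing the
# peptide), optionally adding competing charge/peptide candidates
.expand_rows <- function(spec, pep_acc, design, mass_tab, algorithm,
                         competing = TRUE) {
  rows <- pep_acc[spec, on = "peptide", allow.cartesian = TRUE]
  if (competing) {
    n <- nrow(spec)
    alt <- spec[runif(n) < design$competing_charge_rate]
    if (nrow(alt) > 0) {
      alt[, charge := 5L - charge]
      alt[, p_value := p_value + (1 - p_value) * runif(.N)]
      alt[, precursor_mz := (mass + mod_mass + delta +
                               charge * mass_tab$proton) / charge]
      rows <- data.table::rbindlist(
        list(rows, pep_acc[alt, on = "peptide", allow.cartesian = TRUE]),
        use.names = TRUE)
    }
    alt2 <- spec[runif(n) < design$competing_peptide_rate]
    if (nrow(alt2) > 0) {
      alt2[, peptide := pep_acc$peptide[sample.int(nrow(pep_acc), .N,
                                                   replace = TRUE)]]
      alt2[, p_value := p_value + (1 - p_value) * runif(.N)]
      um <- peptide_mass(unique(alt2$peptide), table = mass_tab)
      alt2[, mass := um[match(peptide, unique(alt2$peptide))]]
      alt2[, precursor_mz := (mass + mod_mass + delta +
                                charge * mass_tab$proton) / charge]
      rows <- data.table::rbindlist(
        list(rows, pep_acc[alt2, on = "peptide", allow.cartesian = TRUE]),
        use.names = TRUE)
    }
  }
  rows[, algorithm := algorithm]
  out <- rows[, .(spectrum_id, precursor_mz, charge, intensity, peptide,
                  prev_aa, next_aa, accession, gene_symbol, p_value,
                  algorithm, sample_id, treatment, time_h, mod_mass)]
  data.table::setorder(out, sample_id, spectrum_id, charge, peptide,
                       accession)
  out <- data.table::setDF(out)
  rownames(out) <- NULL
  out
}

.make_manifest <- function(design) {
  ice_ids <- sprintf("ICE%03d", seq_len(design$n_ice_runs))
  rt_ids <- sprintf("RT%03d", seq_len(design$n_rt_runs))
  data.frame(
    sample_id = c(ice_ids, rt_ids),
    treatment = c(rep("ICE", design$n_ice_runs),
                  rep("RT", design$n_rt_runs)),
    time_h = round(runif(design$n_ice_runs + design$n_rt_runs, 0, 72), 1),
    preservation = c(sample(c("ICE", "LN2", "MINUS80"), design$n_ice_runs,
                            replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                     rep("RT", design$n_rt_runs)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a random-assignment null PSM table
#'
#' The null model of the random spectra generator at the assignment level:
#' `n_correlations` correlations land on tryptic peptides drawn uniformly
#' from the digest of the whole library, so each accession's hit
#' probability is proportional to its tryptic-peptide count and giant
#' proteins accumulate the most hits. All p-values are Uniform(0,1).
#'
#' @param library A `protein_library`.
#' @param n_correlations Number of null correlations (>= 1).
#' @param design A [simulation_design()] (supplies seed, intensity and
#'   delta-mass laws, digest depth).
#' @return A PSM data.frame in the standard schema (single pseudo-run
#'   `NULL001`, treatment ICE).
#' @export
simulate_null_table <- function(library, n_correlations, design) {
  if (n_correlations < 1) stop("n_correlations must be >= 1")
  set.seed(design$seed + 2L)
  mass_tab <- residue_mass_table()
  digest <- data.table::as.data.table(
    in_silico_digest(library, design$max_missed, min_length = 6))
  pick <- digest[sample.int(nrow(digest), n_correlations, replace = TRUE)]
  charge <- sample(as.integer(names(design$charge_probs)), n_correlations,
                   replace = TRUE, prob = design$charge_probs)
  delta <- .truncnorm(n_correlations, design$delta_mass_sd,
                      design$delta_mass_limit)
  upep <- unique(pick$peptide)
  um <- peptide_mass(upep, table = mass_tab)
  mass <- um[match(pick$peptide, upep)]
  out <- data.frame(
    spectrum_id = sprintf("NULL001.S%06d", seq_len(n_correlations)),
    precursor_mz = (mass + delta + charge * mass_tab$proton) / charge,
    charge = charge,
    intensity = round(rlnorm(n_correlations,
                             design$intensity_meanlog[["ICE"]],
                             design$intensity_sdlog)),
    peptide = pick$peptide,
    prev_aa = pick$prev_aa,
    next_aa = pick$next_aa,
    accession = pick$accession,
    gene_symbol = pick$gene_symbol,
    p_value = pmax(.Machine$double.xmin, runif(n_correlations)),
    algorithm = "XTANDEM",
    sample_id = "NULL001",
    treatment = "ICE",
    time_h = 0,
    mod_mass = 0,
    stringsAsFactors = FALSE
  )
  out
}

#' Monte-Carlo false-enrichment rate of the fivefold filter
#'
#' Under the generator's own law, the probability that a gene with no
#' degradation effect (fold 1) nevertheless passes the RT/ICE fold filter,
#' estimated by simulating Poisson counts at the given per-run rates. This
#' is the generator's reference rate for judging how often contaminants or
#' stable genes slip through the filter.
#'
#' @param rate_per_run Per-run expected correlation count(s), one per gene.
#' @param n_ice_runs,n_rt_runs Runs per group.
#' @param fold Fold threshold (default 5).
#' @param pseudocount,normalize_by_runs As in [treatment_ratio()].
#' @param nrep Monte-Carlo replicates per gene (default 500).
#' @return The pooled false-enrichment probability.
#' @export
false_enrichment_rate <- function(rate_per_run, n_ice_runs, n_rt_runs,
                                  fold = 5, pseudocount = 1,
                                  normalize_by_runs = TRUE, nrep = 500) {
  rates <- rep(rate_per_run, each = nrep)
  c_ice <- rpois(length(rates), rates * n_ice_runs)
  c_rt <- rpois(length(rates), rates * n_rt_runs)
  div_rt <- if (normalize_by_runs) n_rt_runs else 1
  div_ice <- if (normalize_by_runs) n_ice_runs else 1
  ratio <- ((c_rt + pseudocount) / div_rt) / ((c_ice + pseudocount) / div_ice)
  mean(ratio >= fold)
}
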