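# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately use plain loops and literal argmin/argmax rules so that they
# stay independent of the data.table implementation they check.

psm_rows <- function(spectrum_id, peptide, accession, gene_symbol = "G1",
                     charge = 2L, p_value = 0.01, intensity = 2000,
                     treatment = "ICE", sample_id = NULL, time_h = 0,
                     algorithm = "XTANDEM", prev_aa = "K", next_aa = "-",
                     mod_mass = 0, precursor_mz = NULL) {
  n <- max(length(spectrum_id), length(peptide), length(accession))
  if (is.null(sample_id))
    sample_id <- ifelse(rep(treatment, length.out = n) == "ICE",
                        "ICE001", "RT001")
  df <- data.frame(
    spectrum_id = rep(spectrum_id, length.out = n),
    precursor_mz = 0,
    charge = as.integer(rep(charge, length.out = n)),
    intensity = rep(intensity, length.out = n),
    peptide = rep(peptide, length.out = n),
    prev_aa = rep(prev_aa, length.out = n),
    next_aa = rep(next_aa, length.out = n),
    accession = rep(accession, length.out = n),
    gene_symbol = rep(gene_symbol, length.out = n),
    p_value = rep(p_value, length.out = n),
    algorithm = rep(algorithm, length.out = n),
    sample_id = rep(sample_id, length.out = n),
    treatment = rep(treatment, length.out = n),
    time_h = rep(time_h, length.out = n),
    mod_mass = rep(mod_mass, length.out = n),
    stringsAsFactors = FALSE
  )
  if (is.null(precursor_mz)) {
    m <- peptide_mass(df$peptide, mod_mass = df$mod_mass)
    df$precursor_mz <- (m + df$charge * 1.007276) / df$charge
  } else {
    df$precursor_mz <- rep(precursor_mz, length.out = n)
  }
  df
}

basic_manifest <- function(n_ice = 1, n_rt = 1) {
  data.frame(
    sample_id = c(sprintf("ICE%03d", seq_len(n_ice)),
                  sprintf("RT%03d", seq_len(n_rt))),
    treatment = c(rep("ICE", n_ice), rep("RT", n_rt)),
    time_h = 0,
    preservation = c(rep("ICE", n_ice), rep("RT", n_rt)),
    stringsAsFactors = FALSE
  )
}

# 20-row fixture in which every cascade stage removes a hand-enumerated
# number of correlations (accessions A1/A2/A3 share gene G1; C1 has no
# symbol). Expected counts derived by manual enumeration, cross-checked by
# the brute-force oracle in the tests.
cascade_fixture <- function() {
  rbind(
    psm_rows("SP01", "PEPK", "A1", intensity = 500),
    psm_rows("SP02", "PEPK", "A1", intensity = 999),
    psm_rows("SP03", "AAAK", "A1", charge = 2L, p_value = 0.010),
    psm_rows("SP03", "AAAK", "A1", charge = 3L, p_value = 0.001),
    psm_rows("SP04", "CCCK", "A1", p_value = 0.010),
    psm_rows("SP04", "DDDK", "A1", p_value = 0.005),
    psm_rows("SP05", "EEEK", "A1", p_value = 0.020),
    psm_rows("SP06", "FFFK", "A2", p_value = 0.010),
    psm_rows("SP06", "FFFK", "A3", p_value = 0.010),
    psm_rows("SP07", "GGGK", "A2", p_value = 0.030),
    psm_rows("SP08", "HHHK", "A2", p_value = 0.010),
    psm_rows("SP09", "IIIK", "A2", p_value = 0.020),
    psm_rows("SP10", "LLLK", "A3", p_value = 0.010),
    psm_rows("SP11", "MMMK", "A3", p_value = 0.020),
    psm_rows("SP12", "NNNK", "B1", gene_symbol = "G2", p_value = 0.010),
    psm_rows("SP13", "QQQK", "B1", gene_symbol = "G2", p_value = 0.020),
    psm_rows("SP14", "RRRK", "B1", gene_symbol = "G2", p_value = 0.030),
    psm_rows("SP15", "SSSK", "B1", gene_symbol = "G2", p_value = 0.040),
    psm_rows("SP16", "TTTK", "C1", gene_symbol = "", p_value = 0.010),
    psm_rows("SP17", "VVVK", "A3", p_value = 0.050)
  )
}

cascade_fixture_expected <- c(
  RAW = 20L, INTENSITY_GE_1000 = 18L, BEST_CHARGE = 17L,
  BEST_PEPTIDE = 16L, RANK1_PEPTIDES = 15L, ACCESSION_GE_K = 14L,
  GENE_ROLLUP = 8L, DISTINCT_GENES = 2L
)

# random PSM table with heavy spectrum/charge/peptide/accession collisions
random_psm_table <- function(n, n_spectra = 12, n_peptides = 8, n_acc = 6) {
  spectra <- sprintf("S%02d", seq_len(n_spectra))
  peps <- c("AAAK", "CCCK", "DDDK", "EEEK", "FFFK", "GGGK", "HHHK",
            "IIIK")[seq_len(n_peptides)]
  accs <- sprintf("P%02d", seq_len(n_acc))
  psm_rows(
    spectrum_id = sample(spectra, n, replace = TRUE),
    peptide = sample(peps, n, replace = TRUE),
    accession = sample(accs, n, replace = TRUE),
    gene_symbol = "G1",
    charge = sample(2:3, n, replace = TRUE),
    p_value = round(runif(n), 4),   # rounding provokes ties
    intensity = sample(c(500, 1500, 5000), n, replace = TRUE)
  )
}

# literal per-spectrum argmin oracle for best charge + best peptide; returns
# the set of surviving complex keys
oracle_dedup_keys <- function(df) {
  keys <- character(0)
  for (s in unique(df$spectrum_id)) {
    sub <- df[df$spectrum_id == s, , drop = FALSE]
    charges <- sort(unique(sub$charge))
    best_p <- vapply(charges, function(z) min(sub$p_value[sub$charge == z]),
                     numeric(1))
    zbest <- charges[order(best_p, charges)][1]
    sub <- sub[sub$charge == zbest, , drop = FALSE]
    peps <- sort(unique(sub$peptide))
    pp <- vapply(peps, function(q) min(sub$p_value[sub$peptide == q]),
                 numeric(1))
    pbest <- peps[order(pp, peps)][1]
    sub <- sub[sub$peptide == pbest, , drop = FALSE]
    keys <- c(keys, unique(paste(s, zbest, pbest, sub$accession,
                                 sep = "\r")))
  }
  sort(keys)
}

# full literal cascade oracle: returns stage counts under the same tie rules
oracle_cascade_counts <- function(df, min_intensity = 1000, k = 5) {
  counts <- c(RAW = nrow(df))
  df <- df[df$intensity >= min_intensity, , drop = FALSE]
  counts["INTENSITY_GE_1000"] <- nrow(df)
  keep <- rep(FALSE, nrow(df))
  for (s in unique(df$spectrum_id)) {
    idx <- which(df$spectrum_id == s)
    sub <- df[idx, , drop = FALSE]
    charges <- sort(unique(sub$charge))
    best_p <- vapply(charges, function(z) min(sub$p_value[sub$charge == z]),
                     numeric(1))
    zbest <- charges[order(best_p, charges)][1]
    keep[idx[sub$charge == zbest]] <- TRUE
  }
  df <- df[keep, , drop = FALSE]
  counts["BEST_CHARGE"] <- nrow(df)
  keep_key <- character(0)
  for (s in unique(df$spectrum_id)) {
    sub <- df[df$spectrum_id == s, , drop = FALSE]
    peps <- sort(unique(sub$peptide))
    pp <- vapply(peps, function(q) min(sub$p_value[sub$peptide == q]),
                 numeric(1))
    pbest <- peps[order(pp, peps)][1]
    sub <- sub[sub$peptide == pbest, , drop = FALSE]
    keep_key <- c(keep_key, unique(paste(s, sub$charge, pbest,
                                         sub$accession, sep = "\r")))
  }
  key <- paste(df$spectrum_id, df$charge, df$peptide, df$accession,
               sep = "\r")
  df <- df[!duplicated(key) & key %in% keep_key, , drop = FALSE]
  counts["BEST_PEPTIDE"] <- nrow(df)
  acc_n <- table(df$accession)
  pick <- rep(FALSE, nrow(df))
  for (s in unique(df$spectrum_id)) {
    idx <- which(df$spectrum_id == s)
    accs <- df$accession[idx]
    n_acc <- as.numeric(acc_n[accs])
    best <- idx[order(-n_acc, accs)][1]
    pick[best] <- TRUE
  }
  df <- df[pick, , drop = FALSE]
  counts["RANK1_PEPTIDES"] <- nrow(df)
  acc_n <- table(df$accession)
  df <- df[as.numeric(acc_n[df$accession]) >= k, , drop = FALSE]
  counts["ACCESSION_GE_K"] <- nrow(df)
  dfg <- df[df$gene_symbol != "", , drop = FALSE]
  roll <- 0L; genes <- character(0)
  for (g in unique(dfg$gene_symbol)) {
    sub <- dfg[dfg$gene_symbol == g, , drop = FALSE]
    an <- table(sub$accession)
    accs <- sort(names(an))
    rep_acc <- accs[order(-as.numeric(an[accs]), accs)][1]
    roll <- roll + sum(sub$accession == rep_acc)
    genes <- c(genes, g)
  }
  counts["GENE_ROLLUP"] <- roll
  counts["DISTINCT_GENES"] <- length(genes)
  counts
}

# independent step-up BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  if (n > 1)
    for (i in (n - 1):1)
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}
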