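small_design <- function(seed = 7, ...) {
  simulation_design(seed = seed, n_genes = 30, psms_per_run = 25,
                    n_ice_runs = 8L, n_rt_runs = 8L, ...)
}

test_that("library construction counts accessions and symbols correctly", {
  d <- simulation_design(seed = 1, n_genes = 10,
                         isoforms_per_gene = c(2L, 2L),
                         contaminant_genes = character(0),
                         symbol_coverage = 1)
  lib <- make_library(d)
  expect_equal(nrow(lib), 20)
  expect_equal(length(unique(lib$gene_symbol)), 10)
  expect_equal(attr(lib, "symbol_fraction"), 1.0)
  # contaminants appended as single accessions with defined symbols
  d2 <- simulation_design(seed = 1, n_genes = 5,
                          isoforms_per_gene = c(1L, 1L),
                          contaminant_genes = c("TTN", "ACTB"))
  lib2 <- make_library(d2)
  expect_true(all(c("TTN.1", "ACTB.1") %in% lib2$accession))
  expect_gt(nchar(lib2$sequence[lib2$accession == "TTN.1"]), 5000)
})

test_that("the same seed reproduces a byte-identical FASTA", {
  d <- small_design()
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_library_fasta(make_library(d), f1)
  write_library_fasta(make_library(d), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene-symbol coverage concentrates near its design value", {
  d <- simulation_design(seed = 5, n_genes = 500,
                         isoforms_per_gene = c(1L, 1L),
                         contaminant_genes = character(0))
  lib <- make_library(d)
  expect_gt(attr(lib, "symbol_fraction"), 0.69)
  expect_lt(attr(lib, "symbol_fraction"), 0.79)
})

test_that("isoforms of a gene share tryptic peptides by construction", {
  d <- simulation_design(seed = 9, n_genes = 10,
                         isoforms_per_gene = c(2L, 2L),
                         contaminant_genes = character(0),
                         symbol_coverage = 1)
  lib <- make_library(d)
  dig <- in_silico_digest(lib, max_missed = 0)
  for (g in unique(lib$gene_symbol)) {
    accs <- lib$accession[lib$gene_symbol == g]
    peps <- lapply(accs, function(a) unique(dig$peptide[dig$accession == a]))
    shared <- length(intersect(peps[[1]], peps[[2]]))
    expect_gte(shared / length(peps[[1]]), 0.5)
  }
})

test_that("the digest matches manual cut-site enumeration", {
  lib <- protein_library("P1", "G1", "AAKGGRCC")
  dig <- in_silico_digest(lib, max_missed = 3)
  # cut sites after K3 and R6: fragments AAK | GGR | CC
  expect_setequal(
    dig$peptide[dig$missed_cleavages == 0], c("AAK", "GGR", "CC"))
  expect_setequal(
    dig$peptide[dig$missed_cleavages == 1], c("AAKGGR", "GGRCC"))
  expect_setequal(
    dig$peptide[dig$missed_cleavages == 2], c("AAKGGRCC"))
  expect_equal(nrow(dig), 6)
  # flanks: first fragment starts at the protein N-terminus
  aak <- dig[dig$peptide == "AAK", ]
  expect_equal(aak$prev_aa, "-")
  expect_equal(aak$next_aa, "G")
  # proline rule suppresses a site
  libp <- protein_library("P2", "G2", "AAKPGGR")
  digp <- in_silico_digest(libp, max_missed = 0)
  expect_equal(digp$peptide, "AAKPGGR")
  expect_equal(nrow(in_silico_digest(libp, 0, proline_rule = FALSE)), 2)
  # max_missed 0 on KKKK: four single-lysine peptides
  libk <- protein_library("P3", "G3", "KKKK")
  expect_equal(in_silico_digest(libk, 0)$peptide, rep("K", 4))
})

test_that("every digested peptide is fully tryptic with the declared misses", {
  d <- small_design()
  lib <- make_library(d)
  dig <- in_silico_digest(lib, max_missed = 3)
  st <- tryptic_status(dig$peptide, dig$prev_aa, dig$next_aa)
  expect_true(all(st$is_fully_tryptic))
  expect_equal(st$missed_cleavages, dig$missed_cleavages)
  expect_true(all(dig$missed_cleavages <= 3))
})

test_that("simulated tables are deterministic and structurally valid", {
  d <- small_design()
  lib <- make_library(d)
  s1 <- simulate_psm_tables(lib, d)
  s2 <- simulate_psm_tables(lib, d)
  expect_identical(s1$xtandem, s2$xtandem)
  expect_identical(s1$sequest, s2$sequest)
  expect_identical(s1$truth, s2$truth)
  # structural checks: schema, manifest coverage, truth consistency
  expect_true(all(c("spectrum_id", "peptide", "p_value", "treatment")
                  %in% names(s1$xtandem)))
  expect_true(validate_manifest(s1$xtandem, s1$manifest))
  expect_true(all(s1$xtandem$charge %in% c(2L, 3L)))
  expect_true(all(s1$xtandem$p_value > 0 & s1$xtandem$p_value <= 1))
  expect_setequal(unique(s1$truth$spectra$spectrum_id),
                  unique(s1$xtandem$spectrum_id))
  # precursor masses honour the truncated delta law
  qq <- delta_mass_quantiles(s1$xtandem)
  expect_true(all(abs(qq$delta) <= d$delta_mass_limit + 1e-6))
  expect_equal(qq$fraction_within_2da, 1)
})

test_that("with no degraded genes ICE and RT counts are homogeneous", {
  d <- simulation_design(seed = 17, n_genes = 50, psms_per_run = 625,
                         n_ice_runs = 8L, n_rt_runs = 8L,
                         degraded_gene_fraction = 0,
                         contaminant_genes = character(0),
                         abundance_sdlog = 0.4)
  lib <- make_library(d)
  sim <- simulate_psm_tables(lib, d)
  tr <- sim$truth$spectra
  tab <- table(tr$gene_id, tr$treatment)
  keep <- rowSums(tab) >= 20
  p <- suppressWarnings(chisq.test(tab[keep, ])$p.value)
  expect_gt(p, 0.01)
})

test_that("designed folds are recovered within the sampling envelope", {
  d <- simulation_design(seed = 23, n_genes = 30, psms_per_run = 30,
                         n_ice_runs = 41L, n_rt_runs = 44L,
                         degraded_gene_fraction = 0.4,
                         fold_log10_range = c(1, 1),  # fold 10 exactly
                         abundance_sdlog = 0.3,
                         contaminant_genes = character(0))
  lib <- make_library(d)
  sim <- simulate_psm_tables(lib, d)
  tg <- sim$truth$genes
  tr <- sim$truth$spectra
  for (g in tg$gene_id[tg$degraded & tg$expected_ice >= 20]) {
    n_rt <- sum(tr$gene_id == g & tr$treatment == "RT")
    n_ice <- sum(tr$gene_id == g & tr$treatment == "ICE")
    ratio <- (n_rt / d$n_rt_runs) / (n_ice / d$n_ice_runs)
    expect_gt(ratio, 5)
    expect_lt(ratio, 20)
  }
})

test_that("null tables hit accessions proportionally to digest size", {
  # two proteins whose tryptic peptide counts differ ~10x
  lib <- protein_library(
    c("BIG", "SMALL"), c("GBIG", "GSMALL"),
    c(paste(rep("AAAGGGLLLK", 100), collapse = ""),
      paste(rep("AAAGGGLLLK", 10), collapse = "")))
  d <- simulation_design(seed = 3, n_genes = 2)
  dig <- in_silico_digest(lib, max_missed = 3, min_length = 6)
  p_big <- mean(dig$accession == "BIG")
  nt <- simulate_null_table(lib, 10000, d)
  obs <- mean(nt$accession == "BIG")
  se <- sqrt(p_big * (1 - p_big) / 10000)
  expect_lt(abs(obs - p_big), 4 * se)
  expect_true(all(nt$p_value > 0 & nt$p_value <= 1))
  expect_equal(nrow(simulate_null_table(lib, 1, d)), 1)
})

test_that("designs serialize and restore losslessly", {
  d <- small_design(seed = 99, degraded_gene_fraction = 0.25)
  path <- tempfile(fileext = ".json")
  write_design(d, path)
  back <- read_design(path)
  expect_equal(back, d)
  expect_error(simulation_design(), "mandatory")
  expect_error(simulation_design(seed = 1, psm_false_rate = 2),
               "probabilities")
})
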