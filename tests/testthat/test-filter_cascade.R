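test_that("intensity filter keeps the boundary by default, strict mode drops it", {
  df <- psm_rows(c("S1", "S2", "S3"), "AAAK", "P1",
                 intensity = c(999, 1000, 1001))
  expect_equal(nrow(intensity_filter(df, 1000)), 2)
  expect_equal(nrow(intensity_filter(df, 1000, strict = TRUE)), 1)
  expect_equal(nrow(intensity_filter(df, 0)), 3)
  expect_equal(nrow(intensity_filter(df, 1e6)), 0)
})

test_that("best charge state keeps the argmin charge with low-charge ties", {
  df <- rbind(
    psm_rows("S1", "AAAK", "P1", charge = 2L, p_value = 0.01),
    psm_rows("S1", "AAAK", "P1", charge = 3L, p_value = 0.05),
    psm_rows("S2", "CCCK", "P1", charge = 3L, p_value = 0.02),
    psm_rows("S3", "DDDK", "P1", charge = 2L, p_value = 0.01),
    psm_rows("S3", "DDDK", "P1", charge = 3L, p_value = 0.01)
  )
  got <- best_charge_state(df)
  expect_equal(got$charge[got$spectrum_id == "S1"], 2L)
  expect_equal(got$charge[got$spectrum_id == "S2"], 3L)  # singleton unchanged
  expect_equal(got$charge[got$spectrum_id == "S3"], 2L)  # tie -> lower charge
})

test_that("best peptide keeps the argmin sequence; shared accessions remain", {
  df <- rbind(
    psm_rows("S1", "AAAK", "P1", p_value = 0.001),
    psm_rows("S1", "CCCK", "P1", p_value = 0.010),
    psm_rows("S2", "DDDK", c("P1", "P2", "P3"), p_value = 0.01),
    psm_rows("S3", "EEEK", "P1", p_value = 0.02),
    psm_rows("S3", "AAAK", "P1", p_value = 0.02)
  )
  got <- best_peptide(df)
  expect_equal(got$peptide[got$spectrum_id == "S1"], "AAAK")
  s2 <- got[got$spectrum_id == "S2", ]
  expect_equal(nrow(s2), 3)               # one peptide, three accessions
  expect_equal(unique(s2$peptide), "DDDK")
  # p tie between peptides -> lexicographically smaller sequence
  expect_equal(got$peptide[got$spectrum_id == "S3"], "AAAK")
})

test_that("rank1 collapse assigns shared peptides to the busiest accession", {
  df <- rbind(
    psm_rows(sprintf("A%02d", 1:10), "AAAK", "A1"),
    psm_rows(sprintf("B%02d", 1:3), "CCCK", "A2"),
    psm_rows("SH1", "DDDK", c("A1", "A2"))
  )
  got <- rank1_collapse(df)
  expect_equal(got$accession[got$spectrum_id == "SH1"], "A1")
  expect_equal(nrow(got), 14)
  # unshared spectra untouched
  expect_equal(sort(unique(got$spectrum_id)),
               sort(unique(df$spectrum_id)))
  # equal counts -> lexicographically smaller accession
  tie <- rbind(psm_rows("T1", "EEEK", c("A9", "A2")))
  expect_equal(rank1_collapse(tie)$accession, "A2")
  # unresolved accession warns but keeps the row
  lib <- protein_library("A1", "G1", "MKAAR")
  expect_warning(kept <- rank1_collapse(df, library = lib), "A2")
  expect_equal(nrow(kept), 14)
})

test_that("minimum count filter is boundary-inclusive and mode-aware", {
  df <- rbind(
    psm_rows(sprintf("A%02d", 1:5), c("AAAK", "AAAK", "AAAK", "CCCK", "DDDK"),
             "A1"),
    psm_rows(sprintf("B%02d", 1:4), "EEEK", "A2")
  )
  expect_equal(unique(min_peptide_count_filter(df, 5)$accession), "A1")
  expect_equal(nrow(min_peptide_count_filter(df, 1)), nrow(df))
  # sequence mode: A1 has 3 distinct sequences, A2 has 1
  expect_equal(unique(min_peptide_count_filter(df, 3,
                                               "sequences")$accession), "A1")
})

test_that("gene rollup picks the representative accession and reports the rest", {
  df <- rbind(
    psm_rows(sprintf("A%02d", 1:7), "AAAK", "A1", gene_symbol = "G1"),
    psm_rows(sprintf("B%02d", 1:5), "CCCK", "A2", gene_symbol = "G1"),
    psm_rows(sprintf("C%02d", 1:4), "DDDK", "B1", gene_symbol = "G2"),
    psm_rows("N1", "EEEK", "X1", gene_symbol = "")
  )
  s <- gene_rollup(df)
  expect_equal(s$accession[s$gene_symbol == "G1"], "A1")
  expect_equal(s$peptide_count[s$gene_symbol == "G1"], 7L)
  expect_equal(s$accession[s$gene_symbol == "G2"], "B1")
  expect_equal(attr(s, "n_no_symbol"), 1L)
  expect_equal(attr(s, "rollup_correlations"), 11L)
  # count tie -> lexicographically smaller accession
  tie <- rbind(
    psm_rows(sprintf("A%02d", 1:3), "AAAK", "A9", gene_symbol = "G1"),
    psm_rows(sprintf("B%02d", 1:3), "CCCK", "A2", gene_symbol = "G1")
  )
  expect_equal(gene_rollup(tie)$accession, "A2")
})

test_that("the full cascade matches hand enumeration on the 20-row fixture", {
  fx <- cascade_fixture()
  res <- run_cascade(fx, min_intensity = 1000, min_peptides = 3)
  got <- setNames(res$report$count, res$report$stage)
  expect_equal(got, cascade_fixture_expected)
  expect_equal(sort(res$summaries$gene_symbol), c("G1", "G2"))
  expect_equal(res$summaries$accession[res$summaries$gene_symbol == "G1"],
               "A2")
  # empty input: every stage reports zero survivors
  empty <- run_cascade(fx[0, , drop = FALSE])
  expect_true(all(empty$report$count == 0))
})

test_that("cascade counts are monotone and re-running is a fixed point", {
  set.seed(31)
  for (i in 1:10) {
    df <- random_psm_table(sample(40:150, 1))
    res <- run_cascade(df, min_peptides = 2)
    corr <- res$report$count[1:6]  # correlation-level stages
    expect_true(all(diff(corr) <= 0))
    # idempotence on the surviving rows
    again <- run_cascade(res$rank1, min_intensity = 0, min_peptides = 2)
    expect_equal(nrow(again$rank1), nrow(res$rank1))
    expect_equal(sort(complex_key(again$rank1)),
                 sort(complex_key(res$rank1)))
  }
})

test_that("after best_peptide no spectrum keeps two peptides or charges", {
  set.seed(32)
  for (i in 1:20) {
    df <- random_psm_table(sample(30:200, 1))
    out <- best_peptide(best_charge_state(df))
    per_spec <- split(out, out$spectrum_id)
    expect_true(all(vapply(per_spec,
                           function(s) length(unique(s$peptide)) == 1 &&
                             length(unique(s$charge)) == 1, logical(1))))
    expect_false(any(duplicated(complex_key(out))))
  }
})

test_that("survivor sets equal the exhaustive oracle on random tables", {
  set.seed(33)
  for (i in 1:25) {
    df <- random_psm_table(sample(20:200, 1))
    out <- best_peptide(best_charge_state(df))
    expect_equal(sort(complex_key(out)), oracle_dedup_keys(df))
  }
})

test_that("complex keys identify 4-tuples exactly", {
  df <- psm_rows(c("S1", "S1", "S1"), c("AAAK", "AAAK", "CCCK"),
                 c("P1", "P2", "P1"))
  k <- complex_key(df)
  expect_equal(length(unique(k)), 3)
  expect_identical(complex_key(df[1, ]), complex_key(df[1, ]))
})
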