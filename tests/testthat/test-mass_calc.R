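test_that("peptide mass matches independent residue-table sums", {
  # hand calculation: Gly residue 57.02146 + water 18.010565
  expect_equal(peptide_mass("G"), 75.032025, tolerance = 1e-6)
  tab <- residue_mass_table()
  # AK + phospho is a plain table lookup
  expect_equal(peptide_mass("AK", mod_mass = tab$modifications[["phospho"]]),
               peptide_mass("AK") + 79.96633, tolerance = 1e-9)
  # a handful of peptides against an independent per-residue sum
  set.seed(11)
  for (i in 1:20) {
    pep <- paste(sample(names(tab$residues), sample(1:15, 1),
                        replace = TRUE), collapse = "")
    manual <- sum(tab$residues[strsplit(pep, "")[[1]]]) + tab$water
    expect_equal(peptide_mass(pep), manual, tolerance = 1e-12)
  }
})

test_that("peptide mass is additive over concatenation minus one water", {
  tab <- residue_mass_table()
  expect_equal(peptide_mass("GG") - peptide_mass("G"),
               tab$residues[["G"]], tolerance = 1e-9)
  set.seed(12)
  for (i in 1:25) {
    a <- paste(sample(names(tab$residues), 4, TRUE), collapse = "")
    b <- paste(sample(names(tab$residues), 6, TRUE), collapse = "")
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - tab$water,
                 tolerance = 1e-9)
  }
})

test_that("unknown residues and invalid inputs error informatively", {
  expect_error(peptide_mass("AXG"), "position 2")
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("AK", mod_mass = -1), "mod_mass")
  expect_error(delta_mass(500, 0, 1000), "charge")
  expect_error(tryptic_status("", "K", "A"), "empty")
})

test_that("delta mass follows the neutral-mass formula and round-trips", {
  tab <- residue_mass_table()
  M <- peptide_mass("AAAK")
  mz <- (M + 2 * tab$proton) / 2
  expect_equal(delta_mass(mz, 2, M), 0, tolerance = 1e-9)
  # +0.5 Th at z=2 is +1.0 Da on the neutral mass
  expect_equal(delta_mass(mz + 0.5, 2, M), 1.0, tolerance = 1e-9)
  set.seed(13)
  for (i in 1:50) {
    z <- sample(1:4, 1)
    M <- runif(1, 400, 4000)
    mz <- runif(1, 300, 2000)
    expect_equal(delta_mass(mz, z, M),
                 (mz * z - z * tab$proton) - M, tolerance = 1e-9)
    # round trip: recompute mz from (M, z), delta must vanish
    expect_equal(delta_mass((M + z * tab$proton) / z, z, M), 0,
                 tolerance = 1e-9)
  }
})

test_that("tryptic status handles the stated reference cases", {
  s <- tryptic_status(c("AAAK", "AKAAR", "AAAA"),
                      c("R", "K", "G"), c("G", "A", "G"))
  expect_equal(s$is_fully_tryptic, c(TRUE, TRUE, FALSE))
  expect_equal(s$missed_cleavages, c(0L, 1L, 0L))
  # protein termini count as valid boundaries
  expect_true(tryptic_status("MAAG", "-", "-")$is_fully_tryptic)
  # proline suppresses cleavage on both sides
  expect_false(tryptic_status("PAAK", "K", "A")$is_fully_tryptic)
  expect_false(tryptic_status("AAAK", "R", "P")$is_fully_tryptic)
  expect_true(tryptic_status("AAAK", "R", "P",
                             proline_rule = FALSE)$is_fully_tryptic)
  expect_equal(tryptic_status("AKPAK", "K", "A")$missed_cleavages, 0L)
  expect_equal(tryptic_status("AKPAK", "K", "A",
                              proline_rule = FALSE)$missed_cleavages, 1L)
})

test_that("tryptic status agrees with brute-force cut-site enumeration", {
  # independent oracle: embed the peptide in prev+pep+next and scan cut
  # sites literally
  oracle <- function(pep, prev, nxt, proline) {
    aa <- strsplit(pep, "")[[1]]
    len <- length(aa)
    full <- c(if (prev != "-") prev, aa, if (nxt != "-") nxt)
    s <- if (prev == "-") 1L else 2L
    e <- s + len - 1L
    cut_after <- function(i) {
      full[i] %in% c("K", "R") &&
        (i == length(full) || !proline || full[i + 1] != "P")
    }
    nterm <- prev == "-" || cut_after(s - 1L)
    cterm <- nxt == "-" || cut_after(e)
    missed <- if (len < 2) 0L else sum(vapply(s:(e - 1L), cut_after,
                                              logical(1)))
    list(ft = nterm && cterm, mc = as.integer(missed))
  }
  alphabet <- c("A", "K", "R", "P")
  flanks <- c(alphabet, "-")
  # exhaustive to length 3, random subsample of lengths 4-6
  peptides <- unlist(lapply(1:3, function(len) {
    apply(expand.grid(rep(list(alphabet), len)), 1, paste, collapse = "")
  }))
  set.seed(14)
  peptides <- c(peptides, vapply(1:300, function(i) {
    paste(sample(alphabet, sample(4:6, 1), TRUE), collapse = "")
  }, character(1)))
  for (proline in c(TRUE, FALSE)) {
    grid <- expand.grid(pep = peptides, prev = flanks, nxt = flanks,
                        stringsAsFactors = FALSE)
    got <- tryptic_status(grid$pep, grid$prev, grid$nxt,
                          proline_rule = proline)
    exp_ft <- logical(nrow(grid))
    exp_mc <- integer(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      o <- oracle(grid$pep[i], grid$prev[i], grid$nxt[i], proline)
      exp_ft[i] <- o$ft
      exp_mc[i] <- o$mc
    }
    expect_equal(got$is_fully_tryptic, exp_ft)
    expect_equal(got$missed_cleavages, exp_mc)
  }
})

test_that("average-mass table and overrides are honoured", {
  avg <- residue_mass_table("average")
  expect_gt(peptide_mass("W", table = avg), peptide_mass("W"))
  ov <- tempfile(fileext = ".tsv")
  writeLines("G\t60.0", ov)
  tab <- residue_mass_table(override_file = ov)
  expect_equal(peptide_mass("G", table = tab), 60 + tab$water)
})
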