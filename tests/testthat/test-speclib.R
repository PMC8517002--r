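test_that("theoretical fragment enumeration follows the charge rules", {
  # length-8 peptide at charge 3: b1-b7 and y1-y7 at charges 1 and 2
  th3 <- theoretical_fragment_mzs("ACDEFGHK", 3L)
  expect_equal(nrow(th3), 28L)
  expect_setequal(unique(th3$charge), c(1L, 2L))
  # charge <= 2 precursors only get singly charged fragments
  th2 <- theoretical_fragment_mzs("ACDEFGHK", 2L)
  expect_equal(nrow(th2), 14L)
  expect_equal(unique(th2$charge), 1L)
  # count formula: |charges| * 2 * (L - 1)
  for (L in c(7L, 12L, 20L)) {
    seqs <- paste(rep("A", L - 1L), collapse = "")
    seqs <- paste0(seqs, "K")
    expect_equal(nrow(theoretical_fragment_mzs(seqs, 2L)), 2L * (L - 1L))
    expect_equal(nrow(theoretical_fragment_mzs(seqs, 4L)), 4L * (L - 1L))
  }
})

test_that("fragment masses agree with an independent mass calculation", {
  # b2 of PEPTIDE: P + E residues + proton (frozen from residue tables)
  th <- theoretical_fragment_mzs("PEPTIDE", 2L)
  expect_equal(th$mz[th$annotation == "b2"], 227.1026, tolerance = 1e-6)
  # complementarity: b_i + y_(L-i) singly charged = M + 2 protons
  M <- peptide_neutral_mass("ELVISLIVK")
  th <- theoretical_fragment_mzs("ELVISLIVK", 2L)
  for (i in c(2L, 5L, 8L)) {
    b <- th$mz[th$annotation == paste0("b", i)]
    y <- th$mz[th$annotation == paste0("y", 9L - i)]
    expect_equal(b + y, M + 2 * 1.007276, tolerance = 1e-4)
  }
  # modified residues shift the fragments containing them
  plain <- theoretical_fragment_mzs("PEPTCK", 2L)
  mod <- theoretical_fragment_mzs("PEPTC(UniMod:4)K", 2L)
  expect_equal(mod$mz[mod$annotation == "b5"],
               plain$mz[plain$annotation == "b5"] + 57.021464,
               tolerance = 1e-5)
  expect_equal(mod$mz[mod$annotation == "b3"],
               plain$mz[plain$annotation == "b3"])
})

test_that("unknown residues and modification tags are rejected by name", {
  expect_error(theoretical_fragment_mzs("PEPTBDE", 2L), "B")
  expect_error(parse_modified_sequence("PEP(UniMod:99)K"), "UniMod:99")
})

test_that("deamidation shift equals the NH -> O replacement mass", {
  # element masses: O 15.994915, N 14.003074, H 1.007825
  delta <- 15.994915 - (14.003074 + 1.007825)
  expect_equal(round(delta, 4), 0.9840)
  # the built-in deamidation modification carries that delta
  d <- peptide_neutral_mass("PEPN(UniMod:7)K") - peptide_neutral_mass("PEPNK")
  expect_equal(round(d, 4), 0.9840)
})

test_that("pseudo mass-shift arithmetic matches the printed formula", {
  expect_equal(apply_pseudo_modification_shift(500, 0, 1), 500)
  expect_equal(apply_pseudo_modification_shift(500, 1, 1), 500.0387)
  # N/C cancellation
  expect_equal(apply_pseudo_modification_shift(500, 2, 2), 500.0387)
  expect_error(apply_pseudo_modification_shift(500, -1, 1), "n_mods")
  expect_error(apply_pseudo_modification_shift(500, 1, 0), "ion_charge")
})

test_that("pseudo-shift library moves only deamidation-bearing ions", {
  exp1 <- generate_experiment(
    synth_config(n_precursors = 20L, deamidation_fraction = 0.5, seed = 3L))
  lib <- exp1$library
  shifted <- build_pseudo_mod_library(lib)
  for (i in seq_along(lib$entries)) {
    e <- lib$entries[[i]]; s <- shifted$entries[[i]]
    if (!grepl("UniMod:7", e$modified_sequence)) {
      expect_identical(e$fragments$mz, s$fragments$mz)
      expect_identical(e$precursor_mz, s$precursor_mz)
    } else {
      expect_equal(s$precursor_mz,
                   e$precursor_mz + (1.0227 - 0.9840) / e$precursor_charge,
                   tolerance = 1e-9)
      # fragments spanning the deamidated residue move, others stay
      moved <- abs(s$fragments$mz - e$fragments$mz) > 1e-9
      tk <- parse_modified_sequence(e$modified_sequence)
      pos <- which(tk$n_deamidation == 1L)
      L <- nrow(tk)
      spans <- ifelse(e$fragments$series == "b", e$fragments$index >= pos,
                      e$fragments$index >= L - pos + 1L)
      expect_equal(moved, spans)
    }
  }
})

test_that("transition-list parse/write round-trips and groups fragments", {
  lib <- small_experiment()$library
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, f1)
  lib2 <- parse_library(f1)
  expect_equal(length(lib2), length(lib))
  i <- 5L
  expect_equal(lib2$entries[[i]]$modified_sequence,
               lib$entries[[i]]$modified_sequence)
  expect_equal(lib2$entries[[i]]$fragments$mz, lib$entries[[i]]$fragments$mz)
  # write(parse(f)) reproduces the file byte-for-byte
  write_library(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("library parsing errors name the problem", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_library(small_experiment()$library, f)
  df <- read.delim(f, check.names = FALSE)
  f_bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[, setdiff(names(df), "ProductMz")], f_bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(parse_library(f_bad), "ProductMz")
  f_empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(df), collapse = "\t"), f_empty)
  expect_error(parse_library(f_empty), "empty")
})

test_that("all fragment rows are kept at parse time (no top-N selection)", {
  # an entry with 25 fragment rows keeps all 25; truncation happens only
  # at matrix assembly
  th <- theoretical_fragment_mzs("ACDEFGHIKLMNPQRSTVWK", 2L)[1:25, ]
  entry <- list(modified_sequence = "ACDEFGHIKLMNPQRSTVWK",
                peptide_sequence = "ACDEFGHIKLMNPQRSTVWK",
                precursor_mz = precursor_mz("ACDEFGHIKLMNPQRSTVWK", 2L),
                precursor_charge = 2L, normalized_rt = 50,
                protein_id = "P1", is_decoy = FALSE,
                fragments = data.frame(
                  annotation = th$annotation, series = th$series,
                  index = th$index, charge = th$charge, mz = th$mz,
                  library_intensity = seq(1000, 40, length.out = 25)))
  lib <- diasense:::new_speclib(list(entry))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, f)
  lib2 <- parse_library(f)
  expect_equal(length(lib2), 1L)
  expect_equal(nrow(lib2$entries[[1L]]$fragments), 25L)
})
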