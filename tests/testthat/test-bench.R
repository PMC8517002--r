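# Two-species library benchmarking and the mass-shift confidence test.

two_species_libs <- function() {
  fx("two_species_libs", function() {
    sample_lib <- generate_experiment(
      synth_config(n_precursors = 40L, seed = 61L))$library
    foreign_lib <- generate_experiment(
      synth_config(n_precursors = 90L, seed = 62L))$library
    list(sample = sample_lib, foreign = foreign_lib)
  })
}

test_that("two-species libraries spike equal numbers with top-6 fragments", {
  ls <- two_species_libs()
  merged <- build_two_species_library(ls$sample, ls$foreign, seed = 1L)
  sp <- library_species(merged)
  expect_equal(sum(sp == "sample"), 40L)
  expect_equal(sum(sp == "foreign"), 40L)
  expect_true(all(vapply(merged$entries, function(e) nrow(e$fragments),
                         integer(1)) <= 6L))
  # fragments kept are the highest-intensity ones
  e0 <- ls$sample$entries[[1L]]
  e1 <- merged$entries[[1L]]
  expect_setequal(e1$fragments$mz,
                  e0$fragments$mz[order(-e0$fragments$library_intensity)][
                    seq_len(min(6L, nrow(e0$fragments)))])
  # seeded subset
  m2 <- build_two_species_library(ls$sample, ls$foreign, seed = 1L)
  expect_identical(vapply(merged$entries, `[[`, character(1),
                          "modified_sequence"),
                   vapply(m2$entries, `[[`, character(1),
                          "modified_sequence"))
})

test_that("overlapping foreign sequences are discarded and counted", {
  ls <- two_species_libs()
  # inject sample sequences into the foreign library
  foreign <- ls$foreign
  foreign$entries[1:10] <- ls$sample$entries[1:10]
  merged <- build_two_species_library(ls$sample, foreign, seed = 2L)
  fseqs <- vapply(merged$entries[library_species(merged) == "foreign"],
                  `[[`, character(1), "modified_sequence")
  sseqs <- vapply(ls$sample$entries, `[[`, character(1), "modified_sequence")
  expect_length(intersect(fseqs, sseqs), 0L)
  # too few foreign precursors is an error with counts
  tiny <- foreign[1:20]
  expect_error(build_two_species_library(ls$sample, tiny, seed = 3L),
               "insufficient foreign")
})

test_that("re-merging the merged library adds nothing new", {
  ls <- two_species_libs()
  merged <- build_two_species_library(ls$sample, ls$foreign, seed = 4L)
  again <- build_two_species_library(merged[library_species(merged) == "sample"],
                                     ls$foreign, seed = 4L)
  expect_equal(length(again), length(merged))
})

test_that("proxy FDR arithmetic matches its definition", {
  res <- data.frame(discriminant_score = c(seq(0.99, 0.01, length.out = 99),
                                           0.5))
  species <- c(rep("sample", 99), "foreign")
  curve <- proxy_fdr_curve(res, species)
  # 1 foreign + 49 sample at or above the foreign score 0.5
  expect_equal(curve$proxy_fdr[1L], 1 / 51, tolerance = 1e-12)
  expect_equal(curve$n_true_species[1L], 50L)
  expect_equal(proxy_fdr_at(res, species, 0.6), 0)
  expect_error(proxy_fdr_curve(res, rep("sample", 100)), "foreign")
  # n_true_species is non-increasing as the cutoff rises
  res2 <- data.frame(discriminant_score = runif(50))
  sp2 <- rep(c("sample", "foreign"), 25)
  c2 <- proxy_fdr_curve(res2, sp2)
  expect_true(all(diff(c2$n_true_species) >= 0))  # cutoff sorted decreasing
  expect_true(all(c2$proxy_fdr >= 0 & c2$proxy_fdr <= 1))
})

test_that("the proxy curve is reproducible from the written table alone", {
  sa <- small_analysis()
  r <- sa$results$results
  tg <- r[!r$is_decoy, ]
  truth <- sa$experiment$truth
  species <- ifelse(truth$present[match(
    paste(tg$modified_sequence, tg$precursor_charge),
    paste(truth$modified_sequence, truth$precursor_charge))],
    "sample", "foreign")
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(tg, species = species), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read.delim(f)
  c1 <- proxy_fdr_curve(tg, species)
  c2 <- proxy_fdr_curve(back, back$species)
  expect_equal(c1$proxy_fdr, c2$proxy_fdr, tolerance = 1e-9)
})

test_that("deamidation analysis requires deamidated entries", {
  sa <- small_analysis()
  expect_error(
    deamidation_confidence_test(sa$experiment$run, sa$experiment$library,
                                sa$model),
    "no deamidated")
})

test_that("the true shift identifies deamidated peptides, the pseudo shift few", {
  exp1 <- fx("deamid_experiment", function() {
    generate_experiment(synth_config(n_precursors = 120L,
                                     deamidation_fraction = 0.5,
                                     fraction_present = 1, seed = 71L))
  })
  m <- small_model()
  out <- deamidation_confidence_test(exp1$run, exp1$library, m, fdr = 0.01,
                                     seed = 72L, n_rt_anchors = 80L,
                                     quantify = FALSE)
  # the correct shift never identifies fewer deamidated precursors
  expect_gte(out$n_true_shift, out$n_pseudo_shift)
  # the pseudo shift strips the co-elution evidence: the representation
  # score of deamidated precursors collapses, and confident elution
  # profiles (dds >= 0.8) are at least five-fold rarer
  expect_gt(median(out$dds_true), median(out$dds_pseudo))
  expect_gte(sum(out$dds_true >= 0.8),
             5L * max(1L, sum(out$dds_pseudo >= 0.8)))
})
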