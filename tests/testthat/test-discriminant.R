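# Candidate enumeration, PU rescoring and target-decoy FDR estimation.

cand_fixture <- function() {
  fx("cand_fixture", function() {
    sa <- small_analysis()
    exp1 <- sa$experiment
    lib <- generate_decoy_library(exp1$library, seed = 28L)
    anchors <- suppressWarnings(
      select_anchors(exp1$run, lib, sa$model, n_sample = 80L, seed = 29L))
    rtm <- fit_rt_model(anchors, "linear", seed = 29L)
    cand <- enumerate_all_candidates(exp1$run, lib, rtm, sa$model)
    list(exp = exp1, lib = lib, rtm = rtm, model = sa$model, cand = cand)
  })
}

test_that("test-time augmentation windows and fallbacks behave as stated", {
  f <- cand_fixture()
  truth <- f$exp$truth
  i <- which(truth$present)[2L]
  e <- f$lib$entries[[i]]
  # impossible threshold: exactly one max-dds fallback candidate
  c1 <- enumerate_candidates(f$exp$run, e, f$rtm, f$model, dds_threshold = 1)
  expect_equal(nrow(c1), 1L)
  # zero threshold: the whole window (2w + 1 candidates when inside the run)
  c0 <- enumerate_candidates(f$exp$run, e, f$rtm, f$model,
                             rt_half_window = 10L, dds_threshold = 0)
  pred <- predict_rt_cycle(f$rtm, e$normalized_rt, f$exp$run)
  if (pred > 10L && pred <= n_cycles(f$exp$run) - 10L) {
    expect_equal(nrow(c0), 21L)
  }
  # a high-SNR present precursor retains its true apex among candidates
  cd <- enumerate_candidates(f$exp$run, e, f$rtm, f$model)
  expect_true(any(abs(cd$center_cycle - truth$apex_cycle[i]) <= 1L))
  # deep features have width 16 and dds within (0, 1)
  expect_true(all(paste0("deep", 1:16) %in% names(cd)))
  expect_true(all(cd$dds > 0 & cd$dds < 1))
})

test_that("predictions far outside the run yield no candidates", {
  f <- cand_fixture()
  e <- f$lib$entries[[1L]]
  e$normalized_rt <- 1e4
  expect_message(
    out <- enumerate_candidates(f$exp$run, e, f$rtm, f$model),
    "outside")
  expect_null(out)
})

test_that("the PU classifier requires both classes and is seeded", {
  f <- cand_fixture()
  cand <- f$cand
  expect_error(train_pu_classifier(cand[!cand$is_decoy, ]), "decoy")
  expect_error(train_pu_classifier(cand[cand$is_decoy, ]), "target")
  clf1 <- train_pu_classifier(cand, seed = 33L)
  clf2 <- train_pu_classifier(cand, seed = 33L)
  s1 <- score_and_select(cand, clf1)
  s2 <- score_and_select(cand, clf2)
  expect_identical(s1$discriminant_score, s2$discriminant_score)
  # random forest path
  clf_rf <- train_pu_classifier(cand, "random_forest", seed = 33L)
  s_rf <- score_and_select(cand, clf_rf)
  expect_equal(nrow(s_rf), nrow(s1))
})

test_that("candidate-level scores separate targets from decoys", {
  f <- cand_fixture()
  clf <- train_pu_classifier(f$cand, seed = 34L)
  scored <- score_and_select(f$cand, clf)
  truth <- f$exp$truth
  scored$present <- truth$present[match(
    paste(scored$modified_sequence, scored$precursor_charge),
    paste(truth$modified_sequence, truth$precursor_charge))]
  pres <- scored[!scored$is_decoy & scored$present %in% TRUE, ]
  dec <- scored[scored$is_decoy, ]
  expect_gt(rank_auc(c(pres$discriminant_score, dec$discriminant_score),
                     rep(c(1, 0), c(nrow(pres), nrow(dec)))), 0.95)
})

test_that("dropping the deep representation features reduces separation", {
  f <- cand_fixture()
  aux_only <- setdiff(diasense:::CANDIDATE_FEATURES,
                      c("dds", paste0("deep", 1:16)))
  full <- score_and_select(f$cand, train_pu_classifier(f$cand, seed = 35L))
  aux <- score_and_select(f$cand, train_pu_classifier(f$cand, seed = 35L,
                                                      features = aux_only))
  lab <- as.numeric(!full$is_decoy)
  expect_gt(rank_auc(full$discriminant_score, lab),
            rank_auc(aux$discriminant_score, lab))
})

test_that("best-candidate selection keeps the max with deterministic ties", {
  cand <- data.frame(
    modified_sequence = rep(c("PEPA", "PEPB"), c(3L, 2L)),
    precursor_charge = 2L, protein_id = "P", is_decoy = FALSE,
    center_cycle = c(10L, 11L, 12L, 21L, 20L),
    rt_s = 1, dds = 0.9, rt_deviation = c(2, 1, 3, 1, 0),
    stringsAsFactors = FALSE)
  cand$discriminant_score <- c(0.2, 0.9, 0.4, 0.7, 0.7)
  sel <- diasense:::select_best_candidates(cand)
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$discriminant_score[sel$modified_sequence == "PEPA"], 0.9)
  # tie on score: smaller RT deviation wins
  expect_equal(sel$center_cycle[sel$modified_sequence == "PEPB"], 20L)
})

test_that("the FDR estimator matches hand enumeration and is monotone", {
  res <- data.frame(
    modified_sequence = c("A", "B", "C", "D"), precursor_charge = 2L,
    protein_id = c("P1", "P2", "P3", "DECOY_P1"),
    is_decoy = c(FALSE, FALSE, FALSE, TRUE),
    discriminant_score = c(0.9, 0.8, 0.7, 0.75), stringsAsFactors = FALSE)
  class(res) <- c("dia_scored", "data.frame")
  out <- estimate_fdr(res, pi0 = 1)
  # targets 0.9, 0.8 sit above the only decoy: q = 0
  expect_equal(out$q_value[out$modified_sequence == "A"], 0)
  expect_equal(out$q_value[out$modified_sequence == "B"], 0)
  # the 0.7 target has 1 decoy / 3 targets above its score
  expect_equal(out$q_value[out$modified_sequence == "C"], 1 / 3)
  # q is non-increasing in score
  ord <- order(-out$discriminant_score)
  expect_true(all(diff(out$q_value[ord]) >= 0))
  expect_error(estimate_fdr(res[res$is_decoy, , drop = FALSE]), "no target")
})

test_that("protein-level estimation rolls up by maximal member score", {
  res <- data.frame(
    modified_sequence = letters[1:6], precursor_charge = 2L,
    protein_id = c("P1", "P1", "P2", "DECOY_P1", "DECOY_P2", "P3"),
    is_decoy = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    discriminant_score = c(0.95, 0.2, 0.8, 0.5, 0.1, 0.3),
    stringsAsFactors = FALSE)
  class(res) <- c("dia_scored", "data.frame")
  prot <- estimate_fdr(res, level = "protein", pi0 = 1)
  expect_equal(nrow(prot), 5L)
  expect_equal(prot$discriminant_score[prot$protein_id == "P1"], 0.95)
  # P3 (0.3) sits below DECOY_P1 (0.5): 1 decoy / 3 targets
  expect_equal(prot$q_value[prot$protein_id == "P3"], 1 / 3)
})

test_that("pi0 correction estimates the absent fraction from low scores", {
  set.seed(44)
  n_abs <- 300L; n_pres <- 700L; n_dec <- 1000L
  res <- data.frame(
    modified_sequence = paste0("s", 1:(n_abs + n_pres + n_dec)),
    precursor_charge = 2L, protein_id = "P",
    is_decoy = rep(c(FALSE, TRUE), c(n_abs + n_pres, n_dec)),
    discriminant_score = c(runif(n_abs, 0, 0.5), runif(n_pres, 0.6, 1),
                           runif(n_dec, 0, 0.5)),
    stringsAsFactors = FALSE)
  class(res) <- c("dia_scored", "data.frame")
  out <- estimate_fdr(res)
  # with 30% of targets drawn from the decoy null, q at the top of the
  # null range is ~pi0-fold smaller than the uncorrected estimate
  plain <- estimate_fdr(res, pi0 = 1)
  ratio <- out$q_value / pmax(plain$q_value, 1e-12)
  expect_lt(abs(stats::median(ratio[plain$q_value > 0]) - 0.3), 0.1)
})
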