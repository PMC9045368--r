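toy_cfg <- function(K1 = 1L, K2 = 1L)
  hmm_config(motif_length = 3L, first_motif_offset = 4L, min_motif_gap = 2L,
             n_components_first = K1, n_components_second = K2,
             n_restarts = 1L, seed = 1L)

test_that("viterbi equals exhaustive path enumeration on toy instances", {
  set.seed(99)
  for (i in 1:15) {
    K1 <- sample(0:2, 1); K2 <- sample(1:2, 1)
    cfg <- toy_cfg(K1, K2)
    model <- random_hmm(cfg, seed = 1000 + i)
    seq <- random_dna(30)
    got <- viterbi(seq, model)
    want <- oracle_viterbi(seq, model)
    expect_equal(got$viterbi_logprob, want$logprob, tolerance = 1e-9)
    expect_equal(got$component_first, want$c1)
    expect_equal(got$start_first, want$s1)
    expect_equal(got$component_second, want$c2)
    expect_equal(got$start_second, want$s2)
    # Viterbi path probability never exceeds the all-path (forward) bound
    expect_lte(got$viterbi_logprob, want$forward + 1e-9)
  }
})

test_that("planted near-deterministic motifs are found at their positions", {
  cfg <- hmm_config(n_components_first = 1L, n_components_second = 1L,
                    n_restarts = 1L)
  sharp_em <- function(motif) {
    bases <- strsplit(motif, "")[[1]]
    e <- matrix((1 - 0.97) / 3, nrow = 10L, ncol = 4L)
    for (j in 1:10) e[j, match(bases[j], c("A", "C", "G", "T"))] <- 0.97
    e
  }
  m35 <- "TTGACAGCGG"; m10 <- "TGTATAATGG"
  model <- promoter_hmm(rep(0.25, 4), list(sharp_em(m35)),
                        list(sharp_em(m10)),
                        c(0.2, 0.8), c(0.2, 0.8), cfg)
  set.seed(4)
  win <- strsplit(random_dna(100), "")[[1]]
  win[41:50] <- strsplit(m35, "")[[1]]
  win[71:80] <- strsplit(m10, "")[[1]]
  ann <- viterbi(paste(win, collapse = ""), model)
  expect_equal(ann$start_first, 40L)
  expect_equal(ann$start_second, 70L)
  expect_equal(ann$match_first, m35)
  expect_equal(ann$match_second, m10)
  expect_gt(ann$llr, 0)
})

test_that("motifs indistinguishable from background lose to the skip path", {
  cfg <- hmm_config(n_components_first = 1L, n_components_second = 1L,
                    n_restarts = 1L)
  flat <- matrix(0.25, nrow = 10L, ncol = 4L)
  model <- promoter_hmm(rep(0.25, 4), list(flat), list(flat),
                        c(0.5, 0.5), c(0.5, 0.5), cfg)
  set.seed(8)
  ann <- viterbi(random_dna(100), model)
  expect_true(is.na(ann$component_first))
  expect_true(is.na(ann$component_second))
  expect_equal(ann$llr, 0)
})

test_that("training is deterministic under a fixed seed", {
  sp <- synthetic_promoter_windows(60, seed = 21)
  cfg <- hmm_config(n_components_first = 0L, n_components_second = 2L,
                    n_restarts = 5L, seed = 33L)
  fit1 <- viterbi_train(sp$seqs, cfg)
  fit2 <- viterbi_train(sp$seqs, cfg)
  expect_identical(fit1$model, fit2$model)
  expect_identical(fit1$annotations, fit2$annotations)
  expect_identical(fit1$restart_logprobs, fit2$restart_logprobs)
})

test_that("the training objective is non-decreasing within every restart", {
  sp <- synthetic_promoter_windows(120, seed = 13)
  fit <- viterbi_train(sp$seqs, hmm_config(
    n_components_first = 0L, n_components_second = 3L,
    n_restarts = 10L, seed = 5L))
  for (tr in fit$objective_traces)
    expect_true(all(diff(tr) >= -1e-6))
})

test_that("a planted motif is recovered with accurate start positions", {
  motif <- "TTGATAATGC"
  set.seed(30)
  seqs <- vapply(1:200, function(i) {
    chars <- strsplit(random_dna(100), "")[[1]]
    s <- 50L + sample(-1:1, 1)
    chars[s + 1:10] <- strsplit(motif, "")[[1]]
    paste(chars, collapse = "")
  }, "")
  fit <- viterbi_train(seqs, hmm_config(
    n_components_first = 0L, n_components_second = 1L,
    n_restarts = 50L, seed = 17L))
  expect_equal(hmm_consensus(fit$model, "second", 1L), motif)
  expect_gte(mean(abs(fit$annotations$start_second - 50L) <= 1, na.rm = TRUE),
             0.95)
})

test_that("pure-background input yields an essentially background model", {
  set.seed(55)
  seqs <- vapply(1:80, function(i) random_dna(100), "")
  fit <- viterbi_train(seqs, hmm_config(
    n_components_first = 0L, n_components_second = 1L,
    n_restarts = 5L, seed = 2L))
  bg_only <- vapply(seqs, function(s) {
    x <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    sum(log(fit$model$background[x]))
  }, numeric(1))
  pure_bg <- sum(bg_only) + length(seqs) *
    (log(fit$model$tau_first[1]) + log(fit$model$tau_second[1]))
  expect_lt(abs(fit$logprob - pure_bg) / abs(pure_bg), 0.01)
})

test_that("decoded paths always respect the architecture constraints", {
  sp <- synthetic_promoter_windows(100, seed = 77)
  fit <- viterbi_train(sp$seqs, hmm_config(
    n_components_first = 2L, n_components_second = 2L,
    n_restarts = 5L, seed = 9L))
  ann <- fit$annotations
  both <- !is.na(ann$start_first) & !is.na(ann$start_second)
  expect_true(all(ann$start_first[!is.na(ann$start_first)] >= 40L))
  first_absent <- is.na(ann$start_first) & !is.na(ann$start_second)
  expect_true(all(ann$start_second[first_absent] >= 40L))
  expect_true(all(ann$start_second[both] >= ann$start_first[both] + 20L))
  expect_true(all(ann$start_second[!is.na(ann$start_second)] <= 90L))
})

test_that("two-phase discovery runs on a single promoter", {
  sp <- synthetic_promoter_windows(1, frac_major = 1, seed = 3)
  res <- two_phase_discovery(sp$seqs, restarts_phase1 = 3L,
                             restarts_phase2 = 3L, seed = 1L)
  expect_equal(length(res$selected), 1L)
  expect_equal(nrow(res$phase2$annotations), 1L)
})

test_that("positional histograms summarize start positions per component", {
  ann <- data.frame(component_first = c(NA, 1L, 1L),
                    start_first = c(NA, 55L, 55L),
                    component_second = c(1L, 1L, 2L),
                    start_second = c(77L, 78L, 70L))
  h <- positional_histogram(ann)
  expect_equal(h$n[h$set == "first"], 2L)
  expect_equal(sum(h$n[h$set == "second"]), 3L)
  expect_equal(h$start[h$set == "second" & h$component == 2L], 70L)

  sp <- synthetic_promoter_windows(300, frac_major = 1, seed = 41)
  fit <- viterbi_train(sp$seqs, hmm_config(
    n_components_first = 0L, n_components_second = 1L,
    n_restarts = 10L, seed = 6L))
  h <- positional_histogram(fit$annotations)
  h <- h[h$set == "second", ]
  sd_hat <- sqrt(sum(h$n * (h$start - sum(h$n * h$start) / sum(h$n))^2) /
                   sum(h$n))
  # planted starts are uniform on 77 +/- 1 (SD 0.816)
  expect_gt(sd_hat, 0.4)
  expect_lt(sd_hat, 1.2)
})

test_that("models survive a JSON round-trip", {
  sp <- synthetic_promoter_windows(40, seed = 61)
  fit <- viterbi_train(sp$seqs, hmm_config(
    n_components_first = 1L, n_components_second = 1L,
    n_restarts = 3L, seed = 11L))
  f <- withr::local_tempfile(fileext = ".json")
  hmm_to_json(fit$model, f)
  back <- hmm_from_json(f)
  expect_equal(back$background, fit$model$background, tolerance = 1e-12)
  expect_equal(back$components_second, fit$model$components_second,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(viterbi(sp$seqs, back), viterbi(sp$seqs, fit$model),
               tolerance = 1e-9)
})

test_that("sequences shorter than the motif footprint are rejected", {
  cfg <- hmm_config(n_components_first = 0L, n_components_second = 1L,
                    n_restarts = 1L)
  expect_error(viterbi_train(random_dna(45), cfg), "footprint")
})
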