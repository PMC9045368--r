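make_profile <- function(counts, total = 1e6, strand = "+",
                         replicon = "CP000352") {
  read_start_profile(replicon, strand,
                     positions = as.integer(names(counts)),
                     counts = unname(counts), total_reads = total)
}

test_that("compute_rrs is counts per million mapped reads", {
  expect_equal(compute_rrs(make_profile(c(`100` = 50), total = 1e7)),
               c(`100` = 5.0))
  expect_equal(length(compute_rrs(make_profile(setNames(numeric(0),
                                                        character(0))))), 0L)
  expect_equal(compute_rrs(make_profile(c(`1` = 1, `2` = 2), total = 1e6)),
               c(`1` = 1.0, `2` = 2.0))
  expect_error(read_start_profile("c1", "+", 1L, 1, total_reads = 0),
               "positive")
})

test_that("clustering pools RRS into the highest peak, ties to the left", {
  got <- cluster_positions(c(`100` = 10, `103` = 2, `120` = 1), radius = 5)
  expect_equal(got, data.frame(position = c(100L, 120L), rrs = c(12, 1)))
  expect_equal(cluster_positions(c(`100` = 10), radius = 0),
               data.frame(position = 100L, rrs = 10))
  got <- cluster_positions(c(`100` = 5, `105` = 5), radius = 5)
  expect_equal(got, data.frame(position = 100L, rrs = 10))
})

test_that("clustering matches the brute-force oracle and conserves mass", {
  set.seed(42)
  for (i in 1:200) {
    rrs <- random_profile(sample(1:40, 1))
    radius <- sample(0:6, 1)
    got <- cluster_positions(rrs, radius)
    expect_equal(got, oracle_cluster(rrs, radius))
    expect_equal(sum(got$rrs), sum(rrs))
    if (nrow(got) > 1L)
      expect_true(all(diff(got$position) > radius))
  }
})

test_that("clustering is deterministic", {
  set.seed(7)
  rrs <- random_profile(30)
  expect_identical(cluster_positions(rrs, 5), cluster_positions(rrs, 5))
})

test_that("candidate scoring applies ratio/control-free modes and cutoffs", {
  cand <- data.frame(position = 500L, rrs = 50)
  ratio_cfg <- tss_calling_config(control_mode = "ratio")
  got <- score_candidates(cand, control_rrs = c(`500` = 2), ratio_cfg)
  expect_equal(got$score, 25)
  expect_false(got$control_floored)

  got <- score_candidates(cand, cfg = tss_calling_config())
  expect_equal(got$score, 50)

  low <- data.frame(position = 500L, rrs = 4)
  expect_equal(nrow(score_candidates(low, cfg = tss_calling_config())), 0L)
  expect_equal(nrow(score_candidates(low, control_rrs = c(`500` = 0.1),
                                     ratio_cfg)), 0L)
})

test_that("zero pooled control RRS falls back to the smallest nonzero floor", {
  cand <- data.frame(position = c(100L, 500L), rrs = c(50, 50))
  ctrl <- c(`100` = 2, `900` = 0.5)   # nothing near 500
  got <- score_candidates(cand, ctrl, tss_calling_config(
    control_mode = "ratio"))
  expect_equal(got$score, c(50 / 2, 50 / 0.5))
  expect_equal(got$control_floored, c(FALSE, TRUE))
})

test_that("replicate merging keeps all-replicate peaks above the cutoff", {
  rep_frame <- function(pos, score, strand = "-", replicon = "CP000352")
    data.frame(replicon = replicon, strand = strand, position = pos,
               score = score, stringsAsFactors = FALSE)
  reps <- list(rep_frame(c(769713L, 1000L), c(38130, 50)),
               rep_frame(c(769713L, 2000L), c(21698, 60)),
               rep_frame(c(769713L, 1000L), c(29914, 70)))
  got <- merge_replicates(reps)
  expect_equal(nrow(got), 1L)           # 1000/2000 fail the 3-of-3 rule
  expect_equal(got$name, "TSS_769713-2")
  expect_equal(got$position, 769713L)
  expect_equal(got$mean_score, mean(c(38130, 21698, 29914)))
  expect_equal(got$score_sd, sd(c(38130, 21698, 29914)))
  expect_equal(got$rank, 1L)

  below <- merge_replicates(list(rep_frame(10L, 9.9)))
  expect_equal(nrow(below), 0L)         # strict > 10
  at <- merge_replicates(list(rep_frame(10L, 10)))
  expect_equal(nrow(at), 0L)
  expect_error(merge_replicates(list()), "replicate")
})

test_that("raising the consensus cutoff never adds records", {
  set.seed(11)
  reps <- lapply(1:3, function(r) {
    pos <- seq(100L, 2000L, by = 100L)
    data.frame(replicon = "CP000353", strand = "+", position = pos,
               score = runif(length(pos), 1, 100) + r)
  })
  cuts <- c(0, 5, 10, 20, 50)
  sizes <- vapply(cuts, function(ct)
    nrow(merge_replicates(reps, tss_calling_config(
      consensus_score_cutoff = ct))), 1L)
  expect_true(all(diff(sizes) <= 0))
  strict <- merge_replicates(reps, tss_calling_config(
    consensus_score_cutoff = 20))
  loose <- merge_replicates(reps, tss_calling_config(
    consensus_score_cutoff = 10))
  expect_true(all(strict$name %in% loose$name))
})
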