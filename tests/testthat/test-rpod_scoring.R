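k <- rpod_constants()

test_that("hexamer scores are weighted consensus matches", {
  expect_equal(score_hexamer("TTGACA", "TTGACA", k$w35), 9)
  expect_equal(score_hexamer("TTGATT", "TTGACA", k$w35), 7)
  expect_equal(score_hexamer("TATAAT", "TATAAT", k$w10), 8)
  expect_equal(score_hexamer("CAGATT", "TATAAT", k$w10), 5)
  expect_equal(score_hexamer("NNNNNN", "TATAAT", k$w10), 0)
  expect_error(score_hexamer("TTGAC", "TTGACA", k$w35), "6-mer")
})

test_that("published housekeeping rows reproduce their printed scores", {
  hk <- housekeeping_promoters()
  expect_equal(nrow(hk), 48L)
  sc <- rpod_score(hk$m35_start, hk$m35_seq, hk$m10_start, hk$m10_seq)
  expect_true(all(abs(sc$score - hk$printed_score) <= 0.05))
  expect_equal(sc$score, sc$s35 + sc$s10 - sc$pos_penalty - sc$spacer_penalty,
               tolerance = 1e-9)
  row <- function(gene, start) which(hk$gene == gene & hk$m35_start == start)
  expect_equal(sc$score[row("rpmB", -35)], 14.2, tolerance = 1e-9)
  expect_equal(sc$score[row("rplY", -34)], 13.6, tolerance = 1e-9)
  expect_equal(sc$score[row("rplM", -35)], 12.6, tolerance = 1e-9)
  expect_equal(sc$spacer[row("rplM", -35)], 14)
  expect_equal(sc$score[row("rpoA", -39)], 4.9, tolerance = 1e-9)
})

test_that("housekeeping summary reproduces the motif geometry statistics", {
  s <- housekeeping_summary()
  stat <- function(q, col) s[s$quantity == q, col]
  expect_equal(round(stat("m35_start", "mean"), 1), -35.6)
  expect_equal(round(stat("m35_start", "sd"), 1), 1.6)
  expect_equal(round(stat("m10_start", "mean"), 1), -13.7)
  expect_equal(round(stat("m10_start", "sd"), 1), 0.9)
  expect_equal(stat("m35_start", "min"), -39)
  expect_equal(stat("m35_start", "max"), -33)
  expect_equal(stat("score", "max"), 14.6, tolerance = 1e-9)
  expect_equal(stat("score", "min"), 1.9, tolerance = 1e-9)

  one <- housekeeping_summary(data.frame(
    m35_start = -35, m35_seq = "TTGACA", m10_start = -13,
    m10_seq = "TATAAT"))
  expect_equal(one[one$quantity == "m35_start", "mean"], -35)
  expect_equal(one[one$quantity == "m35_start", "sd"], 0)
})

test_that("every -10 hexamer keeps the invariant A at 2 and T at 6", {
  hk <- housekeeping_promoters()
  hex10 <- substr(hk$m10_seq, 3, 8)
  expect_true(all(substr(hex10, 2, 2) == "A"))
  expect_true(all(substr(hex10, 6, 6) == "T"))
})

test_that("perfect consensus maximizes at 16.4 with -36/spacer 16", {
  grid <- expand.grid(m35 = -60:-12, m10 = -45:-7)
  sc <- rpod_score(grid$m35, "TTGACA", grid$m10, "TATAAT", k)
  best <- which.max(sc$score)
  expect_equal(sc$score[best], 16.4, tolerance = 1e-9)
  expect_equal(grid$m35[best], -36)
  expect_equal(sc$spacer[best], 16)
  expect_equal(max(sc$s35 + sc$s10), 17)
})

test_that("strength classes follow the published thresholds", {
  expect_equal(classify_strength(c(14.2, 4.9, 3.28, 2.0, 0.22, 0.21, -1, NA)),
               c("strong", "medium", "weak", "weak", "weak", "none", "none",
                 "none"))
  expect_equal(classify_strength(6.35), "medium")   # strict > for strong
  expect_equal(classify_strength(6.36), "strong")
})

test_that("positional categories cover every case exactly once", {
  expect_equal(classify_position(-35, -13), "in_window")
  expect_equal(classify_position(-41, -14), "sba")
  expect_equal(classify_position(-35, -19), "ba")
  expect_equal(classify_position(-40, -19), "nu")   # spacer 15, same side
  expect_equal(classify_position(-30, -9), "nu")    # downstream displacement
  expect_equal(classify_position(-45, -5), "all_wrong")
  expect_equal(classify_position(-50, -25), "all_wrong")  # beyond the margin
  expect_equal(classify_position(-40, -22), "all_wrong")  # spacer 12 too small
  expect_equal(classify_position(NA, -13), "no_motif")

  grid <- expand.grid(m35 = -55:-20, m10 = -30:-2)
  cats <- classify_position(grid$m35, grid$m10)
  expect_true(all(cats %in% c("in_window", "sba", "ba", "nu", "all_wrong")))
  expect_equal(length(cats), nrow(grid))
})

test_that("tier assignment reproduces the grouping rules exactly", {
  combos <- expand.grid(
    strength = c("strong", "medium", "weak", "none"),
    category = c("in_window", "sba", "ba", "nu", "all_wrong", "no_motif"),
    stringsAsFactors = FALSE)
  got <- assign_tier(combos$strength, combos$category)
  expected <- rep("none", nrow(combos))
  expected[combos$category == "in_window" &
             combos$strength %in% c("strong", "medium")] <- "high"
  expected[combos$category %in% c("sba", "ba") &
             combos$strength == "strong"] <- "high"
  expected[combos$category == "in_window" & combos$strength == "weak"] <- "low"
  expected[combos$category %in% c("sba", "ba", "nu") &
             combos$strength == "medium"] <- "low"
  expect_equal(got, expected)
  expect_equal(assign_tier("strong", "nu"), "none")
  expect_error(assign_tier("huge", "in_window"), "strength")
})

test_that("score_promoters assembles complete calls", {
  hk <- housekeeping_promoters()
  calls <- score_promoters(data.frame(
    tss_name = paste0("hk", seq_len(nrow(hk))),
    m35_start = hk$m35_start, m35_seq = hk$m35_seq,
    m10_start = hk$m10_start, m10_seq = hk$m10_seq))
  expect_equal(nrow(calls), 48L)
  expect_true(all(calls$category == "in_window" |
                    calls$m35_start < -39 | calls$m35_start > -31 |
                    calls$m10_start < -18 | calls$m10_start > -10))
  expect_true(all(calls$tier[calls$strength == "strong" &
                               calls$category == "in_window"] == "high"))
  none <- score_promoters(data.frame(m35_start = NA, m35_seq = NA,
                                     m10_start = -13, m10_seq = "TATAAT"))
  expect_equal(none$category, "no_motif")
  expect_equal(none$tier, "none")
})
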