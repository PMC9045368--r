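## Weighted RpoD (sigma-70) consensus scoring of -35/-10 motif matches, and
## classification into strength classes, positional categories and
## RpoD-dependence probability tiers.
##
## The score rewards matches to the TTGACA/TATAAT consensus hexamers with
## position-specific weights reflecting their conservation among
## housekeeping promoters, and penalizes deviation of the -35 element from
## its mean position (-35.6) and of the spacer from its mean length (15.8).

#' Constants of the RpoD scoring scheme
#'
#' @param strong_cutoff,medium_cutoff,weak_cutoff strength-class thresholds
#'   (score > strong_cutoff is "strong", and so on down to "none").
#' @param window_m35,window_m10 inclusive screening windows (TSS-relative)
#'   for a correctly positioned -35 and -10 motif.
#' @param nu_margin maximum bp a motif may lie beyond its window edge to
#'   still qualify for the "nu" category.
#' @param nu_spacer_range inclusive spacer range qualifying for "nu".
#' @param mean_m35_pos,mean_spacer penalty reference points.
#' @return list of class `rpod_constants`: consensus hexamers, weight
#'   vectors, penalty references, thresholds and windows.
#' @export
rpod_constants <- function(strong_cutoff = 6.35, medium_cutoff = 3.28,
                           weak_cutoff = 0.21,
                           window_m35 = c(-39L, -31L),
                           window_m10 = c(-18L, -10L),
                           nu_margin = 5L, nu_spacer_range = c(13L, 19L),
                           mean_m35_pos = -35.6, mean_spacer = 15.8) {
  structure(list(
    consensus35 = "TTGACA", w35 = c(3, 1.5, 1.5, 1, 1, 1),
    consensus10 = "TATAAT", w10 = c(1, 2, 1, 1, 1, 2),
    mean_m35_pos = mean_m35_pos, mean_spacer = mean_spacer,
    strong_cutoff = strong_cutoff, medium_cutoff = medium_cutoff,
    weak_cutoff = weak_cutoff,
    window_m35 = window_m35, window_m10 = window_m10,
    nu_margin = nu_margin, nu_spacer_range = nu_spacer_range
  ), class = "rpod_constants")
}

#' Weighted hexamer match score
#'
#' Sums the weights at positions where the observed base equals the
#' consensus base; `N` never matches.
#'
#' @param observed character vector of 6-mers.
#' @param consensus consensus 6-mer.
#' @param weights numeric weight vector of length 6.
#' @return numeric vector of scores.
#' @export
score_hexamer <- function(observed, consensus, weights) {
  if (length(weights) != 6L) stop("weights must have length 6")
  if (nchar(consensus) != 6L) stop("consensus must be a 6-mer")
  if (any(nchar(observed) != 6L))
    stop("observed sequences must be 6-mers")
  obs <- matrix(unlist(strsplit(toupper(observed), "")), ncol = 6L,
                byrow = TRUE)
  cons <- strsplit(toupper(consensus), "")[[1]]
  hits <- sweep(obs, 2L, cons, `==`)
  as.numeric(hits %*% weights)
}

#' RpoD consensus score for a -35/-10 motif match pair
#'
#' The -35 hexamer is the first 6 nt of the 10-mer -35 model match; the -10
#' hexamer is nt 3-8 of the 10-mer -10 model match (the TATAAT consensus sits
#' at the third position of the -10 model, the two leading bases belonging
#' to the extended -10 "TGn" element, which is reported but carries no
#' weight). The spacer is the number of nt strictly between the 6-nt -35
#' element and the start of the 10-mer -10 match:
#' `spacer = |m35_start| - 6 - |m10_start|`. The score is
#' `s35 + s10 - |m35_start - (-35.6)| - |spacer - 15.8|`.
#'
#' @param m35_start,m10_start TSS-relative start positions (negative) of the
#'   10-mer motif matches.
#' @param m35_seq,m10_seq the matched 10-mers (6-mers are also accepted for
#'   the -35 side; for the -10 side a 6-mer is taken as the hexamer itself).
#' @param k an [rpod_constants()] object.
#' @return data.frame with `s35`, `s10`, `pos_penalty`, `spacer`,
#'   `spacer_penalty`, `extended_m10`, `score`. Rows with any `NA` input get
#'   `NA` scores.
#' @export
rpod_score <- function(m35_start, m35_seq, m10_start, m10_seq,
                       k = rpod_constants()) {
  n <- max(length(m35_start), length(m10_start))
  m35_start <- rep_len(as.numeric(m35_start), n)
  m10_start <- rep_len(as.numeric(m10_start), n)
  m35_seq <- rep_len(as.character(m35_seq), n)
  m10_seq <- rep_len(as.character(m10_seq), n)
  ok <- !(is.na(m35_start) | is.na(m10_start) | is.na(m35_seq) |
            is.na(m10_seq))
  hex35 <- ifelse(nchar(m35_seq) >= 6L, substr(m35_seq, 1L, 6L), m35_seq)
  hex10 <- ifelse(nchar(m10_seq) >= 8L, substr(m10_seq, 3L, 8L), m10_seq)
  ext10 <- ifelse(nchar(m10_seq) >= 8L, substr(m10_seq, 1L, 2L),
                  NA_character_)
  out <- data.frame(
    s35 = NA_real_, s10 = NA_real_, pos_penalty = NA_real_,
    spacer = NA_real_, spacer_penalty = NA_real_,
    extended_m10 = NA_character_, score = NA_real_,
    stringsAsFactors = FALSE
  )[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  if (any(ok)) {
    out$s35[ok] <- score_hexamer(hex35[ok], k$consensus35, k$w35)
    out$s10[ok] <- score_hexamer(hex10[ok], k$consensus10, k$w10)
    out$pos_penalty[ok] <- abs(m35_start[ok] - k$mean_m35_pos)
    out$spacer[ok] <- abs(m35_start[ok]) - 6 - abs(m10_start[ok])
    out$spacer_penalty[ok] <- abs(out$spacer[ok] - k$mean_spacer)
    out$extended_m10[ok] <- ext10[ok]
    out$score[ok] <- out$s35[ok] + out$s10[ok] - out$pos_penalty[ok] -
      out$spacer_penalty[ok]
  }
  out
}

#' Strength class of an RpoD score
#'
#' "strong" above `strong_cutoff`, "medium" in `(medium_cutoff,
#' strong_cutoff]`, "weak" in `(weak_cutoff, medium_cutoff]`, otherwise
#' "none" (upper bounds inclusive, lower bounds exclusive). `NA` scores map
#' to "none".
#'
#' @param score numeric vector of RpoD scores.
#' @param k an [rpod_constants()].
#' @return character vector in `strong, medium, weak, none`.
#' @export
classify_strength <- function(score, k = rpod_constants()) {
  out <- rep("none", length(score))
  out[!is.na(score) & score > k$weak_cutoff] <- "weak"
  out[!is.na(score) & score > k$medium_cutoff] <- "medium"
  out[!is.na(score) & score > k$strong_cutoff] <- "strong"
  out
}

#' Positional category of a -35/-10 match pair
#'
#' `in_window` when both motifs fall inside their screening windows
#' (-39..-31 for the -35 match, -18..-10 for the -10 match); `sba`
#' ("sliding-blocking-another sigma factor") when only the -10 motif is
#' inside; `ba` ("blocking or used by another sigma factor") when only the
#' -35 motif is inside; `nu` ("not used by RpoD") when both are outside but
#' displaced toward the same side, each at most `nu_margin` bp beyond its
#' window edge, with a spacer inside `nu_spacer_range`; `all_wrong`
#' otherwise; `no_motif` when either start is `NA`.
#'
#' @param m35_start,m10_start TSS-relative motif start positions.
#' @param k an [rpod_constants()].
#' @return character vector of categories.
#' @export
classify_position <- function(m35_start, m10_start, k = rpod_constants()) {
  n <- max(length(m35_start), length(m10_start))
  m35 <- rep_len(as.numeric(m35_start), n)
  m10 <- rep_len(as.numeric(m10_start), n)
  out <- rep("no_motif", n)
  ok <- !(is.na(m35) | is.na(m10))
  in35 <- ok & m35 >= k$window_m35[1] & m35 <= k$window_m35[2]
  in10 <- ok & m10 >= k$window_m10[1] & m10 <= k$window_m10[2]
  spacer <- abs(m35) - 6 - abs(m10)
  same_side <- (m35 < k$window_m35[1] & m10 < k$window_m10[1]) |
    (m35 > k$window_m35[2] & m10 > k$window_m10[2])
  within_margin <-
    m35 >= k$window_m35[1] - k$nu_margin &
    m35 <= k$window_m35[2] + k$nu_margin &
    m10 >= k$window_m10[1] - k$nu_margin &
    m10 <= k$window_m10[2] + k$nu_margin
  spacer_ok <- spacer >= k$nu_spacer_range[1] & spacer <= k$nu_spacer_range[2]
  out[ok & in35 & in10] <- "in_window"
  out[ok & !in35 & in10] <- "sba"
  out[ok & in35 & !in10] <- "ba"
  both_out <- ok & !in35 & !in10
  out[both_out] <- ifelse(same_side[both_out] & within_margin[both_out] &
                            spacer_ok[both_out], "nu", "all_wrong")
  out
}

#' RpoD-dependence probability tier
#'
#' `high`: correctly positioned motifs with a strong or medium score, or a
#' strong score in the `sba`/`ba` categories. `low`: correctly positioned
#' with a weak score, or a medium score in `sba`, `ba` or `nu`. Everything
#' else (including strong `nu`, which the penalty structure makes
#' unreachable, and `no_motif`) is `none`.
#'
#' @param strength character vector from [classify_strength()].
#' @param category character vector from [classify_position()].
#' @return character vector in `high, low, none`.
#' @export
assign_tier <- function(strength, category) {
  n <- max(length(strength), length(category))
  strength <- rep_len(strength, n)
  category <- rep_len(category, n)
  ok_str <- strength %in% c("strong", "medium", "weak", "none")
  ok_cat <- category %in% c("in_window", "sba", "ba", "nu", "all_wrong",
                            "no_motif")
  if (any(!ok_str)) stop("unknown strength: ",
                         paste(unique(strength[!ok_str]), collapse = ", "))
  if (any(!ok_cat)) stop("unknown category: ",
                         paste(unique(category[!ok_cat]), collapse = ", "))
  high <- (category == "in_window" & strength %in% c("strong", "medium")) |
    (category %in% c("sba", "ba") & strength == "strong")
  low <- (category == "in_window" & strength == "weak") |
    (category %in% c("sba", "ba", "nu") & strength == "medium")
  ifelse(high, "high", ifelse(low, "low", "none"))
}

#' Full RpoD call for a table of motif matches
#'
#' Applies [rpod_score()], [classify_strength()], [classify_position()] and
#' [assign_tier()] to a table with columns `m35_start`, `m35_seq`,
#' `m10_start`, `m10_seq` (e.g. the motif annotations of the HMM after
#' conversion to TSS-relative coordinates, or a standalone table).
#'
#' @param matches data.frame of motif match pairs; a `tss_name` column is
#'   carried through when present.
#' @param k an [rpod_constants()].
#' @return data.frame of RpoD calls (score breakdown, `strength`,
#'   `category`, `tier`).
#' @export
score_promoters <- function(matches, k = rpod_constants()) {
  sc <- rpod_score(matches$m35_start, matches$m35_seq,
                   matches$m10_start, matches$m10_seq, k)
  out <- data.frame(
    tss_name = if (!is.null(matches$tss_name)) matches$tss_name
               else rep(NA_character_, nrow(sc)),
    m35_start = rep_len(matches$m35_start, nrow(sc)),
    m35_seq = rep_len(matches$m35_seq, nrow(sc)),
    m10_start = rep_len(matches$m10_start, nrow(sc)),
    m10_seq = rep_len(matches$m10_seq, nrow(sc)),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, sc)
  out$strength <- classify_strength(out$score, k)
  out$category <- classify_position(out$m35_start, out$m10_start, k)
  out$tier <- assign_tier(out$strength, out$category)
  out
}

#' The bundled housekeeping promoter table
#'
#' The published table of 48 housekeeping-gene promoters (motif model starts
#' and matched 10-mers with the printed RpoD scores), bundled as the
#' reference fixture for the scoring scheme.
#'
#' @return data.frame with columns `rank`, `model`, `m35_start`, `m35_seq`,
#'   `m10_start`, `m10_seq`, `locus_tag`, `gene`, `printed_score`.
#' @export
housekeeping_promoters <- function() {
  path <- system.file("extdata", "table2_housekeeping.tsv",
                      package = "sigmacall", mustWork = TRUE)
  read_result_table(path, "housekeeping_promoters")
}

#' Summary statistics of a housekeeping promoter table
#'
#' Recomputes the RpoD score for every row and reports mean, SD, min and max
#' of the -35 start, the -10 model start, the spacer and the score.
#'
#' @param table data.frame like [housekeeping_promoters()].
#' @param k an [rpod_constants()].
#' @return data.frame with one row per quantity.
#' @export
housekeeping_summary <- function(table = housekeeping_promoters(),
                                 k = rpod_constants()) {
  if (nrow(table) == 0L) stop("empty table")
  sc <- rpod_score(table$m35_start, table$m35_seq,
                   table$m10_start, table$m10_seq, k)
  stat <- function(x) c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x)
                        else 0, min = min(x), max = max(x))
  m <- rbind(m35_start = stat(table$m35_start),
             m10_start = stat(table$m10_start),
             spacer = stat(sc$spacer),
             score = stat(sc$score))
  data.frame(quantity = rownames(m), as.data.frame(m), row.names = NULL)
}
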