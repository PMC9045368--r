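## TSS calling: relative read scores, peak clustering, quality scores and the
## replicate consensus.

#' Per-position 5'-end read counts for one library/replicate/strand
#'
#' @param replicon_id replicon name; must end in a digit if TSS names are to
#'   be generated downstream.
#' @param strand `"+"` or `"-"`. Minus-strand positions refer to the same
#'   forward coordinate system as plus-strand ones.
#' @param positions 1-based positions with at least one read.
#' @param counts read counts at `positions` (same length).
#' @param total_reads total mapped reads of the library across all replicons
#'   and strands (the denominator N of the relative read score).
#' @param replicon_length optional; when given, positions beyond it are an
#'   error.
#' @return object of class `read_start_profile`.
#' @export
read_start_profile <- function(replicon_id, strand, positions, counts,
                               total_reads, replicon_length = NULL) {
  strand <- match.arg(strand, c("+", "-"))
  positions <- as.integer(positions)
  counts <- as.numeric(counts)
  if (length(positions) != length(counts))
    stop("positions and counts differ in length")
  if (any(counts < 0)) stop("negative read count")
  if (any(positions < 1L)) stop("positions must be >= 1")
  if (!is.null(replicon_length) && any(positions > replicon_length))
    stop("position beyond replicon length")
  if (anyDuplicated(positions)) {
    counts <- as.numeric(tapply(counts, positions, sum))
    positions <- sort(unique(positions))
  } else if (is.unsorted(positions)) {
    o <- order(positions)
    positions <- positions[o]
    counts <- counts[o]
  }
  total_reads <- as.numeric(total_reads)
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads <= 0)
    stop("total_reads must be a positive scalar")
  if (total_reads < sum(counts))
    stop("total_reads smaller than the sum of counts")
  structure(
    list(replicon_id = replicon_id, strand = strand,
         positions = positions, counts = counts, total_reads = total_reads),
    class = "read_start_profile"
  )
}

#' @export
print.read_start_profile <- function(x, ...) {
  cat("read_start_profile:", x$replicon_id, x$strand, "|",
      length(x$positions), "positions,",
      format(sum(x$counts), big.mark = ","), "reads of",
      format(x$total_reads, big.mark = ","), "total\n")
  invisible(x)
}

#' TSS-calling configuration
#'
#' Defaults reproduce the published protocol: clustered relative read score
#' (RRS) cutoff 5, cluster radius 5 bp, per-replicate quality-score cutoff 5
#' (strict), replicate-consensus mean-score cutoff 10 (strict), and
#' control-free scoring (score = RRS) since the non-enriched control library
#' is typically much shallower than the enriched one.
#'
#' @param rrs_cutoff minimum clustered RRS (inclusive) for a candidate.
#' @param cluster_radius bp pooled up- and downstream of a peak.
#' @param consensus_score_cutoff strict lower bound on the mean replicate
#'   score.
#' @param per_replicate_score_cutoff strict lower bound on each replicate's
#'   score.
#' @param control_mode `"control_free"` (score = RRS) or `"ratio"`
#'   (score = RRS_TSS / RRS_control at the peak, control pooled with the same
#'   radius).
#' @return list of class `tss_calling_config`.
#' @export
tss_calling_config <- function(rrs_cutoff = 5, cluster_radius = 5L,
                               consensus_score_cutoff = 10,
                               per_replicate_score_cutoff = 5,
                               control_mode = c("control_free", "ratio")) {
  control_mode <- match.arg(control_mode)
  if (cluster_radius < 0L) stop("cluster_radius must be >= 0")
  if (rrs_cutoff < 0 || consensus_score_cutoff < 0 ||
      per_replicate_score_cutoff < 0)
    stop("cutoffs must be >= 0")
  structure(list(rrs_cutoff = rrs_cutoff,
                 cluster_radius = as.integer(cluster_radius),
                 consensus_score_cutoff = consensus_score_cutoff,
                 per_replicate_score_cutoff = per_replicate_score_cutoff,
                 control_mode = control_mode),
            class = "tss_calling_config")
}

#' Relative read scores (reads per million)
#'
#' RRS at position i is `counts[i] / total_reads * 1e6`; positions without
#' reads are absent from the result.
#'
#' @param profile a [read_start_profile()].
#' @return named numeric vector (names are 1-based positions).
#' @export
compute_rrs <- function(profile) {
  stopifnot(inherits(profile, "read_start_profile"))
  if (profile$total_reads <= 0) stop("total_reads must be positive")
  keep <- profile$counts > 0
  rrs <- profile$counts[keep] / profile$total_reads * 1e6
  names(rrs) <- profile$positions[keep]
  rrs
}

#' Greedy clustering of RRS positions into peaks
#'
#' Repeatedly takes the unconsumed position with the highest RRS (ties broken
#' toward the smaller coordinate), pools (sums) all unconsumed RRS within
#' `radius` bp into it, and marks those positions consumed. Every input
#' position belongs to exactly one cluster, so RRS mass is conserved, and
#' returned peaks are pairwise more than `radius` apart.
#'
#' @param rrs named numeric vector as returned by [compute_rrs()].
#' @param radius pooling radius in bp (>= 0).
#' @return data.frame with columns `position` (peak) and `rrs` (pooled),
#'   sorted by position.
#' @export
cluster_positions <- function(rrs, radius) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0")
  if (length(rrs) == 0L)
    return(data.frame(position = integer(0), rrs = numeric(0)))
  pos <- as.integer(names(rrs))
  if (anyNA(pos)) stop("rrs must be named by integer positions")
  o <- order(pos)                       # work in coordinate order
  pos <- pos[o]; val <- unname(rrs[o])
  cand <- order(-val, pos)              # ties -> smaller coordinate first
  consumed <- logical(length(pos))
  peak_pos <- integer(0); peak_val <- numeric(0)
  for (i in cand) {
    if (consumed[i]) next
    lo <- findInterval(pos[i] - radius - 1L, pos) + 1L
    hi <- findInterval(pos[i] + radius, pos)
    members <- lo:hi
    members <- members[!consumed[members]]
    consumed[members] <- TRUE
    peak_pos <- c(peak_pos, pos[i])
    peak_val <- c(peak_val, sum(val[members]))
  }
  o <- order(peak_pos)
  data.frame(position = peak_pos[o], rrs = peak_val[o])
}

#' Score clustered TSS candidates
#'
#' In `ratio` mode the TSS quality score is the ratio of the clustered
#' enriched-library RRS to the control-library RRS pooled with the same
#' radius around the peak; a peak with zero pooled control RRS is scored
#' against a pseudo-count floor equal to the smallest nonzero control RRS in
#' the track and flagged. In `control_free` mode the score is the clustered
#' RRS itself. Candidates with clustered RRS below `rrs_cutoff` or score not
#' exceeding `per_replicate_score_cutoff` are dropped.
#'
#' @param candidates data.frame from [cluster_positions()].
#' @param control_rrs named numeric vector of raw control-library RRS for the
#'   same replicon/strand (required in ratio mode).
#' @param cfg a [tss_calling_config()].
#' @return data.frame `position`, `rrs`, `rrs_control`, `score`,
#'   `control_floored`.
#' @export
score_candidates <- function(candidates, control_rrs = NULL,
                             cfg = tss_calling_config()) {
  stopifnot(inherits(cfg, "tss_calling_config"))
  n <- nrow(candidates)
  if (cfg$control_mode == "ratio") {
    if (is.null(control_rrs))
      stop("ratio mode requires a control track")
    cpos <- as.integer(names(control_rrs))
    o <- order(cpos); cpos <- cpos[o]; cval <- unname(control_rrs[o])
    csum <- c(0, cumsum(cval))
    pooled <- vapply(candidates$position, function(p) {
      lo <- findInterval(p - cfg$cluster_radius - 1L, cpos) + 1L
      hi <- findInterval(p + cfg$cluster_radius, cpos)
      if (hi < lo) 0 else csum[hi + 1L] - csum[lo]
    }, numeric(1))
    floor_val <- if (any(cval > 0)) min(cval[cval > 0]) else NA_real_
    floored <- pooled == 0
    if (any(floored) && is.na(floor_val))
      stop("control track has no reads; cannot form a ratio score")
    denom <- ifelse(floored, floor_val, pooled)
    out <- data.frame(position = candidates$position, rrs = candidates$rrs,
                      rrs_control = pooled,
                      score = candidates$rrs / denom,
                      control_floored = floored)
  } else {
    out <- data.frame(position = candidates$position, rrs = candidates$rrs,
                      rrs_control = NA_real_, score = candidates$rrs,
                      control_floored = FALSE)
  }
  out <- out[out$rrs >= cfg$rrs_cutoff &
               out$score > cfg$per_replicate_score_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-consensus TSS records
#'
#' Keeps only peaks called at the same replicon, strand and exact clustered
#' position in every replicate, averages their quality scores, and drops
#' records whose mean score does not exceed the consensus cutoff (strict).
#' Records are sorted by descending mean score, ranked, and named
#' `TSS_<position><strand><replicon digit>`.
#'
#' @param replicates list (one element per biological replicate) of
#'   data.frames with columns `replicon`, `strand`, `position`, `score`.
#' @param cfg a [tss_calling_config()].
#' @return data.frame with columns `name`, `replicon`, `position`, `strand`,
#'   `mean_score`, `score_sd`, `rank` plus one `score_rep<i>` column per
#'   replicate.
#' @export
merge_replicates <- function(replicates, cfg = tss_calling_config()) {
  if (length(replicates) == 0L) stop("need at least one replicate")
  keys <- lapply(replicates, function(r)
    paste(r$replicon, r$strand, r$position, sep = "|"))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    empty <- data.frame(name = character(0), replicon = character(0),
                        position = integer(0), strand = character(0),
                        mean_score = numeric(0), score_sd = numeric(0),
                        stringsAsFactors = FALSE)
    for (i in seq_along(replicates))
      empty[[paste0("score_rep", i)]] <- numeric(0)
    empty$rank <- integer(0)
    return(empty)
  }
  base <- replicates[[1]][match(common, keys[[1]]), , drop = FALSE]
  scores <- vapply(seq_along(replicates), function(i)
    replicates[[i]]$score[match(common, keys[[i]])],
    numeric(length(common)))
  scores <- matrix(scores, nrow = length(common))
  mean_score <- rowMeans(scores)
  score_sd <- if (ncol(scores) > 1L) apply(scores, 1L, stats::sd)
              else rep(0, length(common))
  out <- data.frame(
    name = if (length(common)) make_tss_name(base$position, base$strand,
                                             base$replicon) else character(0),
    replicon = base$replicon, position = base$position, strand = base$strand,
    mean_score = mean_score, score_sd = score_sd,
    stringsAsFactors = FALSE
  )
  colnames(scores) <- paste0("score_rep", seq_len(ncol(scores)))
  out <- cbind(out, as.data.frame(scores))
  out <- out[out$mean_score > cfg$consensus_score_cutoff, , drop = FALSE]
  out <- out[order(-out$mean_score, out$replicon, out$position), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Call TSSs from replicate read-start profiles
#'
#' Convenience pipeline over [compute_rrs()], [cluster_positions()],
#' [score_candidates()] and [merge_replicates()]. Each replicate is a list of
#' [read_start_profile()] objects (one per replicon/strand); in ratio mode a
#' parallel structure of control profiles is matched by replicon and strand.
#'
#' @param tss_replicates list over replicates of lists of profiles.
#' @param control_replicates optional matching structure of control profiles.
#' @param cfg a [tss_calling_config()].
#' @return TSS record data.frame (see [merge_replicates()]).
#' @export
call_tss <- function(tss_replicates, control_replicates = NULL,
                     cfg = tss_calling_config()) {
  per_rep <- lapply(seq_along(tss_replicates), function(r) {
    profiles <- tss_replicates[[r]]
    tabs <- lapply(profiles, function(p) {
      ctrl <- NULL
      if (cfg$control_mode == "ratio") {
        ctrl_prof <- Filter(function(q)
          q$replicon_id == p$replicon_id && q$strand == p$strand,
          control_replicates[[r]])
        if (length(ctrl_prof) != 1L)
          stop("no unique control profile for ", p$replicon_id, p$strand)
        ctrl <- compute_rrs(ctrl_prof[[1]])
      }
      cand <- cluster_positions(compute_rrs(p), cfg$cluster_radius)
      scored <- score_candidates(cand, ctrl, cfg)
      if (nrow(scored) == 0L)
        return(data.frame(replicon = character(0), strand = character(0),
                          position = integer(0), score = numeric(0)))
      data.frame(replicon = p$replicon_id, strand = p$strand,
                 position = scored$position, score = scored$score,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })
  merge_replicates(per_rep, cfg)
}
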