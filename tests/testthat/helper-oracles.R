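# Independent brute-force oracles used by the unit and acceptance tests.
# These re-derive expected results from first principles (exhaustive
# enumeration / literal application of the stated rules) and never call the
# implementation paths they check.

# Literal greedy clustering: repeatedly take the highest-RRS unconsumed
# position (ties -> smaller coordinate), pool everything within the radius.
oracle_cluster <- function(rrs, radius) {
  pos <- as.integer(names(rrs))
  val <- unname(rrs)
  out_pos <- integer(0); out_val <- numeric(0)
  while (length(pos) > 0L) {
    best <- which(val == max(val))
    best <- best[which.min(pos[best])]
    members <- abs(pos - pos[best]) <= radius
    out_pos <- c(out_pos, pos[best])
    out_val <- c(out_val, sum(val[members]))
    pos <- pos[!members]; val <- val[!members]
  }
  o <- order(out_pos)
  data.frame(position = out_pos[o], rrs = out_val[o])
}

# Random sparse read-start profile for property tests.
random_profile <- function(n_pos, span = 200L, max_val = 50) {
  pos <- sort(sample.int(span, n_pos))
  rrs <- stats::runif(n_pos, 0.1, max_val)
  names(rrs) <- pos
  rrs
}

# Exhaustive decoding of the two-motif-set model on one sequence: enumerates
# every legal placement in the same canonical order as the decoder (skip,
# set-1-only, set-2-only, pairs; starts ascending before component indices,
# strict improvement) and computes each path's log-probability from first
# principles. Also returns the log-sum over all legal paths.
oracle_viterbi <- function(seq, model) {
  cfg <- model$cfg
  alphabet <- c("A", "C", "G", "T")
  x <- match(strsplit(toupper(seq), "")[[1]], alphabet)  # NA = N
  L <- length(x)
  m <- cfg$motif_length
  off <- cfg$first_motif_offset
  gap <- cfg$min_motif_gap
  smax <- L - m
  lb <- log(model$background)
  bg_ll <- sum(lb[x[!is.na(x)]])
  emit <- function(em, s) {             # s is 0-based
    idx <- x[(s + 1):(s + m)]
    lo <- 0
    for (j in seq_len(m))
      if (!is.na(idx[j])) lo <- lo + log(em[j, idx[j]]) - lb[idx[j]]
    unname(lo)
  }
  K1 <- length(model$components_first)
  K2 <- length(model$components_second)
  lt1 <- log(model$tau_first); lt2 <- log(model$tau_second)
  S <- smax - off + 1L
  s1_range <- if (S > 0) off:smax else integer(0)
  n_pair <- sum(pmax(0L, smax - (s1_range + m + gap) + 1L))
  lp_single <- -log(S)
  lp_pair <- if (n_pair > 0) -log(n_pair) else -Inf

  na <- NA_integer_
  cand <- list(list(lp = unname(lt1[1] + lt2[1]),
                    c1 = na, s1 = na, c2 = na, s2 = na))
  for (s in s1_range) for (k in seq_len(K1))
    cand[[length(cand) + 1L]] <- list(
      lp = unname(lt1[k + 1] + lt2[1] +
                    emit(model$components_first[[k]], s) + lp_single),
      c1 = as.integer(k), s1 = as.integer(s), c2 = na, s2 = na)
  for (s in s1_range) for (k in seq_len(K2))
    cand[[length(cand) + 1L]] <- list(
      lp = unname(lt1[1] + lt2[k + 1] +
                    emit(model$components_second[[k]], s) + lp_single),
      c1 = na, s1 = na, c2 = as.integer(k), s2 = as.integer(s))
  for (s1 in s1_range) for (k1 in seq_len(K1)) for (k2 in seq_len(K2)) {
    s2min <- s1 + m + gap
    if (s2min > smax) next
    for (s2 in s2min:smax)
      cand[[length(cand) + 1L]] <- list(
        lp = unname(lt1[k1 + 1] + lt2[k2 + 1] +
                      emit(model$components_first[[k1]], s1) +
                      emit(model$components_second[[k2]], s2) + lp_pair),
        c1 = as.integer(k1), s1 = as.integer(s1),
        c2 = as.integer(k2), s2 = as.integer(s2))
  }
  lps <- vapply(cand, `[[`, numeric(1), "lp")
  best <- cand[[1]]
  for (i in seq_along(cand))
    if (cand[[i]]$lp > best$lp + 1e-12) best <- cand[[i]]
  mx <- max(lps)
  list(logprob = unname(bg_ll + best$lp),
       c1 = best$c1, s1 = best$s1, c2 = best$c2, s2 = best$s2,
       forward = unname(bg_ll + mx + log(sum(exp(lps - mx)))))
}

# Random promoter HMM for the oracle-equivalence tests.
random_hmm <- function(cfg, seed) {
  set.seed(seed)
  rand_em <- function() {
    e <- matrix(stats::rgamma(cfg$motif_length * 4L, 1), ncol = 4L)
    e / rowSums(e)
  }
  rand_tau <- function(K) { t <- stats::rgamma(K + 1L, 1); t / sum(t) }
  bg <- stats::rgamma(4L, 1); bg <- bg / sum(bg)
  promoter_hmm(
    bg,
    replicate(cfg$n_components_first, rand_em(), simplify = FALSE),
    replicate(cfg$n_components_second, rand_em(), simplify = FALSE),
    rand_tau(cfg$n_components_first), rand_tau(cfg$n_components_second),
    cfg
  )
}

random_dna <- function(L, p = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
        collapse = "")
}
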