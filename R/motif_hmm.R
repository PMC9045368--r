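## Two-motif-set promoter HMM: constrained Viterbi decoding, Viterbi
## training with random restarts, and the two-phase discovery protocol
## (phase 1: 0 upstream + 5 downstream components to find the -10 motif;
## phase 2: 5 upstream + 1 downstream component, the downstream one seeded
## from the dominant phase-1 component, to find the -35 motif).
##
## The model: two ordered sets of alternative position-specific motif
## components (length `motif_length` each), every non-motif position
## emitting from one shared homogeneous background distribution. Each set
## may be skipped. A path is fully determined by the component choice and
## start position of each set, subject to: the first present motif starts
## at or after `first_motif_offset` (window index, 0-based), and when both
## are present the second starts at least `motif_length + min_motif_gap`
## after the first. The prior over legal placements given the skip pattern
## is uniform, so decoding maximizes emission log-odds plus the
## component-choice log-probabilities.

.HMM_ALPHABET <- c("A", "C", "G", "T")

#' Configuration of the promoter motif HMM
#'
#' @param motif_length length of every motif component in bp.
#' @param first_motif_offset minimum 0-based window index of the first
#'   present motif (40 confines search to the -50..+10 subwindow of a
#'   -90..+10 promoter).
#' @param min_motif_gap minimum number of background positions between the
#'   two motifs.
#' @param n_components_first,n_components_second number of alternative motif
#'   components in the upstream (-35 side) and downstream (-10 side) sets
#'   (0..5).
#' @param n_restarts random restarts of Viterbi training.
#' @param max_iterations iteration cap per restart.
#' @param pseudo_count added to all emission/usage counts at re-estimation.
#' @param seed base RNG seed; restart r uses `seed + r - 1`.
#' @return list of class `hmm_config`.
#' @export
hmm_config <- function(motif_length = 10L, first_motif_offset = 40L,
                       min_motif_gap = 10L, n_components_first = 0L,
                       n_components_second = 5L, n_restarts = 100L,
                       max_iterations = 100L, pseudo_count = 0.5,
                       seed = 42L) {
  if (motif_length < 1L) stop("motif_length must be >= 1")
  if (first_motif_offset < 0L || min_motif_gap < 0L)
    stop("offset and gap must be >= 0")
  if (n_components_first < 0L || n_components_first > 5L ||
      n_components_second < 0L || n_components_second > 5L)
    stop("component counts must be in 0..5")
  if (n_restarts < 1L || max_iterations < 1L)
    stop("n_restarts and max_iterations must be positive")
  if (pseudo_count <= 0) stop("pseudo_count must be positive")
  structure(list(
    motif_length = as.integer(motif_length),
    first_motif_offset = as.integer(first_motif_offset),
    min_motif_gap = as.integer(min_motif_gap),
    n_components_first = as.integer(n_components_first),
    n_components_second = as.integer(n_components_second),
    n_restarts = as.integer(n_restarts),
    max_iterations = as.integer(max_iterations),
    pseudo_count = pseudo_count, seed = as.integer(seed)
  ), class = "hmm_config")
}

## encode sequences as an n x L integer matrix, 0..3 = A,C,G,T, 4 = N/other
.encode_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  x <- toupper(as.character(x))
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("all promoter sequences must have the same length")
  chars <- matrix(unlist(strsplit(x, "")), nrow = length(x), byrow = TRUE)
  codes <- match(chars, .HMM_ALPHABET) - 1L
  codes[is.na(codes)] <- 4L
  matrix(codes, nrow = length(x))
}

## uniform placement-prior log terms for a given sequence length
.placement_prior <- function(L, cfg) {
  m <- cfg$motif_length
  smax <- L - m
  S <- smax - cfg$first_motif_offset + 1L
  if (S <= 0L)
    stop("sequences shorter than the minimum motif footprint (",
         cfg$first_motif_offset + m, " nt)")
  s1 <- cfg$first_motif_offset:smax
  n_pair <- sum(pmax(0L, smax - (s1 + m + cfg$min_motif_gap) + 1L))
  list(lp_single = -log(S), lp_pair = if (n_pair > 0) -log(n_pair) else -Inf)
}

#' Construct a promoter HMM from explicit parameters
#'
#' Mostly useful for tests and for loading stored models; training models is
#' done with [viterbi_train()].
#'
#' @param background emission probabilities over A,C,G,T shared by all
#'   non-motif states.
#' @param components_first,components_second lists of `motif_length` x 4
#'   emission matrices (rows = motif positions, columns = A,C,G,T).
#' @param tau_first,tau_second component-choice probabilities of each set;
#'   element 1 is the skip path, elements 2..K+1 the components. Each must
#'   sum to 1.
#' @param cfg the [hmm_config()] the model was built under.
#' @return object of class `promoter_hmm`.
#' @export
promoter_hmm <- function(background, components_first, components_second,
                         tau_first, tau_second, cfg) {
  background <- background / sum(background)
  names(background) <- .HMM_ALPHABET
  check_em <- function(e) {
    stopifnot(is.matrix(e), nrow(e) == cfg$motif_length, ncol(e) == 4L)
    stopifnot(all(abs(rowSums(e) - 1) < 1e-9))
    colnames(e) <- .HMM_ALPHABET
    e
  }
  components_first <- lapply(components_first, check_em)
  components_second <- lapply(components_second, check_em)
  stopifnot(length(tau_first) == length(components_first) + 1L,
            length(tau_second) == length(components_second) + 1L,
            abs(sum(tau_first) - 1) < 1e-9,
            abs(sum(tau_second) - 1) < 1e-9)
  structure(list(background = background,
                 components_first = components_first,
                 components_second = components_second,
                 tau_first = tau_first, tau_second = tau_second,
                 cfg = cfg),
            class = "promoter_hmm")
}

#' @export
print.promoter_hmm <- function(x, ...) {
  cat("promoter_hmm:", length(x$components_first), "upstream +",
      length(x$components_second), "downstream components, motif length",
      x$cfg$motif_length, "\n")
  invisible(x)
}

## random initialization for one restart: Dirichlet(1) motif emissions,
## empirical background, uniform component choices
.init_model <- function(cfg, X, seed, init_second = NULL) {
  set.seed(seed)
  base_tab <- tabulate(X + 1L, nbins = 5L)[1:4]
  background <- (base_tab + 1) / sum(base_tab + 4)
  rand_em <- function() {
    e <- matrix(stats::rgamma(cfg$motif_length * 4L, shape = 1), ncol = 4L)
    e / rowSums(e)
  }
  comp1 <- replicate(cfg$n_components_first, rand_em(), simplify = FALSE)
  comp2 <- replicate(cfg$n_components_second, rand_em(), simplify = FALSE)
  if (!is.null(init_second)) {
    stopifnot(length(init_second) <= length(comp2))
    comp2[seq_along(init_second)] <- init_second
  }
  promoter_hmm(background, comp1, comp2,
               rep(1, cfg$n_components_first + 1L) /
                 (cfg$n_components_first + 1L),
               rep(1, cfg$n_components_second + 1L) /
                 (cfg$n_components_second + 1L),
               cfg)
}

## decode an encoded matrix under a model; returns the raw placement table
.decode <- function(X, model) {
  cfg <- model$cfg
  L <- ncol(X)
  pp <- .placement_prior(L, cfg)
  lb <- log(model$background)
  lodds <- function(e) sweep(log(e), 2L, lb, `-`)
  D1 <- lapply(model$components_first, lodds)
  D2 <- lapply(model$components_second, lodds)
  res <- decode_promoters_cpp(X, D1, D2,
                              log(model$tau_first), log(model$tau_second),
                              cfg$first_motif_offset, cfg$min_motif_gap,
                              cfg$motif_length, pp$lp_single, pp$lp_pair)
  lookup <- c(lb, 0)                    # N emits with log-probability 0
  bg_ll <- rowSums(matrix(lookup[X + 1L], nrow = nrow(X)))
  list(c1 = res$c1, s1 = res$s1, c2 = res$c2, s2 = res$s2,
       logprob = bg_ll + res$rel_lp, llr = res$llr)
}

## turn a raw placement table into the user-facing annotation data.frame
.annotate <- function(dec, seqs, names, cfg) {
  L <- unique(nchar(seqs))
  sub10 <- function(s, start) {        # start is 0-based or -1
    ifelse(start < 0L, NA_character_,
           substr(s, start + 1L, start + cfg$motif_length))
  }
  to_rel <- function(start) {
    if (L == 100L)
      ifelse(start < 0L, NA_integer_,
             window_index_to_relative(pmax(start, 0L)))
    else rep(NA_integer_, length(start))
  }
  data.frame(
    tss_name = names,
    component_first = ifelse(dec$c1 < 0L, NA_integer_, dec$c1 + 1L),
    start_first = ifelse(dec$s1 < 0L, NA_integer_, dec$s1),
    match_first = sub10(seqs, dec$s1),
    component_second = ifelse(dec$c2 < 0L, NA_integer_, dec$c2 + 1L),
    start_second = ifelse(dec$s2 < 0L, NA_integer_, dec$s2),
    match_second = sub10(seqs, dec$s2),
    m35_start = to_rel(dec$s1), m35_seq = sub10(seqs, dec$s1),
    m10_start = to_rel(dec$s2), m10_seq = sub10(seqs, dec$s2),
    viterbi_logprob = dec$logprob, llr = dec$llr,
    stringsAsFactors = FALSE
  )
}

#' Viterbi decoding of promoter sequences under a trained model
#'
#' Returns, per sequence, the maximum-log-probability legal path: chosen
#' component and 0-based start index of each motif set (`NA` when the skip
#' path wins), the matched 10-mers, the path log-probability, and the
#' log-likelihood ratio against the all-background (both sets skipped)
#' path. For 100-nt windows, TSS-relative starts (`m35_start`, `m10_start`)
#' are included. Ties are broken toward the skip path, then earlier motif
#' starts, then lower component indices.
#'
#' @param seqs promoter sequences ([Biostrings::DNAStringSet] or character),
#'   all of equal length.
#' @param model a [promoter_hmm()].
#' @return annotation data.frame, one row per sequence.
#' @export
viterbi <- function(seqs, model) {
  stopifnot(inherits(model, "promoter_hmm"))
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  X <- .encode_seqs(seqs)
  dec <- .decode(X, model)
  .annotate(dec, toupper(seqs), nm, model$cfg)
}

## re-estimate emissions and component-choice probabilities from the
## decoded paths (Viterbi training M-step, pseudo-count smoothed)
.reestimate <- function(X, dec, model, cfg) {
  pc <- cfg$pseudo_count
  m <- cfg$motif_length
  total_tab <- tabulate(X + 1L, nbins = 5L)[1:4]
  motif_tab <- numeric(4L)
  count_set <- function(comp_idx, starts, K) {
    out <- vector("list", K)
    for (k in seq_len(K)) {
      rows <- which(comp_idx == k - 1L)
      counts <- matrix(pc, nrow = m, ncol = 4L)
      if (length(rows) > 0L) {
        for (j in seq_len(m)) {
          v <- X[cbind(rows, starts[rows] + j)]
          tab <- tabulate(v + 1L, nbins = 5L)[1:4]
          counts[j, ] <- counts[j, ] + tab
          motif_tab <<- motif_tab + tab
        }
      }
      out[[k]] <- counts / rowSums(counts)
    }
    out
  }
  comp1 <- count_set(dec$c1, dec$s1, cfg$n_components_first)
  comp2 <- count_set(dec$c2, dec$s2, cfg$n_components_second)
  bg_tab <- pmax(total_tab - motif_tab, 0) + pc
  ## element 1 = skip (-1 in the decoded index), elements 2..K+1 = components
  tau_counts <- function(comp_idx, K) {
    counts <- c(sum(comp_idx < 0L),
                vapply(seq_len(K), function(k) sum(comp_idx == k - 1L),
                       numeric(1)))
    counts <- counts + pc
    counts / sum(counts)
  }
  promoter_hmm(bg_tab / sum(bg_tab), comp1, comp2,
               tau_counts(dec$c1, cfg$n_components_first),
               tau_counts(dec$c2, cfg$n_components_second),
               cfg)
}

#' Viterbi training with random restarts
#'
#' Each restart initializes motif emissions from per-position Dirichlet(1)
#' draws (background from the empirical base composition, component choices
#' uniform) under seed `cfg$seed + restart - 1`, then alternates decoding
#' all sequences with [viterbi()] and re-estimating emissions and
#' component-choice probabilities from the path-aligned counts
#' (pseudo-count smoothed) until no sequence changes its path or
#' `max_iterations` is reached. The restart with the highest total Viterbi
#' log-probability wins.
#'
#' @param promoters equal-length promoter sequences
#'   ([Biostrings::DNAStringSet] or character).
#' @param cfg an [hmm_config()].
#' @param init_second optional list of emission matrices used to initialize
#'   the first components of the second set in every restart (phase-2
#'   seeding from a phase-1 component).
#' @return list of class `viterbi_fit`: `model`, `annotations`, `logprob`
#'   (total Viterbi log-probability of the winning restart), `traces`
#'   (per-restart iteration traces of the total Viterbi log-probability),
#'   `objective_traces` (same, plus the pseudo-count regularizer; this
#'   penalized objective is the quantity each training step maximizes and
#'   is non-decreasing within every restart, whereas the raw Viterbi
#'   log-probability can dip on the order of the pseudo-count's pull),
#'   `restart_logprobs`, `best_restart`.
#' @export
viterbi_train <- function(promoters, cfg = hmm_config(),
                          init_second = NULL) {
  stopifnot(inherits(cfg, "hmm_config"))
  if (length(promoters) < 1L) stop("need at least one promoter")
  nm <- names(promoters)
  if (is.null(nm)) nm <- paste0("seq", seq_along(promoters))
  seqs <- if (inherits(promoters, "DNAStringSet")) as.character(promoters)
          else as.character(promoters)
  seqs <- toupper(seqs)
  X <- .encode_seqs(seqs)
  .placement_prior(ncol(X), cfg)        # validates the footprint up front

  ## pseudo-count regularizer: the M-step maximizes complete-data
  ## log-likelihood plus this term, making the penalized objective monotone
  penalty <- function(model) {
    cfg$pseudo_count * (sum(log(model$background)) +
      sum(vapply(c(model$components_first, model$components_second),
                 function(e) sum(log(e)), numeric(1))) +
      sum(log(model$tau_first)) + sum(log(model$tau_second)))
  }

  best <- NULL
  traces <- vector("list", cfg$n_restarts)
  obj_traces <- vector("list", cfg$n_restarts)
  restart_lp <- numeric(cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    model <- .init_model(cfg, X, cfg$seed + r - 1L, init_second)
    prev_paths <- NULL
    trace <- numeric(0)
    obj_trace <- numeric(0)
    dec <- NULL
    for (it in seq_len(cfg$max_iterations)) {
      dec <- .decode(X, model)
      trace <- c(trace, sum(dec$logprob))
      obj_trace <- c(obj_trace, sum(dec$logprob) + penalty(model))
      paths <- cbind(dec$c1, dec$s1, dec$c2, dec$s2)
      if (!is.null(prev_paths) && identical(paths, prev_paths)) break
      prev_paths <- paths
      if (it < cfg$max_iterations)
        model <- .reestimate(X, dec, model, cfg)
    }
    traces[[r]] <- trace
    obj_traces[[r]] <- obj_trace
    restart_lp[r] <- trace[length(trace)]
    if (is.null(best) || restart_lp[r] > best$logprob)
      best <- list(model = model, dec = dec, logprob = restart_lp[r],
                   restart = r)
  }
  structure(list(
    model = best$model,
    annotations = .annotate(best$dec, seqs, nm, cfg),
    logprob = best$logprob, traces = traces,
    objective_traces = obj_traces,
    restart_logprobs = restart_lp, best_restart = best$restart
  ), class = "viterbi_fit")
}

#' @export
print.viterbi_fit <- function(x, ...) {
  cat("viterbi_fit:", nrow(x$annotations), "promoters, total Viterbi",
      "log-probability", format(x$logprob), "(best of",
      length(x$restart_logprobs), "restarts)\n")
  invisible(x)
}

#' Two-phase motif discovery
#'
#' Phase 1 trains a model with 0 upstream and `n_components_phase1`
#' downstream components (the -10 search, confined by the offset to the
#' -50..+10 subwindow of a -90..+10 promoter) from `restarts_phase1` random
#' initializations. The downstream component matched by the largest number
#' of promoters is the dominant (-10) component; promoters whose Viterbi
#' path uses it are selected. Phase 2 trains a model with
#' `n_components_phase2` upstream components and a single downstream
#' component, initialized from the dominant phase-1 component, on the
#' selected promoters from `restarts_phase2` random initializations.
#'
#' @param promoters equal-length promoter windows.
#' @param motif_length,first_motif_offset,min_motif_gap,max_iterations,
#'   pseudo_count,seed see [hmm_config()].
#' @param n_components_phase1 downstream components in phase 1.
#' @param n_components_phase2 upstream components in phase 2.
#' @param restarts_phase1,restarts_phase2 random restarts per phase.
#' @return list: `phase1` and `phase2` ([viterbi_train()] fits),
#'   `dominant_component` (phase-1 second-set component index),
#'   `selected` (names of promoters entering phase 2).
#' @export
two_phase_discovery <- function(promoters, motif_length = 10L,
                                first_motif_offset = 40L,
                                min_motif_gap = 10L,
                                n_components_phase1 = 5L,
                                n_components_phase2 = 5L,
                                restarts_phase1 = 100L,
                                restarts_phase2 = 500L,
                                max_iterations = 100L, pseudo_count = 0.5,
                                seed = 42L) {
  nm <- names(promoters)
  if (is.null(nm)) {
    nm <- paste0("seq", seq_along(promoters))
    names(promoters) <- nm
  }
  cfg1 <- hmm_config(motif_length, first_motif_offset, min_motif_gap,
                     n_components_first = 0L,
                     n_components_second = n_components_phase1,
                     n_restarts = restarts_phase1,
                     max_iterations = max_iterations,
                     pseudo_count = pseudo_count, seed = seed)
  phase1 <- viterbi_train(promoters, cfg1)
  used <- phase1$annotations$component_second
  if (all(is.na(used)))
    stop("degenerate result: no promoter matches any phase-1 component")
  tab <- table(factor(used, levels = seq_len(n_components_phase1)))
  dominant <- as.integer(names(tab)[which.max(tab)])
  sel <- !is.na(used) & used == dominant
  selected <- promoters[sel]
  cfg2 <- hmm_config(motif_length, first_motif_offset, min_motif_gap,
                     n_components_first = n_components_phase2,
                     n_components_second = 1L,
                     n_restarts = restarts_phase2,
                     max_iterations = max_iterations,
                     pseudo_count = pseudo_count, seed = seed + 1L)
  phase2 <- viterbi_train(selected, cfg2,
                          init_second =
                            phase1$model$components_second[dominant])
  list(phase1 = phase1, phase2 = phase2, dominant_component = dominant,
       selected = nm[sel])
}

#' Histogram of motif start positions per component
#'
#' @param annotations annotation data.frame from [viterbi()] or
#'   [viterbi_train()].
#' @return data.frame with columns `set` ("first"/"second"), `component`,
#'   `start` (0-based window index) and `n`.
#' @export
positional_histogram <- function(annotations) {
  one <- function(set, comp, start) {
    keep <- !is.na(comp)
    if (!any(keep))
      return(data.frame(set = character(0), component = integer(0),
                        start = integer(0), n = integer(0)))
    tab <- as.data.frame(table(component = comp[keep], start = start[keep]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    data.frame(set = set, component = as.integer(tab$component),
               start = as.integer(tab$start), n = as.integer(tab$Freq))
  }
  out <- rbind(
    one("first", annotations$component_first, annotations$start_first),
    one("second", annotations$component_second, annotations$start_second)
  )
  out <- out[order(out$set, out$component, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus sequence of a motif component
#'
#' Per-position argmax of the emission matrix (ties broken toward A < C <
#' G < T).
#'
#' @param model a [promoter_hmm()].
#' @param set `"first"` or `"second"`.
#' @param component component index.
#' @return character scalar.
#' @export
hmm_consensus <- function(model, set = c("second", "first"), component = 1L) {
  set <- match.arg(set)
  comp <- if (set == "first") model$components_first[[component]]
          else model$components_second[[component]]
  paste(.HMM_ALPHABET[apply(comp, 1L, which.max)], collapse = "")
}

#' Save a promoter HMM as JSON
#'
#' @param model a [promoter_hmm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
hmm_to_json <- function(model, path) {
  x <- list(
    background = as.list(model$background),
    components_first = lapply(model$components_first, unclass),
    components_second = lapply(model$components_second, unclass),
    tau_first = model$tau_first, tau_second = model$tau_second,
    cfg = unclass(model$cfg)
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a promoter HMM from JSON
#'
#' @param path file written by [hmm_to_json()].
#' @return a [promoter_hmm()].
#' @export
hmm_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(hmm_config, x$cfg)
  as_mat <- function(rows)
    do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  comp1 <- lapply(x$components_first, as_mat)
  comp2 <- lapply(x$components_second, as_mat)
  promoter_hmm(unlist(x$background), comp1, comp2,
               unlist(x$tau_first), unlist(x$tau_second), cfg)
}
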