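## Synthetic benchmark generator: plants sigma-70-style promoters into a
## random high-GC replicon and simulates replicate 5'-end read-start tracks
## (enriched TSS library + non-enriched control) with the statistical
## structure the pipeline assumes: reads concentrated at true TSSs with
## rounded Gaussian start jitter truncated to +/-5 bp, a uniform
## processed-end background, and Poisson replicate noise.

#' Configuration of the synthetic benchmark
#'
#' Defaults emulate the study conditions the pipeline targets: a high-GC
#' betaproteobacterial base composition, -35 elements at -35.6 +/- 1.6 with
#' 15.8 +/- 1.4 bp spacers, +/-1 bp start jitter (truncated at the 5 bp
#' cluster radius), three biological replicates, 100x 5'-triphosphate
#' enrichment over the control, and strongly expressed promoters (mean 500
#' reads per TSS out of a 5e6-read library).
#'
#' @param replicon_length replicon size in bp.
#' @param gc_fraction GC content of the random background sequence.
#' @param n_promoters promoters planted (on both strands).
#' @param m35_mutation_rate,m10_mutation_rate per-position probability of
#'   mutating the planted TTGACA / TATAAT hexamer away from consensus.
#' @param m35_pos_mean,m35_pos_sd distribution of the -35 hexamer start
#'   (TSS-relative, clamped to -39..-31).
#' @param spacer_mean,spacer_sd distribution of the spacer (clamped so the
#'   -10 model start stays in -18..-10).
#' @param tss_jitter_sd SD (bp) of the rounded Gaussian read-start jitter,
#'   truncated to +/-5 bp.
#' @param reads_per_tss_mean Poisson mean of enriched-library reads per TSS
#'   per replicate.
#' @param background_rate processed-end reads per bp per strand.
#' @param n_replicates biological replicates.
#' @param enrichment_factor ratio of enriched to control capture of true
#'   starts.
#' @param total_reads library size (the RRS denominator N); the simulated
#'   replicon is a small window of a full library.
#' @param min_separation minimum bp between planted TSSs.
#' @param replicon_id replicon name (must end in a digit for TSS naming).
#' @param seed RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(replicon_length = 50000L, gc_fraction = 0.635,
                             n_promoters = 100L, m35_mutation_rate = 0.1,
                             m10_mutation_rate = 0.1,
                             m35_pos_mean = -35.6, m35_pos_sd = 1.6,
                             spacer_mean = 15.8, spacer_sd = 1.4,
                             tss_jitter_sd = 1, reads_per_tss_mean = 500,
                             background_rate = 0.02, n_replicates = 3L,
                             enrichment_factor = 100, total_reads = 5e6,
                             min_separation = 250L,
                             replicon_id = "SYNREP1", seed = 1L) {
  stopifnot(replicon_length > 500L, gc_fraction >= 0, gc_fraction <= 1,
            n_promoters >= 0L,
            m35_mutation_rate >= 0, m35_mutation_rate <= 1,
            m10_mutation_rate >= 0, m10_mutation_rate <= 1,
            tss_jitter_sd >= 0, reads_per_tss_mean >= 0,
            background_rate >= 0, n_replicates >= 1L,
            enrichment_factor > 0, total_reads > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

## mutate each base of `seq` away from itself with probability `rate`
.mutate_seq <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit))
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(bases, collapse = "")
}

.random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## write `seq` into the genome at TSS-relative start `rel` (negative), on
## `strand`, around TSS `pos`; returns the modified character vector
.plant <- function(genome_chars, pos, strand, rel, seq) {
  bases <- strsplit(seq, "")[[1]]
  len <- length(bases)
  if (strand == "+") {
    fwd_from <- pos + rel                 # rel < 0, motif stays upstream
    genome_chars[fwd_from:(fwd_from + len - 1L)] <- bases
  } else {
    fwd_from <- pos - (rel + len - 1L)    # motif on the reverse strand
    genome_chars[fwd_from:(fwd_from + len - 1L)] <-
      rev(unname(.REVCOMP[bases]))
  }
  genome_chars
}

#' Generate a synthetic TSS-calling benchmark
#'
#' Builds a random replicon, plants `n_promoters` promoters (consensus
#' hexamers mutated at the configured rates, geometry drawn from the
#' configured position/spacer distributions), and simulates per-replicate
#' enriched and control read-start tracks. The ground truth carries the
#' exact planted hexamers, so the RpoD scores of planted promoters are
#' computable analytically with [rpod_score()].
#'
#' @param config a [synthetic_config()].
#' @return list: `genome` (named [Biostrings::DNAStringSet]), `truth`
#'   (data.frame: `replicon`, `position`, `strand`, `m35_start`, `m35_seq`,
#'   `m10_start`, `m10_seq`, `spacer`, `score`, `strength`), `replicates`
#'   (per replicate, lists `tss` and `control` of [read_start_profile()]s
#'   keyed by strand), and `config`.
#' @export
generate_tss_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  L <- config$replicon_length
  genome_chars <- .random_bases(L, config$gc_fraction)

  ## place TSSs with a minimum separation, away from the replicon ends
  positions <- integer(0); strands <- character(0)
  attempts <- 0L
  while (length(positions) < config$n_promoters) {
    p <- sample(101:(L - 100L), 1L)
    if (all(abs(p - positions) >= config$min_separation)) {
      positions <- c(positions, p)
      strands <- c(strands, sample(c("+", "-"), 1L))
      attempts <- 0L
    } else {
      attempts <- attempts + 1L
      if (attempts >= 1000L)
        stop("could not place ", config$n_promoters, " promoters ",
             config$min_separation, " bp apart after 1000 attempts")
    }
  }
  o <- order(positions); positions <- positions[o]; strands <- strands[o]

  n <- config$n_promoters
  m35_start <- pmin(pmax(round(stats::rnorm(n, config$m35_pos_mean,
                                            config$m35_pos_sd)), -39L), -31L)
  spacer <- round(stats::rnorm(n, config$spacer_mean, config$spacer_sd))
  m10_start <- pmin(pmax(m35_start + 6L + spacer, -18L), -10L)
  spacer <- abs(m35_start) - 6L - abs(m10_start)
  m35_seq <- character(n); m10_seq <- character(n)
  for (i in seq_len(n)) {
    m35_seq[i] <- .mutate_seq("TTGACA", config$m35_mutation_rate)
    m10_seq[i] <- paste0("TG", .mutate_seq("TATAAT",
                                           config$m10_mutation_rate),
                         paste(.random_bases(2L, config$gc_fraction),
                               collapse = ""))
    genome_chars <- .plant(genome_chars, positions[i], strands[i],
                           m35_start[i], m35_seq[i])
    genome_chars <- .plant(genome_chars, positions[i], strands[i],
                           m10_start[i], m10_seq[i])
  }

  sc <- rpod_score(m35_start, m35_seq, m10_start, m10_seq)
  truth <- data.frame(
    replicon = rep(config$replicon_id, n), position = positions,
    strand = strands,
    m35_start = m35_start, m35_seq = m35_seq,
    m10_start = m10_start, m10_seq = m10_seq,
    spacer = spacer, score = sc$score,
    strength = classify_strength(sc$score),
    stringsAsFactors = FALSE
  )

  jitter_reads <- function(center, strand, n_reads) {
    if (n_reads == 0L) return(integer(0))
    off <- pmin(pmax(round(stats::rnorm(n_reads, 0, config$tss_jitter_sd)),
                     -5L), 5L)
    center + if (strand == "+") off else -off
  }
  track <- function(per_tss_mean) {
    counts <- list(`+` = integer(L), `-` = integer(L))
    for (s in c("+", "-")) {
      nbg <- stats::rpois(1L, config$background_rate * L)
      bg <- tabulate(sample.int(L, nbg, replace = TRUE), nbins = L)
      counts[[s]] <- counts[[s]] + bg
    }
    for (i in seq_len(n)) {
      nr <- stats::rpois(1L, per_tss_mean)
      reads <- jitter_reads(positions[i], strands[i], nr)
      counts[[strands[i]]] <- counts[[strands[i]]] +
        tabulate(reads, nbins = L)
    }
    out <- lapply(c("+", "-"), function(s) {
      nz <- which(counts[[s]] > 0L)
      read_start_profile(config$replicon_id, strand = s,
                         positions = nz, counts = counts[[s]][nz],
                         total_reads = config$total_reads)
    })
    names(out) <- c("+", "-")
    out
  }
  replicates <- lapply(seq_len(config$n_replicates), function(r) {
    tss_tracks <- track(config$reads_per_tss_mean)
    ctrl_tracks <- track(config$reads_per_tss_mean /
                           config$enrichment_factor)
    list(tss = tss_tracks, control = ctrl_tracks)
  })

  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- config$replicon_id
  list(genome = genome, truth = truth, replicates = replicates,
       config = config)
}

#' Generate synthetic promoter windows for motif-discovery benchmarks
#'
#' Builds `n` random 100-nt windows; a fraction `frac_major` carry a planted
#' -35 10-mer at window index 55 (TSS-relative -35) and a planted -10
#' 10-mer at index 77 (-13), both shifted together by a per-promoter
#' integer jitter, the remainder carry a decoy 10-mer at index 70 instead.
#' Planted 10-mers are mutated per position at `mutation_rate`.
#'
#' @param n number of windows.
#' @param frac_major fraction carrying the major promoter architecture.
#' @param m35_10mer,m10_10mer,decoy_10mer planted 10-mers; the defaults
#'   embed TTGACA at the -35 and TG+TATAAT (extended -10) at the -10.
#' @param mutation_rate per-position mutation probability.
#' @param jitter maximum absolute shift (uniform on `-jitter..jitter`).
#' @param gc_fraction background composition.
#' @param seed RNG seed.
#' @return list: `seqs` (named [Biostrings::DNAStringSet]), `truth`
#'   (data.frame: `name`, `class`, `shift`, `m35_idx`, `m10_idx`).
#' @export
synthetic_promoter_windows <- function(n, frac_major = 0.8,
                                       m35_10mer = "TTGACAGCGG",
                                       m10_10mer = "TGTATAATGG",
                                       decoy_10mer = "GCCGTTAACG",
                                       mutation_rate = 0.05, jitter = 1L,
                                       gc_fraction = 0.635, seed = 1L) {
  set.seed(seed)
  n_major <- round(n * frac_major)
  cls <- c(rep("major", n_major), rep("decoy", n - n_major))
  seqs <- character(n)
  shift <- integer(n); m35_idx <- integer(n); m10_idx <- integer(n)
  for (i in seq_len(n)) {
    chars <- .random_bases(100L, gc_fraction)
    shift[i] <- sample(seq(-jitter, jitter), 1L)
    if (cls[i] == "major") {
      m35_idx[i] <- 55L + shift[i]
      m10_idx[i] <- 77L + shift[i]
      chars[m35_idx[i] + 1:10] <-
        strsplit(.mutate_seq(m35_10mer, mutation_rate), "")[[1]]
      chars[m10_idx[i] + 1:10] <-
        strsplit(.mutate_seq(m10_10mer, mutation_rate), "")[[1]]
    } else {
      m35_idx[i] <- NA_integer_
      m10_idx[i] <- 70L + shift[i]
      chars[m10_idx[i] + 1:10] <-
        strsplit(.mutate_seq(decoy_10mer, mutation_rate), "")[[1]]
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("prom%04d", seq_len(n))
  list(seqs = out,
       truth = data.frame(name = names(out), class = cls, shift = shift,
                          m35_idx = m35_idx, m10_idx = m10_idx,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic benchmark to disk
#'
#' Emits the replicon FASTA, the ground-truth TSV and one bedGraph per
#' replicate/library/strand, reproducibly (identical config, identical
#' bytes).
#'
#' @param sim result of [generate_tss_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_result_table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     "ground_truth")
  strand_tag <- c(`+` = "plus", `-` = "minus")
  for (r in seq_along(sim$replicates)) {
    for (lib in c("tss", "control")) {
      for (s in c("+", "-")) {
        write_bedgraph(sim$replicates[[r]][[lib]][[s]],
                       file.path(dir, sprintf("rep%d_%s_%s.bedGraph",
                                              r, lib, strand_tag[[s]])))
      }
    }
  }
  invisible(dir)
}
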