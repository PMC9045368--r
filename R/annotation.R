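## Linking TSSs to downstream genes and the transcript-responsibility
## heuristic (a responsible promoter's TSS score lies within 3-fold of the
## downstream gene's NPKM).

#' Build a gene table from a GFF3 file and an expression table
#'
#' @param gff_path GFF3 file of gene features; the `locus_tag` attribute (or
#'   `ID` as fallback) identifies each gene.
#' @param expression data.frame with columns `locus_tag` and `npkm`, or a
#'   path to a TSV with those columns.
#' @param feature_type GFF3 feature type to keep.
#' @return data.frame with columns `locus_tag`, `replicon`, `strand`,
#'   `start`, `end`, `npkm` (NA when the expression table lacks the gene).
#' @export
read_genes <- function(gff_path, expression = NULL, feature_type = "gene") {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
  lt <- S4Vectors::mcols(gr)$locus_tag
  if (is.null(lt)) lt <- S4Vectors::mcols(gr)$ID
  genes <- data.frame(
    locus_tag = as.character(lt),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(expression)) {
    if (is.character(expression))
      expression <- utils::read.table(expression, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
    genes$npkm <- expression$npkm[match(genes$locus_tag,
                                        expression$locus_tag)]
  } else genes$npkm <- NA_real_
  genes
}

#' Link TSSs to the nearest same-strand downstream gene start
#'
#' The gene start is `start` on the plus strand and `end` on the minus
#' strand; the distance is measured from the TSS to the gene start and must
#' be in `[0, max_distance]`. Ties (two genes starting equidistant) are
#' broken toward the lexicographically smaller locus tag. TSSs with no
#' qualifying gene are emitted with an empty locus.
#'
#' @param tss TSS record data.frame (`name`, `replicon`, `position`,
#'   `strand`, optionally `mean_score`).
#' @param genes gene data.frame from [read_genes()] (columns `locus_tag`,
#'   `replicon`, `strand`, `start`, `end`, optionally `npkm`).
#' @param max_distance maximum linking distance in bp.
#' @return data.frame with columns `tss_name`, `locus_tag`, `distance_bp`,
#'   `npkm`.
#' @export
assign_tss_to_genes <- function(tss, genes, max_distance = 5000L) {
  if (any(genes$start > genes$end)) stop("gene with start > end")
  n <- nrow(tss)
  locus <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  npkm <- rep(NA_real_, n)
  has_npkm <- !is.null(genes$npkm)
  for (i in seq_len(n)) {
    g <- genes[genes$replicon == tss$replicon[i] &
                 genes$strand == tss$strand[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    gstart <- if (tss$strand[i] == "+") g$start else g$end
    d <- if (tss$strand[i] == "+") gstart - tss$position[i]
         else tss$position[i] - gstart
    ok <- d >= 0L & d <= max_distance
    if (!any(ok)) next
    g <- g[ok, , drop = FALSE]; d <- d[ok]
    pick <- order(d, g$locus_tag)[1L]
    locus[i] <- g$locus_tag[pick]
    dist[i] <- d[pick]
    if (has_npkm) npkm[i] <- g$npkm[pick]
  }
  data.frame(tss_name = tss$name, locus_tag = locus, distance_bp = dist,
             npkm = npkm, stringsAsFactors = FALSE)
}

#' Transcript-responsibility heuristic
#'
#' A promoter is deemed responsible for (or contributing to) the transcript
#' level of its downstream gene when its TSS quality score lies within
#' 3-fold of the gene's NPKM: `npkm/3 <= score <= 3*npkm`. The
#' accompanying ratio `log10(npkm) / log10(score)` is reported only when
#' both values exceed 1 (log10 of either would otherwise be non-positive
#' and the ratio sign-flips).
#'
#' @param score positive TSS quality scores.
#' @param npkm non-negative transcript abundances.
#' @return data.frame with columns `responsible` (logical) and `log_ratio`.
#' @export
responsibility <- function(score, npkm) {
  n <- max(length(score), length(npkm))
  score <- rep_len(as.numeric(score), n)
  npkm <- rep_len(as.numeric(npkm), n)
  if (any(!is.na(score) & score <= 0)) stop("score must be positive")
  if (any(!is.na(npkm) & npkm < 0)) stop("npkm must be non-negative")
  responsible <- !is.na(score) & !is.na(npkm) & npkm > 0 &
    score >= npkm / 3 & score <= 3 * npkm
  ratio_ok <- !is.na(score) & !is.na(npkm) & score > 1 & npkm > 1
  log_ratio <- ifelse(ratio_ok, log10(npkm) / log10(score), NA_real_)
  data.frame(responsible = responsible, log_ratio = log_ratio)
}

#' Merge TSS records, gene links and RpoD calls into one table
#'
#' @param tss TSS record data.frame.
#' @param genes gene data.frame from [read_genes()].
#' @param rpod optional RpoD call data.frame from [score_promoters()]
#'   (matched by `tss_name`).
#' @param max_distance maximum gene-linking distance in bp.
#' @return one row per TSS: coordinates, mean score, RpoD tier, linked gene,
#'   distance, NPKM, responsibility flag and log ratio.
#' @export
annotate_tss <- function(tss, genes, rpod = NULL, max_distance = 5000L) {
  links <- assign_tss_to_genes(tss, genes, max_distance)
  out <- data.frame(
    name = tss$name, replicon = tss$replicon, position = tss$position,
    strand = tss$strand,
    mean_score = if (!is.null(tss$mean_score)) tss$mean_score else NA_real_,
    tier = NA_character_,
    locus_tag = links$locus_tag, distance_bp = links$distance_bp,
    npkm = links$npkm, stringsAsFactors = FALSE
  )
  if (!is.null(rpod)) {
    idx <- match(out$name, rpod$tss_name)
    out$tier <- rpod$tier[idx]
    out$rpod_score <- rpod$score[idx]
    out$strength <- rpod$strength[idx]
    out$category <- rpod$category[idx]
  }
  resp <- responsibility(pmax(out$mean_score, .Machine$double.eps),
                         ifelse(is.na(out$npkm), 0, out$npkm))
  out$responsible <- ifelse(is.na(out$mean_score) | is.na(out$npkm),
                            NA, resp$responsible)
  out$log_ratio <- resp$log_ratio
  out
}
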