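## Strand-aware extraction of the -90..+10 promoter window around each TSS.
##
## Relative coordinates follow molecular-biology convention: the TSS is +1,
## the base immediately upstream is -1, and there is no position 0, so the
## window holds exactly 100 nt. Minus-strand windows are reverse-complemented
## so that the TSS-proximal end is always 3'.

.WINDOW_UP <- 90L     # bases upstream (-90..-1)
.WINDOW_DOWN <- 10L   # bases downstream including the TSS (+1..+10)
.WINDOW_LEN <- .WINDOW_UP + .WINDOW_DOWN

#' Extract the promoter window around one TSS
#'
#' Returns the 100-nt window covering relative positions -90..-1, +1..+10.
#' On the plus strand this is forward positions `position - 90` to
#' `position + 9`; on the minus strand the forward slice
#' `position - 9` to `position + 90` is taken and reverse-complemented.
#'
#' @param replicon a single DNA sequence ([Biostrings::DNAString], a
#'   length-one [Biostrings::DNAStringSet], or a character scalar).
#' @param position 1-based TSS coordinate (forward coordinate system on both
#'   strands).
#' @param strand `"+"` or `"-"`.
#' @return character scalar of length 100 over `A,C,G,T,N`.
#' @export
extract_window <- function(replicon, position, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (inherits(replicon, "DNAStringSet")) {
    stopifnot(length(replicon) == 1L)
    replicon <- replicon[[1]]
  }
  if (!inherits(replicon, "DNAString"))
    replicon <- Biostrings::DNAString(toupper(as.character(replicon)))
  len <- length(replicon)
  position <- as.integer(position)
  if (strand == "+") {
    from <- position - .WINDOW_UP
    to <- position + .WINDOW_DOWN - 1L
  } else {
    from <- position - .WINDOW_DOWN + 1L
    to <- position + .WINDOW_UP
  }
  if (from < 1L || to > len)
    stop("window-out-of-bounds: -90..+10 region of position ", position,
         " (", strand, ") extends beyond the replicon [1, ", len, "]")
  win <- Biostrings::subseq(replicon, from, to)
  if (strand == "-") win <- Biostrings::reverseComplement(win)
  as.character(win)
}

#' Extract promoter windows for a TSS table
#'
#' TSSs whose window would extend beyond a replicon end are dropped with a
#' warning (mirroring the treatment of replicon-terminal TSSs), and their
#' names are recorded in the `dropped` attribute of the result.
#'
#' @param genome [Biostrings::DNAStringSet] of replicon sequences, named by
#'   replicon id.
#' @param tss TSS record data.frame with columns `name`, `replicon`,
#'   `position`, `strand`.
#' @return [Biostrings::DNAStringSet] of 100-nt windows named by TSS name.
#' @export
extract_promoters <- function(genome, tss) {
  stopifnot(inherits(genome, "DNAStringSet"))
  miss <- setdiff(unique(tss$replicon), names(genome))
  if (length(miss) > 0L)
    stop("replicon(s) absent from genome: ", paste(miss, collapse = ", "))
  seqs <- character(nrow(tss))
  ok <- logical(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    res <- tryCatch(
      extract_window(genome[[tss$replicon[i]]], tss$position[i],
                     tss$strand[i]),
      error = function(e) NULL
    )
    if (!is.null(res)) { seqs[i] <- res; ok[i] <- TRUE }
  }
  if (any(!ok))
    warning(sum(!ok), " TSS window(s) extended beyond a replicon end and ",
            "were dropped: ", paste(tss$name[!ok], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs[ok])
  names(out) <- tss$name[ok]
  attr(out, "dropped") <- tss$name[!ok]
  out
}

#' Convert TSS-relative positions to 0-based window indices
#'
#' The window index runs 0..99; relative position -90 maps to 0, -1 to 89,
#' +1 to 90 and +10 to 99. Position 0 does not exist.
#'
#' @param rel integer vector of relative positions in -90..-1 or +1..+10.
#' @return integer vector of 0-based window indices.
#' @export
relative_to_window_index <- function(rel) {
  rel <- as.integer(rel)
  bad <- is.na(rel) | rel == 0L | rel < -.WINDOW_UP | rel > .WINDOW_DOWN
  if (any(bad))
    stop("relative position(s) outside -90..-1, +1..+10: ",
         paste(rel[bad], collapse = ", "))
  ifelse(rel < 0L, rel + .WINDOW_UP, rel + .WINDOW_UP - 1L)
}

#' Convert 0-based window indices to TSS-relative positions
#'
#' Inverse of [relative_to_window_index()].
#'
#' @param idx integer vector of window indices in 0..99.
#' @return integer vector of relative positions (no 0).
#' @export
window_index_to_relative <- function(idx) {
  idx <- as.integer(idx)
  bad <- is.na(idx) | idx < 0L | idx >= .WINDOW_LEN
  if (any(bad))
    stop("window index(es) outside 0..99: ", paste(idx[bad], collapse = ", "))
  ifelse(idx < .WINDOW_UP, idx - .WINDOW_UP, idx - .WINDOW_UP + 1L)
}

#' Write promoter windows as FASTA
#'
#' @param promoters named [Biostrings::DNAStringSet] from
#'   [extract_promoters()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}
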