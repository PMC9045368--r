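## Shared readers/writers and the versioned TSV result schemas.

.SCHEMA_VERSION <- "v1"

## Required columns per schema; writers emit a "# sigmacall <schema> <version>"
## header comment and readers reject files that do not carry it.
.SCHEMAS <- list(
  tss = c("name", "replicon", "position", "strand", "mean_score",
          "score_sd", "rank"),
  annotations = c("tss_name", "component_first", "start_first", "match_first",
                  "component_second", "start_second", "match_second",
                  "m35_start", "m10_start", "viterbi_logprob", "llr"),
  rpod_calls = c("tss_name", "m35_start", "m35_seq", "m10_start", "m10_seq",
                 "s35", "s10", "pos_penalty", "spacer", "spacer_penalty",
                 "score", "strength", "category", "tier"),
  merged = c("name", "replicon", "position", "strand", "mean_score",
             "tier", "locus_tag", "distance_bp", "npkm", "responsible"),
  ground_truth = c("replicon", "position", "strand", "m35_start", "m35_seq",
                   "m10_start", "m10_seq", "spacer", "score", "strength"),
  histogram = c("set", "component", "start", "n"),
  housekeeping_promoters = c("rank", "model", "m35_start", "m35_seq",
                             "m10_start", "m10_seq", "locus_tag", "gene",
                             "printed_score")
)

#' Write a result table with a schema header
#'
#' All sigmacall result tables are tab-separated files whose first line is a
#' comment naming the schema and its version, so that downstream stages can
#' refuse tables they do not understand.
#'
#' @param x data.frame holding at least the schema's columns.
#' @param path output file path.
#' @param schema one of `r paste(names(sigmacall:::.SCHEMAS), collapse = ", ")`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  missing_cols <- setdiff(.SCHEMAS[[schema]], names(x))
  if (length(missing_cols) > 0L)
    stop("missing columns for schema '", schema, "': ",
         paste(missing_cols, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# sigmacall", schema, .SCHEMA_VERSION, sep = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table, checking its schema header
#'
#' @param path file written by [write_result_table()].
#' @param schema expected schema name; the read fails if the file's header
#'   names a different schema or an unknown version.
#' @return data.frame.
#' @export
read_result_table <- function(path, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  header <- readLines(path, n = 1L)
  parts <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  if (length(parts) != 3L || parts[1] != "sigmacall")
    stop("not a sigmacall result table: ", path)
  if (parts[2] != schema)
    stop("expected schema '", schema, "' but file carries '", parts[2], "'")
  if (parts[3] != .SCHEMA_VERSION)
    stop("unknown schema version '", parts[3], "' in ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SCHEMAS[[schema]], names(x))
  if (length(missing_cols) > 0L)
    stop("file lacks schema columns: ", paste(missing_cols, collapse = ", "))
  x
}

#' Read one strand's 5'-end counts from a bedGraph track
#'
#' bedGraph intervals are 0-based half-open; they are converted to 1-based
#' single positions, expanding multi-base intervals so that each covered base
#' receives the interval's count.
#'
#' @param path bedGraph file (4 columns) holding the counts of one library,
#'   one replicate, one strand.
#' @param strand `"+"` or `"-"`; bedGraph itself is strand-less, so the strand
#'   is supplied by the caller (conventionally from the file name).
#' @param total_reads total mapped reads of the library (the RRS denominator
#'   N). Defaults to the sum of the counts in the file, which is only
#'   appropriate when the file covers the whole library.
#' @return a list of [read_start_profile()] objects, one per replicon present
#'   in the file, named by replicon.
#' @export
read_bedgraph <- function(path, strand = c("+", "-"), total_reads = NULL) {
  strand <- match.arg(strand)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("failed to parse bedGraph '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  counts <- S4Vectors::mcols(gr)$score
  if (any(counts < 0)) stop("negative count in bedGraph '", path, "'")
  if (any(counts != round(counts)))
    stop("non-integer count in bedGraph '", path, "'")
  ## expand intervals to single 1-based positions
  widths <- GenomicRanges::width(gr)
  pos <- GenomicRanges::start(gr)  # rtracklayer already yields 1-based starts
  repl <- as.character(GenomicRanges::seqnames(gr))
  all_pos <- sequence(widths, from = pos)
  all_repl <- rep(repl, widths)
  all_counts <- rep(as.integer(counts), widths)
  keep <- all_counts > 0L
  all_pos <- all_pos[keep]; all_repl <- all_repl[keep]
  all_counts <- all_counts[keep]
  if (is.null(total_reads)) total_reads <- sum(all_counts)
  profiles <- lapply(split(seq_along(all_pos), all_repl), function(i) {
    read_start_profile(replicon_id = all_repl[i[1]], strand = strand,
                       positions = all_pos[i], counts = all_counts[i],
                       total_reads = total_reads)
  })
  profiles
}

#' Write a read-start profile as a bedGraph track
#'
#' @param profile a [read_start_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "read_start_profile"))
  df <- data.frame(chrom = profile$replicon_id,
                   start = profile$positions - 1L,
                   end = profile$positions,
                   count = profile$counts)
  df <- df[order(df$start), ]
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a TSS name into position, strand and replicon digit
#'
#' Names follow the schema `TSS_<position><strand><replicon digit>`, the
#' replicon being identified by the last digit of its accession (e.g.
#' `TSS_769713-2` is position 769713 on the minus strand of the replicon
#' whose accession ends in 2).
#'
#' @param name character vector of TSS names.
#' @return data.frame with columns `position`, `strand`, `replicon_digit`.
#' @export
parse_tss_name <- function(name) {
  m <- regmatches(name, regexec("^TSS_([0-9]+)([+-])([0-9])$", name))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed TSS name(s): ", paste(name[bad], collapse = ", "))
  data.frame(
    position = as.integer(vapply(m, `[`, "", 2L)),
    strand = vapply(m, `[`, "", 3L),
    replicon_digit = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Build TSS names from coordinates
#'
#' Inverse of [parse_tss_name()]. The replicon digit is taken from the last
#' character of `replicon_id`, which must be a digit.
#'
#' @param position,strand,replicon_id vectors (recycled) of TSS coordinates.
#' @return character vector of names.
#' @export
make_tss_name <- function(position, strand, replicon_id) {
  digit <- substr(replicon_id, nchar(replicon_id), nchar(replicon_id))
  if (any(!grepl("^[0-9]$", digit)))
    stop("replicon id must end in a digit to form TSS names: ",
         paste(unique(replicon_id[!grepl("[0-9]$", replicon_id)]),
               collapse = ", "))
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  paste0("TSS_", position, strand, digit)
}

#' Write TSS records as BED6
#'
#' The BED score column is the consensus TSS quality score capped at 1000
#' (the BED format limit); the uncapped value stays in the TSV output.
#'
#' @param records TSS record data.frame from [merge_replicates()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(records, path) {
  df <- data.frame(
    chrom = records$replicon,
    start = records$position - 1L,
    end = records$position,
    name = records$name,
    score = pmin(round(records$mean_score), 1000),
    strand = records$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
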