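#' Collapse PCR-duplicate alignments
#'
#' Sequencing libraries amplified by PCR contain repeated copies of the same
#' molecule; before computing coverage, alignment records are collapsed so
#' that exactly one record survives per distinct
#' `(chrom, start, end, strand)` tuple. The first occurrence is kept and the
#' result is sorted by that tuple.
#'
#' @param records Tibble/data frame of alignment records with columns
#'   `chrom`, `start`, `end`, `strand` (0-based half-open) and optionally
#'   `name`.
#' @return A tibble of deduplicated, sorted records.
#' @export
#' @examples
#' recs <- tibble::tibble(chrom = "c", start = c(0, 0, 5), end = c(10, 10, 9),
#'                        strand = "+")
#' collapse_alignments(recs)
collapse_alignments <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(records)))
  records |>
    dplyr::distinct(
      dplyr::across(dplyr::all_of(c("chrom", "start", "end", "strand"))),
      .keep_all = TRUE
    ) |>
    dplyr::arrange(
      dplyr::across(dplyr::all_of(c("chrom", "start", "end", "strand")))
    )
}

#' Compute per-base coverage from alignment records
#'
#' Each position's depth is the number of records whose `[start, end)`
#' interval covers it. On circular genomes, records whose interval runs past
#' the origin wrap around; total coverage mass always equals the summed
#' record lengths.
#'
#' @param records Alignment tibble (single chromosome).
#' @param genome_length Genome length, bp.
#' @param circular Wrap intervals past the origin?
#' @param ... Labels passed to [coverage_track()] (`sample`, `condition`,
#'   `replicate`).
#' @return A [coverage_track()].
#' @export
compute_coverage <- function(records, genome_length, circular = TRUE, ...) {
  records <- tibble::as_tibble(records)
  genome_length <- as.integer(genome_length)
  chrom <- if (nrow(records) > 0) records$chrom[1] else "chr"
  if (nrow(records) > 0 && length(unique(records$chrom)) > 1) {
    stop("records must come from a single chromosome")
  }
  diffs <- numeric(genome_length + 1L)
  if (nrow(records) > 0) {
    s <- records$start
    e <- records$end
    if (any(s < 0) || any(s >= e)) stop("malformed record intervals")
    if (circular) {
      s <- s %% genome_length
      e <- s + (records$end - records$start)
    } else if (any(e > genome_length)) {
      stop("record exceeds genome bounds on a linear genome")
    }
    wraps <- e > genome_length
    # non-wrapping part
    s1 <- s
    e1 <- pmin(e, genome_length)
    diffs <- tabulate(s1 + 1L, genome_length + 1L) -
      tabulate(e1 + 1L, genome_length + 1L)
    # wrapped tails start back at the origin
    if (any(wraps)) {
      tail_len <- e[wraps] - genome_length
      if (any(tail_len > genome_length)) stop("record longer than the genome")
      diffs[1L] <- diffs[1L] + sum(wraps)
      diffs <- diffs - tabulate(tail_len + 1L, genome_length + 1L)
    }
  }
  values <- cumsum(diffs[seq_len(genome_length)])
  coverage_track(values, chrom = chrom, circular = circular, ...)
}

#' Read alignment records from BED or SAM
#'
#' BED input uses columns 1-6 (0-based half-open, strand in column 6). SAM
#' input keeps primary mapped records only; for proper pairs the fragment
#' interval spans from the leftmost to the rightmost mapped base of the pair
#' (`unit = "fragment"`, the default), otherwise each read contributes its
#' own interval (`unit = "read"`).
#'
#' @param path BED or SAM file.
#' @param format `"bed"` or `"sam"` (guessed from the extension by default).
#' @param unit For SAM: collapse paired reads to one fragment interval
#'   (`"fragment"`) or keep per-read intervals (`"read"`).
#' @return Alignment tibble (`chrom`, `start`, `end`, `strand`, `name`).
#' @export
read_alignments <- function(path, format = NULL,
                            unit = c("fragment", "read")) {
  unit <- match.arg(unit)
  if (is.null(format)) {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    return(tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                      "-", "+"),
      name = if (!is.null(gr$name)) gr$name else NA_character_
    ))
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  par <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "pos", "qwidth", "strand", "flag",
             "mpos", "isize", "cigar")
  )
  b <- Rsamtools::scanBam(bam, param = par)[[1]]
  aln_end <- b$pos + cigar_ref_width(b$cigar) - 1L  # 1-based inclusive
  rec <- tibble::tibble(
    name = b$qname,
    chrom = as.character(b$rname),
    start = b$pos - 1L,
    end = aln_end,
    strand = ifelse(as.character(b$strand) == "-", "-", "+"),
    flag = b$flag,
    isize = b$isize
  )
  if (unit == "fragment") {
    proper <- bitwAnd(rec$flag, 2L) > 0L & !is.na(rec$isize)
    frag <- rec[proper, , drop = FALSE] |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c("name", "chrom")))) |>
      dplyr::summarise(
        start = min(.data$start), end = max(.data$end),
        strand = .data$strand[which.min(.data$start)], .groups = "drop"
      )
    single <- rec[!proper, c("name", "chrom", "start", "end", "strand")]
    rec <- dplyr::bind_rows(frag, single)
  }
  rec |>
    dplyr::select(dplyr::all_of(c("chrom", "start", "end", "strand", "name"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c("chrom", "start", "end"))))
}

# Reference-consuming width of a CIGAR string (M/D/N/=/X advance).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth become one 0-based half-open interval each, so the
#' file has exactly as many lines as the track has maximal constant runs.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = track$chrom, start = starts, end = ends,
                   value = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Intervals must be sorted and non-overlapping; positions not covered by
#' any interval read as depth 0.
#'
#' @param path bedGraph file.
#' @param genome_length Genome length; defaults to the largest interval end.
#' @param ... Labels passed to [coverage_track()] plus `circular`.
#' @return A [coverage_track()].
#' @export
read_track <- function(path, genome_length = NULL, ...) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (length(gr) > 1) {
    o <- order(start0)
    if (any(start0[o][-1] < end0[o][-length(end0)])) {
      stop("bedGraph intervals overlap")
    }
  }
  if (is.null(genome_length)) genome_length <- max(end0, 0L)
  values <- numeric(genome_length)
  widths <- end0 - start0
  values[sequence(widths, from = start0 + 1L)] <- rep(gr$score, widths)
  coverage_track(values, chrom = as.character(GenomicRanges::seqnames(gr))[1],
                 ...)
}
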