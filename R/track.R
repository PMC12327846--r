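#' Per-base coverage track
#'
#' A `coverage_track` holds non-negative per-base sequencing depth across one
#' (typically circular) bacterial chromosome for a single sample, together
#' with the sample labels the downstream consolidation steps key on.
#'
#' @param values Numeric vector of per-base depth, one element per genome
#'   position (position 1 = genome coordinate 0). All values must be >= 0.
#' @param chrom Chromosome identifier.
#' @param circular Is the chromosome circular? Bacterial chromosomes
#'   typically are; coordinate arithmetic wraps modulo the length.
#' @param sample,condition,replicate Sample labels carried through peak
#'   calling and consolidation. `replicate` is an integer.
#'
#' @return An object of class `coverage_track`.
#' @export
#' @examples
#' trk <- coverage_track(rpois(1000, 10), chrom = "chr")
#' mean_depth(trk)
coverage_track <- function(values, chrom = "chr", circular = TRUE,
                           sample = NA_character_, condition = NA_character_,
                           replicate = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("coverage track must have positive length")
  if (anyNA(values) || any(values < 0)) {
    stop("coverage values must be non-negative and non-missing")
  }
  structure(
    list(
      chrom = chrom, values = values, circular = isTRUE(circular),
      sample = sample, condition = condition,
      replicate = as.integer(replicate)
    ),
    class = "coverage_track"
  )
}

#' @export
length.coverage_track <- function(x) length(x$values)

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s: %d bp (%s), mean depth %.2f\n",
    x$chrom, length(x$values), if (x$circular) "circular" else "linear",
    mean(x$values)
  ))
  if (!is.na(x$sample)) {
    cat(sprintf(
      "  sample=%s condition=%s replicate=%s\n",
      x$sample, x$condition, x$replicate
    ))
  }
  invisible(x)
}

#' Genome-wide mean depth of a track
#'
#' The mean is taken over the whole genome, peak regions included; it is the
#' baseline against which the `3 * mean` detection threshold is applied.
#'
#' @param track A [coverage_track()].
#' @return A single number.
#' @export
mean_depth <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  mean(track$values)
}

# Minimal circular distance between positions a and b (0-based), on a genome
# of length L. For linear genomes pass circular = FALSE.
circ_dist <- function(a, b, genome_length, circular = TRUE) {
  d <- abs(a - b)
  if (circular) pmin(d, genome_length - d) else d
}

# Signed circular difference a - b mapped into (-L/2, L/2].
circ_diff <- function(a, b, genome_length, circular = TRUE) {
  d <- a - b
  if (!circular) return(d)
  d <- (d + genome_length / 2) %% genome_length - genome_length / 2
  ifelse(d == -genome_length / 2, genome_length / 2, d)
}

# 0-based positions of interval [start, end) wrapped onto 1-based vector
# indices of a genome of length L.
wrap_index <- function(start, end, genome_length) {
  (seq.int(start, end - 1L) %% genome_length) + 1L
}
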