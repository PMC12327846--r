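#' Estimate the expected peak width of a coverage track
#'
#' Width estimation proceeds in three steps: (i) every maximal run of
#' positions with depth above three times the genome-wide mean is taken as a
#' provisional peak, represented by its local maximum; (ii) from each
#' maximum, the profile is walked left and right to the first positions
#' where depth drops below half the maximum, and the distance between the
#' outermost positions still at or above half-maximum is that peak's width
#' (its FWHM); (iii) the estimate is the median of those widths. With an
#' even number of provisional peaks the lower middle value is used, keeping
#' the result an observed integer width.
#'
#' @param track A [coverage_track()].
#' @param min_fold Detection threshold as a multiple of the mean depth.
#' @return Expected width in bp (single number).
#' @export
estimate_expected_width <- function(track, min_fold = 3) {
  stopifnot(inherits(track, "coverage_track"))
  v <- track$values
  L <- length(v)
  mu <- mean(v)
  above <- v > min_fold * mu
  if (!any(above)) {
    stop(sprintf(
      "no peaks detectable: no position exceeds %g x mean coverage (mean = %g)",
      min_fold, mu
    ))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]
  # on a circular genome a run may wrap the origin: merge first and last
  if (track$circular && length(starts) > 1 &&
      starts[1] == 1L && ends[length(ends)] == L) {
    starts[1] <- starts[length(starts)] - L
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }

  widths <- vapply(seq_along(starts), function(i) {
    idx <- ((seq.int(starts[i], ends[i]) - 1L) %% L) + 1L
    apex <- idx[which.max(v[idx])]
    fwhm_at(v, apex, track$circular)
  }, numeric(1))

  median_lower(widths)
}

# FWHM around an apex: outermost positions still >= half-maximum on each
# side, bounded by one genome length of walking.
fwhm_at <- function(v, apex, circular) {
  L <- length(v)
  half <- v[apex] / 2
  step_idx <- function(i, d) {
    j <- i + d
    if (circular) ((j - 1L) %% L) + 1L else j
  }
  left <- apex
  for (k in seq_len(L)) {
    j <- step_idx(apex, -k)
    if (j < 1L || v[j] < half) break
    left <- j
  }
  right <- apex
  for (k in seq_len(L)) {
    j <- step_idx(apex, k)
    if (j > L || v[j] < half) break
    right <- j
  }
  # circular distance between the outermost >= half positions
  if (circular) {
    ((right - left) %% L)
  } else {
    right - left
  }
}

# Lower-middle median: the floor(n/2)-th smallest for even n.
median_lower <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Build the Mexican-hat detection kernel
#'
#' The kernel is the negated second derivative of a Gaussian density,
#' truncated at four standard deviations and scaled so that its full
#' support (2 x 4 sigma) equals the expected peak width, i.e.
#' `sigma = expected_width / 8`. Negation turns coverage maxima into maxima
#' of the convolution profile. Discrete truncation breaks the analytic
#' zero-sum of the second derivative, so the weights are mean-shifted to
#' sum to zero exactly; a constant track then convolves to an exactly zero
#' profile.
#'
#' @param expected_width Expected peak width (FWHM), bp; must be >= 8 so
#'   that sigma >= 1.
#' @param sigma_ratio Ratio sigma / expected_width. The default 1/8 makes
#'   the truncated support match the expected width.
#' @return A list of class `chap_kernel`: `sigma`, `radius`, `weights`
#'   (indexed -radius..radius).
#' @export
build_kernel <- function(expected_width, sigma_ratio = 1 / 8) {
  if (expected_width < 8) {
    stop("expected width must be >= 8 bp (sigma >= 1)")
  }
  sigma <- expected_width * sigma_ratio
  radius <- as.integer(ceiling(4 * sigma))
  i <- seq.int(-radius, radius)
  g <- stats::dnorm(i, sd = sigma)
  w <- (sigma^2 - i^2) / sigma^4 * g   # -g''(i; sigma)
  w <- w - mean(w)                     # restore exact zero sum
  structure(
    list(sigma = sigma, radius = radius, weights = w),
    class = "chap_kernel"
  )
}

#' @export
print.chap_kernel <- function(x, ...) {
  cat(sprintf("<chap_kernel> sigma = %.2f bp, radius = %d bp (4 sigma)\n",
              x$sigma, x$radius))
  invisible(x)
}

#' Convolve a coverage track with a detection kernel
#'
#' Computes `profile[x] = sum_i weights[i] * values[x - i]`, with circular
#' wrap-around on circular genomes and zero padding on linear ones. The
#' operation is linear in the track.
#'
#' @param track A [coverage_track()].
#' @param kernel A `chap_kernel` from [build_kernel()].
#' @return Numeric profile of genome length.
#' @export
convolve_track <- function(track, kernel) {
  stopifnot(inherits(track, "coverage_track"), inherits(kernel, "chap_kernel"))
  v <- track$values
  L <- length(v)
  if (kernel$radius >= L / 2) {
    stop("kernel radius must be smaller than half the genome length")
  }
  # symmetric kernel: convolution == centered weighted running sum
  if (track$circular) {
    as.numeric(stats::filter(v, kernel$weights, method = "convolution",
                             sides = 2, circular = TRUE))
  } else {
    pad <- kernel$radius
    vp <- c(numeric(pad), v, numeric(pad))
    out <- stats::filter(vp, kernel$weights, method = "convolution",
                         sides = 2, circular = FALSE)
    as.numeric(out[(pad + 1L):(pad + L)])
  }
}

#' Detect candidate summits in a convolution profile
#'
#' A summit is reported wherever the discrete first difference of the
#' profile changes sign from positive to negative; across a flat plateau
#' the center position (rounded down) is reported. Candidates whose profile
#' value is not positive are discarded.
#'
#' @param profile Numeric convolution profile.
#' @param circular Treat the profile as circular?
#' @return Integer vector of 0-based summit positions, sorted.
#' @export
detect_summits <- function(profile, circular = TRUE) {
  L <- length(profile)
  d <- if (circular) {
    c(profile[-1], profile[1]) - profile    # d[x] = p[x+1] - p[x]
  } else {
    diff(profile)
  }
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))

  cands <- integer(0)
  n <- length(nz)
  pair_count <- if (circular) n else n - 1L
  for (k in seq_len(pair_count)) {
    a <- nz[k]
    b <- if (k < n) nz[k + 1L] else nz[1L] + L  # wrap pair on circle
    if (s[a] > 0 && s[((b - 1L) %% L) + 1L] < 0) {
      # profile is flat (and maximal) on positions a+1 .. b
      cand <- (a + 1L + b) %/% 2L
      cands <- c(cands, ((cand - 1L) %% L) + 1L)
    }
  }
  cands <- sort(unique(cands))
  cands <- cands[profile[cands] > 0]
  as.integer(cands - 1L)  # 0-based
}

#' Score, filter and merge candidate summits into a peak set
#'
#' Each candidate receives the convolution profile value at its summit as
#' its score and the raw coverage there as its height. Candidates are kept
#' when the raw height reaches `min_fold` times the mean depth and the
#' score is positive; peak extents (summit +/- half the expected width)
#' that overlap are merged, keeping the higher-scoring summit.
#'
#' @param candidates 0-based summit positions from [detect_summits()].
#' @param profile Convolution profile the candidates came from.
#' @param track The underlying [coverage_track()].
#' @param expected_width Expected peak width, bp.
#' @param min_fold Raw-height threshold as a multiple of mean depth.
#' @return A `peak_set` (unnormalized: `norm_intensity` is `NA` until
#'   [normalize_peakset()] runs).
#' @export
score_filter <- function(candidates, profile, track, expected_width,
                         min_fold = 3) {
  stopifnot(inherits(track, "coverage_track"))
  L <- length(track$values)
  mu <- mean(track$values)
  half <- as.integer(floor(expected_width / 2))

  pk <- tibble::tibble(
    summit = as.integer(candidates),
    score = profile[candidates + 1L],
    raw_height = track$values[candidates + 1L]
  ) |>
    dplyr::filter(.data$raw_height >= min_fold * mu, .data$score > 0) |>
    dplyr::mutate(
      start = .data$summit - half,
      end = .data$summit + half
    ) |>
    dplyr::arrange(.data$summit)

  # merge overlapping extents, keep the higher-scoring summit
  if (nrow(pk) > 1) {
    keep <- rep(TRUE, nrow(pk))
    repeat {
      idx <- which(keep)
      if (length(idx) < 2) break
      merged_any <- FALSE
      for (k in seq_len(length(idx) - 1L)) {
        i <- idx[k]; j <- idx[k + 1L]
        if (pk$end[i] > pk$start[j]) {
          drop <- if (pk$score[i] >= pk$score[j]) j else i
          keep[drop] <- FALSE
          merged_any <- TRUE
          break
        }
      }
      # wrap-around overlap on circular genomes
      if (!merged_any && track$circular && length(idx) >= 2) {
        i <- idx[length(idx)]; j <- idx[1L]
        if (pk$end[i] - L > pk$start[j]) {
          drop <- if (pk$score[i] >= pk$score[j]) j else i
          keep[drop] <- FALSE
          merged_any <- TRUE
        }
      }
      if (!merged_any) break
    }
    pk <- pk[keep, , drop = FALSE]
  }

  pk <- pk |>
    dplyr::mutate(norm_intensity = NA_real_) |>
    dplyr::select(dplyr::all_of(
      c("summit", "start", "end", "raw_height", "score", "norm_intensity")
    ))

  new_peak_set(pk, track, expected_width = expected_width,
               mean_coverage = mu, min_fold = min_fold)
}

new_peak_set <- function(peaks, track, expected_width, mean_coverage,
                         min_fold, norm_coefficient = NA_real_) {
  structure(
    list(
      peaks = peaks,
      expected_width = expected_width,
      mean_coverage = mean_coverage,
      min_fold = min_fold,
      norm_coefficient = norm_coefficient,
      genome_length = length(track$values),
      circular = track$circular,
      chrom = track$chrom,
      sample = track$sample,
      condition = track$condition,
      replicate = track$replicate
    ),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf(
    "<peak_set> %d peaks on %s (%d bp), expected width %g bp, mean depth %.2f\n",
    nrow(x$peaks), x$chrom, x$genome_length, x$expected_width,
    x$mean_coverage
  ))
  if (!is.na(x$norm_coefficient)) {
    cat(sprintf("  normalization coefficient B = %.4g\n", x$norm_coefficient))
  }
  invisible(x)
}

#' Normalize peak scores for inter-sample comparison
#'
#' The normalization coefficient `B` is the background mass: the total
#' genomic coverage minus the coverage inside all detected peak extents.
#' Each peak's normalized intensity is `score / B * 1e6`; the `1e6` factor
#' only keeps the numbers readable. Because both the score and `B` scale
#' linearly with sequencing depth, normalized intensities are invariant
#' under rescaling a sample's track.
#'
#' @param peakset A `peak_set` from [score_filter()].
#' @param track The track the peaks were called on.
#' @return The `peak_set` with `norm_intensity` filled and
#'   `norm_coefficient` stored.
#' @export
normalize_peakset <- function(peakset, track) {
  stopifnot(inherits(peakset, "peak_set"), inherits(track, "coverage_track"))
  v <- track$values
  L <- length(v)
  total <- sum(v)
  peak_mass <- 0
  pk <- peakset$peaks
  for (i in seq_len(nrow(pk))) {
    idx <- wrap_index(max(pk$start[i], if (track$circular) pk$start[i] else 0L),
                      min(pk$end[i], if (track$circular) pk$end[i] else L), L)
    peak_mass <- peak_mass + sum(v[idx])
  }
  B <- total - peak_mass
  if (B <= 0) {
    stop("normalization coefficient is not positive: peaks cover the genome")
  }
  peakset$norm_coefficient <- B
  peakset$peaks$norm_intensity <- pk$score / B * 1e6
  peakset
}

#' Call peaks on a coverage track
#'
#' Runs the full detection chain: expected-width estimation, Mexican-hat
#' kernel construction, convolution, summit detection at first-derivative
#' sign changes, score filtering, optional blacklist removal, and
#' background-mass normalization.
#'
#' @param track A [coverage_track()].
#' @param min_fold Detection threshold, multiples of mean depth.
#' @param sigma_ratio Kernel scale relative to the expected width.
#' @param blacklist Optional tibble/data frame of 0-based half-open
#'   intervals (`start`, `end`); peaks whose summit falls inside any
#'   interval are dropped before normalization. Meant for artifact regions
#'   such as cryptic peaks from technical issues.
#' @param expected_width Override the estimated width (bp); `NULL`
#'   estimates it from the track.
#' @return A normalized `peak_set`.
#' @export
#' @examples
#' truth <- plant_peaks(generate_genome(20000, 0.5, 4, seed = 1)$genome,
#'                      generate_genome(20000, 0.5, 4, seed = 1)$genes,
#'                      n_peaks = 3, seed = 2)
#' trk <- simulate_coverage(truth, "iron", noise = "none")
#' call_peaks(trk)
call_peaks <- function(track, min_fold = 3, sigma_ratio = 1 / 8,
                       blacklist = NULL, expected_width = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(expected_width)) {
    expected_width <- with_stage(
      "estimate_expected_width",
      estimate_expected_width(track, min_fold = min_fold)
    )
  }
  kernel <- with_stage("build_kernel",
                       build_kernel(expected_width, sigma_ratio = sigma_ratio))
  profile <- with_stage("convolve", convolve_track(track, kernel))
  cands <- with_stage("detect_summits",
                      detect_summits(profile, circular = track$circular))
  ps <- with_stage(
    "score_filter",
    score_filter(cands, profile, track, expected_width, min_fold = min_fold)
  )
  if (!is.null(blacklist) && nrow(ps$peaks) > 0) {
    bl <- tibble::as_tibble(blacklist)
    bad <- vapply(ps$peaks$summit, function(s) {
      any(s >= bl$start & s < bl$end)
    }, logical(1))
    ps$peaks <- ps$peaks[!bad, , drop = FALSE]
  }
  with_stage("normalize_peakset", normalize_peakset(ps, track))
}

# Tag stage errors with the stage name so pipeline failures are locatable.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a peak set into one row per peak
#' @param x A `peak_set`.
#' @param ... Unused.
#' @return Tibble with one row per peak plus sample labels.
#' @method tidy peak_set
#' @export
tidy.peak_set <- function(x, ...) {
  dplyr::mutate(
    x$peaks,
    chrom = x$chrom, sample = x$sample, condition = x$condition,
    replicate = x$replicate
  )
}

#' One-row summary of a peak set
#' @param x A `peak_set`.
#' @param ... Unused.
#' @return One-row tibble: peak count, expected width, mean coverage, B.
#' @method glance peak_set
#' @export
glance.peak_set <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$peaks),
    expected_width = x$expected_width,
    mean_coverage = x$mean_coverage,
    norm_coefficient = x$norm_coefficient,
    sample = x$sample, condition = x$condition, replicate = x$replicate
  )
}

#' Write a peak set as TSV
#' @param peakset A `peak_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks <- function(peakset, path) {
  stopifnot(inherits(peakset, "peak_set"))
  utils::write.table(
    tidy(peakset), path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
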