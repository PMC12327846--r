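#' Build a position weight matrix from aligned binding sites
#'
#' Per-position nucleotide counts are augmented with
#' `pseudocount * background` and normalized to probabilities; log-odds
#' scores are `log2(prob / background)`.
#'
#' @param sites Character vector of equal-length ACGT sequences.
#' @param pseudocount Total pseudocount distributed by the background.
#' @param background Named nucleotide frequencies (A, C, G, T) summing
#'   to 1.
#' @return A `chap_pwm`: `length`, `probs` (4 x L matrix, rows ACGT),
#'   `log_odds`, `background`, `pseudocount`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(length(sites) >= 1, pseudocount > 0)
  sites <- toupper(sites)
  W <- unique(nchar(sites))
  if (length(W) != 1) stop("sites must all have the same length")
  mat <- do.call(rbind, strsplit(sites, ""))
  if (!all(mat %in% c("A", "C", "G", "T"))) {
    stop("sites must contain only A, C, G, T")
  }
  bases <- c("A", "C", "G", "T")
  background <- background[bases] / sum(background[bases])
  counts <- vapply(seq_len(W), function(j) {
    tabulate(factor(mat[, j], levels = bases), 4L)
  }, numeric(4))
  probs <- counts + pseudocount * as.numeric(background)
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- bases
  new_pwm(probs, background, pseudocount)
}

new_pwm <- function(probs, background, pseudocount) {
  structure(
    list(
      length = ncol(probs),
      probs = probs,
      log_odds = log2(sweep(probs, 1, as.numeric(background), "/")),
      background = background,
      pseudocount = pseudocount
    ),
    class = "chap_pwm"
  )
}

#' @export
print.chap_pwm <- function(x, ...) {
  cat(sprintf("<chap_pwm> length %d, consensus %s\n", x$length,
              paste(rownames(x$probs)[apply(x$probs, 2, which.max)],
                    collapse = "")))
  invisible(x)
}

#' Turn an IUPAC consensus into a PWM
#'
#' At each position the bases allowed by the IUPAC code share `match_prob`
#' equally and the disallowed bases share the remainder; a fully ambiguous
#' code (N) yields the uniform distribution.
#'
#' @param consensus IUPAC string, e.g. `"TAGGTTAGSCTAACCTAA"`.
#' @param match_prob Total probability assigned to allowed bases.
#' @param background Background frequencies for the log-odds.
#' @return A `chap_pwm`.
#' @export
consensus_to_pwm <- function(consensus, match_prob = 0.9,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  codes <- iupac_table()
  letters_c <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters_c %in% names(codes))) {
    stop("invalid IUPAC code in consensus")
  }
  bases <- c("A", "C", "G", "T")
  background <- background[bases] / sum(background[bases])
  probs <- vapply(letters_c, function(cd) {
    allowed <- bases %in% codes[[cd]]
    k <- sum(allowed)
    if (k == 4L) rep(0.25, 4) else {
      ifelse(allowed, match_prob / k, (1 - match_prob) / (4 - k))
    }
  }, numeric(4))
  rownames(probs) <- bases
  new_pwm(probs, background, pseudocount = 0)
}

# Integer-binned score distribution of a PWM under the background model:
# position-wise dynamic programming (convolution of per-position score
# distributions). Returns bin offsets and probabilities.
pwm_score_distribution <- function(pwm, granularity = 0.001,
                                   background = NULL) {
  lo <- score_bins(pwm, granularity, background)
  bg <- if (is.null(background)) pwm$background else background
  bg <- as.numeric(bg[c("A", "C", "G", "T")] / sum(bg))
  mins <- apply(lo, 2, min)
  maxs <- apply(lo, 2, max)
  total_min <- sum(mins)
  n_bins <- sum(maxs - mins) + 1L
  # dist[k] = P(binned score so far == total_min_so_far + k - 1)
  dist <- 1
  off_min <- 0L
  for (j in seq_len(pwm$length)) {
    rel <- lo[, j] - mins[j]
    width <- length(dist) + max(rel)
    nd <- numeric(width)
    for (b in 1:4) {
      sh <- rel[b]
      nd[(sh + 1L):(sh + length(dist))] <-
        nd[(sh + 1L):(sh + length(dist))] + bg[b] * dist
    }
    dist <- nd
    off_min <- off_min + mins[j]
  }
  list(bins = off_min + seq_along(dist) - 1L, prob = dist,
       granularity = granularity)
}

# Per-position binned log-odds scores (4 x L integer matrix).
score_bins <- function(pwm, granularity, background = NULL) {
  lo <- pwm$log_odds
  if (!is.null(background)) {
    bg <- background[c("A", "C", "G", "T")] / sum(background)
    lo <- log2(sweep(pwm$probs, 1, as.numeric(bg), "/"))
  }
  matrix(as.integer(round(lo / granularity)), nrow = 4,
         dimnames = dimnames(lo))
}

#' Exact p-value of a PWM score
#'
#' The p-value is the probability that a random window drawn from the
#' background model scores at least as high as `score`. It is computed
#' exactly (up to score binning at `granularity`) by dynamic programming
#' over the per-position score distributions; the binning displaces the
#' effective score threshold by at most `length * granularity`.
#'
#' @param pwm A `chap_pwm`.
#' @param score Log-odds score.
#' @param granularity Score bin width.
#' @param background Optional override of the background model.
#' @return Tail probability in `[0, 1]`.
#' @export
pwm_pvalue <- function(pwm, score, granularity = 0.001, background = NULL) {
  stopifnot(granularity > 0)
  d <- pwm_score_distribution(pwm, granularity, background)
  sbin <- as.integer(round(score / granularity))
  sum(d$prob[d$bins >= sbin])
}

#' Scan a sequence for PWM matches with exact p-values
#'
#' Both strands are scanned (the reverse strand by scoring the reverse
#' complement of each window); hits are windows whose score's exact
#' background p-value is below `p_threshold`, reported at the forward-strand
#' window start (0-based) and sorted by p-value then position. Circular
#' sequences are scanned across the origin.
#'
#' @param genome Genome list (from [generate_genome()] /
#'   [read_genome_fasta()]) or a plain character sequence.
#' @param pwm A `chap_pwm`.
#' @param p_threshold Report hits with `p_value < p_threshold`.
#' @param granularity Score bin width for the exact p-value.
#' @param background `"sequence"` (0-order model from the scanned
#'   sequence's own base frequencies, the default) or a named frequency
#'   vector, or `"pwm"` to keep the PWM's stored background.
#' @return Tibble of hits: `position`, `strand`, `score`, `p_value`.
#' @export
scan_pwm <- function(genome, pwm, p_threshold = 1e-5, granularity = 0.001,
                     background = "sequence") {
  if (is.character(genome)) {
    genome <- list(chrom_id = "seq", sequence = genome, circular = FALSE)
  }
  seqc <- toupper(genome$sequence)
  L <- nchar(seqc)
  W <- pwm$length
  if (L < W) stop("sequence shorter than the PWM")

  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  x <- codes[strsplit(seqc, "")[[1]]]
  if (anyNA(x)) {
    x[is.na(x)] <- 1L  # Ns scored as A against the background; rare input
  }

  bg <- if (identical(background, "sequence")) {
    tab <- tabulate(x, 4L)
    freq <- tab / sum(tab)
    freq <- pmax(freq, 1e-6); freq <- freq / sum(freq)
    stats::setNames(freq, c("A", "C", "G", "T"))
  } else if (identical(background, "pwm")) {
    pwm$background
  } else {
    background
  }

  bins <- score_bins(pwm, granularity, background = bg)
  d <- pwm_score_distribution(pwm, granularity, background = bg)
  tail_p <- rev(cumsum(rev(d$prob)))
  # smallest binned score whose tail is < threshold
  ok <- tail_p < p_threshold
  if (!any(ok)) {
    return(tibble::tibble(position = integer(), strand = character(),
                          score = numeric(), p_value = numeric()))
  }
  pval_of <- function(sbin) {
    i <- findInterval(sbin, d$bins)
    ifelse(sbin > d$bins[length(d$bins)], 0,
           ifelse(sbin < d$bins[1], 1, tail_p[pmax(i, 1L)]))
  }

  if (genome$circular) {
    xx <- c(x, x[seq_len(W - 1L)])
    n_win <- L
  } else {
    xx <- x
    n_win <- L - W + 1L
  }
  # forward-strand binned scores, vectorized over windows
  fwd <- integer(n_win)
  for (j in seq_len(W)) {
    fwd <- fwd + bins[cbind(xx[seq_len(n_win) + j - 1L], j)]
  }
  # reverse strand: score of revcomp(window) == scoring with the
  # reverse-complemented PWM on the forward window
  rc_bins <- bins[4:1, W:1, drop = FALSE]
  rev_ <- integer(n_win)
  for (j in seq_len(W)) {
    rev_ <- rev_ + rc_bins[cbind(xx[seq_len(n_win) + j - 1L], j)]
  }

  sthr <- min(d$bins[ok])
  hit_f <- which(fwd >= sthr)
  hit_r <- which(rev_ >= sthr)
  hits <- tibble::tibble(
    position = c(hit_f, hit_r) - 1L,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score_bin = c(fwd[hit_f], rev_[hit_r])
  )
  hits$score <- hits$score_bin * granularity
  hits$p_value <- pval_of(hits$score_bin)
  hits |>
    dplyr::select(dplyr::all_of(c("position", "strand", "score", "p_value"))) |>
    dplyr::arrange(.data$p_value, .data$position)
}

#' Write a PWM in MEME minimal motif format
#' @param pwm A `chap_pwm`.
#' @param path Output path.
#' @param name Motif name.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwm, path, name = "motif1") {
  stopifnot(inherits(pwm, "chap_pwm"))
  bg <- pwm$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            pwm$length),
    apply(pwm$probs, 2, function(p) {
      sprintf(" %.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4])
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read the first motif from a MEME minimal motif file
#' @param path MEME file.
#' @return A `chap_pwm`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) > 0 && bgi[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  mi <- grep("^letter-probability matrix", lines)
  if (length(mi) == 0) stop("no letter-probability matrix found")
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mi[1]]))
  rows <- lines[(mi[1] + 1L):(mi[1] + w)]
  probs <- t(vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }, numeric(4), USE.NAMES = FALSE))
  probs <- t(probs)  # 4 x W, rows ACGT
  rownames(probs) <- c("A", "C", "G", "T")
  new_pwm(probs, bg, pseudocount = 0)
}
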