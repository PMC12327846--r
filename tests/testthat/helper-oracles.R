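# Independent reference implementations used as oracles. These deliberately
# use the dumbest correct algorithm (explicit sums, all-pairs scans) and
# share no code with the package internals they check.

# Direct O(L * R) convolution sum with explicit wrap / zero padding.
naive_convolve <- function(values, weights, circular = TRUE) {
  L <- length(values)
  radius <- (length(weights) - 1L) %/% 2L
  out <- numeric(L)
  for (x in seq_len(L)) {
    acc <- 0
    for (i in seq.int(-radius, radius)) {
      j <- x - i
      if (circular) {
        j <- ((j - 1L) %% L) + 1L
        acc <- acc + weights[i + radius + 1L] * values[j]
      } else if (j >= 1L && j <= L) {
        acc <- acc + weights[i + radius + 1L] * values[j]
      }
    }
    out[x] <- acc
  }
  out
}

# Brute-force expected-width oracle: literal transcription of the 3-step
# rule, scanning positions one by one.
brute_expected_width <- function(values, circular = TRUE, min_fold = 3) {
  L <- length(values)
  mu <- mean(values)
  above <- values > min_fold * mu
  if (!any(above)) stop("no peaks")
  # maximal runs of `above` (merge wrap-around run on circles)
  runs <- list()
  x <- 1L
  while (x <= L) {
    if (above[x]) {
      start <- x
      while (x <= L && above[x]) x <- x + 1L
      runs[[length(runs) + 1L]] <- c(start, x - 1L)
    } else {
      x <- x + 1L
    }
  }
  if (circular && length(runs) > 1 &&
      runs[[1]][1] == 1L && runs[[length(runs)]][2] == L) {
    runs[[1]] <- c(runs[[length(runs)]][1] - L, runs[[1]][2])
    runs[[length(runs)]] <- NULL
  }
  widths <- vapply(runs, function(r) {
    idx <- ((seq.int(r[1], r[2]) - 1L) %% L) + 1L
    apex <- idx[which.max(values[idx])]
    half <- values[apex] / 2
    l <- 0L
    repeat {
      j <- apex - l - 1L
      if (circular) j <- ((j - 1L) %% L) + 1L
      if (is.na(j) || j < 1L || values[j] < half) break
      l <- l + 1L
      if (l >= L) break
    }
    r_ <- 0L
    repeat {
      j <- apex + r_ + 1L
      if (circular) j <- ((j - 1L) %% L) + 1L
      if (is.na(j) || j > L || values[j] < half) break
      r_ <- r_ + 1L
      if (r_ >= L) break
    }
    as.numeric(l + r_)
  }, numeric(1))
  s <- sort(widths)
  s[ceiling(length(s) / 2)]
}

# All-pairs union-find single-linkage clustering oracle.
brute_single_linkage <- function(pos, threshold, genome_length,
                                 circular = TRUE) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- abs(pos[i] - pos[j])
        if (circular) d <- min(d, genome_length - d)
        if (d <= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Reference circular distance, written out directly.
circ_dist_ref <- function(a, b, genome_length) {
  d <- abs(a - b)
  pmin(d, genome_length - d)
}

# Gaussian bump track builder shared by many tests.
gaussian_track <- function(length, summits, heights, fwhms, background = 0,
                           circular = TRUE, ...) {
  v <- rep(background, length)
  for (k in seq_along(summits)) {
    sigma <- fwhms[k] / 2.355
    d <- abs(seq_len(length) - 1L - summits[k])
    if (circular) d <- pmin(d, length - d)
    v <- v + heights[k] * exp(-d^2 / (2 * sigma^2))
  }
  coverage_track(v, circular = circular, ...)
}

# Match called summits against planted ones within a tolerance; returns
# recall, precision and per-match absolute summit errors.
match_peaks <- function(called, planted, genome_length, tol) {
  dmat <- outer(called, planted, function(a, b) {
    d <- abs(a - b)
    pmin(d, genome_length - d)
  })
  if (length(called) == 0 || length(planted) == 0) {
    return(list(recall = 0, precision = 0, errors = numeric(0)))
  }
  hit_planted <- apply(dmat, 2, min) <= tol
  hit_called <- apply(dmat, 1, min) <= tol
  list(
    recall = mean(hit_planted),
    precision = mean(hit_called),
    errors = apply(dmat, 1, min)[hit_called]
  )
}

# Exhaustive PWM scoring oracle: enumerate all 4^W windows with their
# background probabilities and score them directly from the log-odds.
enumerate_pwm <- function(pwm, background = NULL) {
  bases <- c("A", "C", "G", "T")
  bg <- if (is.null(background)) pwm$background else background
  bg <- as.numeric(bg[bases] / sum(bg[bases]))
  lo <- if (is.null(background)) {
    pwm$log_odds
  } else {
    log2(sweep(pwm$probs, 1, bg, "/"))
  }
  W <- pwm$length
  grid <- expand.grid(rep(list(1:4), W))
  scores <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    scores[r] <- sum(lo[cbind(idx, seq_len(W))])
    probs[r] <- prod(bg[idx])
  }
  list(scores = scores, probs = probs)
}
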