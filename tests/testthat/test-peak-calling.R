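test_that("expected width estimation recovers FWHM geometry", {
  # symmetric triangle: linear rise over 100 bp to 100, fall over 100 bp
  L <- 2000
  v <- numeric(L)
  apex <- 1000
  for (d in -100:100) v[apex + d] <- max(0, 100 - abs(d))
  trk <- coverage_track(v, circular = FALSE)
  expect_equal(estimate_expected_width(trk), 100)

  # two noise-free Gaussian bumps, FWHM 50 and 90: median = lower middle
  trk2 <- gaussian_track(10000, summits = c(2000, 7000),
                         heights = c(100, 100), fwhms = c(50, 90))
  expect_lte(abs(estimate_expected_width(trk2) - 50), 2)

  # detection threshold: apex at 2.9x mean contributes nothing, 3.1x does
  base <- rep(10, 5000)
  lo <- base; lo[2500 + (-20:20)] <- 28.9  # < 3x of its own mean
  hi <- base; hi[2500 + (-20:20)] <- 31.5
  expect_error(estimate_expected_width(coverage_track(lo)),
               "no peaks detectable")
  expect_silent(estimate_expected_width(coverage_track(hi)))

  # flat track carries the mean in its error
  expect_error(estimate_expected_width(coverage_track(rep(5, 100))),
               "mean = 5")
})

test_that("width estimator matches the brute-force FWHM-median oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n_bumps <- sample(2:5, 1)
    L <- 20000
    summits <- sort(sample(seq(1000, L - 1000, by = 700), n_bumps))
    trk <- gaussian_track(
      L, summits = summits,
      heights = runif(n_bumps, 50, 200),
      fwhms = runif(n_bumps, 30, 120),
      background = 1
    )
    expect_equal(estimate_expected_width(trk),
                 brute_expected_width(trk$values), tolerance = 1e-12)
  }
})

test_that("the Mexican-hat kernel is symmetric, zero-sum, center-positive", {
  for (w in c(8, 40, 80, 121)) {
    k <- build_kernel(w)
    expect_equal(k$sigma, w / 8)
    expect_equal(k$radius, ceiling(4 * k$sigma))
    expect_equal(k$weights, rev(k$weights))
    expect_equal(sum(k$weights), 0, tolerance = 1e-15)
    expect_gt(k$weights[k$radius + 1], 0)
  }
  expect_error(build_kernel(7), ">= 8")
})

test_that("convolving a matched bump peaks at the bump center", {
  trk <- gaussian_track(4000, summits = 2000, heights = 100, fwhms = 80)
  k <- build_kernel(80)
  prof <- convolve_track(trk, k)
  expect_lte(abs(which.max(prof) - 1 - 2000), 1)
})

test_that("convolution matches the direct sum and is linear", {
  # zero track -> zero profile
  k <- build_kernel(40)
  z <- coverage_track(rep(0, 500))
  expect_true(all(convolve_track(z, k) == 0))

  # impulse response reproduces the kernel
  imp <- numeric(500)
  imp[250] <- 1
  prof <- convolve_track(coverage_track(imp), k)
  expect_equal(prof[250 + seq.int(-k$radius, k$radius)], k$weights,
               tolerance = 1e-12)

  # random tracks vs naive O(L R) sum, circular and linear
  set.seed(7)
  for (rep in 1:10) {
    v <- rpois(400, 5)
    kk <- build_kernel(sample(c(16, 40, 64), 1))
    for (circ in c(TRUE, FALSE)) {
      trk <- coverage_track(v, circular = circ)
      got <- convolve_track(trk, kk)
      want <- naive_convolve(v, kk$weights, circular = circ)
      expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)
    }
  }

  # linearity
  v1 <- rpois(300, 4); v2 <- rpois(300, 6)
  c1 <- convolve_track(coverage_track(v1), k)
  c2 <- convolve_track(coverage_track(v2), k)
  c12 <- convolve_track(coverage_track(2 * v1 + 3 * v2), k)
  expect_equal(c12, 2 * c1 + 3 * c2, tolerance = 1e-9)
})

test_that("summit detection finds derivative sign changes and plateaus", {
  # single smooth bump: one candidate at the argmax
  trk <- gaussian_track(2000, summits = 700, heights = 50, fwhms = 60)
  prof <- convolve_track(trk, build_kernel(60))
  cands <- detect_summits(prof)
  expect_equal(length(cands), 1)
  expect_equal(cands, which.max(prof) - 1)

  # two bumps separated by 3x width: two candidates near truth
  trk2 <- gaussian_track(4000, summits = c(1000, 1240),
                         heights = c(80, 80), fwhms = c(80, 80))
  prof2 <- convolve_track(trk2, build_kernel(80))
  cands2 <- detect_summits(prof2)
  expect_equal(length(cands2), 2)
  expect_true(all(abs(cands2 - c(1000, 1240)) <= 20))

  # constant profile: no candidates
  expect_equal(length(detect_summits(rep(3.2, 100))), 0)

  # plateau: candidate at the (floor-rounded) center
  prof3 <- c(rep(0, 10), 1, 2, rep(3, 4), 2, 1, rep(0, 10))
  cand3 <- detect_summits(prof3, circular = FALSE)
  # plateau spans 1-based positions 13..16 -> center 14 -> 0-based 13
  expect_equal(cand3, 13L)

  # negative-valued maxima are dropped
  prof4 <- c(rep(-5, 10), -4, -3, -4, rep(-5, 10))
  expect_equal(length(detect_summits(prof4, circular = FALSE)), 0)
})

test_that("score_filter applies the 3x-mean rule and merges overlaps", {
  L <- 10000
  trk <- gaussian_track(L, summits = c(3000, 7000),
                        heights = c(100, 100), fwhms = c(60, 60),
                        background = 10)
  # raw heights: summit 1 at ~110 (over 3x mean ~ 31), summit 2 damped to 2.9x
  v <- trk$values
  v[7000 + (-200:200) + 1] <- 10
  v[7001] <- 2.9 * mean(v)  # spike below the 3x-mean cut
  trk2 <- coverage_track(v)
  prof <- convolve_track(trk2, build_kernel(60))
  ps <- score_filter(detect_summits(prof), prof, trk2, 60)
  expect_equal(nrow(ps$peaks), 1)
  expect_lte(abs(ps$peaks$summit - 3000), 2)

  # empty candidate list is a valid empty result, not an error
  ps0 <- score_filter(integer(0), prof, trk2, 60)
  expect_equal(nrow(ps0$peaks), 0)

  # overlapping extents merge, keeping the higher-scoring summit
  trk3 <- gaussian_track(L, summits = c(5000, 5030),
                         heights = c(120, 60), fwhms = c(80, 80),
                         background = 5)
  prof3 <- convolve_track(trk3, build_kernel(80))
  ps3 <- score_filter(detect_summits(prof3), prof3, trk3, 80)
  expect_equal(nrow(ps3$peaks), 1)
  expect_lte(abs(ps3$peaks$summit - 5000), 10)
})

test_that("normalization uses background mass and is scale invariant", {
  # worked arithmetic: total 15000, extent mass 5000 -> B = 10000,
  # score 2.5 -> intensity 250.0
  v <- numeric(1000)
  v[101:200] <- 50          # extent [100, 200) holds 5000
  v[300:999] <- 10000 / 700 # remaining mass 10000
  stopifnot(sum(v) == 15000)
  trk <- coverage_track(v)
  ps <- chapkit:::new_peak_set(
    tibble::tibble(summit = 150L, start = 100L, end = 200L,
                   raw_height = 50, score = 2.5, norm_intensity = NA_real_),
    trk, expected_width = 100, mean_coverage = mean(v), min_fold = 3
  )
  ps <- normalize_peakset(ps, trk)
  expect_equal(ps$norm_coefficient, 10000)
  expect_equal(ps$peaks$norm_intensity, 250.0)

  # empty peak list: B = total mass
  ps_empty <- chapkit:::new_peak_set(
    ps$peaks[0, ], trk, 100, mean(v), 3
  )
  expect_equal(normalize_peakset(ps_empty, trk)$norm_coefficient, 15000)

  # scale invariance of full calling at c in {0.1, 10, 137}
  trk0 <- gaussian_track(20000, summits = c(4000, 12000),
                         heights = c(90, 140), fwhms = c(60, 80),
                         background = 10)
  base <- call_peaks(trk0)
  for (cc in c(0.1, 10, 137)) {
    scaled <- coverage_track(trk0$values * cc)
    res <- call_peaks(scaled)
    expect_equal(res$peaks$summit, base$peaks$summit)
    expect_equal(res$peaks$norm_intensity, base$peaks$norm_intensity,
                 tolerance = 1e-6)
  }

  # peaks covering everything -> normalization error
  all_cov <- chapkit:::new_peak_set(
    tibble::tibble(summit = 500L, start = 0L, end = 1000L,
                   raw_height = 1, score = 1, norm_intensity = NA_real_),
    trk, 100, mean(v), 3
  )
  expect_error(normalize_peakset(all_cov, trk), "not positive")
})

test_that("call_peaks recovers well-separated planted peaks end to end", {
  g <- generate_genome(50000, 0.5, 15, seed = 21)
  truth <- plant_peaks(g$genome, g$genes, n_peaks = 5,
                       height_range = c(100, 200), width_range = c(50, 80),
                       background_mean = 10, seed = 22,
                       condition_pattern = rep("iron", 5))
  trk <- simulate_coverage(truth, "iron", noise = "none")
  ps <- call_peaks(trk)
  expect_equal(nrow(ps$peaks), 5)
  d <- vapply(ps$peaks$summit, function(s) {
    min(circ_dist_ref(s, truth$peaks$summit, 50000))
  }, numeric(1))
  expect_true(all(d <= 2))

  # blacklisting one planted summit drops exactly that peak
  bl <- tibble::tibble(start = truth$peaks$summit[1] - 5,
                       end = truth$peaks$summit[1] + 5)
  ps_bl <- call_peaks(trk, blacklist = bl)
  expect_equal(nrow(ps_bl$peaks), 4)

  # background-only track: stage-tagged "no peaks detectable" error
  flat <- simulate_coverage(
    plant_peaks(g$genome, g$genes, 0, background_mean = 10, seed = 1),
    "iron", noise = "none"
  )
  expect_error(call_peaks(flat), "no peaks detectable")
})

test_that("rotating a circular track rotates all summits with it", {
  trk <- gaussian_track(20000, summits = c(3000, 11000),
                        heights = c(100, 150), fwhms = c(60, 60),
                        background = 10)
  base <- call_peaks(trk)
  for (k in c(137, 5000)) {
    rot <- coverage_track(c(trk$values[-seq_len(k)],
                            trk$values[seq_len(k)]))
    res <- call_peaks(rot)
    expect_setequal((base$peaks$summit - k) %% 20000, res$peaks$summit)
  }
})

test_that("raising a planted peak never lowers its convolution score", {
  heights <- c(50, 80, 120, 200, 300)
  scores <- vapply(heights, function(h) {
    trk <- gaussian_track(20000, summits = c(5000, 15000),
                          heights = c(h, 100), fwhms = c(60, 60),
                          background = 10)
    ps <- call_peaks(trk, expected_width = 60)
    ps$peaks$score[which.min(abs(ps$peaks$summit - 5000))]
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("tidy and glance expose peak tables and sample summaries", {
  trk <- gaussian_track(10000, summits = 4000, heights = 100, fwhms = 60,
                        background = 10, sample = "s1", condition = "iron",
                        replicate = 1L)
  ps <- call_peaks(trk)
  td <- tidy(ps)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("summit", "score", "norm_intensity", "sample",
                    "condition") %in% names(td)))
  gl <- glance(ps)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_peaks, nrow(ps$peaks))
})
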