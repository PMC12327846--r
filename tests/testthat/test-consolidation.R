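# Build a peak_set directly from summit/intensity vectors, bypassing the
# caller, so consolidation is tested in isolation.
fake_peakset <- function(summits, intensities, sample, condition = "iron",
                         replicate = 1L, genome_length = 100000,
                         expected_width = 60) {
  trk <- coverage_track(rep(1, genome_length), sample = sample,
                        condition = condition, replicate = replicate)
  ps <- chapkit:::new_peak_set(
    tibble::tibble(
      summit = as.integer(summits),
      start = as.integer(summits - expected_width / 2),
      end = as.integer(summits + expected_width / 2),
      raw_height = intensities, score = intensities,
      norm_intensity = intensities
    ),
    trk, expected_width = expected_width, mean_coverage = 1, min_fold = 3,
    norm_coefficient = 1
  )
  ps
}

test_that("merge_replicates clusters summits and counts support", {
  s <- c(1000, 5000, 20000)
  ps1 <- fake_peakset(s, c(10, 20, 30), "a", replicate = 1L)
  ps2 <- fake_peakset(s, c(11, 19, 29), "b", replicate = 2L)
  ps3 <- fake_peakset(s, c(12, 21, 31), "c", replicate = 3L)

  tg <- merge_replicates(list(ps1, ps2, ps3))
  expect_equal(nrow(tg), 3)
  expect_true(all(tg$support == 3))
  expect_equal(tg$locus, s, tolerance = 1)

  # disjoint far-apart peaks: every target support 1
  psA <- fake_peakset(c(1000, 3000), c(5, 5), "a", replicate = 1L)
  psB <- fake_peakset(c(50000, 70000), c(5, 5), "b", replicate = 2L)
  tg2 <- merge_replicates(list(psA, psB))
  expect_equal(nrow(tg2), 4)
  expect_true(all(tg2$support == 1))
  # absent samples read intensity 0
  expect_equal(tg2$intensity_b[tg2$locus == 1000], 0)

  # permutation invariance in peakset order
  tg_perm <- merge_replicates(list(ps3, ps1, ps2))
  expect_equal(tg_perm$locus, tg$locus)
  expect_equal(tg_perm$support, tg$support)
  expect_equal(tg_perm$intensity_a, tg$intensity_a)

  # genome-length mismatch errors
  ps_bad <- fake_peakset(1000, 5, "z", genome_length = 50000)
  expect_error(merge_replicates(list(ps1, ps_bad)), "genome length")
})

test_that("replicate merging matches brute-force single linkage", {
  set.seed(31)
  L <- 100000
  for (rep in 1:20) {
    base <- sort(sample.int(L, 12) - 1L)
    pss <- lapply(1:3, function(r) {
      jitter <- sample(-15:15, length(base), replace = TRUE)
      keep <- runif(length(base)) < 0.8
      fake_peakset(((base + jitter) %% L)[keep],
                   runif(sum(keep), 5, 50),
                   sample = paste0("s", r), replicate = r)
    })
    md <- 30
    tg <- merge_replicates(pss, merge_distance = md)
    all_sum <- unlist(lapply(pss, function(p) p$peaks$summit))
    oracle <- brute_single_linkage(all_sum, md, L)
    expect_equal(nrow(tg), length(unique(oracle)))
  }

  # jittered single truth across 3 replicates: cluster count = truth count
  g <- generate_genome(100000, 0.5, 30, seed = 32)
  truth <- plant_peaks(g$genome, g$genes, n_peaks = 25,
                       height_range = c(100, 200), seed = 33,
                       condition_pattern = rep("iron", 25))
  pss <- lapply(1:3, function(r) {
    jit <- sample(-10:10, 25, replace = TRUE)
    fake_peakset((truth$peaks$summit + jit) %% 100000,
                 runif(25, 10, 100), paste0("rep", r), replicate = r)
  })
  tg <- merge_replicates(pss, merge_distance = 40)
  expect_equal(nrow(tg), 25)
})

test_that("clusters that span the circular origin merge", {
  ps1 <- fake_peakset(c(99990, 40000), c(5, 5), "a", replicate = 1L)
  ps2 <- fake_peakset(c(15, 40010), c(5, 5), "b", replicate = 2L)
  tg <- merge_replicates(list(ps1, ps2), merge_distance = 50)
  expect_equal(nrow(tg), 2)
  expect_true(all(tg$support == 2))
})

test_that("pearson_matrix has unit diagonal, symmetry, scale invariance", {
  s <- c(1000, 5000, 20000, 44000)
  int1 <- c(10, 20, 30, 5)
  ps1 <- fake_peakset(s, int1, "r1", replicate = 1L)
  ps2 <- fake_peakset(s, 2 * int1, "r2", replicate = 2L)
  r <- pearson_matrix(list(ps1, ps2))
  expect_equal(diag(r), c(r1 = 1, r2 = 1))
  expect_equal(r, t(r))
  expect_equal(r["r1", "r2"], 1.0)  # scaling one replicate leaves r = 1

  # zero-variance sample marked NA, not an error
  ps3 <- fake_peakset(s, rep(7, 4), "r3", replicate = 3L)
  ps0 <- fake_peakset(integer(0), numeric(0), "r0", replicate = 4L)
  r2 <- pearson_matrix(list(ps3, ps0, ps1))
  expect_true(is.na(r2["r0", "r1"]))
  expect_equal(r2["r0", "r0"], 1)
})

test_that("within-condition replicates correlate above between-condition", {
  g <- generate_genome(100000, 0.5, 40, seed = 41)
  # 40% condition-specific peaks
  pattern <- c(rep("iron", 6), rep("heme", 6), rep("iron+heme", 18))
  truth <- plant_peaks(g$genome, g$genes, n_peaks = 30,
                       height_range = c(100, 300), seed = 42,
                       condition_pattern = pattern)
  pss <- list()
  for (cond in c("iron", "heme")) {
    for (r in 1:3) {
      trk <- simulate_coverage(truth, cond, r, noise = "poisson",
                               seed = 100 * r + (cond == "heme"))
      pss[[paste(cond, r)]] <- call_peaks(trk)
    }
  }
  r <- pearson_matrix(pss)
  labels <- vapply(pss, function(p) p$condition, character(1))
  within <- r[labels == "iron", labels == "iron"]
  between <- r[labels == "iron", labels == "heme"]
  expect_gt(mean(within[upper.tri(within)]), mean(between))

  # entries match the textbook Pearson formula on the same vectors
  tg <- merge_replicates(pss)
  v1 <- tg[[paste0("intensity_", pss[[1]]$sample)]]
  v2 <- tg[[paste0("intensity_", pss[[2]]$sample)]]
  hand <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(r[pss[[1]]$sample, pss[[2]]$sample], hand, tolerance = 1e-12)
})

test_that("compare_regulons partitions shared and private targets", {
  a <- tibble::tibble(locus = c(100, 5000, 9000),
                      gene_id = c("g1", "g2", "g3"))
  b <- tibble::tibble(locus = c(102, 5005, 40000),
                      gene_id = c("g1", "g2", "g9"))

  # identical lists: all shared
  r_id <- compare_regulons(a, a, mode = "by_gene")
  expect_equal(nrow(r_id$shared), 3)
  expect_equal(nrow(r_id$only_a), 0)
  expect_equal(nrow(r_id$only_b), 0)

  # disjoint gene sets: nothing shared
  c_ <- tibble::tibble(locus = 1:2, gene_id = c("x1", "x2"))
  r_dis <- compare_regulons(a, c_, mode = "by_gene")
  expect_equal(nrow(r_dis$shared), 0)

  # constructed overlap of exactly k = 2 genes
  r_ab <- compare_regulons(a, b, mode = "by_gene")
  expect_equal(sort(r_ab$shared$gene_id), c("g1", "g2"))
  expect_equal(r_ab$only_a$gene_id, "g3")
  expect_equal(r_ab$only_b$gene_id, "g9")
  # partitions disjoint and exhaustive
  expect_equal(nrow(r_ab$shared) + nrow(r_ab$only_a), nrow(a))
  expect_equal(sum(r_ab$shared$gene_id %in% r_ab$only_a$gene_id), 0)

  # by_locus matching with circular distance
  r_loc <- compare_regulons(a, b, mode = "by_locus", distance = 10,
                            genome_length = 100000)
  expect_equal(r_loc$shared$locus, c(100, 5000))
  expect_equal(r_loc$only_b$locus, 40000)

  # unannotated targets in by_gene mode error
  expect_error(
    compare_regulons(dplyr::select(a, -"gene_id"), b, mode = "by_gene"),
    "annotated"
  )
})

test_that("condition partition reproduces planted 11/17/3 class sizes", {
  g <- generate_genome(100000, 0.5, 40, seed = 51)
  pattern <- c(rep("iron", 11), rep("heme", 17), rep("iron+heme", 3))
  truth <- plant_peaks(g$genome, g$genes, n_peaks = 31,
                       height_range = c(100, 300), seed = 52,
                       condition_pattern = pattern)
  pss <- list()
  for (cond in c("iron", "heme")) {
    trk <- simulate_coverage(truth, cond, 1, noise = "none")
    pss[[cond]] <- call_peaks(trk)
  }
  tg <- merge_replicates(pss)
  css <- condition_specific_sets(tg)
  counts <- setNames(css$counts$n, css$counts$condition_class)
  expect_equal(unname(counts["iron"]), 11)
  expect_equal(unname(counts["heme"]), 17)
  expect_equal(unname(counts["all"]), 3)

  # all-present targets form a single class
  allp <- tibble::tibble(locus = 1:4, present_iron = TRUE,
                         present_heme = TRUE)
  css2 <- condition_specific_sets(allp)
  expect_equal(css2$counts$condition_class, "all")

  # empty input: empty partition
  css3 <- condition_specific_sets(allp[0, ])
  expect_equal(nrow(css3$counts), 0)
})

test_that("intensity-expression correlation pairs genes and permutes", {
  tg <- tibble::tibble(
    locus = seq(1000, 20000, length.out = 20),
    gene_id = sprintf("g%02d", 1:20),
    intensity_s1 = seq(100, 5, length.out = 20)
  )
  # anti-proportional construction: |log2| inversely ranked to intensity
  expr <- tibble::tibble(
    gene_id = tg$gene_id,
    log2_ratio = -seq(0.1, 2, length.out = 20)
  )
  cc <- intensity_expression_correlation(tg, expr, method = "spearman",
                                         n_perm = 200, seed = 1)
  expect_equal(cc$estimate, -1)
  expect_lt(cc$p_value, 0.05)

  # genes missing from the expression table are dropped, count reported
  expr_miss <- expr[-1, ]
  cc2 <- intensity_expression_correlation(tg, expr_miss, n_perm = 100,
                                          seed = 1)
  expect_equal(cc2$n, 19)

  # fewer than 3 pairs errors
  expect_error(
    intensity_expression_correlation(tg[1:2, ], expr, n_perm = 10),
    "at least 3"
  )

  # tidy/glance expose the estimate
  td <- tidy(cc)
  expect_equal(td$estimate, -1)
  expect_s3_class(glance(cc), "tbl_df")
})

test_that("fold change follows the 2^-ddCt closed form", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1.0)
  expect_equal(ddct_fold_change(20, 21, 20, 20), 2.0)
  # ddCt = log2(10) -> fold change 0.1
  expect_equal(ddct_fold_change(20 + log2(10), 20, 20, 20), 0.1,
               tolerance = 1e-6)
  # identity ddct(a, b, a, b) = 1 for arbitrary a, b
  for (a in c(15.3, 22.8)) {
    for (b in c(18.1, 30)) {
      expect_equal(ddct_fold_change(a, b, a, b), 1.0)
    }
  }
  expect_error(ddct_fold_change(NA, 1, 1, 1), "finite")
})
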