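#' Merge peak sets across replicates into consolidated targets
#'
#' Summits from all samples are clustered by single linkage with a circular
#' distance threshold: two summits join a cluster when they are within
#' `merge_distance` of each other or connected through intermediates. Each
#' cluster becomes one consolidated target whose locus is the
#' intensity-weighted mean summit, whose support is the number of distinct
#' replicates contributing a significant peak, and which carries one
#' intensity column per sample (0 when that sample has no peak there).
#'
#' @param peaksets List of normalized `peak_set` objects sharing a genome.
#' @param merge_distance Linkage threshold in bp; the default `NULL` uses
#'   half the median expected width of the peak sets.
#' @return Tibble with `locus`, `support`, `n_samples`, one
#'   `intensity_<sample>` column per sample and one `present_<condition>`
#'   logical column per condition seen. The sample-to-condition map is in
#'   `attr(, "samples")`.
#' @export
merge_replicates <- function(peaksets, merge_distance = NULL) {
  stopifnot(length(peaksets) >= 1,
            all(vapply(peaksets, inherits, logical(1), "peak_set")))
  L <- unique(vapply(peaksets, function(p) p$genome_length, numeric(1)))
  if (length(L) != 1) stop("peak sets disagree on genome length")
  circular <- peaksets[[1]]$circular
  if (is.null(merge_distance)) {
    merge_distance <-
      median_lower(vapply(peaksets, function(p) p$expected_width,
                          numeric(1))) / 2
  }

  all_pk <- purrr::map_dfr(peaksets, function(p) {
    dplyr::mutate(
      p$peaks,
      sample = p$sample, condition = p$condition, replicate = p$replicate
    )
  })
  sample_info <- tibble::tibble(
    sample = vapply(peaksets, function(p) p$sample, character(1)),
    condition = vapply(peaksets, function(p) p$condition, character(1)),
    replicate = vapply(peaksets, function(p) p$replicate, integer(1))
  )
  conditions <- unique(sample_info$condition)

  empty <- tibble::tibble(
    locus = integer(), support = integer(), n_samples = integer()
  )
  for (s in sample_info$sample) empty[[paste0("intensity_", s)]] <- numeric()
  for (cc in conditions) empty[[paste0("present_", cc)]] <- logical()
  if (nrow(all_pk) == 0) {
    attr(empty, "samples") <- sample_info
    attr(empty, "merge_distance") <- merge_distance
    return(empty)
  }

  all_pk$cluster <- cluster_summits_1d(all_pk$summit, merge_distance,
                                       L, circular)

  targets <- all_pk |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(function(g, key) {
      locus <- weighted_circ_mean(g$summit, g$norm_intensity, L, circular)
      row <- tibble::tibble(
        locus = as.integer(locus),
        support = length(unique(paste(g$condition, g$replicate))),
        n_samples = length(unique(g$sample))
      )
      for (s in sample_info$sample) {
        ints <- g$norm_intensity[g$sample == s]
        row[[paste0("intensity_", s)]] <- if (length(ints)) max(ints) else 0
      }
      for (cc in conditions) {
        row[[paste0("present_", cc)]] <- any(g$condition == cc)
      }
      row
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$locus)

  attr(targets, "samples") <- sample_info
  attr(targets, "merge_distance") <- merge_distance
  targets
}

# Single-linkage clustering of 1-D (optionally circular) positions: sort,
# cut where the gap between neighbours exceeds the threshold, and on a
# circle merge the first and last cluster when the wrap gap is small.
cluster_summits_1d <- function(pos, threshold, genome_length, circular) {
  n <- length(pos)
  o <- order(pos)
  sorted <- pos[o]
  cl_sorted <- integer(n)
  cl_sorted[1] <- 1L
  if (n > 1) {
    gaps <- diff(sorted)
    cl_sorted[-1] <- 1L + cumsum(gaps > threshold)
  }
  if (circular && max(cl_sorted) > 1) {
    wrap_gap <- (sorted[1] + genome_length) - sorted[n]
    if (wrap_gap <= threshold) {
      cl_sorted[cl_sorted == max(cl_sorted)] <- 1L
    }
  }
  out <- integer(n)
  out[o] <- cl_sorted
  out
}

# Intensity-weighted mean of summit positions; on a circle, positions are
# unwrapped relative to the first summit before averaging.
weighted_circ_mean <- function(pos, w, genome_length, circular) {
  if (all(is.na(w)) || sum(w, na.rm = TRUE) == 0) w <- rep(1, length(pos))
  w[is.na(w)] <- 0
  if (circular) {
    ref <- pos[1]
    rel <- circ_diff(pos, ref, genome_length)
    m <- (ref + sum(rel * w) / sum(w)) %% genome_length
  } else {
    m <- sum(pos * w) / sum(w)
  }
  round(m)
}

#' Pearson reproducibility matrix across samples
#'
#' Union target loci are built by [merge_replicates()]; each sample becomes
#' a vector of normalized intensities over those loci (0 where the sample
#' has no peak), and the matrix holds the pairwise Pearson correlations.
#' Replicates of the same condition should correlate strongly; samples from
#' different conditions correlate less when binding is condition-specific.
#'
#' @param peaksets List of >= 2 normalized `peak_set` objects.
#' @param merge_distance Passed to [merge_replicates()].
#' @return Symmetric correlation matrix with unit diagonal, dimnames =
#'   sample labels. A sample with a zero-variance intensity vector gets
#'   `NA` in its row and column.
#' @export
pearson_matrix <- function(peaksets, merge_distance = NULL) {
  stopifnot(length(peaksets) >= 2)
  targets <- merge_replicates(peaksets, merge_distance)
  samples <- attr(targets, "samples")$sample
  mat <- as.matrix(targets[paste0("intensity_", samples)])
  colnames(mat) <- samples
  r <- suppressWarnings(stats::cor(mat, method = "pearson"))
  diag(r) <- 1
  r
}

#' Compare the target sets of two regulators
#'
#' Splits two consolidated target tables into shared targets and targets
#' private to either regulator, matching either by assigned gene
#' (`by_gene`) or by summit proximity (`by_locus`, circular distance at
#' most `distance`).
#'
#' @param targets_a,targets_b Consolidated target tibbles; `by_gene` needs
#'   a `gene_id` column (see [annotate_targets()]).
#' @param mode `"by_gene"` or `"by_locus"`.
#' @param distance Locus matching distance, bp.
#' @param genome_length,circular Genome geometry for `by_locus`.
#' @return List `shared`, `only_a`, `only_b`: subsets of the inputs
#'   (for `shared`, rows of `targets_a` with the matched `b` locus/gene).
#' @export
compare_regulons <- function(targets_a, targets_b,
                             mode = c("by_gene", "by_locus"),
                             distance = 100, genome_length = NULL,
                             circular = TRUE) {
  mode <- match.arg(mode)
  a <- tibble::as_tibble(targets_a)
  b <- tibble::as_tibble(targets_b)
  if (mode == "by_gene") {
    if (!"gene_id" %in% names(a) || !"gene_id" %in% names(b) ||
        anyNA(a$gene_id) || anyNA(b$gene_id)) {
      stop("by_gene comparison requires annotated targets (gene_id)")
    }
    shared_genes <- intersect(a$gene_id, b$gene_id)
    list(
      shared = a[a$gene_id %in% shared_genes, , drop = FALSE],
      only_a = a[!a$gene_id %in% shared_genes, , drop = FALSE],
      only_b = b[!b$gene_id %in% shared_genes, , drop = FALSE]
    )
  } else {
    if (is.null(genome_length)) stop("by_locus needs genome_length")
    near <- function(x, ys) {
      any(circ_dist(x, ys, genome_length, circular) <= distance)
    }
    a_shared <- vapply(a$locus, near, logical(1), ys = b$locus)
    b_shared <- vapply(b$locus, near, logical(1), ys = a$locus)
    list(
      shared = a[a_shared, , drop = FALSE],
      only_a = a[!a_shared, , drop = FALSE],
      only_b = b[!b_shared, , drop = FALSE]
    )
  }
}

#' Partition targets by condition-presence pattern
#'
#' Groups consolidated targets by the exact set of conditions they were
#' detected in (e.g. iron-only, heme-only, both) and counts each class.
#'
#' @param targets Consolidated target tibble with `present_<condition>`
#'   columns.
#' @param conditions Condition labels; default: inferred from the columns.
#' @return List with `targets` (input plus a `condition_class` column) and
#'   `counts` (tibble `condition_class`, `n`).
#' @export
condition_specific_sets <- function(targets, conditions = NULL) {
  targets <- tibble::as_tibble(targets)
  if (is.null(conditions)) {
    conditions <- sub("^present_", "",
                      grep("^present_", names(targets), value = TRUE))
  }
  cols <- paste0("present_", conditions)
  stopifnot(all(cols %in% names(targets)))
  if (nrow(targets) == 0) {
    return(list(
      targets = dplyr::mutate(targets, condition_class = character(0)),
      counts = tibble::tibble(condition_class = character(0), n = integer(0))
    ))
  }
  pres <- as.matrix(targets[cols])
  cls <- apply(pres, 1, function(p) {
    on <- conditions[as.logical(p)]
    if (length(on) == length(conditions)) "all"
    else paste(on, collapse = "+")
  })
  targets$condition_class <- cls
  list(
    targets = targets,
    counts = dplyr::count(targets, .data$condition_class,
                          name = "n", sort = TRUE)
  )
}

#' Correlate binding intensity with differential gene expression
#'
#' Pairs each annotated target's maximal per-sample intensity with the
#' magnitude of the gene's log2 expression ratio and reports the chosen
#' correlation coefficient with a permutation p-value (labels permuted
#' `n_perm` times under the seed). Magnitudes are used because binding may
#' activate or repress; the question is whether stronger binding means
#' stronger regulation.
#'
#' @param targets Annotated consolidated targets (needs `gene_id` and
#'   `intensity_*` columns).
#' @param expression Tibble with `gene_id`, `log2_ratio` (unique genes).
#' @param method `"spearman"` or `"pearson"`.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return A `chap_correlation` object; see [tidy.chap_correlation()].
#' @export
intensity_expression_correlation <- function(targets, expression,
                                             method = c("spearman", "pearson"),
                                             n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  targets <- tibble::as_tibble(targets)
  if (!"gene_id" %in% names(targets)) {
    stop("targets must be annotated (gene_id)")
  }
  if (anyDuplicated(expression$gene_id)) {
    stop("expression table has duplicate gene ids")
  }
  int_cols <- grep("^intensity_", names(targets), value = TRUE)
  paired <- targets |>
    dplyr::mutate(
      intensity = do.call(pmax, c(as.list(targets[int_cols]), na.rm = TRUE))
    ) |>
    dplyr::inner_join(expression, by = "gene_id") |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      intensity = .data$intensity,
      abs_log2_ratio = abs(.data$log2_ratio)
    )
  if (nrow(paired) < 3) {
    stop("need at least 3 targets with matching expression entries")
  }
  perm_correlation(paired$intensity, paired$abs_log2_ratio, method,
                   n_perm, seed,
                   label = "intensity_vs_expression", pairs = paired)
}

# Shared permutation-correlation engine (also used for the distance trend).
perm_correlation <- function(x, y, method, n_perm, seed, label, pairs) {
  r_obs <- suppressWarnings(stats::cor(x, y, method = method))
  p <- NA_real_
  if (!is.na(r_obs)) {
    withr_seed(seed)
    if (method == "spearman") {
      x <- rank(x); y <- rank(y)
    }
    perm <- vapply(seq_len(n_perm), function(i) {
      stats::cor(x, sample(y))
    }, numeric(1))
    # add-one correction keeps the permutation p-value in (0, 1]
    p <- (1 + sum(abs(perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  }
  structure(
    list(
      label = label, method = method, estimate = r_obs, p_value = p,
      n = length(x), n_perm = n_perm, pairs = pairs
    ),
    class = "chap_correlation"
  )
}

#' @export
print.chap_correlation <- function(x, ...) {
  cat(sprintf(
    "<chap_correlation> %s: %s r = %s, permutation p = %s (n = %d, %d perms)\n",
    x$label, x$method,
    if (is.na(x$estimate)) "undefined (zero variance)"
    else sprintf("%.3f", x$estimate),
    if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 3),
    x$n, x$n_perm
  ))
  invisible(x)
}

#' Tidy a correlation result
#' @param x A `chap_correlation`.
#' @param ... Unused.
#' @return One-row tibble: estimate, p_value, method, n.
#' @method tidy chap_correlation
#' @export
tidy.chap_correlation <- function(x, ...) {
  tibble::tibble(
    label = x$label, method = x$method, estimate = x$estimate,
    p_value = x$p_value, n = x$n, n_perm = x$n_perm
  )
}

#' @rdname tidy.chap_correlation
#' @method glance chap_correlation
#' @export
glance.chap_correlation <- function(x, ...) tidy.chap_correlation(x, ...)

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' Computes `2^-((ct_target_test - ct_ref_test) -
#' (ct_target_ctrl - ct_ref_ctrl))`: the expression of a target gene
#' relative to a reference (housekeeping) gene, in a test condition
#' relative to a control condition.
#'
#' @param ct_target_test,ct_ref_test Ct values in the test condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control condition.
#' @return Fold change (vectorized over inputs).
#' @export
#' @examples
#' ddct_fold_change(20, 21, 20, 20)  # ddCt = -1 -> fold change 2
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(
    is.finite(ct_target_test), is.finite(ct_ref_test),
    is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl)
  )
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Write consolidated targets as TSV
#' @param targets Consolidated target tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_targets <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
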