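#' Read gene models from GFF3
#'
#' Keeps `gene` features, converts 1-based inclusive GFF coordinates to the
#' internal 0-based half-open convention, and derives the TSS from the
#' strand (start for `+`, end - 1 for `-`).
#'
#' @param path GFF3 file.
#' @return Gene tibble (`gene_id`, `start`, `end`, `strand`, `tss`), sorted
#'   by start.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  tibble::tibble(
    gene_id = ids,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tss = as.integer(ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                            GenomicRanges::start(gr) - 1L,
                            GenomicRanges::end(gr) - 1L))
  ) |>
    dplyr::arrange(.data$start)
}

# Oriented, signed distance from a gene's TSS to a summit: positive
# downstream of the TSS (into the gene), negative upstream of it.
oriented_tss_distance <- function(summit, gene, genome_length, circular) {
  raw <- circ_diff(summit, gene$tss, genome_length, circular)
  if (gene$strand == "+") raw else -raw
}

#' Assign a single summit to a gene and location class
#'
#' Assignment rule: a summit inside exactly one gene body is intragenic for
#' that gene, with a non-negative oriented distance from its TSS. Otherwise
#' the summit is assigned to the gene whose TSS lies downstream of it (in
#' that gene's orientation) within `upstream_window` bp — class upstream,
#' negative distance; with several such genes the nearest TSS wins, then
#' the lexicographically smallest gene id. A summit matching neither rule
#' is assigned to the nearest TSS overall and classified by the sign of
#' the oriented distance.
#'
#' @param summit 0-based summit position.
#' @param genes Gene tibble (sorted).
#' @param upstream_window Promoter window size, bp.
#' @param genome_length Genome length, bp.
#' @param circular Circular genome?
#' @return One-row tibble: `gene_id`, `distance_to_tss`, `location_class`.
#' @export
assign_target <- function(summit, genes, upstream_window = 500,
                          genome_length, circular = TRUE) {
  if (nrow(genes) == 0) stop("gene list is empty")
  dists <- vapply(seq_len(nrow(genes)), function(i) {
    oriented_tss_distance(summit, genes[i, ], genome_length, circular)
  }, numeric(1))

  inside <- genes$start <= summit & summit < genes$end
  if (sum(inside) == 1) {
    i <- which(inside)
    return(tibble::tibble(
      gene_id = genes$gene_id[i],
      distance_to_tss = dists[i],
      location_class = "intragenic"
    ))
  }

  upstream <- dists < 0 & dists >= -upstream_window
  if (any(upstream)) {
    cand <- which(upstream)
    cand <- cand[order(abs(dists[cand]), genes$gene_id[cand])]
    i <- cand[1]
    return(tibble::tibble(
      gene_id = genes$gene_id[i],
      distance_to_tss = dists[i],
      location_class = "upstream"
    ))
  }

  ord <- order(abs(dists), genes$gene_id)
  i <- ord[1]
  tibble::tibble(
    gene_id = genes$gene_id[i],
    distance_to_tss = dists[i],
    location_class = if (dists[i] < 0) "upstream" else "intragenic"
  )
}

#' Annotate consolidated targets with genes and TSS distances
#'
#' Applies [assign_target()] to every target locus and appends `gene_id`,
#' `distance_to_tss` and `location_class` columns.
#'
#' @param targets Consolidated target tibble (needs a `locus` column).
#' @param genes Gene tibble.
#' @param upstream_window Promoter window size, bp.
#' @param genome_length Genome length, bp.
#' @param circular Circular genome?
#' @return The input tibble with annotation columns appended.
#' @export
annotate_targets <- function(targets, genes, upstream_window = 500,
                             genome_length, circular = TRUE) {
  targets <- tibble::as_tibble(targets)
  ann <- purrr::map_dfr(targets$locus, assign_target, genes = genes,
                        upstream_window = upstream_window,
                        genome_length = genome_length, circular = circular)
  dplyr::bind_cols(
    targets[setdiff(names(targets), names(ann))],
    ann
  )
}

#' Count upstream vs intragenic targets
#'
#' @param targets Annotated target tibble (needs `location_class`).
#' @return Named integer vector `c(upstream = ..., intragenic = ...)`.
#' @export
classify_counts <- function(targets) {
  cls <- targets$location_class
  c(
    upstream = sum(cls == "upstream"),
    intragenic = sum(cls == "intragenic")
  )
}

#' TSS-distance versus peak-intensity trend
#'
#' Spearman correlation (with permutation p-value) between the absolute
#' TSS distance of each annotated target and its maximal normalized
#' intensity. A negative coefficient means peaks closer to the TSS are
#' stronger.
#'
#' @param targets Annotated target tibble with `distance_to_tss` and
#'   `intensity_*` columns (or a single `intensity` column).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `chap_correlation`; `estimate` is `NA` (not an error) when one
#'   variable has zero variance.
#' @export
distance_intensity_trend <- function(targets, n_perm = 10000, seed = 1L) {
  targets <- tibble::as_tibble(targets)
  if (nrow(targets) < 3) stop("need at least 3 annotated targets")
  intensity <- if ("intensity" %in% names(targets)) {
    targets$intensity
  } else {
    int_cols <- grep("^intensity_", names(targets), value = TRUE)
    if (length(int_cols) == 0) stop("no intensity columns found")
    do.call(pmax, c(as.list(targets[int_cols]), na.rm = TRUE))
  }
  pairs <- tibble::tibble(
    abs_distance = abs(targets$distance_to_tss),
    intensity = intensity
  )
  perm_correlation(pairs$abs_distance, pairs$intensity, "spearman",
                   n_perm, seed, label = "distance_vs_intensity",
                   pairs = pairs)
}
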