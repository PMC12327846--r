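#' Run the full ChAP-Seq analysis pipeline
#'
#' Orchestrates the end-to-end analysis from a configuration: read or
#' simulate per-sample coverage, call peaks per sample, consolidate
#' replicates per regulator, compute the replicate Pearson matrix, annotate
#' targets against the gene models, partition targets by condition,
#' optionally scan a motif and correlate intensities with differential
#' expression, and write every result plus a machine-readable run manifest
#' (parameters, seed, input checksums) into `outdir`. Re-running the same
#' configuration reproduces identical outputs.
#'
#' @param config Either a YAML file path or a list with elements:
#'   `genome` (FASTA path), `annotation` (GFF3 path), `samples` (data frame
#'   or TSV path with columns `sample`, `regulator`, `condition`,
#'   `replicate`, `track` = bedGraph path), and optional `parameters`
#'   (`min_fold`, `sigma_ratio`, `merge_distance`, `upstream_window`,
#'   `p_threshold`, `circular`), `motif` (consensus string or MEME file),
#'   `expression` (TSV with `gene_id`, `log2_ratio`), `seed`.
#' @param outdir Output directory.
#' @param keep_going Continue past per-sample failures instead of halting?
#' @return Invisibly, a list with `peaksets`, `targets` (per regulator),
#'   `pearson`, `condition_sets`, `scan_hits`, `correlations`, `manifest`.
#' @export
run_chap_pipeline <- function(config, outdir, keep_going = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  par <- config$parameters %||% list()
  p_min_fold <- par$min_fold %||% 3
  p_sigma_ratio <- par$sigma_ratio %||% (1 / 8)
  p_merge <- par$merge_distance %||% NULL
  p_upwin <- par$upstream_window %||% 500
  p_pthr <- par$p_threshold %||% 1e-5
  p_circ <- par$circular %||% TRUE
  seed <- config$seed %||% 1L

  genome <- read_genome_fasta(config$genome, circular = p_circ)
  genes <- read_genes_gff3(config$annotation)
  L <- nchar(genome$sequence)

  samples <- config$samples
  if (is.character(samples) && length(samples) == 1) {
    samples <- utils::read.delim(samples, stringsAsFactors = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  need <- c("sample", "regulator", "condition", "replicate", "track")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  missing <- !file.exists(samples$track)
  if (any(missing)) {
    stop("sample sheet row(s) reference missing track files: ",
         paste(samples$sample[missing], collapse = ", "))
  }

  peaksets <- list()
  for (i in seq_len(nrow(samples))) {
    row <- samples[i, ]
    res <- tryCatch({
      trk <- read_track(row$track, genome_length = L, circular = p_circ,
                        sample = row$sample, condition = row$condition,
                        replicate = as.integer(row$replicate))
      ps <- call_peaks(trk, min_fold = p_min_fold,
                       sigma_ratio = p_sigma_ratio)
      write_peaks(ps, file.path(outdir,
                                sprintf("peaks_%s.tsv", row$sample)))
      ps
    }, error = function(e) {
      msg <- sprintf("sample '%s': %s", row$sample, conditionMessage(e))
      if (keep_going) {
        warning(msg, call. = FALSE)
        NULL
      } else {
        stop(msg, call. = FALSE)
      }
    })
    if (!is.null(res)) peaksets[[row$sample]] <- res
  }

  results <- list(peaksets = peaksets, targets = list(),
                  pearson = list(), condition_sets = list(),
                  scan_hits = NULL, correlations = list())

  for (reg in unique(samples$regulator)) {
    reg_samples <- samples$sample[samples$regulator == reg]
    ps <- peaksets[intersect(reg_samples, names(peaksets))]
    if (length(ps) == 0) next
    targets <- merge_replicates(ps, merge_distance = p_merge)
    targets <- annotate_targets(targets, genes, upstream_window = p_upwin,
                                genome_length = L, circular = p_circ)
    css <- condition_specific_sets(targets)
    targets <- css$targets
    write_targets(targets, file.path(outdir,
                                     sprintf("targets_%s.tsv", reg)))
    utils::write.table(
      css$counts,
      file.path(outdir, sprintf("condition_classes_%s.tsv", reg)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    results$targets[[reg]] <- targets
    results$condition_sets[[reg]] <- css$counts
    if (length(ps) >= 2) {
      r <- pearson_matrix(ps, merge_distance = p_merge)
      utils::write.table(
        r, file.path(outdir, sprintf("pearson_%s.tsv", reg)),
        sep = "\t", quote = FALSE
      )
      results$pearson[[reg]] <- r
    }
  }

  if (!is.null(config$motif)) {
    pwm <- if (file.exists(config$motif)) {
      read_meme(config$motif)
    } else {
      consensus_to_pwm(config$motif)
    }
    hits <- scan_pwm(genome, pwm, p_threshold = p_pthr)
    utils::write.table(hits, file.path(outdir, "motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$scan_hits <- hits
  }

  if (!is.null(config$expression)) {
    expr <- config$expression
    if (is.character(expr) && length(expr) == 1) {
      expr <- utils::read.delim(expr, stringsAsFactors = FALSE)
    }
    expr <- tibble::as_tibble(expr)
    for (reg in names(results$targets)) {
      tg <- results$targets[[reg]]
      if (nrow(tg) >= 3 && sum(tg$gene_id %in% expr$gene_id) >= 3) {
        cc <- intensity_expression_correlation(tg, expr, seed = seed)
        results$correlations[[reg]] <- cc
        utils::write.table(
          tidy(cc),
          file.path(outdir, sprintf("expression_correlation_%s.tsv", reg)),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("chapkit")),
    seed = seed,
    parameters = list(
      min_fold = p_min_fold, sigma_ratio = p_sigma_ratio,
      merge_distance = p_merge, upstream_window = p_upwin,
      p_threshold = p_pthr, circular = p_circ
    ),
    inputs = c(
      stats::setNames(
        vapply(c(config$genome, config$annotation), file_checksum,
               character(1)),
        c("genome", "annotation")
      ),
      stats::setNames(vapply(samples$track, file_checksum, character(1)),
                      samples$sample)
    ),
    samples = samples,
    n_peaks = vapply(peaksets, function(p) nrow(p$peaks), integer(1)),
    n_targets = vapply(results$targets, nrow, integer(1))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# Plain-R content checksum (sum of byte values mixed with position) so the
# manifest records input identity without external digest tools.
file_checksum <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  idx <- seq_along(bytes)
  sprintf("%015.0f", sum(bytes * ((idx %% 9973) + 1)) %% 1e15)
}

#' Generate the demo fixture and run the pipeline end to end
#'
#' Builds a seeded synthetic study — a 100 kb circular genome with 40
#' genes, 30 planted binding sites split across iron and heme conditions,
#' three Poisson-noise replicates per condition and a planted binding
#' motif — writes it to disk, and runs [run_chap_pipeline()] on it.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param n_peaks Number of planted sites.
#' @param consensus Motif consensus planted and scanned.
#' @return The pipeline result list, plus `truth` (the planted ground
#'   truth).
#' @export
chap_demo <- function(outdir, seed = 1L, n_peaks = 30,
                      consensus = "TAGGTTAGSCTAACCTAA") {
  g <- generate_genome(100000, 0.54, n_genes = 40, seed = seed)
  truth <- plant_peaks(g$genome, g$genes, n_peaks = n_peaks,
                       height_range = c(100, 300), seed = seed + 1L,
                       motif_fraction = 0.5)
  truth$genome <- plant_motif(truth$genome, truth, consensus,
                              seed = seed + 2L)
  paths <- write_truth_bundle(truth, outdir, replicates = 3L,
                              noise = "poisson", seed = seed)
  samples <- expand.grid(condition = truth$conditions, replicate = 1:3,
                         stringsAsFactors = FALSE)
  samples <- tibble::tibble(
    sample = paste(samples$condition, samples$replicate, sep = "_rep"),
    regulator = "demoTF",
    condition = samples$condition,
    replicate = samples$replicate,
    track = file.path(outdir, paste0(samples$condition, "_rep",
                                     samples$replicate, ".bedgraph"))
  )
  expr <- simulate_expression(truth, "anti_proportional", noise_sd = 0.1,
                              seed = seed + 3L)
  expr_path <- file.path(outdir, "expression.tsv")
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config <- list(
    genome = paths$fasta, annotation = paths$gff3, samples = samples,
    motif = consensus, expression = expr_path, seed = seed,
    parameters = list(circular = TRUE)
  )
  out <- run_chap_pipeline(config, file.path(outdir, "results"))
  out$truth <- truth
  invisible(out)
}
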